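#' Hypsographic (depth-area) model of a lake basin
#'
#' Builds a validated hypsography object from a depth -> planar area table.
#' Depths must start at 0 (the lake surface, area `A0`) and increase
#' strictly; areas must be non-increasing with depth.  Between table rows
#' the area is interpolated linearly and volumes are trapezoid integrals,
#' the standard limnological convention.  Sediment ("benthic") area at depth
#' is approximated by planar-area differences, without slope correction.
#'
#' @param depth_m Depths (m), strictly increasing from 0 to `z_max`.
#' @param area_m2 Planar areas (m^2), non-increasing, `area_m2[1] > 0`.
#' @return An object of class `hypsography` with elements `depth_m`,
#'   `area_m2`, `a0`, `z_max`, `volume_m3`, `z_avg`.
#' @examples
#' cone <- hypsography(c(0, 10), c(1000, 0))
#' cone$volume_m3  # 5000
#' @export
hypsography <- function(depth_m, area_m2) {
  stopifnot(is.numeric(depth_m), is.numeric(area_m2),
            length(depth_m) == length(area_m2))
  if (length(depth_m) < 2L) stop("hypsography needs at least 2 rows")
  if (any(!is.finite(depth_m)) || any(!is.finite(area_m2))) {
    stop("hypsography table must be finite")
  }
  if (depth_m[1L] != 0) stop("hypsography must start at depth 0")
  if (any(diff(depth_m) <= 0)) stop("depths must be strictly increasing")
  if (area_m2[1L] <= 0) stop("surface area A0 must be positive")
  if (any(area_m2 < 0)) stop("areas must be non-negative")
  if (any(diff(area_m2) > 0)) stop("areas must be non-increasing with depth")
  n <- length(depth_m)
  vol <- sum(diff(depth_m) * (area_m2[-n] + area_m2[-1L]) / 2)
  structure(list(depth_m = depth_m, area_m2 = area_m2,
                 a0 = area_m2[1L], z_max = depth_m[n],
                 volume_m3 = vol, z_avg = vol / area_m2[1L]),
            class = "hypsography")
}

#' @export
print.hypsography <- function(x, ...) {
  cat(sprintf(
    "hypsography: A0 %.0f m2, z_max %.2f m, volume %.0f m3, z_avg %.2f m\n",
    x$a0, x$z_max, x$volume_m3, x$z_avg))
  invisible(x)
}

#' Planar area at depth (linear interpolation of the hypsographic table)
#'
#' @param hypso A [hypsography()] object.
#' @param z Depth (m), within `[0, z_max]`; vectorized.
#' @return Interpolated planar area (m^2).
#' @export
area_at <- function(hypso, z) {
  stopifnot(inherits(hypso, "hypsography"))
  if (any(z < 0) || any(z > hypso$z_max)) {
    stop("depth outside [0, z_max] = [0, ", hypso$z_max, "]")
  }
  stats::approx(hypso$depth_m, hypso$area_m2, xout = z, rule = 1)$y
}

#' Split a lake into depth strata
#'
#' For each stratum `[z_top, z_bot)` returns the planar sediment area
#' (`A(z_top) - A(z_bot)`) and the trapezoid water volume.  Any residual
#' planar area at `z_max` (a flat lake bottom) is assigned to the deepest
#' stratum.  Breakpoints must span the full basin (start at 0, end at
#' `z_max`), so strata areas sum to `A0` and volumes to the lake volume
#' exactly.
#'
#' @param hypso A [hypsography()] object.
#' @param breakpoints Sorted depths from 0 to `z_max`.
#' @return `data.frame` with `z_top`, `z_bot`, `sediment_area_m2`,
#'   `volume_m3`.
#' @export
hypso_strata <- function(hypso, breakpoints) {
  stopifnot(inherits(hypso, "hypsography"), is.numeric(breakpoints))
  if (length(breakpoints) < 2L) stop("need at least 2 breakpoints")
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly sorted")
  if (breakpoints[1L] != 0 || breakpoints[length(breakpoints)] != hypso$z_max) {
    stop("breakpoints must start at 0 and end at z_max")
  }
  # integrate on the union of table depths and breakpoints so trapezoid
  # volumes are exact for the piecewise-linear area function
  z_top <- breakpoints[-length(breakpoints)]
  z_bot <- breakpoints[-1L]
  vol <- function(a, b) {
    zz <- sort(unique(c(a, b, hypso$depth_m[hypso$depth_m > a &
                                              hypso$depth_m < b])))
    aa <- area_at(hypso, zz)
    sum(diff(zz) * (aa[-length(aa)] + aa[-1L]) / 2)
  }
  sed <- area_at(hypso, z_top) - area_at(hypso, z_bot)
  sed[length(sed)] <- sed[length(sed)] + area_at(hypso, hypso$z_max)
  data.frame(z_top = z_top, z_bot = z_bot, sediment_area_m2 = sed,
             volume_m3 = mapply(vol, z_top, z_bot))
}

#' @export
summary.hypsography <- function(object, ...) {
  c(a0 = object$a0, volume_m3 = object$volume_m3,
    z_avg = object$z_avg, z_max = object$z_max)
}

#' Littoral benthic habitat fraction
#'
#' Percentage of the lake's (planar) sediment area receiving more than 1 %
#' of surface light, i.e. shallower than the euphotic depth `ln(100)/kd`.
#' Equals 100 when the euphotic depth reaches the maximum depth.
#'
#' @param hypso A [hypsography()] object.
#' @param kd Light attenuation coefficient (m^-1), positive.
#' @return Percentage in `[0, 100]`.
#' @examples
#' littoral_fraction(hypsography(c(0, 10), c(1000, 0)), kd = 4.1)
#' @export
littoral_fraction <- function(hypso, kd) {
  stopifnot(inherits(hypso, "hypsography"))
  if (kd <= 0) stop("kd must be positive")
  z1 <- min(euphotic_depth(kd), hypso$z_max)
  100 * (hypso$a0 - area_at(hypso, z1)) / hypso$a0
}
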