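#' Build an incubation record
#'
#' Container for one enclosure's time series.  Concentrations are mg C L^-1
#' for the DIC-core method and mg O2 L^-1 for domes.  `volume_L` is the
#' enclosed water volume and `footprint_m2` the sediment area sealed off by
#' a benthic enclosure (NA for pelagic bottles).
#'
#' @param method One of `"dic_core"`, `"dome"`, `"c14_bottle"`.
#' @param depth_m Deployment depth (m).
#' @param times_h Sampling times (h), strictly increasing.
#' @param conc Concentrations, same length as `times_h`.
#' @param light Logical; transparent (`TRUE`) or darkened enclosure.
#' @param volume_L Enclosed water volume (L), positive.
#' @param footprint_m2 Sediment footprint (m^2); required positive for
#'   benthic methods.
#' @param dark_start,dark_end Start/end (h) of the dark window within a
#'   24-h dome deployment.
#' @return A list of class `incubation_record`.
#' @export
incubation_record <- function(method, depth_m, times_h, conc, light = TRUE,
                              volume_L, footprint_m2 = NA_real_,
                              dark_start = NA_real_, dark_end = NA_real_) {
  method <- match.arg(method, c("dic_core", "dome", "c14_bottle"))
  stopifnot(length(times_h) == length(conc))
  if (length(times_h) >= 2L && any(diff(times_h) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (volume_L <= 0) stop("volume_L must be positive")
  if (method %in% c("dic_core", "dome") &&
      (!is.finite(footprint_m2) || footprint_m2 <= 0)) {
    stop("benthic enclosures need a positive sediment footprint")
  }
  structure(list(method = method, depth_m = depth_m, times_h = times_h,
                 conc = conc, light = isTRUE(light), volume_L = volume_L,
                 footprint_m2 = footprint_m2, dark_start = dark_start,
                 dark_end = dark_end),
            class = "incubation_record")
}

#' Concentration change rate of an incubation series
#'
#' OLS slope of concentration against time, scaled to a daily rate.  With
#' exactly two points this reduces to the endpoint difference divided by the
#' elapsed time.
#'
#' @param times_h Times (h), strictly increasing, >= 2 points.
#' @param conc Concentrations (mg L^-1).
#' @return Rate in mg L^-1 d^-1 (positive = increase).
#' @export
linear_rate <- function(times_h, conc) {
  stopifnot(length(times_h) == length(conc))
  if (length(times_h) < 2L) stop("need at least 2 time points")
  if (any(duplicated(times_h)) || any(diff(times_h) <= 0)) {
    stop("times must be strictly increasing without duplicates")
  }
  unname(stats::coef(stats::lm(conc ~ times_h))[2L]) * 24
}

#' Benthic GPP at depth from paired light/dark DIC core incubations
#'
#' Respiration releases DIC in the dark core; photosynthesis consumes DIC in
#' the transparent core.  With volumetric rates `r = linear_rate(dark)` and
#' `nl = linear_rate(light)` (mg C L^-1 d^-1), areal respiration is
#' `R = r * V / A` and GPP is `R - nl * V / A` (mg C m^-2 d^-1).
#'
#' @param light,dark [incubation_record()]s from the same depth and geometry.
#' @return Areal GPP (mg C m^-2 d^-1).
#' @examples
#' d <- incubation_record("dic_core", 1, c(0, 24), c(10, 10.5), FALSE, 1, 0.005)
#' l <- incubation_record("dic_core", 1, c(0, 24), c(10, 9.8), TRUE, 1, 0.005)
#' benthic_gpp_dic(l, d)  # 140
#' @export
benthic_gpp_dic <- function(light, dark) {
  stopifnot(inherits(light, "incubation_record"),
            inherits(dark, "incubation_record"))
  if (light$method != "dic_core" || dark$method != "dic_core") {
    stop("both records must use the dic_core method")
  }
  if (!isTRUE(all.equal(light$depth_m, dark$depth_m))) {
    stop("light and dark cores must come from the same depth")
  }
  if (!isTRUE(all.equal(light$volume_L, dark$volume_L)) ||
      !isTRUE(all.equal(light$footprint_m2, dark$footprint_m2))) {
    stop("light and dark cores must share geometry")
  }
  va_l <- light$volume_L / light$footprint_m2
  va_d <- dark$volume_L / dark$footprint_m2
  r_areal <- linear_rate(dark$times_h, dark$conc) * va_d
  net_light <- linear_rate(light$times_h, light$conc) * va_l
  r_areal - net_light
}

#' Benthic GPP at depth from a 24-h transparent dome O2 series
#'
#' GPP is reconstructed as NEP + R: respiration is the O2 decline rate over
#' the dark window, assumed constant and extrapolated to 24 h; NEP is the
#' net O2 change over the full deployment.  Both are converted to areal
#' rates via the dome volume-to-footprint ratio, and O2 is converted to
#' carbon with `(12/32) / pq` where `pq` is the photosynthetic quotient.
#' An O2 *rise* in the dark (negative respiration) is clamped to zero with
#' a warning, as are negative GPP estimates.
#'
#' @param record A `"dome"` [incubation_record()] with `dark_start` /
#'   `dark_end` set (hours within the series).
#' @param pq Photosynthetic quotient (mol O2 : mol C), default 1.
#' @return Areal GPP (mg C m^-2 d^-1).
#' @export
benthic_gpp_dome <- function(record, pq = 1) {
  stopifnot(inherits(record, "incubation_record"))
  if (record$method != "dome") stop("record must use the dome method")
  if (!is.finite(record$dark_start) || !is.finite(record$dark_end) ||
      record$dark_end <= record$dark_start) {
    stop("dome record needs a dark window (dark_start < dark_end)")
  }
  if (pq <= 0) stop("pq must be positive")
  va <- record$volume_L / record$footprint_m2
  in_dark <- record$times_h >= record$dark_start &
    record$times_h <= record$dark_end
  if (sum(in_dark) < 2L) stop("fewer than 2 O2 readings in the dark window")
  r_vol <- -linear_rate(record$times_h[in_dark], record$conc[in_dark])
  if (r_vol < 0) {
    warning("O2 rising during dark window; respiration clamped to 0")
    r_vol <- 0
  }
  n <- length(record$conc)
  span_d <- (record$times_h[n] - record$times_h[1L]) / 24
  nep_vol <- (record$conc[n] - record$conc[1L]) / span_d
  gpp_o2 <- (nep_vol + r_vol) * va
  gpp_c <- gpp_o2 * (12 / 32) / pq
  if (gpp_c < 0) {
    warning("negative dome GPP estimate floored at 0")
    gpp_c <- 0
  }
  gpp_c
}

#' Daily volumetric pelagic GPP from 14C light/dark bottle uptake
#'
#' Dark-corrected carbon uptake over a short midday incubation, scaled to a
#' daily rate by the incident-PAR ratio (see [daily_scaling_factor()]).
#' Negative dark-corrected uptake is floored at zero with a warning.
#'
#' @param light_uptake,dark_uptake Carbon uptake over the incubation
#'   (mg C m^-3), non-negative.
#' @param incubation_par,daily_par PAR sums during the incubation window and
#'   over 24 h, positive.
#' @return Volumetric GPP (mg C m^-3 d^-1).
#' @export
pelagic_gpp_daily <- function(light_uptake, dark_uptake,
                              incubation_par, daily_par) {
  if (light_uptake < 0 || dark_uptake < 0) stop("uptakes must be non-negative")
  net <- light_uptake - dark_uptake
  if (net < 0) {
    warning("dark uptake exceeds light uptake; GPP floored at 0")
    net <- 0
  }
  net * daily_scaling_factor(daily_par, incubation_par)
}

#' Discrete depth-rate profile
#'
#' @param habitat `"benthic"` (areal, mg C m^-2 d^-1) or `"pelagic"`
#'   (volumetric, mg C m^-3 d^-1).
#' @param depth_m Measurement depths (m), unique; sorted internally.
#' @param rate Rates at those depths.
#' @return A `depth_rates` object.
#' @export
depth_rates <- function(habitat, depth_m, rate) {
  habitat <- match.arg(habitat, c("benthic", "pelagic"))
  stopifnot(length(depth_m) == length(rate))
  if (length(depth_m) == 0L) stop("empty rate profile")
  if (any(duplicated(depth_m))) stop("depths must be unique")
  o <- order(depth_m)
  structure(list(habitat = habitat, depth_m = depth_m[o], rate = rate[o]),
            class = "depth_rates")
}

# rate-vs-depth function: linear between measured depths, constant beyond
.rate_fun <- function(rates) {
  if (length(rates$depth_m) == 1L) {
    stop("need rates at >= 2 depths to interpolate over the basin")
  }
  function(z) stats::approx(rates$depth_m, rates$rate, xout = z, rule = 2)$y
}

#' Upscale benthic areal rates to a lake average
#'
#' The discrete areal rates are interpolated to a continuous rate-depth
#' function (linear between measured depths, constant extrapolation to the
#' surface and to `z_max`), integrated over the sediment area per fine depth
#' stratum, and related to the total lake surface area:
#' `GPP_lake = sum_i rate(z_mid,i) * (A(z_i) - A(z_i+1)) / A0`, with any
#' residual flat bottom at `z_max` contributing `rate(z_max) * A(z_max)`.
#'
#' @param rates A benthic [depth_rates()] profile (>= 2 depths).
#' @param hypso A [hypsography()] object.
#' @param n_strata Number of integration strata (default 1000).
#' @return Lake-average benthic GPP (mg C m^-2 d^-1).
#' @export
upscale_benthic <- function(rates, hypso, n_strata = 1000L) {
  stopifnot(inherits(rates, "depth_rates"), inherits(hypso, "hypsography"))
  if (rates$habitat != "benthic") stop("expected a benthic rate profile")
  f <- .rate_fun(rates)
  z <- seq(0, hypso$z_max, length.out = n_strata + 1L)
  a <- area_at(hypso, z)
  mid <- (z[-1L] + z[-length(z)]) / 2
  (sum(f(mid) * (a[-length(a)] - a[-1L])) +
      f(hypso$z_max) * a[length(a)]) / hypso$a0
}

#' Upscale pelagic volumetric rates to a lake average per unit surface area
#'
#' Integrates the interpolated volumetric rate over the water volume per
#' fine stratum and relates the sum to the lake surface area:
#' `GPP_lake = integral rate(z) A(z) dz / A0`.  For a uniform rate this
#' reduces to `rate * z_avg`.
#'
#' @inheritParams upscale_benthic
#' @param rates A pelagic [depth_rates()] profile (>= 2 depths).
#' @return Lake-average pelagic GPP (mg C m^-2 d^-1).
#' @export
upscale_pelagic <- function(rates, hypso, n_strata = 1000L) {
  stopifnot(inherits(rates, "depth_rates"), inherits(hypso, "hypsography"))
  if (rates$habitat != "pelagic") stop("expected a pelagic rate profile")
  f <- .rate_fun(rates)
  # include table depths so the trapezoid rule is exact for piecewise-linear
  # area and rate functions
  z <- sort(unique(c(seq(0, hypso$z_max, length.out = n_strata + 1L),
                     hypso$depth_m, rates$depth_m[rates$depth_m <= hypso$z_max])))
  g <- f(z) * area_at(hypso, z)
  sum(diff(z) * (g[-length(g)] + g[-1L]) / 2) / hypso$a0
}

#' Combine habitat lake-averages into whole-lake productivity
#'
#' @param benthic_avg,pelagic_avg Lake-average GPP per habitat
#'   (mg C m^-2 d^-1), non-negative; `pelagic_avg = NA` marks a lake where
#'   pelagic GPP was not measured (total and structuring flagged undefined).
#' @return A `lake_productivity` list: `benthic_avg`, `pelagic_avg`,
#'   `total_avg`, `structuring` (% benthic of total) and a character vector
#'   of `flags`.
#' @examples
#' lake_productivity(300, 100)$structuring  # 75
#' @export
lake_productivity <- function(benthic_avg, pelagic_avg) {
  flags <- character()
  if (is.na(benthic_avg)) stop("benthic lake-average is required")
  if (benthic_avg < 0 || (!is.na(pelagic_avg) && pelagic_avg < 0)) {
    stop("lake-average GPP must be non-negative (floor rates upstream)")
  }
  if (is.na(pelagic_avg)) {
    flags <- c(flags, "missing_pelagic")
    total <- NA_real_
    struct <- NA_real_
  } else {
    total <- benthic_avg + pelagic_avg
    if (total == 0) {
      flags <- c(flags, "structuring_undefined")
      struct <- NA_real_
    } else {
      struct <- 100 * benthic_avg / total
    }
  }
  structure(list(benthic_avg = benthic_avg, pelagic_avg = pelagic_avg,
                 total_avg = total, structuring = struct, flags = flags),
            class = "lake_productivity")
}

#' @export
print.lake_productivity <- function(x, ...) {
  cat(sprintf(
    "GPP (mg C m-2 d-1): benthic %.1f, pelagic %s, total %s; benthic share %s\n",
    x$benthic_avg,
    ifelse(is.na(x$pelagic_avg), "NA", sprintf("%.1f", x$pelagic_avg)),
    ifelse(is.na(x$total_avg), "NA", sprintf("%.1f", x$total_avg)),
    ifelse(is.na(x$structuring), "undefined", sprintf("%.1f%%", x$structuring))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
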