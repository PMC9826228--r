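#' Fit the vertical light-attenuation coefficient Kd from a PAR profile
#'
#' Kd is estimated as the absolute value of the ordinary-least-squares slope
#' of `ln(PAR)` against depth.  All profile points participate in the fit
#' (including near-surface 0.25/0.5 m readings); goodness of fit is reported
#' as the r-squared of the regression.
#'
#' @param depths Depths (m, positive downward, surface = 0), strictly
#'   increasing, at least 3 points.
#' @param par PAR readings (umol photons m^-2 s^-1), strictly positive, same
#'   length as `depths`.
#' @return A `light_field` list: `kd` (m^-1), `r_squared`, `euphotic_depth`
#'   (m, the 1 % light depth `ln(100)/kd`), `n`.
#' @examples
#' fit_kd(c(0, 1, 2), 100 * exp(-1 * c(0, 1, 2)))$kd  # 1
#' @export
fit_kd <- function(depths, par) {
  stopifnot(is.numeric(depths), is.numeric(par), length(depths) == length(par))
  if (length(depths) < 3L) stop("need at least 3 profile points to fit Kd")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (any(depths < 0)) stop("depths must be non-negative")
  if (any(!is.finite(par)) || any(par <= 0)) {
    stop("all PAR values must be strictly positive")
  }
  fit <- stats::lm(log(par) ~ depths)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) {
    stop("PAR does not decrease with depth; Kd fit slope is non-negative")
  }
  kd <- -slope
  # direct R2 (summary.lm warns on the perfect fits we routinely see)
  lp <- log(par)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((lp - mean(lp))^2)
  structure(list(kd = kd, r_squared = r2,
                 euphotic_depth = euphotic_depth(kd), n = length(depths)),
            class = "light_field")
}

#' @export
print.light_field <- function(x, ...) {
  cat(sprintf("Kd = %.4f m^-1 (r2 = %.4f, n = %d); 1%% light depth %.2f m\n",
              x$kd, x$r_squared, x$n, x$euphotic_depth))
  invisible(x)
}

#' Beer-Lambert PAR at depth
#'
#' @param surface_par PAR just below the surface (any unit).
#' @param kd Attenuation coefficient (m^-1), positive.
#' @param z Depth (m), non-negative; vectorized.
#' @return `surface_par * exp(-kd * z)`.
#' @export
par_at_depth <- function(surface_par, kd, z) {
  if (kd <= 0) stop("kd must be positive")
  if (any(z < 0)) stop("depth must be non-negative")
  surface_par * exp(-kd * z)
}

#' Euphotic (1 % light) depth
#'
#' @param kd Attenuation coefficient (m^-1), positive.
#' @return `ln(100) / kd` in metres.
#' @export
euphotic_depth <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive")
  log(100) / kd
}

#' Scaling factor from incubation-window PAR to daily PAR
#'
#' Short midday incubations are scaled to daily rates by the ratio of the
#' 24-h incident PAR sum to the PAR sum received during the incubation
#' window.  The factor is not forced to be >= 1 (an overcast afternoon after
#' a bright incubation can push it below 1).
#'
#' @param daily_incident_par 24-h incident PAR sum (mol m^-2 d^-1).
#' @param incubation_par PAR sum over the incubation window (mol m^-2).
#' @return Dimensionless scaling factor `daily / incubation`.
#' @export
daily_scaling_factor <- function(daily_incident_par, incubation_par) {
  if (daily_incident_par <= 0 || incubation_par <= 0) {
    stop("PAR sums must be positive")
  }
  daily_incident_par / incubation_par
}
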