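#' Freshwater carbonate dissociation and solubility constants
#'
#' Temperature-dependent equilibrium constants of the dissolved CO2 system at
#' infinite dilution, as used for soft, low-ionic-strength lake waters.
#' `k1` and `k2` are the first and second dissociation constants of carbonic
#' acid and `kh` is the Henry's-law solubility of CO2.
#'
#' The temperature polynomials are the ones of Plummer & Busenberg (1982,
#' Geochim. Cosmochim. Acta 46, 1011-1040), valid for 0-90 degrees C; here the
#' accepted range is restricted to 0-40 degrees C, the span of surface waters.
#' Ionic-strength corrections are deliberately omitted: the target waters are
#' dilute (conductivity of a few mS/m) so activity coefficients are ~1.
#'
#' @param temperature Water temperature in degrees Celsius, in `[0, 40]`.
#' @return A named list with `k1`, `k2` (mol L^-1) and `kh`
#'   (mol L^-1 atm^-1).
#' @examples
#' ks <- dissociation_constants(25)
#' -log10(ks$k1)  # ~6.35
#' @export
dissociation_constants <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (temperature < 0 || temperature > 40) {
    stop("temperature must be within [0, 40] degrees C, got ", temperature)
  }
  tk <- temperature + 273.15
  # Plummer & Busenberg (1982) log10 polynomials, T in kelvin
  log_k1 <- -356.3094 - 0.06091964 * tk + 21834.37 / tk +
    126.8339 * log10(tk) - 1684915 / tk^2
  log_k2 <- -107.8871 - 0.03252849 * tk + 5151.79 / tk +
    38.92561 * log10(tk) - 563713.9 / tk^2
  log_kh <- 108.3865 + 0.01985076 * tk - 6919.53 / tk -
    40.45154 * log10(tk) + 669365 / tk^2
  list(k1 = 10^log_k1, k2 = 10^log_k2, kh = 10^log_kh)
}

#' Speciate dissolved inorganic carbon from DIC, pH and temperature
#'
#' Splits a DIC concentration into free CO2 (CO2* = CO2(aq) + H2CO3),
#' bicarbonate and carbonate using the ionization fractions
#' `alpha0 = (1 + K1/h + K1*K2/h^2)^-1` etc., with `h = 10^-pH`.
#' All species are expressed as mg of carbon per litre, so mass balance
#' `co2 + hco3 + co3 == dic` holds exactly.
#'
#' @param dic Dissolved inorganic carbon (mg C L^-1), non-negative.
#' @param ph pH, in `[3, 11]`.
#' @param temperature Water temperature (degrees C), passed to
#'   [dissociation_constants()].
#' @return An object of class `carbonate_state`: list with `dic`, `ph`,
#'   `temperature`, `co2`, `hco3`, `co3` (mg C L^-1) and the constants
#'   `k1`, `k2`, `kh`.
#' @examples
#' st <- speciate(1.0, 5.3, 15)
#' st$co2  # most of the DIC is free CO2 at this pH
#' @export
speciate <- function(dic, ph, temperature) {
  stopifnot(is.numeric(dic), length(dic) == 1L, is.finite(dic))
  if (dic < 0) stop("dic must be non-negative")
  if (!is.finite(ph) || ph < 3 || ph > 11) {
    stop("ph must be within [3, 11], got ", ph)
  }
  ks <- dissociation_constants(temperature)
  h <- 10^(-ph)
  denom <- 1 + ks$k1 / h + ks$k1 * ks$k2 / h^2
  alpha0 <- 1 / denom
  alpha1 <- (ks$k1 / h) / denom
  alpha2 <- (ks$k1 * ks$k2 / h^2) / denom
  out <- list(dic = dic, ph = ph, temperature = temperature,
              co2 = dic * alpha0, hco3 = dic * alpha1, co3 = dic * alpha2,
              k1 = ks$k1, k2 = ks$k2, kh = ks$kh)
  class(out) <- "carbonate_state"
  out
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf(
    "carbonate state: DIC %.3f mg C/L at pH %.2f, %.1f degC\n",
    x$dic, x$ph, x$temperature))
  cat(sprintf("  CO2 %.4f  HCO3 %.4f  CO3 %.6f (mg C/L)\n",
              x$co2, x$hco3, x$co3))
  invisible(x)
}

#' Recover pH from a CO2/DIC pair (inverse of speciation)
#'
#' Root-finds the pH at which [speciate()] assigns the given free-CO2 share
#' of DIC.  Used as an internal consistency oracle; exported because it is
#' occasionally useful for QC of field pH readings.
#'
#' @param co2,dic Free CO2 and DIC (mg C L^-1), `0 < co2 < dic`.
#' @param temperature Degrees C.
#' @return pH value in `[3, 11]`.
#' @export
ph_from_co2 <- function(co2, dic, temperature) {
  stopifnot(co2 > 0, dic > 0, co2 < dic)
  f <- function(ph) speciate(dic, ph, temperature)$co2 - co2
  stats::uniroot(f, c(3, 11), tol = 1e-12)$root
}

#' DIC from headspace CO2 of an acidified sample
#'
#' In a sealed vial of acidified lake water all DIC is converted to free CO2
#' and partitions between the headspace and the water according to Henry's
#' law.  Total carbon (gas-phase moles by the ideal-gas law plus dissolved
#' moles `kh * pCO2 * v_water`) divided by the water volume gives the DIC of
#' the original sample.
#'
#' @param headspace_co2 Headspace CO2 mixing ratio (ppmv).
#' @param v_headspace,v_water Headspace and water volumes (mL), positive.
#' @param temperature Equilibration temperature (degrees C).
#' @param pressure Total pressure (atm), default 1.
#' @return DIC in mg C L^-1.
#' @examples
#' dic_from_headspace(10000, 10, 20, 20)
#' @export
dic_from_headspace <- function(headspace_co2, v_headspace, v_water,
                               temperature, pressure = 1) {
  stopifnot(is.numeric(headspace_co2), headspace_co2 >= 0)
  if (v_headspace <= 0 || v_water <= 0) stop("volumes must be positive")
  if (pressure <= 0) stop("pressure must be positive")
  ks <- dissociation_constants(temperature)
  tk <- temperature + 273.15
  r_gas <- 0.08205736            # L atm mol^-1 K^-1
  p_co2 <- headspace_co2 * 1e-6 * pressure         # atm
  n_gas <- p_co2 * (v_headspace / 1000) / (r_gas * tk)
  n_aq <- ks$kh * p_co2 * (v_water / 1000)
  mg_c <- (n_gas + n_aq) * 12.011 * 1000
  mg_c / (v_water / 1000)
}
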