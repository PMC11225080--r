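#' Air-saturated oxygen concentration in fresh water
#'
#' Equilibrium dissolved-oxygen concentration (mg O2 per litre) of fresh water
#' in contact with air, from the Benson--Krause relation in temperature with
#' the standard barometric-pressure correction (water-vapour pressure and the
#' oxygen fugacity/pressure factor). This is the relation behind the widely
#' used USGS solubility tables, which the implementation is tested against.
#'
#' @param temp_c Water temperature in degrees Celsius (vector allowed).
#' @param pressure_kpa Barometric pressure in kPa. Defaults to one standard
#'   atmosphere (101.325 kPa). At mountain field sites the true pressure is
#'   lower and should be supplied; at ~1800 m elevation it is roughly 81 kPa.
#' @return Saturation concentration in mg O2 L^-1, same length as `temp_c`.
#' @examples
#' o2_solubility(15)        # ~10.08 mg/L
#' o2_solubility(20, 81.3)  # lower pressure, lower solubility
#' @export
o2_solubility <- function(temp_c, pressure_kpa = 101.325) {
  if (any(!is.finite(temp_c)) || any(temp_c <= -5) || any(temp_c >= 45)) {
    stop("`temp_c` must be finite and within (-5, 45) degrees C", call. = FALSE)
  }
  stopifnot_scalar_number(pressure_kpa, "pressure_kpa", positive = TRUE)
  tk <- temp_c + 273.15
  # Benson & Krause unit-standard-atmosphere saturation concentration, mg/L.
  ln_c <- -139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
    1.243800e10 / tk^3 - 8.621949e11 / tk^4
  c_star <- exp(ln_c)
  p_atm <- pressure_kpa / 101.325
  # Water vapour pressure (atm) and oxygen pressure factor theta.
  ln_pwv <- 11.8571 - 3840.70 / tk - 216961 / tk^2
  pwv <- exp(ln_pwv)
  theta <- 0.000975 - 1.426e-5 * temp_c + 6.436e-8 * temp_c^2
  c_star * p_atm * (1 - pwv / p_atm) * (1 - theta * p_atm) /
    ((1 - pwv) * (1 - theta))
}

#' Convert a saturation slope to an oxygen uptake rate
#'
#' Respirometry traces record dissolved oxygen as percent air saturation. A
#' within-seal regression slope in %-saturation per minute is converted to a
#' mass uptake rate by scaling with the saturation concentration of the water
#' at the seal's temperature and the respirometer water volume:
#' `rate = -slope/100 * C_s(temp, pressure) * volume`. Oxygen removal gives a
#' negative slope, hence a positive rate.
#'
#' @param slope_sat Regression slope in percent saturation per minute
#'   (negative during uptake). Vectorized.
#' @param temp_c Water temperature of the measurement window, degrees C.
#' @param volume_l Respirometer water volume in litres.
#' @param pressure_kpa Barometric pressure in kPa (see [o2_solubility()]).
#' @return Oxygen uptake rate in mg O2 min^-1 (positive for uptake).
#' @examples
#' saturation_to_mass_rate(-1, temp_c = 15, volume_l = 0.133)
#' @export
saturation_to_mass_rate <- function(slope_sat, temp_c, volume_l,
                                    pressure_kpa = 101.325) {
  stopifnot_scalar_number(volume_l, "volume_l", positive = TRUE)
  -slope_sat / 100 * o2_solubility(temp_c, pressure_kpa) * volume_l
}

# Inverse map used by the trace generator: uptake rate (mg/min) -> saturation
# slope (%/min, negative).
mass_rate_to_sat_slope <- function(rate_mg_min, temp_c, volume_l,
                                   pressure_kpa = 101.325) {
  -rate_mg_min * 100 / (o2_solubility(temp_c, pressure_kpa) * volume_l)
}
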