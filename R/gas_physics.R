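# Closed-form physical chemistry used throughout the package: Schmidt
# numbers, conversion between K600 and gas-specific exchange coefficients,
# oxygen saturation, barometric pressure correction, Henry's-law CO2
# solubility and the O2-to-C stoichiometric conversion.

# Molar masses used for all unit conversions (g/mol).
.MOLAR_MASS_C <- 12
.MOLAR_MASS_O2 <- 32

.check_temperature <- function(temp) {
  if (any(!is.finite(temp)) || any(temp < -1) || any(temp > 40)) {
    stop("water temperature must be finite and within [-1, 40] degC",
         call. = FALSE)
  }
  invisible(temp)
}

#' Schmidt number of oxygen in fresh water
#'
#' Cubic polynomial in water temperature, with the coefficients in standard
#' use for freshwater gas-exchange work. The Schmidt number is the
#' dimensionless ratio of the kinematic viscosity of water to the molecular
#' diffusivity of the gas; it is the quantity through which a normalized gas
#' exchange coefficient (`K600`) is rescaled to a specific gas.
#'
#' @param temp Water temperature in degrees Celsius, in `[-1, 40]`.
#' @return Dimensionless Schmidt number (vectorized over `temp`).
#' @seealso [schmidt_co2()], [k600_to_kgas()]
#' @examples
#' schmidt_o2(20) # 529.8
#' @export
schmidt_o2 <- function(temp) {
  .check_temperature(temp)
  1800.6 - 120.1 * temp + 3.78 * temp^2 - 0.0476 * temp^3
}

#' Schmidt number of carbon dioxide in fresh water
#'
#' @inheritParams schmidt_o2
#' @return Dimensionless Schmidt number. At 20 degC the value is within
#'   0.5% of 600, the reference Schmidt number to which `K600` is normalized.
#' @examples
#' schmidt_co2(20) / 600 # ~= 1
#' @export
schmidt_co2 <- function(temp) {
  .check_temperature(temp)
  1911.1 - 118.1 * temp + 3.45 * temp^2 - 0.0413 * temp^3
}

#' Convert a normalized gas exchange coefficient to a specific gas
#'
#' `Kx = K600 * (600 / Sc)^0.5`: the standard Schmidt-number scaling with
#' exponent -1/2 appropriate for rippled/turbulent water surfaces.
#'
#' @param k600 Gas exchange coefficient normalized to Schmidt number 600
#'   (per day), non-negative.
#' @param sc Schmidt number of the target gas (dimensionless, > 0).
#' @return Gas-specific exchange coefficient in per day.
#' @seealso [kgas_to_k600()] for the exact inverse.
#' @examples
#' k600_to_kgas(10, schmidt_o2(20)) # 10.64
#' @export
k600_to_kgas <- function(k600, sc) {
  if (any(!is.finite(k600)) || any(k600 < 0)) {
    stop("k600 must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    stop("Schmidt number must be finite and > 0", call. = FALSE)
  }
  k600 * (600 / sc)^0.5
}

#' Convert a gas-specific exchange coefficient back to K600
#'
#' Exact inverse of [k600_to_kgas()].
#'
#' @param kgas Gas-specific exchange coefficient (per day), non-negative.
#' @param sc Schmidt number of that gas (dimensionless, > 0).
#' @return `K600` in per day.
#' @export
kgas_to_k600 <- function(kgas, sc) {
  if (any(!is.finite(kgas)) || any(kgas < 0)) {
    stop("kgas must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    stop("Schmidt number must be finite and > 0", call. = FALSE)
  }
  kgas * (sc / 600)^0.5
}

# Saturation vapor pressure of water (atm) as a function of temperature,
# used in the pressure correction of the oxygen saturation concentration.
.water_vapor_pressure <- function(temp) {
  tk <- temp + 273.15
  exp(11.8571 - 3840.70 / tk - 216961 / tk^2)
}

#' Oxygen saturation concentration in fresh water
#'
#' Equilibrium dissolved O2 concentration at a given temperature and ambient
#' barometric pressure, from the Garcia and Gordon (1992) polynomial fit to
#' the Benson and Krause solubility data (salinity zero), with a standard
#' vapor-pressure-aware barometric correction. This is the convention of the
#' open-channel stream metabolism literature.
#'
#' @inheritParams schmidt_o2
#' @param pressure Barometric pressure in atm (default 1). See
#'   [barometric_pressure()] to correct a reference-station reading to the
#'   site elevation.
#' @return Saturation concentration in g O2 per cubic metre (mg/L).
#' @examples
#' o2_saturation(0)  # ~14.6
#' o2_saturation(20) # ~9.1
#' @export
o2_saturation <- function(temp, pressure = 1) {
  .check_temperature(temp)
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("pressure must be finite and > 0 atm", call. = FALSE)
  }
  # Garcia & Gordon (1992) combined fit, Benson & Krause data, umol/kg.
  ts <- log((298.15 - temp) / (273.15 + temp))
  lnc <- 5.80871 + 3.20291 * ts + 4.17887 * ts^2 + 5.10006 * ts^3 -
    9.86643e-2 * ts^4 + 3.80369 * ts^5
  c_umol_kg <- exp(lnc)
  c_1atm <- c_umol_kg * .MOLAR_MASS_O2 / 1000 # ~ g/m3 (density ~ 1 kg/L)
  pv <- .water_vapor_pressure(temp)
  c_1atm * (pressure - pv) / (1 - pv)
}

#' Barometric pressure at an elevation offset
#'
#' Isothermal barometric formula `P = P0 * exp(-dz / H)` with scale height
#' `H = 8434 m` (15 degC standard atmosphere), used to transfer a
#' meteorological-station pressure reading to a site at a different
#' elevation.
#'
#' @param p0 Pressure at the reference elevation (atm).
#' @param dz Elevation of the site minus elevation of the reference (m);
#'   positive when the site is higher.
#' @param scale_height Atmospheric scale height in metres.
#' @return Pressure at the site (atm).
#' @export
barometric_pressure <- function(p0, dz, scale_height = 8434) {
  if (any(!is.finite(p0)) || any(p0 <= 0)) {
    stop("p0 must be finite and > 0 atm", call. = FALSE)
  }
  if (any(!is.finite(dz))) stop("dz must be finite", call. = FALSE)
  p0 * exp(-dz / scale_height)
}

#' Henry's law solubility of CO2 in fresh water
#'
#' Weiss (1974) freshwater CO2 solubility `K0` as a function of temperature
#' (salinity terms dropped).
#'
#' @inheritParams schmidt_o2
#' @return Solubility in mol per litre per atm.
#' @export
co2_henry_constant <- function(temp) {
  .check_temperature(temp)
  tk <- temp + 273.15
  exp(-58.0931 + 90.5069 * (100 / tk) + 22.2940 * log(tk / 100))
}

#' Convert a CO2 partial pressure to a molar concentration
#'
#' `C = pCO2 * 1e-6 atm * K0(T)`, with `K0` from [co2_henry_constant()],
#' returned in mol per cubic metre. Linear in `pCO2`.
#'
#' @param pco2 Partial pressure of CO2 in ppm (>= 0).
#' @inheritParams schmidt_o2
#' @return Dissolved CO2 concentration in mol per cubic metre.
#' @examples
#' co2_ppm_to_molar(400, 25) # ~0.0135
#' @export
co2_ppm_to_molar <- function(pco2, temp) {
  if (any(!is.finite(pco2)) || any(pco2 < 0)) {
    stop("pco2 must be finite and >= 0 ppm", call. = FALSE)
  }
  pco2 * 1e-6 * co2_henry_constant(temp) * 1000
}

#' Convert a molar CO2 concentration back to a partial pressure
#'
#' Exact inverse of [co2_ppm_to_molar()].
#'
#' @param conc Dissolved CO2 in mol per cubic metre (>= 0).
#' @inheritParams schmidt_o2
#' @return Partial pressure in ppm.
#' @export
co2_molar_to_ppm <- function(conc, temp) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("conc must be finite and >= 0", call. = FALSE)
  }
  conc / (co2_henry_constant(temp) * 1000) * 1e6
}

#' Convert an O2 rate to a carbon rate
#'
#' Assumes one mole of O2 produced or consumed per mole of CO2 (respiratory
#' and photosynthetic quotients of 1), i.e. multiply by 12/32. Sign is
#' preserved.
#'
#' @param rate Rate in g O2 per square metre per day (any sign).
#' @return Rate in g C per square metre per day.
#' @examples
#' o2_to_carbon(32) # 12
#' @export
o2_to_carbon <- function(rate) {
  if (any(!is.finite(rate))) stop("rate must be finite", call. = FALSE)
  rate * .MOLAR_MASS_C / .MOLAR_MASS_O2
}
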