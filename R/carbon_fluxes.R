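# CO2 evasion and the diel flux metrics: instantaneous and daily evasion,
# the within-day pCO2 range, the day-night contrast in evasion, and the
# noon/midnight evasion rates.

#' Instantaneous CO2 evasion rate
#'
#' `E = KCO2 * z * ([CO2]w - [CO2]a)`, converted from mol to g C by the
#' molar mass of carbon. Positive values are effluxes (supersaturated
#' water), negative values influxes.
#'
#' @param kco2 CO2 gas exchange coefficient (day^-1, >= 0).
#' @param depth Channel depth z (m, > 0).
#' @param co2_w Dissolved CO2 concentration (mol m^-3).
#' @param co2_a CO2 concentration in equilibrium with the atmosphere
#'   (mol m^-3), see [atmospheric_reference()].
#' @return Evasion rate in g C m^-2 day^-1 (vectorized).
#' @examples
#' evasion_rate(10, 0.2, 0.08, 0.03) # 1.2
#' @export
evasion_rate <- function(kco2, depth, co2_w, co2_a) {
  if (any(!is.finite(kco2)) || any(kco2 < 0)) {
    stop("kco2 must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(depth)) || any(depth <= 0)) {
    stop("depth must be finite and > 0", call. = FALSE)
  }
  kco2 * depth * (co2_w - co2_a) * .MOLAR_MASS_C
}

#' Atmospheric-equilibrium CO2 concentration
#'
#' The dissolved concentration in equilibrium with an atmospheric pCO2 of
#' `ppm` (default 380, a field-measured air value) at the water
#' temperature, via Henry's law. Override `ppm` for sensitivity runs.
#'
#' @param temp Water temperature (degC), vectorized.
#' @param ppm Atmospheric pCO2 (ppm).
#' @return Equilibrium concentration (mol m^-3).
#' @export
atmospheric_reference <- function(temp, ppm = 380) {
  co2_ppm_to_molar(ppm, temp)
}

#' Within-day pCO2 range
#'
#' Difference between the highest and lowest CO2 concentration within the
#' day.
#'
#' @param pco2 One day's pCO2 series (ppm).
#' @return Range in ppm (>= 0).
#' @export
delta_co2 <- function(pco2) {
  if (any(!is.finite(pco2))) stop("pco2 must be finite", call. = FALSE)
  max(pco2) - min(pco2)
}

#' Day-night contrast in cumulative CO2 evasion
#'
#' Cumulative evasion between sunrise and sunset minus the night-time
#' evasion scaled to the same duration: computed as
#' `(mean daytime rate - mean night rate) * daytime duration`, a
#' duration-normalized convention that stays well defined for any
#' photoperiod. Negative values mean daytime evasion is depressed
#' (photosynthetic CO2 drawdown). On polar days or nights the contrast is
#' undefined and `NA` is returned.
#'
#' @param evasion Instantaneous evasion series (g C m^-2 day^-1).
#' @param time Matching POSIXct timestamps (UTC).
#' @param sunrise,sunset POSIXct solar times for the day (`NA` on polar
#'   days/nights).
#' @return Contrast in g C m^-2, or `NA` when undefined.
#' @export
diel_evasion_change <- function(evasion, time, sunrise, sunset) {
  if (length(evasion) != length(time)) {
    stop("evasion and time must have equal length", call. = FALSE)
  }
  if (is.na(sunrise) || is.na(sunset)) return(NA_real_)
  day_sel <- time >= sunrise & time < sunset
  if (!any(day_sel) || all(day_sel)) return(NA_real_)
  day_dur <- as.numeric(difftime(sunset, sunrise, units = "days"))
  (mean(evasion[day_sel]) - mean(evasion[!day_sel])) * day_dur
}

#' Mean evasion rates at solar noon and solar midnight
#'
#' Mean instantaneous evasion within 1-hour bins centred on solar noon and
#' solar midnight (solar, not clock, time: at high latitudes in summer the
#' two differ).
#'
#' @inheritParams diel_evasion_change
#' @param solar_noon,solar_midnight POSIXct solar times for the day.
#' @param half_window_min Half width of the bin (minutes).
#' @return A list with `noon` and `midnight` rates (g C m^-2 day^-1).
#' @export
noon_midnight <- function(evasion, time, solar_noon, solar_midnight,
                          half_window_min = 30) {
  bin_mean <- function(center) {
    sel <- abs(as.numeric(difftime(time, center, units = "mins"))) <=
      half_window_min
    if (!any(sel)) return(NA_real_)
    mean(evasion[sel])
  }
  list(noon = bin_mean(solar_noon), midnight = bin_mean(solar_midnight))
}

#' Per-day CO2 flux metrics for a sensor series
#'
#' Computes the instantaneous evasion series from per-timestep KCO2
#' (Schmidt-scaled from a per-timestep K600), depth and the Henry's-law
#' CO2 concentrations, then summarizes each day: time-weighted daily mean
#' evasion, the within-day pCO2 range, the day-night evasion contrast and
#' the solar noon/midnight rates.
#'
#' @param series Sensor data.frame (`time`, `pco2`, `temperature`, `depth`
#'   columns, uniform clock).
#' @param k600 Per-timestep K600 (day^-1): either a single value or a
#'   vector matching `series`.
#' @param lat,lon Site coordinates for solar geometry.
#' @param co2_atm_ppm Atmospheric reference pCO2 (ppm).
#' @return A list with `instantaneous` (per-timestep `time`, `evasion`)
#'   and `daily`, a data.frame with one row per day: `date`, `evasion`
#'   (daily mean), `delta_co2`, `diel_change`, `noon`, `midnight`.
#' @export
co2_flux_metrics <- function(series, k600, lat, lon, co2_atm_ppm = 380) {
  .check_uniform_clock(series$time)
  kco2 <- k600_to_kgas(k600, schmidt_co2(series$temperature))
  co2_w <- co2_ppm_to_molar(series$pco2, series$temperature)
  co2_a <- atmospheric_reference(series$temperature, co2_atm_ppm)
  evasion <- evasion_rate(kco2, series$depth, co2_w, co2_a)
  dates <- .utc_date(series$time)
  daily <- lapply(unique(dates), function(d) {
    sel <- dates == d
    st <- sun_times(lat, lon, d)
    nm <- noon_midnight(evasion[sel], series$time[sel],
                        st$solar_noon, st$solar_midnight)
    data.frame(date = d,
               evasion = mean(evasion[sel]),
               delta_co2 = delta_co2(series$pco2[sel]),
               diel_change = diel_evasion_change(
                 evasion[sel], series$time[sel], st$sunrise, st$sunset),
               noon = nm$noon, midnight = nm$midnight)
  })
  list(instantaneous = data.frame(time = series$time, evasion = evasion),
       daily = do.call(rbind, daily))
}
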