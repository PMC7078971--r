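# Solar geometry: declination, equation of time, solar elevation, sunrise,
# sunset and solar noon. All times are UTC; longitude enters only through
# the solar-time offset. Accuracy of a few minutes, which is ample for
# photoperiod bookkeeping at high latitudes (including midnight-sun days).

.deg2rad <- function(x) x * pi / 180

# Fractional year (radians) from a POSIXct UTC timestamp.
.solar_gamma <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
}

# Equation of time (minutes) and solar declination (radians), NOAA
# low-precision expansions.
.equation_of_time <- function(gamma) {
  229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
              0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
}

.solar_declination <- function(gamma) {
  0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
}

#' Sine of the solar elevation angle
#'
#' @param lat,lon Site latitude and longitude in decimal degrees
#'   (`abs(lat) <= 90`); east longitudes positive.
#' @param time POSIXct timestamps (UTC).
#' @return Sine of the solar elevation; negative when the sun is below the
#'   horizon.
#' @export
sin_solar_elevation <- function(lat, lon, time) {
  if (!is.finite(lat) || abs(lat) > 90) {
    stop("latitude must be within [-90, 90]", call. = FALSE)
  }
  gamma <- .solar_gamma(time)
  eqt <- .equation_of_time(gamma)
  decl <- .solar_declination(gamma)
  lt <- as.POSIXlt(time, tz = "UTC")
  clock_min <- lt$hour * 60 + lt$min + lt$sec / 60
  tst <- (clock_min + eqt + 4 * lon) %% 1440 # true solar time, minutes
  ha <- .deg2rad(tst / 4 - 180)              # hour angle
  phi <- .deg2rad(lat)
  sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
}

#' Sunrise, sunset and solar noon for one date
#'
#' Computes UTC sunrise/sunset (zenith 90.833 degrees, i.e. with standard
#' refraction) and solar noon for a site and calendar date. Above the polar
#' circles the sun can stay up (or down) all day; those cases are flagged
#' and the rise/set times are `NA`.
#'
#' @inheritParams sin_solar_elevation
#' @param date A `Date` (or string coercible to one).
#' @return A list with POSIXct `sunrise`, `sunset`, `solar_noon`,
#'   `solar_midnight`, numeric `daylength_hours` and `night_hours`, and
#'   logicals `polar_day`, `polar_night`.
#' @export
sun_times <- function(lat, lon, date) {
  if (!is.finite(lat) || abs(lat) > 90) {
    stop("latitude must be within [-90, 90]", call. = FALSE)
  }
  date <- as.Date(date)
  noon_guess <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
  gamma <- .solar_gamma(noon_guess)
  eqt <- .equation_of_time(gamma)
  decl <- .solar_declination(gamma)
  phi <- .deg2rad(lat)

  day_start <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  noon_min <- 720 - 4 * lon - eqt
  solar_noon <- day_start + noon_min * 60
  # the solar midnight falling within this civil day
  solar_midnight <- solar_noon + if (noon_min < 720) 12 * 3600 else -12 * 3600

  cos_h0 <- (cos(.deg2rad(90.833)) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  if (cos_h0 < -1) {
    # sun never sets
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA),
                solar_noon = solar_noon, solar_midnight = solar_midnight,
                daylength_hours = 24, night_hours = 0,
                polar_day = TRUE, polar_night = FALSE))
  }
  if (cos_h0 > 1) {
    # sun never rises
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA),
                solar_noon = solar_noon, solar_midnight = solar_midnight,
                daylength_hours = 0, night_hours = 24,
                polar_day = FALSE, polar_night = TRUE))
  }
  h0 <- acos(cos_h0) # radians
  half_day_min <- h0 * 180 / pi * 4
  sunrise <- day_start + (noon_min - half_day_min) * 60
  sunset <- day_start + (noon_min + half_day_min) * 60
  daylength <- 2 * half_day_min / 60
  list(sunrise = sunrise, sunset = sunset,
       solar_noon = solar_noon, solar_midnight = solar_midnight,
       daylength_hours = daylength, night_hours = 24 - daylength,
       polar_day = FALSE, polar_night = FALSE)
}

#' Simulate a clear-sky photosynthetically active radiation series
#'
#' Clear-sky PAR proportional to the sine of the solar elevation (zero when
#' the sun is below the horizon): the half-sinusoid diel light curve used as
#' the within-day weight that distributes daily gross primary production
#' across time steps. Above the Arctic circle in midsummer the series is
#' positive at every time step (midnight sun).
#'
#' @inheritParams sun_times
#' @param timestep_min Sampling interval in minutes; must divide 1440.
#' @param par_max PAR at solar elevation 90 degrees
#'   (umol photons m^-2 s^-1).
#' @return A data.frame with POSIXct `time` (UTC, left-closed steps covering
#'   the date) and numeric `par`.
#' @export
simulate_par <- function(lat, lon, date, timestep_min = 10,
                         par_max = 1500) {
  if (1440 %% timestep_min != 0) {
    stop("timestep_min must divide 1440", call. = FALSE)
  }
  date <- as.Date(date)
  n <- 1440 %/% timestep_min
  time <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    seq(0, by = timestep_min * 60, length.out = n)
  s <- sin_solar_elevation(lat, lon, time)
  data.frame(time = time, par = par_max * pmax(0, s))
}
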