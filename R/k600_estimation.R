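# Gas exchange from data: the depth-discharge rating, the multi-window
# night-time regression for KO2, its quality filters, and the site-level
# K600-discharge relation whose predictions become the daily K priors of
# the metabolism model.

#' Fit a linear depth-discharge rating curve
#'
#' Ordinary least squares of discharge on depth. Ratings with R^2 at or
#' below `r2_min` are flagged as rejected; the monitoring convention
#' requires R^2 above 0.85 for a usable rating.
#'
#' @param depths Water depths (m).
#' @param discharges Paired discharges (same length, any consistent unit).
#' @param r2_min Minimum acceptable R^2 (exclusive bound).
#' @return A list of class `"rating_curve"` with `intercept`, `slope`,
#'   `r_squared`, `accepted` and `n`. `predict()` maps depth to discharge.
#' @export
fit_rating_curve <- function(depths, discharges, r2_min = 0.85) {
  if (length(depths) != length(discharges)) {
    stop("depths and discharges must have equal length", call. = FALSE)
  }
  if (length(depths) < 3) {
    stop("at least 3 paired observations are required", call. = FALSE)
  }
  if (stats::sd(depths) == 0) {
    stop("depth has no variation; rating curve is undetermined",
         call. = FALSE)
  }
  fit <- stats::lm(discharges ~ depths)
  r2 <- suppressWarnings(summary(fit))$r.squared # exact fits are fine
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 accepted = r2 > r2_min,
                 n = length(depths)),
            class = "rating_curve")
}

#' @export
predict.rating_curve <- function(object, depth, ...) {
  object$intercept + object$slope * depth
}

#' Night-time regression of O2 change rate on the saturation deficit
#'
#' After sunset photosynthesis stops, and the O2 change rate is
#' `dO2/dt = ER/z + KO2 * (O2sat - O2)`: a straight line in the saturation
#' deficit whose slope is KO2 (day^-1) and whose intercept absorbs the
#' (constant) volumetric respiration. The rate is computed as a lagged
#' forward difference, `(O2[t+lag] - O2[t]) / (lag * dt)`, regressed on the
#' mean saturation deficit over the lagged span. For the one-step oxygen
#' recursion used throughout the package this pairing is exact at any lag
#' (the lagged difference telescopes into the mean deficit), so noise-free
#' simulated nights are recovered to machine precision, while a lag of
#' around an hour suppresses the sensor-noise amplification that
#' point-to-point differencing of 10-minute data suffers from. The slope
#' is converted to K600 by Schmidt scaling at the window-mean temperature.
#'
#' @param o2 Dissolved O2 (g m^-3) within the window, in time order.
#' @param o2sat Saturation O2 (g m^-3), same length.
#' @param temp Water temperature (degC), same length.
#' @param dt Time step in days.
#' @param lag Differencing span in time steps (default 1).
#' @return A list of class `"night_window"` with `ko2` and `k600` (day^-1),
#'   `intercept` (the ER/z term, g m^-3 day^-1), `r_squared` and `n`
#'   (number of regression points).
#' @export
night_regression <- function(o2, o2sat, temp, dt, lag = 1) {
  n <- length(o2)
  if (length(o2sat) != n || length(temp) != n) {
    stop("o2, o2sat and temp must have equal length", call. = FALSE)
  }
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1", call. = FALSE)
  if (n < lag + 4) {
    stop("window must contain at least lag + 4 points", call. = FALSE)
  }
  idx <- seq_len(n - lag)
  rate <- (o2[idx + lag] - o2[idx]) / (lag * dt)    # per day
  def_all <- o2sat - o2
  cs <- cumsum(c(0, def_all))
  deficit <- (cs[idx + lag] - cs[idx]) / lag        # mean over the span
  if (stats::sd(deficit) == 0) {
    stop("saturation deficit has no variation in window", call. = FALSE)
  }
  fit <- stats::lm(rate ~ deficit)
  ko2 <- unname(stats::coef(fit)[2])
  structure(list(ko2 = ko2,
                 k600 = if (ko2 >= 0) {
                   kgas_to_k600(ko2, schmidt_o2(mean(temp)))
                 } else NA_real_,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 n = length(idx)),
            class = "night_window")
}

# The six staggered night windows: equal-length overlapping windows of half
# the night, with starts evenly spaced from sunset to mid-night, so their
# union covers the whole night.
.night_windows <- function(sunset, sunrise, n_windows = 6) {
  night_len <- as.numeric(difftime(sunrise, sunset, units = "secs"))
  win_len <- night_len / 2
  starts <- sunset + seq(0, night_len - win_len, length.out = n_windows)
  data.frame(start = starts, end = starts + win_len)
}

#' Best nightly K600 estimate from staggered regression windows
#'
#' Evaluates six equal-length overlapping regression windows spanning the
#' night between this date's sunset and the next sunrise, drops windows
#' with regression R^2 at or below `r2_min` or a negative slope, and
#' returns the retained window with the highest R^2. Nights shorter than
#' `min_night_hours` (including polar days, when the sun never sets) yield
#' no estimate -- a valid outcome, not an error.
#'
#' @param series Sensor data.frame with `time`, `o2`, `temperature`,
#'   `pressure` columns (uniform clock), spanning the night following
#'   `date`.
#' @param date Calendar date (UTC) whose night (sunset to next sunrise) is
#'   analysed.
#' @param lat,lon Site coordinates (decimal degrees).
#' @param r2_min Minimum regression R^2 (exclusive).
#' @param min_night_hours Minimum night duration (hours).
#' @param n_windows Number of staggered windows.
#' @param lag_min Differencing span of the regression in minutes (see
#'   [night_regression()]); rounded to whole time steps.
#' @return `NULL` when no estimate can be made, otherwise a list of class
#'   `"nightly_k600"` with `k600`, `ko2`, `r_squared`, `n`, the window
#'   `start`/`end`, and the night duration.
#' @export
nightly_k600 <- function(series, date, lat, lon, r2_min = 0.7,
                         min_night_hours = 2, n_windows = 6,
                         lag_min = 60) {
  .check_uniform_clock(series$time)
  st <- sun_times(lat, lon, date)
  if (st$polar_day) return(NULL)
  nxt <- sun_times(lat, lon, as.Date(date) + 1)
  if (st$polar_night) {
    sunset <- st$solar_noon   # whole civil night; degenerate but defined
    sunrise <- nxt$solar_noon
  } else {
    sunset <- st$sunset
    sunrise <- if (nxt$polar_night) nxt$solar_noon else nxt$sunrise
  }
  night_hours <- as.numeric(difftime(sunrise, sunset, units = "hours"))
  if (!is.finite(night_hours) || night_hours < min_night_hours) return(NULL)

  dt_days <- as.numeric(difftime(series$time[2], series$time[1],
                                 units = "days"))
  lag <- max(1L, as.integer(round(lag_min / (dt_days * 1440))))
  wins <- .night_windows(sunset, sunrise, n_windows)
  best <- NULL
  for (w in seq_len(nrow(wins))) {
    sel <- series$time >= wins$start[w] & series$time <= wins$end[w]
    if (sum(sel) < lag + 4) next
    o2sat <- o2_saturation(series$temperature[sel], series$pressure[sel])
    reg <- tryCatch(
      night_regression(series$o2[sel], o2sat, series$temperature[sel],
                       dt_days, lag = lag),
      error = function(e) NULL)
    if (is.null(reg) || reg$r_squared <= r2_min || reg$ko2 <= 0) next
    if (is.null(best) || reg$r_squared > best$r_squared) {
      best <- c(reg, list(start = wins$start[w], end = wins$end[w]))
    }
  }
  if (is.null(best)) return(NULL)
  structure(c(best, list(date = as.Date(date), night_hours = night_hours)),
            class = "nightly_k600")
}

#' Fit the site-level K600-discharge relation
#'
#' Ordinary least squares of nightly K600 estimates on daily discharge.
#' Within a site, discharge is typically the dominant control on gas
#' exchange, and the fitted relation (mean prediction plus residual SD)
#' supplies the informed daily K prior that guards the metabolism model
#' against equifinality.
#'
#' @param k600 Nightly K600 estimates (day^-1).
#' @param discharge Matching daily discharges (m^3/s).
#' @return A list of class `"k600_q_relation"` with `intercept`, `slope`,
#'   `slope_se`, `residual_sd`, `r_squared` and `n`.
#' @export
fit_k600_q <- function(k600, discharge) {
  if (length(k600) != length(discharge)) {
    stop("k600 and discharge must have equal length", call. = FALSE)
  }
  if (length(k600) < 3) {
    stop("at least 3 (K600, Q) pairs are required", call. = FALSE)
  }
  fit <- stats::lm(k600 ~ discharge)
  s <- suppressWarnings(summary(fit)) # exact synthetic fits are fine
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 slope_se = unname(s$coefficients[2, 2]),
                 residual_sd = s$sigma,
                 r_squared = s$r.squared,
                 n = length(k600)),
            class = "k600_q_relation")
}

#' Predict K600 (mean and SD) at a discharge
#'
#' The mean is the fitted line; the SD is the relation's residual SD, used
#' directly as the spread of the daily K prior.
#'
#' @param object A [fit_k600_q()] result.
#' @param discharge Discharge (m^3/s).
#' @param ... Unused.
#' @return A list with `mean` and `sd` (day^-1).
#' @export
predict.k600_q_relation <- function(object, discharge, ...) {
  list(mean = object$intercept + object$slope * discharge,
       sd = rep(object$residual_sd, length(discharge)))
}
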