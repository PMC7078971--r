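# Seeded virtual sensor deployments with known ground truth. The generator
# emulates a high-latitude summer deployment: midnight-sun photoperiods
# early in the season, diel O2 curves produced by GPP/ER/reaeration, a CO2
# series coupled to net ecosystem production plus an optional groundwater
# CO2 input, discharge-dependent K600 and iid sensor noise. Every
# downstream stage of the package is validated against these deployments.

#' Ground-truth parameter set for one simulated day
#'
#' @param gpp Daily gross primary production (g O2 m^-2 day^-1, >= 0).
#' @param er Daily ecosystem respiration (g O2 m^-2 day^-1, <= 0).
#' @param k600 Normalized gas exchange coefficient (day^-1, >= 0).
#' @param depth Mean channel depth (m, > 0).
#' @param noise_sd O2 sensor noise SD (g m^-3, >= 0).
#' @param co2_gw_flux Groundwater CO2 input (g C m^-2 day^-1, >= 0),
#'   an external CO2 source uncoupled from O2 dynamics.
#' @return A list of class `"true_params"`.
#' @export
true_params <- function(gpp, er, k600, depth, noise_sd = 0,
                        co2_gw_flux = 0) {
  stopifnot(gpp >= 0, er <= 0, k600 >= 0, depth > 0, noise_sd >= 0,
            co2_gw_flux >= 0)
  structure(list(gpp = gpp, er = er, k600 = k600, depth = depth,
                 noise_sd = noise_sd, co2_gw_flux = co2_gw_flux),
            class = "true_params")
}

#' Simulate a diel dissolved O2 series
#'
#' Runs the forward diel oxygen recursion ([o2_forward()], the same code
#' path later used in fitting) and adds iid Gaussian sensor noise.
#'
#' @inheritParams o2_forward
#' @param noise_sd Sensor noise SD (g m^-3); 0 gives the exact noise-free
#'   recursion.
#' @return O2 series (g m^-3).
#' @export
simulate_o2 <- function(gpp, er, ko2, depth, par, o2sat, dt, o2_init,
                        noise_sd = 0) {
  o2 <- o2_forward(gpp, er, ko2, depth, par, o2sat, dt, o2_init)
  if (noise_sd > 0) o2 <- o2 + stats::rnorm(length(o2), 0, noise_sd)
  o2
}

#' Simulate a dissolved CO2 series coupled to metabolism
#'
#' Mirror of the diel O2 recursion for molar CO2: each time step's net
#' ecosystem production adds CO2 mole-for-mole as it removes O2 (quotients
#' of 1), a constant groundwater flux adds CO2 uncoupled from O2, and gas
#' exchange relaxes the concentration towards atmospheric equilibrium.
#' With no groundwater input and exchange switched off, the molar O2 and
#' CO2 departures from equilibrium are mirror images (the 1:1 coupling
#' line).
#'
#' @inheritParams o2_forward
#' @param kco2 CO2 gas exchange coefficient (day^-1).
#' @param temp Water temperature series (degC), for Henry's-law conversion.
#' @param co2_init_ppm Initial pCO2 (ppm).
#' @param co2_atm_ppm Atmospheric pCO2 (ppm) defining equilibrium.
#' @param gw_flux Groundwater CO2 input (g C m^-2 day^-1).
#' @param noise_cv Multiplicative lognormal sensor noise (sdlog) on pCO2.
#' @return pCO2 series (ppm), same length as `par`.
#' @export
simulate_co2 <- function(gpp, er, kco2, depth, par, temp, dt,
                         co2_init_ppm, co2_atm_ppm = 380, gw_flux = 0,
                         noise_cv = 0) {
  n <- length(par)
  stopifnot(length(temp) == n, depth > 0, dt > 0, gw_flux >= 0)
  sum_par <- sum(par)
  par_frac <- if (sum_par > 0) par / sum_par else rep(0, n)
  co2_eq <- co2_ppm_to_molar(co2_atm_ppm, temp)      # mol m^-3
  conc <- numeric(n)
  conc[1] <- co2_ppm_to_molar(co2_init_ppm, temp[1])
  for (t in 2:n) {
    nep_o2 <- gpp * par_frac[t - 1] + er * dt       # g O2 m^-2 this step
    conc[t] <- conc[t - 1] +
      (-nep_o2 / .MOLAR_MASS_O2) / depth +           # mol CO2 from NEP
      gw_flux * dt / (.MOLAR_MASS_C * depth) +       # groundwater input
      kco2 * (co2_eq[t - 1] - conc[t - 1]) * dt      # atmospheric exchange
  }
  pco2 <- co2_molar_to_ppm(conc, temp)
  if (noise_cv > 0) pco2 <- pco2 * stats::rlnorm(n, 0, noise_cv)
  pco2
}

#' Configuration of a synthetic sensor deployment
#'
#' Defaults describe a small subarctic tundra stream in midsummer:
#' latitude above the Arctic circle, 10-minute sampling, cold water with a
#' modest diel temperature cycle, strongly heterotrophic metabolism
#' (|ER| about eight times GPP, both in g O2), base flow around
#' 0.1 m^3/s with lognormal AR(1) day-to-day variation, gas exchange
#' increasing linearly with discharge, persistent CO2 supersaturation
#' supported by a small groundwater CO2 input, and sensor-grade noise.
#'
#' @param site Site identifier.
#' @param lat,lon Site coordinates (decimal degrees).
#' @param elevation Site elevation (m a.s.l.).
#' @param station_elevation Elevation of the barometric reference station.
#' @param pressure_station Barometric pressure at the station (atm).
#' @param start_date First deployment date (UTC).
#' @param n_days Number of deployment days.
#' @param timestep_min Sampling interval (minutes; divides 1440).
#' @param gpp_mean,gpp_sd Day-to-day Normal distribution of GPP
#'   (g O2 m^-2 day^-1; truncated at 0).
#' @param er_mean,er_sd Day-to-day Normal distribution of ER
#'   (g O2 m^-2 day^-1; truncated at 0 from below, i.e. ER <= 0).
#' @param q_base Base discharge (m^3/s).
#' @param q_ar1_phi,q_ar1_sd Lognormal AR(1) parameters of day-to-day
#'   discharge variation.
#' @param spate_days Integer day indices on which a within-day discharge
#'   ramp (a spate) is planted, raising depth by `spate_rise` over the day.
#' @param spate_rise Relative depth rise on spate days.
#' @param k600_intercept,k600_slope,k600_resid_sd Linear dependence of the
#'   true K600 (day^-1) on discharge (m^3/s), with Normal residual scatter.
#' @param rating_intercept,rating_slope Linear depth-discharge rating
#'   `Q = a + b * depth` used to derive depth from discharge.
#' @param temp_mean,temp_amplitude Sinusoidal diel water temperature
#'   (degC), warmest mid-afternoon.
#' @param par_max Clear-sky PAR ceiling (umol m^-2 s^-1).
#' @param noise_sd_o2 O2 sensor noise SD (g m^-3).
#' @param noise_cv_co2 Lognormal sdlog of pCO2 sensor noise.
#' @param co2_gw_flux Groundwater CO2 input (g C m^-2 day^-1).
#' @param co2_init_ppm Initial pCO2 (ppm).
#' @param co2_atm_ppm Atmospheric reference pCO2 (ppm).
#' @return A list of class `"deployment_config"`.
#' @export
deployment_config <- function(site = "S1",
                              lat = 68.35, lon = 18.94,
                              elevation = 700, station_elevation = 360,
                              pressure_station = 0.96,
                              start_date = "2015-07-25",
                              n_days = 30, timestep_min = 10,
                              gpp_mean = 0.6, gpp_sd = 0.2,
                              er_mean = -4.8, er_sd = 1.2,
                              q_base = 0.1, q_ar1_phi = 0.8,
                              q_ar1_sd = 0.25,
                              spate_days = integer(0), spate_rise = 0.3,
                              k600_intercept = 5, k600_slope = 100,
                              k600_resid_sd = 1.5,
                              rating_intercept = -0.05, rating_slope = 0.5,
                              temp_mean = 7, temp_amplitude = 1.5,
                              par_max = 1500,
                              noise_sd_o2 = 0.005, noise_cv_co2 = 0.02,
                              co2_gw_flux = 0.5,
                              co2_init_ppm = 1000, co2_atm_ppm = 380) {
  cfg <- as.list(environment())
  stopifnot(1440 %% cfg$timestep_min == 0, cfg$n_days >= 1,
            cfg$rating_slope > 0, cfg$q_base > 0)
  structure(cfg, class = "deployment_config")
}

#' Simulate a full sensor deployment with known ground truth
#'
#' Draws per-day true parameters (GPP, ER, discharge, K600, depth) from the
#' configured distributions, then integrates the O2 and CO2 recursions
#' continuously across the deployment (state carries over midnight) and
#' adds sensor noise. Reproducible: the same seed yields an identical
#' deployment.
#'
#' @param config A [deployment_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `"deployment"` with `series` (one row per time
#'   step: `time, o2, pco2, temperature, depth, par, pressure, discharge`),
#'   `truth` (one row per day of true parameters) and `config`.
#' @export
simulate_deployment <- function(config = deployment_config(), seed = 1) {
  stopifnot(inherits(config, "deployment_config"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  n_per_day <- 1440 %/% config$timestep_min
  dt <- config$timestep_min / 1440
  dates <- as.Date(config$start_date) + seq_len(config$n_days) - 1

  pressure <- barometric_pressure(config$pressure_station,
                                  config$elevation - config$station_elevation)

  # day-to-day discharge: lognormal AR(1) around the base flow
  loq <- numeric(config$n_days)
  loq[1] <- stats::rnorm(1, 0, config$q_ar1_sd)
  for (d in seq_len(config$n_days)[-1]) {
    loq[d] <- config$q_ar1_phi * loq[d - 1] +
      stats::rnorm(1, 0, config$q_ar1_sd * sqrt(1 - config$q_ar1_phi^2))
  }
  q_day <- config$q_base * exp(loq)

  gpp_day <- pmax(0, stats::rnorm(config$n_days, config$gpp_mean, config$gpp_sd))
  er_day <- pmin(0, stats::rnorm(config$n_days, config$er_mean, config$er_sd))
  k600_day <- pmax(0.1, config$k600_intercept + config$k600_slope * q_day +
                     stats::rnorm(config$n_days, 0, config$k600_resid_sd))
  depth_day <- (q_day - config$rating_intercept) / config$rating_slope

  series <- vector("list", config$n_days)
  truth <- vector("list", config$n_days)
  o2_state <- NULL
  co2_state_ppm <- config$co2_init_ppm

  for (d in seq_len(config$n_days)) {
    par_df <- simulate_par(config$lat, config$lon, dates[d],
                           config$timestep_min, config$par_max)
    hours <- as.numeric(difftime(par_df$time,
                                 as.POSIXct(paste(dates[d], "00:00:00"),
                                            tz = "UTC"), units = "hours"))
    temp <- config$temp_mean +
      config$temp_amplitude * sin(2 * pi * (hours - 9) / 24)
    o2sat <- o2_saturation(temp, pressure)

    depth <- rep(depth_day[d], n_per_day)
    q <- rep(q_day[d], n_per_day)
    if (d %in% config$spate_days) {
      ramp <- seq(0, config$spate_rise, length.out = n_per_day)
      depth <- depth * (1 + ramp)
      q <- config$rating_intercept + config$rating_slope * depth
    }

    tmean <- mean(temp)
    ko2 <- k600_to_kgas(k600_day[d], schmidt_o2(tmean))
    kco2 <- k600_to_kgas(k600_day[d], schmidt_co2(tmean))
    if (is.null(o2_state)) o2_state <- o2sat[1] + er_day[d] / (ko2 * depth[1])

    o2_clean <- o2_forward(gpp_day[d], er_day[d], ko2, depth_day[d],
                           par_df$par, o2sat, dt, o2_state)
    o2 <- o2_clean
    if (config$noise_sd_o2 > 0) {
      o2 <- o2 + stats::rnorm(n_per_day, 0, config$noise_sd_o2)
    }
    pco2_clean <- simulate_co2(gpp_day[d], er_day[d], kco2, depth_day[d],
                               par_df$par, temp, dt, co2_state_ppm,
                               config$co2_atm_ppm, config$co2_gw_flux)
    pco2 <- pco2_clean
    if (config$noise_cv_co2 > 0) {
      pco2 <- pco2 * stats::rlnorm(n_per_day, 0, config$noise_cv_co2)
    }
    o2_state <- o2_clean[n_per_day]
    co2_state_ppm <- pco2_clean[n_per_day]

    series[[d]] <- data.frame(time = par_df$time, o2 = o2, pco2 = pco2,
                              temperature = temp, depth = depth,
                              par = par_df$par, pressure = pressure,
                              discharge = q)
    truth[[d]] <- data.frame(site = config$site, date = dates[d],
                             gpp = gpp_day[d], er = er_day[d],
                             k600 = k600_day[d], ko2 = ko2, kco2 = kco2,
                             discharge = q_day[d], depth = depth_day[d],
                             noise_sd = config$noise_sd_o2,
                             co2_gw_flux = config$co2_gw_flux)
  }
  structure(list(series = do.call(rbind, series),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "deployment")
}

#' Write a simulated deployment to CSV files
#'
#' @param deployment A [simulate_deployment()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (defaults to the site id).
#' @return Invisibly, the two file paths (sensor series and truth ledger).
#' @export
write_deployment <- function(deployment, dir, prefix = NULL) {
  stopifnot(inherits(deployment, "deployment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- deployment$config$site
  series_path <- file.path(dir, paste0(prefix, "_sensors.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  ser <- deployment$series
  ser$time <- format(ser$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(ser, series_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(deployment$truth, truth_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(series = series_path, truth = truth_path))
}

#' Read a sensor series CSV written by [write_deployment()]
#'
#' @param path CSV path with ISO-8601 `time` and the sensor columns.
#' @return A data.frame with POSIXct `time` (UTC).
#' @export
read_sensor_csv <- function(path) {
  ser <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time", "o2", "pco2", "temperature", "depth", "par",
                "pressure")
  missing <- setdiff(required, names(ser))
  if (length(missing)) {
    stop("sensor CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ser$time <- as.POSIXct(ser$time, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                        "%Y-%m-%d %H:%M:%OS"))
  .check_uniform_clock(ser$time)
  ser
}
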