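# The synthetic deployment generator: forward O2/CO2 recursions, coupling
# between the gases, and reproducibility.

test_that("O2 recursion degenerates correctly", {
  n <- 144
  o2sat <- rep(10, n)
  # all processes off: constant series
  expect_equal(o2_forward(0, 0, 0, 0.3, rep(0, n), o2sat, 1 / 144, 8),
               rep(8, n))
  # pure reaeration from below saturation: monotone approach to O2sat
  o2 <- o2_forward(0, 0, 5, 0.3, rep(0, n), o2sat, 1 / 144, 8)
  expect_true(all(diff(o2) > 0))
  expect_true(all(o2 < 10))
  expect_equal(o2[n], 10, tolerance = 0.1)
})

test_that("a single reaeration step matches hand arithmetic", {
  o2 <- o2_forward(0, 0, 10, 0.5, rep(0, 2), rep(10, 2), 1 / 144, 9)
  expect_equal(o2[2], 9 + 10 * 1 * (1 / 144), tolerance = 1e-12)
})

test_that("noise-free simulation satisfies the recursion exactly at every step", {
  day <- make_day(gpp = 2, er = -5, k600 = 15, noise_sd = 0, seed = 3)
  refit <- o2_forward(2, -5, day$ko2, 0.3, day$data$par, day$data$o2sat,
                      day$data$dt, day$data$o2[1])
  expect_equal(refit, day$data$o2, tolerance = 1e-12)
  # step-by-step identity
  stepwise <- day$data$o2[-1] -
    (day$data$o2[-144] +
       2 / 0.3 * (day$data$par / sum(day$data$par))[-144] +
       -5 * day$data$dt / 0.3 +
       day$ko2 * (day$data$o2sat - day$data$o2)[-144] * day$data$dt)
  expect_equal(max(abs(stepwise)), 0, tolerance = 1e-12)
})

test_that("CO2 stays at atmospheric equilibrium when nothing forces it", {
  n <- 144
  temp <- rep(8, n)
  pco2 <- simulate_co2(0, 0, 10, 0.3, rep(0, n), temp, 1 / 144,
                       co2_init_ppm = 380, co2_atm_ppm = 380)
  expect_equal(pco2, rep(380, n), tolerance = 1e-9)
})

test_that("heterotrophy supersaturates the CO2 series", {
  n <- 288
  temp <- rep(8, n)
  pco2 <- simulate_co2(0, -5, 10, 0.3, rep(0, n), temp, 1 / 144,
                       co2_init_ppm = 380)
  expect_true(all(pco2[-1] > 380))
})

test_that("molar O2 and CO2 departures are conserved under NEP-only forcing", {
  day <- make_day(gpp = 2, er = -5, k600 = 0.001, noise_sd = 0, seed = 4)
  # exchange off in both gases, no groundwater
  temp <- day$temp
  o2 <- o2_forward(2, -5, 0, 0.3, day$data$par, day$data$o2sat,
                   day$data$dt, 10)
  pco2 <- simulate_co2(2, -5, 0, 0.3, day$data$par, temp, day$data$dt,
                       co2_init_ppm = 800)
  total <- o2 / 32 + co2_ppm_to_molar(pco2, temp)
  expect_equal(max(total) - min(total), 0, tolerance = 1e-10)
})

test_that("groundwater CO2 input raises evasion above the NEP-supported level", {
  cfgs <- list(deployment_config(n_days = 6, noise_sd_o2 = 0,
                                 noise_cv_co2 = 0, co2_gw_flux = 0,
                                 gpp_sd = 0, er_sd = 0, q_ar1_sd = 0,
                                 k600_resid_sd = 0),
               deployment_config(n_days = 6, noise_sd_o2 = 0,
                                 noise_cv_co2 = 0, co2_gw_flux = 0.5,
                                 gpp_sd = 0, er_sd = 0, q_ar1_sd = 0,
                                 k600_resid_sd = 0))
  gaps <- vapply(cfgs, function(cfg) {
    dep <- simulate_deployment(cfg, seed = 1)
    ser <- dep$series
    sel <- as.Date(ser$time, tz = "UTC") == dep$truth$date[5]
    tr <- dep$truth[5, ]
    ev <- evasion_rate(tr$kco2, tr$depth,
                       co2_ppm_to_molar(ser$pco2[sel], ser$temperature[sel]),
                       atmospheric_reference(ser$temperature[sel]))
    mean(ev) - (-o2_to_carbon(tr$gpp + tr$er))
  }, numeric(1))
  expect_equal(gaps[1], 0, tolerance = 0.02)
  expect_equal(gaps[2], 0.5, tolerance = 0.02)
})

test_that("ground-truth parameter sets enforce their sign conventions", {
  tp <- true_params(gpp = 1, er = -4, k600 = 12, depth = 0.3,
                    noise_sd = 0.01, co2_gw_flux = 0.5)
  expect_s3_class(tp, "true_params")
  expect_error(true_params(gpp = -1, er = -4, k600 = 12, depth = 0.3))
  expect_error(true_params(gpp = 1, er = 2, k600 = 12, depth = 0.3))
  expect_error(true_params(gpp = 1, er = -4, k600 = 12, depth = 0))
})

test_that("deployments are reproducible for a fixed seed", {
  cfg <- deployment_config(n_days = 2)
  expect_identical(simulate_deployment(cfg, seed = 7),
                   simulate_deployment(cfg, seed = 7))
  d1 <- simulate_deployment(cfg, seed = 7)
  d2 <- simulate_deployment(cfg, seed = 8)
  expect_false(identical(d1$series$o2, d2$series$o2))
})

test_that("deployment series respect physical invariants", {
  dep <- simulate_deployment(deployment_config(n_days = 4), seed = 11)
  expect_true(all(dep$series$o2 > 0))
  expect_true(all(dep$series$pco2 > 0))
  expect_true(all(dep$series$par >= 0))
  expect_true(all(dep$truth$gpp >= 0))
  expect_true(all(dep$truth$er <= 0))
  expect_true(all(diff(as.numeric(dep$series$time)) == 600))
})

test_that("deployment CSV files round-trip through the reader", {
  dep <- simulate_deployment(deployment_config(n_days = 2), seed = 3)
  dir <- tempfile("dep")
  paths <- write_deployment(dep, dir)
  ser <- read_sensor_csv(paths["series"])
  expect_equal(nrow(ser), nrow(dep$series))
  expect_equal(ser$o2, dep$series$o2, tolerance = 1e-6)
  expect_equal(ser$time, dep$series$time)
})
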