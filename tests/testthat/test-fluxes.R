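# CO2 evasion and the diel flux metrics.

test_that("evasion rate matches hand arithmetic and sign convention", {
  expect_equal(evasion_rate(10, 0.2, 0.05, 0.05), 0)
  expect_equal(evasion_rate(10, 0.2, 0.08, 0.03), 1.2)
  expect_lt(evasion_rate(10, 0.2, 0.01, 0.03), 0) # undersaturated: influx
  expect_error(evasion_rate(-1, 0.2, 0.08, 0.03), "kco2")
  expect_error(evasion_rate(10, 0, 0.08, 0.03), "depth")
})

test_that("atmospheric reference tracks temperature and is overridable", {
  expect_equal(atmospheric_reference(10), co2_ppm_to_molar(380, 10))
  expect_false(atmospheric_reference(5) == atmospheric_reference(20))
  expect_equal(atmospheric_reference(10, ppm = 420),
               co2_ppm_to_molar(420, 10))
})

test_that("delta CO2 is the within-day range", {
  expect_equal(delta_co2(c(800, 900, 850)), 100)
  expect_equal(delta_co2(rep(700, 10)), 0)
  set.seed(3)
  x <- runif(200, 500, 1500)
  expect_equal(delta_co2(x), max(x) - min(x))
})

test_that("coefficient of variation matches the SD/mean definition", {
  expect_equal(cv_percent(rep(3, 8)), 0)
  expect_equal(cv_percent(c(2, 4)), 100 * sd(c(2, 4)) / 3)
  expect_equal(cv_percent(c(2, 4)), 47.1, tolerance = 1e-2)
  set.seed(1)
  x <- rlnorm(50)
  expect_equal(cv_percent(3 * x), cv_percent(x), tolerance = 1e-12)
})

test_that("diel evasion contrast vanishes for a flat series and flags polar days", {
  time <- as.POSIXct("2015-08-05", tz = "UTC") +
    seq(0, by = 600, length.out = 144)
  st <- sun_times(68.35, 18.94, "2015-08-05")
  expect_equal(diel_evasion_change(rep(1.5, 144), time, st$sunrise,
                                   st$sunset), 0)
  expect_true(is.na(diel_evasion_change(rep(1.5, 144), time,
                                        as.POSIXct(NA), as.POSIXct(NA))))
})

test_that("photosynthesis makes the diel evasion contrast negative and GPP-scaled", {
  changes <- vapply(c(1, 3), function(gpp) {
    day <- make_day(gpp = gpp, er = -5, k600 = 10, noise_sd = 0, seed = 31)
    pco2 <- simulate_co2(gpp, -5, k600_to_kgas(10, schmidt_co2(7)), 0.3,
                         day$data$par, day$temp, day$data$dt,
                         co2_init_ppm = 1000)
    ev <- evasion_rate(k600_to_kgas(10, schmidt_co2(7)), 0.3,
                       co2_ppm_to_molar(pco2, day$temp),
                       atmospheric_reference(day$temp))
    st <- sun_times(68.35, 18.94, "2015-08-05")
    diel_evasion_change(ev, day$data$time, st$sunrise, st$sunset)
  }, numeric(1))
  expect_true(all(changes < 0))
  expect_gt(abs(changes[2]), abs(changes[1]))
})

test_that("noon and midnight rates bracket a GPP-driven diel cycle", {
  fx <- pipeline_fixture()
  daily <- fx$res$daily
  expect_true(all(daily$midnight > daily$noon))
  # flat series: equal rates
  time <- as.POSIXct("2015-08-05", tz = "UTC") +
    seq(0, by = 600, length.out = 144)
  st <- sun_times(68.35, 18.94, "2015-08-05")
  nm <- noon_midnight(rep(2, 144), time, st$solar_noon, st$solar_midnight)
  expect_equal(nm$noon, nm$midnight)
})

test_that("the diel CO2 range shrinks as K600 grows", {
  deltas <- vapply(c(5, 15, 40), function(k600) {
    day <- make_day(gpp = 2, er = -5, k600 = k600, noise_sd = 0, seed = 32)
    kco2 <- k600_to_kgas(k600, schmidt_co2(7))
    pco2 <- simulate_co2(2, -5, kco2, 0.3, day$data$par, day$temp,
                         day$data$dt, co2_init_ppm = 1200)
    # drop the spin-up transient: use the second half of the day
    delta_co2(pco2[73:144])
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
})
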