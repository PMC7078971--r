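# Gas exchange from data: rating curve, night-time regression and the
# K600-discharge relation.

test_that("rating curve recovers exact linear ratings and flags weak ones", {
  depth <- seq(0.2, 0.6, by = 0.05)
  q <- -0.05 + 0.5 * depth
  rc <- fit_rating_curve(depth, q)
  expect_equal(rc$intercept, -0.05, tolerance = 1e-10)
  expect_equal(rc$slope, 0.5, tolerance = 1e-10)
  expect_equal(rc$r_squared, 1)
  expect_true(rc$accepted)
  expect_equal(predict(rc, 0.3), 0.1, tolerance = 1e-10)

  set.seed(1)
  q_noisy <- q + rnorm(length(q), 0, 0.08)
  rc2 <- fit_rating_curve(depth, q_noisy)
  if (rc2$r_squared <= 0.85) expect_false(rc2$accepted)

  expect_error(fit_rating_curve(rep(0.3, 5), 1:5), "variation")
  expect_error(fit_rating_curve(c(0.1, 0.2), c(1, 2)), "at least 3")
})

test_that("night regression is exact on noise-free reaeration nights", {
  for (ko2 in c(2, 8, 20)) {
    night <- make_night(ko2 = ko2)
    for (lag in c(1, 6)) {
      nr <- night_regression(night$o2, night$o2sat, night$temp, night$dt,
                             lag = lag)
      expect_equal(nr$ko2, ko2, tolerance = 1e-6)
      expect_equal(nr$r_squared, 1, tolerance = 1e-9)
      # intercept absorbs volumetric respiration ER/z
      expect_equal(nr$intercept, -4 / 0.4, tolerance = 1e-6)
    }
  }
})

test_that("KO2 slope is converted to K600 by Schmidt scaling", {
  night <- make_night(ko2 = 8, temp = 20)
  nr <- night_regression(night$o2, night$o2sat, night$temp, night$dt)
  expect_equal(nr$k600, 8 / (600 / 529.8)^0.5, tolerance = 1e-6)
  expect_equal(nr$k600, 7.52, tolerance = 1e-3)
})

test_that("night regression is invariant to a joint offset of O2 and O2sat", {
  night <- make_night(ko2 = 8, noise_sd = 0)
  nr1 <- night_regression(night$o2, night$o2sat, night$temp, night$dt)
  nr2 <- night_regression(night$o2 + 2, night$o2sat + 2, night$temp,
                          night$dt)
  expect_equal(nr2$ko2, nr1$ko2, tolerance = 1e-9)
})

test_that("white noise yields near-zero R squared", {
  set.seed(5)
  n <- 60
  o2 <- rnorm(n, 9, 0.5)
  o2sat <- o2_saturation(rep(8, n), 1)
  nr <- night_regression(o2, rep(o2sat[1], n) + rnorm(n, 0, 0.3),
                         rep(8, n), 1 / 144, lag = 6)
  expect_lt(nr$r_squared, 0.3)
})

test_that("the staggered windows cover the whole night", {
  sunset <- as.POSIXct("2015-08-05 21:30:00", tz = "UTC")
  sunrise <- as.POSIXct("2015-08-06 02:30:00", tz = "UTC")
  wins <- dielcarbon:::.night_windows(sunset, sunrise)
  expect_equal(nrow(wins), 6)
  expect_equal(wins$start[1], sunset)
  expect_equal(wins$end[6], sunrise)
  # consecutive windows overlap: no gap in coverage
  expect_true(all(wins$start[-1] <= wins$end[-6]))
})

test_that("nightly estimate is absent under midnight sun", {
  dep <- simulate_deployment(
    deployment_config(n_days = 2, start_date = "2015-06-21"), seed = 9)
  expect_null(nightly_k600(dep$series, "2015-06-21", 68.35, 18.94))
})

test_that("nightly estimate is absent when every window fails the R2 bar", {
  set.seed(8)
  cfg <- deployment_config(n_days = 3, start_date = "2015-08-10",
                           noise_sd_o2 = 0)
  dep <- simulate_deployment(cfg, seed = 2)
  ser <- dep$series
  ser$o2 <- rnorm(nrow(ser), mean(ser$o2), 0.5) # destroy the signal
  expect_null(nightly_k600(ser, dep$truth$date[1], cfg$lat, cfg$lon))
})

test_that("a clean night recovers the true K600 within 5%", {
  cfg <- deployment_config(n_days = 3, start_date = "2015-08-10",
                           noise_sd_o2 = 0, q_ar1_sd = 0, k600_resid_sd = 0,
                           gpp_sd = 0, er_sd = 0)
  dep <- simulate_deployment(cfg, seed = 4)
  est <- nightly_k600(dep$series, dep$truth$date[1], cfg$lat, cfg$lon)
  expect_false(is.null(est))
  expect_equal(est$k600, dep$truth$k600[1], tolerance = 0.05)
  expect_gt(est$r_squared, 0.7)
})

test_that("K600-discharge relation: degenerate and exact cases", {
  q <- c(50, 150, 300, 450)
  k <- 2 + 0.01 * q
  rel <- fit_k600_q(k, q)
  expect_equal(rel$slope, 0.01, tolerance = 1e-10)
  expect_equal(rel$residual_sd, 0, tolerance = 1e-10)
  pr <- predict(rel, 200)
  expect_equal(pr$mean, 4, tolerance = 1e-10)
  expect_equal(pr$sd, 0, tolerance = 1e-10)
  expect_error(fit_k600_q(c(1, 2), c(1, 2)), "at least 3")
})

test_that("K600-discharge slope is recovered within 2 SE over 40 nights", {
  set.seed(17)
  n_nights <- 40
  q <- runif(n_nights, 50, 500) # L/s
  k_true <- pmax(0.5, 2 + 0.01 * q + rnorm(n_nights, 0, 1))
  k_est <- vapply(seq_len(n_nights), function(i) {
    night <- make_night(ko2 = k600_to_kgas(k_true[i], schmidt_o2(8)),
                        n = 40)
    night_regression(night$o2, night$o2sat, night$temp, night$dt,
                     lag = 6)$k600
  }, numeric(1))
  rel <- fit_k600_q(k_est, q)
  expect_lt(abs(rel$slope - 0.01), 2 * rel$slope_se)
  expect_equal(rel$residual_sd, 1, tolerance = 0.5)
})
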