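# The Bayesian diel oxygen model: forward recursion, posterior density and
# the Metropolis sampler.

test_that("forward model handles degenerate inputs", {
  expect_equal(o2_forward(0, 0, 0, 0.3, rep(0, 10), rep(10, 10), 1 / 144, 9),
               rep(9, 10))
  # constant per-step respiration decrement ER*dt/z
  o2 <- o2_forward(0, -4.8, 0, 0.5, rep(0, 10), rep(10, 10), 1 / 144, 9)
  expect_equal(unique(round(diff(o2), 10)), -4.8 / 144 / 0.5)
  expect_equal(diff(o2)[1], -0.0667, tolerance = 1e-3)
  expect_error(o2_forward(1, 0, 0, 0.3, rep(0, 5), rep(10, 5), 1 / 144, 9),
               "PAR")
  expect_error(o2_forward(0, 0, 0, -1, rep(0, 5), rep(10, 5), 1 / 144, 9),
               "depth")
})

test_that("a synthetic day refit with its own parameters is identical", {
  day <- make_day(gpp = 2, er = -5, k600 = 15, noise_sd = 0, seed = 2)
  refit <- o2_forward(2, -5, day$ko2, 0.3, day$data$par, day$data$o2sat,
                      day$data$dt, day$data$o2[1])
  expect_equal(refit, day$data$o2, tolerance = 1e-12)
})

test_that("with a flat likelihood the posterior is maximized at the prior means", {
  day <- make_day(gpp = 1, er = -5, k600 = 15, noise_sd = 0, seed = 6)
  priors <- metab_priors(ko2_mean = day$ko2, ko2_sd = 2)
  # a large observation error makes the likelihood flat in (GPP, ER, KO2)
  obj <- function(th) {
    -log_posterior(c(th, 300), day$data, priors)
  }
  opt <- optim(c(0, 0, 10), obj, control = list(reltol = 1e-12,
                                                maxit = 2000))
  expect_equal(opt$par[1], 1, tolerance = 0.05)
  expect_equal(opt$par[2], -5, tolerance = 0.05)
  expect_equal(opt$par[3], day$ko2, tolerance = 0.1)
})

test_that("on noise-free data the posterior peaks at the truth (grid oracle)", {
  day <- make_day(gpp = 2, er = -5, k600 = 15, noise_sd = 0, seed = 7)
  priors <- metab_priors(ko2_mean = day$ko2, ko2_sd = 1)
  sigma <- 0.01
  grid <- expand.grid(gpp = c(1.5, 2, 2.5), er = c(-5.5, -5, -4.5),
                      ko2 = day$ko2 + c(-1, 0, 1))
  lp <- apply(grid, 1, function(g) {
    log_posterior(c(g[["gpp"]], g[["er"]], g[["ko2"]], sigma), day$data,
                  priors)
  })
  best <- grid[which.max(lp), ]
  expect_equal(best$gpp, 2)
  expect_equal(best$er, -5)
  expect_equal(best$ko2, day$ko2)
  # density decreases moving any one parameter off the optimum
  lp0 <- log_posterior(c(2, -5, day$ko2, sigma), day$data, priors)
  for (delta in list(c(0.2, 0, 0), c(0, 0.3, 0), c(0, 0, 0.5))) {
    expect_lt(log_posterior(c(2 + delta[1], -5 + delta[2],
                              day$ko2 + delta[3], sigma),
                            day$data, priors), lp0)
  }
})

test_that("a fixed seed gives bit-identical fits", {
  day <- make_day(gpp = 1.5, er = -4, k600 = 12, seed = 9)
  f1 <- fit_day(day, ko2_prior_sd = 2, n_iter = 3000, n_keep = 2000,
                seed = 42)
  f2 <- fit_day(day, ko2_prior_sd = 2, n_iter = 3000, n_keep = 2000,
                seed = 42)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws, f2$draws)
})

test_that("zero-noise data with a point-mass K prior recovers truth within 1%", {
  day <- make_day(gpp = 2, er = -5, k600 = 15, noise_sd = 0, seed = 10)
  fit <- fit_day(day, ko2_prior_sd = 0, seed = 3)
  expect_equal(fit$summary["gpp", "mean"], 2, tolerance = 0.01)
  expect_equal(fit$summary["er", "mean"], -5, tolerance = 0.01)
  expect_equal(fit$summary["nep", "mean"], -3, tolerance = 0.01)
  expect_equal(fit$mae, 0, tolerance = 1e-3)
})

test_that("posterior trajectory fits within twice the sensor noise", {
  day <- make_day(gpp = 1.5, er = -4.5, k600 = 12, noise_sd = 0.02,
                  seed = 12)
  fit <- fit_day(day, ko2_prior_sd = 0.1 * day$ko2, seed = 4)
  expect_lt(fit$mae, 2 * 0.02)
  expect_true(fit$acceptance_ok)
  expect_equal(fit$summary["sigma", "mean"], 0.02, tolerance = 0.25)
})

test_that("GPP stays effectively positive when the true GPP is large", {
  day <- make_day(gpp = 1.5, er = -4, k600 = 12, noise_sd = 0.01,
                  seed = 13)
  fit <- fit_day(day, ko2_prior_sd = 0.1 * day$ko2, seed = 5)
  expect_lt(mean(fit$draws[, "gpp"] < 0), 0.01)
})

test_that("broadening the K prior inflates the K posterior (equifinality)", {
  day <- make_day(gpp = 1.5, er = -4.5, k600 = 12, noise_sd = 0.1,
                  seed = 14)
  tight <- fit_day(day, ko2_prior_sd = 0.02 * day$ko2, seed = 6)
  broad <- fit_day(day, ko2_prior_sd = 0.2 * day$ko2, seed = 6)
  expect_gt(broad$summary["ko2", "sd"], 1.5 * tight$summary["ko2", "sd"])
})

test_that("an irregular clock is rejected", {
  day <- make_day(gpp = 1, er = -4, k600 = 10, seed = 15)
  day$data$time[10] <- day$data$time[10] + 120
  priors <- metab_priors(ko2_mean = day$ko2, ko2_sd = 1)
  expect_error(metropolis_fit(day$data, priors, n_iter = 100, n_keep = 50),
               "uniform")
})

test_that("carbon conversion of a fit is the 12/32 scaling and keeps NEP additive", {
  day <- make_day(gpp = 0.56, er = -7.0, k600 = 10, noise_sd = 0, seed = 16)
  fit <- fit_day(day, ko2_prior_sd = 0, n_iter = 6000, n_keep = 4000,
                 seed = 7)
  cfit <- daily_rates_to_carbon(fit)
  expect_equal(cfit$summary["gpp", "mean"], 0.21, tolerance = 0.01)
  expect_equal(cfit$summary["er", "mean"], -2.63, tolerance = 0.02)
  expect_equal(cfit$summary["nep", "mean"],
               cfit$summary["gpp", "mean"] + cfit$summary["er", "mean"],
               tolerance = 1e-9)
  expect_identical(cfit$units, "g C")
  # idempotent
  expect_identical(daily_rates_to_carbon(cfit)$summary, cfit$summary)
})
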