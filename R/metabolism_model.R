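# Bayesian inversion of the diel oxygen curve. The model has three process
# parameters per day -- daily gross primary production (GPP), daily
# ecosystem respiration (ER, stored negative) and the O2 gas exchange
# coefficient (KO2) -- plus the observation-error SD, and is fitted by
# component-wise random-walk Metropolis with proposal scales tuned during a
# discarded warm-up phase.

#' Forward diel oxygen model
#'
#' One-step Euler recursion for dissolved O2 driven by photosynthesis,
#' respiration and atmospheric exchange:
#' `O2[t] = O2[t-1] + (GPP/z) * PAR[t-1]/sum(PAR) + ER*dt/z +
#'  KO2 * (O2sat[t-1] - O2[t-1]) * dt`.
#' Daily GPP is distributed over time steps in proportion to PAR; ER is
#' spread uniformly; exchange relaxes the concentration towards saturation.
#' The first observation anchors the trajectory. The recursion is linear in
#' `O2`, so it is evaluated with a fast recursive filter.
#'
#' @param gpp Daily gross primary production (g O2 m^-2 day^-1).
#' @param er Daily ecosystem respiration (g O2 m^-2 day^-1, usually <= 0).
#' @param ko2 O2 gas exchange coefficient (day^-1).
#' @param depth Mean channel depth z (m, > 0).
#' @param par PAR series (any units; only relative weights matter).
#' @param o2sat O2 saturation concentration series (g m^-3), same length.
#' @param dt Time step in days (e.g. `1/144` for 10-minute data).
#' @param o2_init Observed O2 at the first time step (g m^-3).
#' @return Modelled O2 series (g m^-3), same length as `par`.
#' @export
o2_forward <- function(gpp, er, ko2, depth, par, o2sat, dt, o2_init) {
  n <- length(par)
  if (length(o2sat) != n) stop("par and o2sat lengths differ", call. = FALSE)
  if (!is.finite(depth) || depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  sum_par <- sum(par)
  if (gpp != 0 && sum_par <= 0) {
    stop("positive GPP requires positive total PAR", call. = FALSE)
  }
  par_frac <- if (sum_par > 0) par / sum_par else rep(0, n)
  # input at step t uses step t-1 forcing
  u <- gpp / depth * par_frac[-n] + er * dt / depth + ko2 * dt * o2sat[-n]
  phi <- 1 - ko2 * dt
  c(o2_init, stats::filter(u, phi, method = "recursive", init = o2_init))
}

#' Assemble per-day priors for the metabolism model
#'
#' GPP and ER get broad Normal priors (mean 1 and -5 g O2 m^-2 day^-1, SD 2,
#' the weakly informative defaults for small oligotrophic streams); the KO2
#' prior is Normal with mean and SD taken from a fitted gas
#' exchange-discharge relation ([predict.k600_q_relation()]) converted from
#' K600 to KO2 at the day's mean water temperature. A `ko2_sd` of zero fixes
#' KO2 at its prior mean (a point-mass prior). The observation-error SD gets
#' a half-Normal prior.
#'
#' @param gpp_mean,gpp_sd,er_mean,er_sd Normal prior moments for GPP and ER
#'   (g O2 m^-2 day^-1).
#' @param ko2_mean,ko2_sd Normal prior moments for KO2 (day^-1);
#'   `ko2_sd = 0` fixes KO2.
#' @param sigma_scale Scale of the half-Normal prior on the observation
#'   error SD (g O2 m^-3).
#' @return A list of class `"metab_priors"`.
#' @export
metab_priors <- function(gpp_mean = 1, gpp_sd = 2,
                         er_mean = -5, er_sd = 2,
                         ko2_mean, ko2_sd,
                         sigma_scale = 1) {
  stopifnot(gpp_sd > 0, er_sd > 0, ko2_sd >= 0, sigma_scale > 0,
            is.finite(ko2_mean))
  structure(list(gpp_mean = gpp_mean, gpp_sd = gpp_sd,
                 er_mean = er_mean, er_sd = er_sd,
                 ko2_mean = ko2_mean, ko2_sd = ko2_sd,
                 sigma_scale = sigma_scale),
            class = "metab_priors")
}

# Floor on the observation-error SD (g O2 m^-3); keeps the likelihood
# finite on noise-free (synthetic) data.
.SIGMA_FLOOR <- 1e-6

#' Log posterior density of the diel oxygen model
#'
#' Gaussian iid observation-error log-likelihood of the observed O2 series
#' against the [o2_forward()] trajectory, plus Normal prior log-densities
#' for GPP, ER and KO2 and a half-Normal prior for the observation-error SD.
#'
#' @param theta Numeric vector `c(gpp, er, ko2, sigma)`.
#' @param data A list with elements `o2`, `o2sat`, `par`, `depth`, `dt` as
#'   in [o2_forward()] (the first O2 value anchors the trajectory).
#' @param priors A [metab_priors()] object.
#' @return Log posterior density (`-Inf` outside the support).
#' @export
log_posterior <- function(theta, data, priors) {
  gpp <- theta[1]; er <- theta[2]; ko2 <- theta[3]; sigma <- theta[4]
  if (!all(is.finite(theta))) return(-Inf)
  if (sigma < .SIGMA_FLOOR) return(-Inf)
  mu <- o2_forward(gpp, er, ko2, data$depth, data$par, data$o2sat,
                   data$dt, data$o2[1])
  n <- length(data$o2)
  resid <- data$o2 - mu
  ll <- -n * log(sigma) - sum(resid^2) / (2 * sigma^2) - n / 2 * log(2 * pi)
  lp <- stats::dnorm(gpp, priors$gpp_mean, priors$gpp_sd, log = TRUE) +
    stats::dnorm(er, priors$er_mean, priors$er_sd, log = TRUE) +
    stats::dnorm(sigma, 0, priors$sigma_scale, log = TRUE)
  if (priors$ko2_sd > 0) {
    lp <- lp + stats::dnorm(ko2, priors$ko2_mean, priors$ko2_sd, log = TRUE)
  } else if (ko2 != priors$ko2_mean) {
    return(-Inf)
  }
  ll + lp
}

#' Fit one day of diel oxygen data by random-walk Metropolis
#'
#' Component-wise Gaussian random-walk Metropolis over
#' `(GPP, ER, KO2, sigma)`. The first `n_iter - n_keep` iterations are
#' discarded as warm-up, during which each proposal scale is tuned towards
#' a per-component acceptance rate of ~0.44; the last `n_keep` draws are
#' kept and summarized. Initialization is at the prior means, with the
#' observation-error SD started at the residual SD of the prior-mean
#' trajectory so that early exploration is not frozen by an over-tight
#' likelihood.
#'
#' @inheritParams log_posterior
#' @param n_iter Total Metropolis iterations (default 150000).
#' @param n_keep Number of final draws kept (default 100000).
#' @param seed Integer RNG seed; fixed seed gives bit-identical fits.
#' @param day_id Optional identifier carried into the result.
#' @param temp_mean Day-mean water temperature (degC) used to express the
#'   fitted KO2 as K600; if `NULL` no K600 summary is attached.
#' @return An object of class `"day_fit"`: posterior means, SDs and 0.025,
#'   0.05, 0.5, 0.95, 0.975 quantiles for GPP, ER, KO2, sigma and the
#'   derived NEP = GPP + ER (and K600 when `temp_mean` is given); the
#'   posterior-mean O2 trajectory with its mean absolute error; the
#'   acceptance rate over the kept phase (flagged if outside [0.1, 0.6]);
#'   and the kept draws.
#' @export
metropolis_fit <- function(data, priors, n_iter = 150000, n_keep = 100000,
                           seed = 1, day_id = NA, temp_mean = NULL) {
  stopifnot(inherits(priors, "metab_priors"), n_keep < n_iter)
  .check_uniform_clock(data$time)
  n_obs <- length(data$o2)
  if (length(data$par) != n_obs || length(data$o2sat) != n_obs) {
    stop("o2, par and o2sat must have equal length", call. = FALSE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))

  fix_k <- priors$ko2_sd == 0
  theta <- c(priors$gpp_mean, priors$er_mean, priors$ko2_mean, NA)
  mu0 <- o2_forward(theta[1], theta[2], theta[3], data$depth, data$par,
                    data$o2sat, data$dt, data$o2[1])
  theta[4] <- max(stats::sd(data$o2 - mu0), 1e-3)

  lp <- log_posterior(theta, data, priors)
  scales <- c(0.5, 0.5, max(0.1, priors$ko2_sd / 2), theta[4] / 2)
  active <- if (fix_k) c(1, 2, 4) else 1:4
  n_warm <- n_iter - n_keep
  draws <- matrix(NA_real_, n_keep, 4,
                  dimnames = list(NULL, c("gpp", "er", "ko2", "sigma")))
  acc_kept <- 0; prop_kept <- 0
  batch <- 50; acc_batch <- numeric(4); n_batch <- 0

  for (i in seq_len(n_iter)) {
    for (j in active) {
      cand <- theta
      cand[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
      lp_cand <- log_posterior(cand, data, priors)
      if (is.finite(lp_cand) &&
          log(stats::runif(1)) < lp_cand - lp) {
        theta <- cand
        lp <- lp_cand
        if (i <= n_warm) acc_batch[j] <- acc_batch[j] + 1
        else acc_kept <- acc_kept + 1
      }
      if (i > n_warm) prop_kept <- prop_kept + 1
    }
    if (i <= n_warm) {
      n_batch <- n_batch + 1
      if (n_batch == batch) {
        rate <- acc_batch / batch
        adj <- exp(pmin(0.5, pmax(-0.5, rate - 0.44)))
        scales[active] <- scales[active] * adj[active]
        acc_batch[] <- 0; n_batch <- 0
      }
    } else {
      draws[i - n_warm, ] <- theta
    }
  }

  acc_rate <- acc_kept / prop_kept
  qs <- c(0.025, 0.05, 0.5, 0.95, 0.975)
  summarize <- function(x) {
    c(mean = mean(x), sd = stats::sd(x), stats::quantile(x, qs, names = TRUE))
  }
  nep <- draws[, "gpp"] + draws[, "er"]
  summ <- rbind(gpp = summarize(draws[, "gpp"]),
                er = summarize(draws[, "er"]),
                ko2 = summarize(draws[, "ko2"]),
                sigma = summarize(draws[, "sigma"]),
                nep = summarize(nep))
  if (!is.null(temp_mean)) {
    k600 <- kgas_to_k600(pmax(draws[, "ko2"], 0), schmidt_o2(temp_mean))
    summ <- rbind(summ, k600 = summarize(k600))
  }
  mu_hat <- o2_forward(mean(draws[, "gpp"]), mean(draws[, "er"]),
                       mean(draws[, "ko2"]), data$depth, data$par,
                       data$o2sat, data$dt, data$o2[1])
  structure(list(day_id = day_id,
                 summary = summ,
                 mae = mean(abs(data$o2 - mu_hat)),
                 modelled_o2 = mu_hat,
                 acceptance_rate = acc_rate,
                 acceptance_ok = acc_rate >= 0.1 && acc_rate <= 0.6,
                 n_kept = n_keep,
                 units = "g O2",
                 temp_mean = temp_mean,
                 draws = draws),
            class = "day_fit")
}

#' @export
print.day_fit <- function(x, ...) {
  cat("Diel O2 metabolism fit", if (!is.na(x$day_id)) paste0("(", x$day_id, ")"),
      "\n")
  cat(sprintf("  units: %s m^-2 day^-1 (rates); MAE %.4f g O2 m^-3; acc %.2f%s\n",
              x$units, x$mae, x$acceptance_rate,
              if (x$acceptance_ok) "" else " [outside 0.1-0.6]"))
  print(round(x$summary, 3))
  invisible(x)
}

#' Convert a day fit from oxygen to carbon units
#'
#' Applies the 1:1 molar O2:CO2 conversion (multiply by 12/32) to the GPP,
#' ER, NEP summaries of a [metropolis_fit()] result. NEP remains GPP + ER
#' after conversion (linearity).
#'
#' @param fit A `"day_fit"` object in g O2 units.
#' @return The fit with GPP, ER and NEP summaries in g C m^-2 day^-1 and
#'   the units flag flipped.
#' @export
daily_rates_to_carbon <- function(fit) {
  stopifnot(inherits(fit, "day_fit"))
  if (identical(fit$units, "g C")) return(fit)
  for (row in c("gpp", "er", "nep")) {
    fit$summary[row, ] <- o2_to_carbon(fit$summary[row, ])
  }
  fit$units <- "g C"
  fit
}
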