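# Shared builders for simulated site-days and deployments. All fixtures
# are generated in code under fixed seeds; MCMC iteration counts are kept
# modest (the sampler mixes quickly on single well-identified days).

# One simulated site-day with known truth: diel PAR at the study latitude,
# sinusoidal temperature, Euler O2 recursion plus iid noise.
make_day <- function(gpp, er, k600, depth = 0.3, noise_sd = 0.005,
                     date = "2015-08-05", lat = 68.35, lon = 18.94,
                     temp_mean = 7, temp_amplitude = 1.5,
                     pressure = 0.92, timestep_min = 10, seed = 1) {
  set.seed(seed)
  par_df <- simulate_par(lat, lon, date, timestep_min)
  n <- nrow(par_df)
  hours <- seq(0, by = timestep_min / 60, length.out = n)
  temp <- temp_mean + temp_amplitude * sin(2 * pi * (hours - 9) / 24)
  o2sat <- o2_saturation(temp, pressure)
  dt <- timestep_min / 1440
  ko2 <- k600_to_kgas(k600, schmidt_o2(mean(temp)))
  o2_clean <- o2_forward(gpp, er, ko2, depth, par_df$par, o2sat, dt,
                         o2sat[1] + er / (ko2 * depth))
  o2 <- o2_clean + stats::rnorm(n, 0, noise_sd)
  list(data = list(time = par_df$time, o2 = o2, o2sat = o2sat,
                   par = par_df$par, depth = depth, dt = dt),
       o2_clean = o2_clean, temp = temp, ko2 = ko2,
       truth = list(gpp = gpp, er = er, k600 = k600, ko2 = ko2,
                    noise_sd = noise_sd))
}

# A single synthetic night of pure reaeration (optionally with constant
# respiration): constant temperature, no light.
make_night <- function(ko2, er = -4, depth = 0.4, n = 60, temp = 8,
                       dt = 1 / 144, deficit0 = 1.5, noise_sd = 0) {
  o2sat <- o2_saturation(rep(temp, n), 1)
  o2 <- o2_forward(0, er, ko2, depth, rep(0, n), o2sat, dt,
                   o2sat[1] - deficit0)
  if (noise_sd > 0) o2 <- o2 + stats::rnorm(n, 0, noise_sd)
  list(o2 = o2, o2sat = o2sat, temp = rep(temp, n), dt = dt)
}

# Fit one day with reduced iteration counts (warm-up 10000, kept 20000).
fit_day <- function(day, ko2_prior_mean = day$truth$ko2, ko2_prior_sd,
                    n_iter = 30000, n_keep = 20000, seed = 1) {
  priors <- metab_priors(ko2_mean = ko2_prior_mean, ko2_sd = ko2_prior_sd)
  metropolis_fit(day$data, priors, n_iter = n_iter, n_keep = n_keep,
                 seed = seed, temp_mean = mean(day$temp))
}

# Lazily computed 12-day pipeline fixture shared across test files.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- deployment_config(n_days = 12, start_date = "2015-08-03",
                             spate_days = 6)
    dep <- simulate_deployment(cfg, seed = 21)
    res <- run_pipeline(dep$series,
                        site_config(n_iter = 8000, n_keep = 5000, seed = 5))
    cache <<- list(dep = dep, res = res)
    cache
  }
})
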