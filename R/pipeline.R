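# End-to-end orchestration: sensor series in, one row per site-day out
# (metabolic rates in g C, gas exchange, evasion and diel metrics, QC
# flags), plus the site-level report of means and quantiles.

#' Pipeline configuration for one site
#'
#' Defaults are the method's standard constants: MAE threshold 0.2 g O2
#' m^-3, within-day depth change threshold 10%, night-regression R^2
#' threshold 0.7, minimum night length 2 h, and 150000 Metropolis
#' iterations per day of which the last 100000 are kept.
#'
#' @param site Site identifier.
#' @param lat,lon Site coordinates (decimal degrees).
#' @param mae_max,depth_max_pct,r2_min,min_night_hours Quality-control and
#'   night-regression thresholds.
#' @param n_iter,n_keep Metropolis iteration counts per day.
#' @param co2_atm_ppm Atmospheric reference pCO2 (ppm).
#' @param seed Base RNG seed; each day uses `seed + day index`.
#' @return A list of class `"site_config"`.
#' @export
site_config <- function(site = "S1", lat = 68.35, lon = 18.94,
                        mae_max = 0.2, depth_max_pct = 10,
                        r2_min = 0.7, min_night_hours = 2,
                        n_iter = 150000, n_keep = 100000,
                        co2_atm_ppm = 380, seed = 1) {
  structure(as.list(environment()), class = "site_config")
}

#' Run the full inference chain on one site's sensor series
#'
#' Stages: (1) nightly K600 by staggered night-time regressions and the
#' site K600-discharge relation; (2) per-day Bayesian diel O2 fits with
#' the discharge-informed K prior; (3) day-level quality control; (4) CO2
#' evasion and diel metrics. Discharge is taken from the `discharge`
#' column when present, otherwise from a rating curve fitted to
#' `rating_pairs`.
#'
#' @param series Sensor data.frame (`time`, `o2`, `pco2`, `temperature`,
#'   `depth`, `par`, `pressure`, optionally `discharge`; uniform clock).
#' @param config A [site_config()].
#' @param rating_pairs Optional data.frame with `depth` and `discharge`
#'   columns for the rating curve (required when `series` has no
#'   `discharge` column).
#' @param k600_q Optional pre-fitted [fit_k600_q()] relation; when `NULL`
#'   it is estimated from the series itself.
#' @return A list of class `"pipeline_result"` with `daily` (one row per
#'   day: GPP, ER, NEP in g C m^-2 day^-1 with 90% credible bounds, K600,
#'   evasion and diel metrics, QC columns), `k600_q`, `qc` report, `fits`
#'   (kept day fits, carbon units) and `config`.
#' @export
run_pipeline <- function(series, config = site_config(),
                         rating_pairs = NULL, k600_q = NULL) {
  required <- c("time", "o2", "pco2", "temperature", "depth", "par",
                "pressure")
  missing <- setdiff(required, names(series))
  if (length(missing)) {
    stop("series is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  .check_uniform_clock(series$time)
  dt <- as.numeric(difftime(series$time[2], series$time[1], units = "days"))
  dates <- .utc_date(series$time)
  days <- unique(dates)

  if (!"discharge" %in% names(series)) {
    if (is.null(rating_pairs)) {
      stop("series has no discharge column and no rating_pairs given",
           call. = FALSE)
    }
    rating <- fit_rating_curve(rating_pairs$depth, rating_pairs$discharge)
    if (!rating$accepted) {
      warning("rating curve R^2 below threshold; discharge is uncertain")
    }
    series$discharge <- predict(rating, series$depth)
  }

  # --- stage 1: gas exchange from night-time regressions -----------------
  if (is.null(k600_q)) {
    nightly <- list()
    for (d in days) {
      est <- nightly_k600(series, as.Date(d), config$lat, config$lon,
                          r2_min = config$r2_min,
                          min_night_hours = config$min_night_hours)
      if (!is.null(est)) {
        nightly[[length(nightly) + 1]] <-
          data.frame(date = as.Date(d), k600 = est$k600,
                     r_squared = est$r_squared,
                     discharge = mean(series$discharge[dates == d]))
      }
    }
    if (length(nightly) < 3) {
      stop("fewer than 3 nightly K600 estimates; cannot build K prior",
           call. = FALSE)
    }
    nightly <- do.call(rbind, nightly)
    k600_q <- fit_k600_q(nightly$k600, nightly$discharge)
  }

  # --- stage 2: per-day Bayesian metabolism fits -------------------------
  fits <- list()
  for (i in seq_along(days)) {
    sel <- dates == days[i]
    if (sum(sel) * dt < 0.99) next # incomplete day
    day <- series[sel, ]
    o2sat <- o2_saturation(day$temperature, day$pressure)
    kq <- predict(k600_q, mean(day$discharge))
    tmean <- mean(day$temperature)
    sc <- schmidt_o2(tmean)
    priors <- metab_priors(ko2_mean = k600_to_kgas(max(kq$mean, 0.1), sc),
                           ko2_sd = max(kq$sd, 1e-8) * (600 / sc)^0.5)
    data <- list(time = day$time, o2 = day$o2, o2sat = o2sat,
                 par = day$par, depth = mean(day$depth), dt = dt)
    fits[[length(fits) + 1]] <-
      metropolis_fit(data, priors, n_iter = config$n_iter,
                     n_keep = config$n_keep,
                     seed = config$seed + i, day_id = days[i],
                     temp_mean = tmean)
  }
  if (!length(fits)) stop("no complete days to fit", call. = FALSE)

  # --- stage 3: quality control ------------------------------------------
  qc <- apply_qc(fits, series, mae_max = config$mae_max,
                 depth_max_pct = config$depth_max_pct)

  # --- stage 4: CO2 evasion and diel metrics -----------------------------
  # evasion uses the same gas exchange as the metabolism model: each day's
  # posterior-mean K600 where a fit exists, the K600-Q prediction elsewhere
  k600_series <- pmax(predict(k600_q, series$discharge)$mean, 0.1)
  for (fit in fits) {
    k600_series[dates == as.Date(fit$day_id)] <- fit$summary["k600", "mean"]
  }
  flux <- co2_flux_metrics(series, k600_series, config$lat,
                           config$lon, config$co2_atm_ppm)

  kept <- lapply(qc$kept, daily_rates_to_carbon)
  daily <- do.call(rbind, lapply(kept, function(fit) {
    s <- fit$summary
    fd <- flux$daily[flux$daily$date == as.Date(fit$day_id), ]
    data.frame(site = config$site, date = as.Date(fit$day_id),
               gpp = s["gpp", "mean"],
               gpp_q05 = s["gpp", "5%"], gpp_q95 = s["gpp", "95%"],
               er = s["er", "mean"],
               er_q05 = s["er", "5%"], er_q95 = s["er", "95%"],
               nep = s["nep", "mean"],
               nep_q05 = s["nep", "5%"], nep_q95 = s["nep", "95%"],
               k600 = s["k600", "mean"],
               mae = fit$mae,
               acceptance = fit$acceptance_rate,
               evasion = fd$evasion, delta_co2 = fd$delta_co2,
               diel_change = fd$diel_change,
               noon = fd$noon, midnight = fd$midnight)
  }))
  structure(list(daily = daily, k600_q = k600_q, qc = qc$report,
                 fits = kept, flux = flux, config = config),
            class = "pipeline_result")
}

#' Site-level summary of daily results
#'
#' One row per site: day count, means and 0.05-0.95 quantiles (type-7
#' linear interpolation) of NEP, GPP, ER and evasion, mean noon and
#' midnight evasion, and the median per-day NEP/evasion fraction (percent
#' of evasion accounted for by net ecosystem production).
#'
#' @param daily A daily results table as produced by [run_pipeline()]
#'   (`site`, `nep`, `gpp`, `er`, `evasion`, `noon`, `midnight` columns);
#'   several sites may be stacked.
#' @return A data.frame with one row per site.
#' @export
report <- function(daily) {
  stopifnot(is.data.frame(daily), nrow(daily) >= 1)
  q <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))
  do.call(rbind, lapply(split(daily, daily$site), function(d) {
    data.frame(site = d$site[1], n_days = nrow(d),
               nep = mean(d$nep), nep_q05 = q(d$nep, 0.05),
               nep_q95 = q(d$nep, 0.95),
               gpp = mean(d$gpp), gpp_q05 = q(d$gpp, 0.05),
               gpp_q95 = q(d$gpp, 0.95),
               er = mean(d$er), er_q05 = q(d$er, 0.05),
               er_q95 = q(d$er, 0.95),
               evasion = mean(d$evasion),
               evasion_noon = mean(d$noon, na.rm = TRUE),
               evasion_midnight = mean(d$midnight, na.rm = TRUE),
               nep_evasion_pct = stats::median(100 * -d$nep / d$evasion,
                                               na.rm = TRUE))
  }))
}
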