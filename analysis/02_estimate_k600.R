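#!/usr/bin/env Rscript
# Estimate gas exchange from the simulated sensor records: staggered
# night-time regressions on each night with a >2 h night and regression
# R^2 > 0.7, then the site-level K600-discharge relation that will supply
# the daily K priors of the metabolism model.

library(dielcarbon)

lat <- 68.35; lon <- 18.94
dir.create("results", showWarnings = FALSE)

for (site in c("low_k", "high_k")) {
  ser <- read_sensor_csv(sprintf("scratch/deployments/%s_sensors.csv", site))
  dates <- unique(as.Date(ser$time, tz = "UTC"))
  rows <- list()
  for (d in dates) {
    est <- nightly_k600(ser, as.Date(d), lat, lon)
    if (!is.null(est)) {
      rows[[length(rows) + 1]] <- data.frame(
        date = as.Date(d), k600 = est$k600, r_squared = est$r_squared,
        night_hours = est$night_hours,
        discharge = mean(ser$discharge[as.Date(ser$time, tz = "UTC") == d]))
    }
  }
  nightly <- do.call(rbind, rows)
  rel <- fit_k600_q(nightly$k600, nightly$discharge)
  utils::write.csv(nightly, sprintf("results/%s_nightly_k600.csv", site),
                   row.names = FALSE)
  jsonlite::write_json(rel[c("intercept", "slope", "slope_se",
                             "residual_sd", "r_squared", "n")],
                       sprintf("results/%s_k600_q.json", site),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d/%d nights gave K600; K600 = %.1f + %.0f Q, resid SD %.2f /d\n",
              site, nrow(nightly), length(dates), rel$intercept, rel$slope,
              rel$residual_sd))
}
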