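#!/usr/bin/env Rscript
# Simulate two contrasting virtual sensor deployments -- a low-turbulence
# stream with a large groundwater CO2 subsidy (M16-like) and a more
# turbulent, better-flushed stream (M6-like) -- and write their sensor
# series plus ground-truth ledgers. Everything downstream of this script
# works from the CSVs alone; the truth ledgers are used only to judge
# recovery.

library(dielcarbon)

out_dir <- "scratch/deployments"
cond <- site_conditions_table()

sites <- list(
  # low K600, strong diel pCO2 signal, groundwater-supported supersaturation
  low_k = deployment_config(
    site = "low_k", elevation = cond$elevation_m[cond$site == "M16"],
    start_date = "2015-07-28", n_days = 20, q_ar1_sd = 0.5,
    q_base = cond$discharge_ls[cond$site == "M16"] / 1000,
    k600_intercept = 4, k600_slope = 40, k600_resid_sd = 1,
    temp_mean = cond$temperature_c[cond$site == "M16"],
    co2_gw_flux = 1.0, co2_init_ppm = cond$pco2_ppm[cond$site == "M16"]),
  # high K600, weak diel pCO2 signal, small groundwater input
  high_k = deployment_config(
    site = "high_k", elevation = cond$elevation_m[cond$site == "M6"],
    start_date = "2015-07-28", n_days = 20, q_ar1_sd = 0.5,
    q_base = cond$discharge_ls[cond$site == "M6"] / 1000,
    k600_intercept = 18, k600_slope = 60, k600_resid_sd = 2,
    temp_mean = cond$temperature_c[cond$site == "M6"],
    co2_gw_flux = 0.2, co2_init_ppm = cond$pco2_ppm[cond$site == "M6"]))

for (nm in names(sites)) {
  dep <- simulate_deployment(sites[[nm]], seed = match(nm, names(sites)))
  paths <- write_deployment(dep, out_dir)
  cat(sprintf("%s: %d days, K600 %.1f-%.1f /d, pCO2 %.0f-%.0f ppm -> %s\n",
              nm, nrow(dep$truth), min(dep$truth$k600), max(dep$truth$k600),
              min(dep$series$pco2), max(dep$series$pco2), paths["series"]))
}
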