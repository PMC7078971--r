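# Published site-level summaries from a multi-year sensor campaign in six
# streams of the Miellajokka catchment (northern Sweden): per-site day
# counts, metabolic rates and CO2 evasion (g C m^-2 day^-1, 0.05-0.95
# quantiles), and the physical/chemical site conditions. These tables are
# worked-example inputs: they let the reporting arithmetic (NEP identity,
# day-count-weighted cross-site means) be checked against reported values
# without access to the raw sensor records, and they parameterize
# realistic synthetic deployments.

#' Published site summary table
#'
#' Site-level means of NEP, GPP, ER and CO2 evasion (g C m^-2 day^-1, with
#' 0.05-0.95 quantiles) and the noon/midnight evasion rates for six
#' monitored subarctic streams, with the number of quality-controlled
#' metabolism days per site.
#'
#' @return A data.frame with one row per site.
#' @export
site_summary_table <- function() {
  utils::read.csv(system.file("extdata", "miellajokka_site_summary.csv",
                              package = "dielcarbon"),
                  stringsAsFactors = FALSE)
}

#' Published site conditions table
#'
#' Elevation, catchment area, stream order and the campaign means (with
#' 0.05-0.95 quantiles) of discharge, water temperature and pCO2 for the
#' same six streams.
#'
#' @return A data.frame with one row per site.
#' @export
site_conditions_table <- function() {
  utils::read.csv(system.file("extdata", "miellajokka_site_conditions.csv",
                              package = "dielcarbon"),
                  stringsAsFactors = FALSE)
}

#' Day-count-weighted cross-site mean of a summary column
#'
#' Cross-site averages weight each site by its number of retained
#' metabolism days, i.e. they are means over site-days.
#'
#' @param tbl A site summary table ([site_summary_table()] or a [report()]
#'   result) with an `n_days` column.
#' @param column Name of the column to average.
#' @return The weighted mean.
#' @export
weighted_site_mean <- function(tbl, column) {
  stopifnot("n_days" %in% names(tbl), column %in% names(tbl))
  sum(tbl[[column]] * tbl$n_days) / sum(tbl$n_days)
}

#' Recompute NEP from GPP and signed ER
#'
#' The identity `NEP = GPP + ER` (ER stored negative), applied to a site
#' summary table; used to verify the internal consistency of reported
#' site means at their printed precision.
#'
#' @param tbl A site summary table with `gpp` and `er` columns.
#' @return Numeric vector of recomputed NEP values, named by site.
#' @export
nep_from_components <- function(tbl) {
  stopifnot(all(c("gpp", "er") %in% names(tbl)))
  stats::setNames(tbl$gpp + tbl$er, tbl$site)
}
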