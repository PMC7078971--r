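# Day-level quality control of fitted metabolism days: goodness of fit of
# the modelled O2 trajectory and stability of depth (the proxy for K600,
# which the diel model assumes constant within a day).

#' Mean absolute error between observed and modelled series
#'
#' @param observed,modelled Numeric vectors of equal length.
#' @return Mean of absolute differences (g O2 m^-3 for O2 series).
#' @export
mae <- function(observed, modelled) {
  if (length(observed) != length(modelled)) {
    stop("observed and modelled must have equal length", call. = FALSE)
  }
  mean(abs(observed - modelled))
}

#' Within-day relative depth range
#'
#' `100 * (max - min) / mean` of the day's depth series: the percentage by
#' which depth changed within the day. Days above the threshold violate
#' the constant-depth (and constant-K600) assumption of the diel model.
#'
#' @param depth Positive depth series (m).
#' @return Relative range in percent.
#' @export
depth_stability <- function(depth) {
  if (any(!is.finite(depth)) || any(depth <= 0)) {
    stop("depth must be finite and > 0", call. = FALSE)
  }
  100 * (max(depth) - min(depth)) / mean(depth)
}

#' Apply the day-level quality filters
#'
#' A day is kept only if (a) the MAE of the posterior-mean O2 trajectory is
#' at most `mae_max` (strictly larger discards) and (b) depth changed by at
#' most `depth_max_pct` percent within the day (strictly larger discards).
#' Both bounds are inclusive: a day exactly at a threshold is kept.
#'
#' @param fits A list of `"day_fit"` objects ([metropolis_fit()]).
#' @param series Sensor data.frame covering the fitted days (`time`,
#'   `depth` columns).
#' @param mae_max MAE threshold (g O2 m^-3).
#' @param depth_max_pct Depth relative-range threshold (percent).
#' @return A list with `kept` (the retained fits) and `report`, a
#'   data.frame with one row per day: `day_id`, `mae`, `depth_range_pct`,
#'   pass flags per rule and the overall `keep` decision.
#' @export
apply_qc <- function(fits, series, mae_max = 0.2, depth_max_pct = 10) {
  stopifnot(length(fits) >= 1)
  dates <- .utc_date(series$time)
  rows <- lapply(fits, function(fit) {
    day_depth <- series$depth[dates == as.Date(fit$day_id)]
    if (!length(day_depth)) {
      stop("no depth data for day ", fit$day_id, call. = FALSE)
    }
    dr <- depth_stability(day_depth)
    data.frame(day_id = as.character(fit$day_id),
               mae = fit$mae,
               depth_range_pct = dr,
               mae_ok = fit$mae <= mae_max,
               depth_ok = dr <= depth_max_pct,
               keep = fit$mae <= mae_max && dr <= depth_max_pct)
  })
  report <- do.call(rbind, rows)
  list(kept = fits[report$keep], report = report)
}
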