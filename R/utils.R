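# Shared clock and table helpers.

# A sensor series clock must be strictly increasing and uniform. `time`
# may be NULL (e.g. in purely synthetic fits where only dt matters).
.check_uniform_clock <- function(time, tol = 1e-6) {
  if (is.null(time)) return(invisible(NULL))
  if (length(time) < 2) return(invisible(time))
  dt <- as.numeric(diff(as.numeric(time)))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > tol * stats::median(dt)) {
    stop("time series must have a uniform time step", call. = FALSE)
  }
  invisible(time)
}

# Civil date (UTC) of each timestamp.
.utc_date <- function(time) as.Date(time, tz = "UTC")

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample SD.
#'
#' @param x Numeric vector (mean must be non-zero).
#' @return CV in percent.
#' @examples
#' cv_percent(c(2, 4)) # 47.1
#' @export
cv_percent <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) stop("mean of x must be non-zero", call. = FALSE)
  100 * stats::sd(x) / m
}
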