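#' Most active window of a day
#'
#' Slides a fixed-length window (default 10 h) across one civil day of
#' epochs, one epoch at a time, and returns the window maximising the chosen
#' activity metric; ties break to the earliest start. Non-wear epochs
#' contribute zero. The sliding sum is computed incrementally via cumulative
#' sums; windows do not wrap past midnight unless `wrap = TRUE`.
#'
#' Metrics: `tpa_minutes` counts wear epochs at or above the light cut-off
#' (total physical activity time, minutes); `enmo_sum` sums wear-epoch ENMO.
#'
#' @param epochs `epoch_series` for one civil day with full coverage.
#' @param length_hours window length, hours (< 24).
#' @param metric `"tpa_minutes"` or `"enmo_sum"`.
#' @param scheme a [cutoff_scheme()] (defines the TPA threshold).
#' @param wrap allow windows crossing midnight (treats the day as circular).
#' @return list of class `window_result`: `date`, `window_start`,
#'   `midpoint` (seconds since midnight), `window_start_clock`,
#'   `midpoint_clock`, `length_hours`, `metric`, `value`.
#' @export
most_active_window <- function(epochs, length_hours = 10,
                               metric = c("tpa_minutes", "enmo_sum"),
                               scheme = cutoff_scheme(), wrap = FALSE) {
  metric <- match.arg(metric)
  if (length_hours >= 24) stop("window length must be < 24 h", call. = FALSE)
  el <- epoch_len(epochs)
  dates <- unique(as.Date(epochs$time))
  if (length(dates) != 1L) stop("epochs span more than one civil day", call. = FALSE)
  n <- nrow(epochs)
  wlen <- as.integer(round(length_hours * 3600 / el))
  if (wlen > n) stop("window longer than the day's epoch coverage", call. = FALSE)

  x <- if (metric == "tpa_minutes") {
    as.numeric(epochs$wear & epochs$enmo >= scheme$light) * el / 60
  } else {
    ifelse(epochs$wear, epochs$enmo, 0)
  }
  if (wrap) x <- c(x, x[seq_len(wlen - 1L)])
  cs <- cumsum(c(0, x))
  n_starts <- if (wrap) n else n - wlen + 1L
  sums <- cs[(wlen + 1L):(wlen + n_starts)] - cs[1:n_starts]
  best <- which.max(sums)                 # ties -> earliest start
  start_sec <- (best - 1L) * el
  mid_sec <- (start_sec + length_hours * 3600 / 2) %% 86400
  structure(list(
    date = dates, window_start = start_sec, midpoint = mid_sec,
    window_start_clock = clock_time(start_sec),
    midpoint_clock = clock_time(mid_sec),
    length_hours = length_hours, metric = metric, value = sums[best]
  ), class = "window_result")
}

#' @export
print.window_result <- function(x, ...) {
  cat(sprintf("<window_result> %s: most active %g h window starts %s (midpoint %s), %s = %.2f\n",
              format(x$date), x$length_hours, x$window_start_clock,
              x$midpoint_clock, x$metric, x$value))
  invisible(x)
}

#' Histogram of most-active-window midpoints
#'
#' Bins midpoints into half-open clock-time bins `[t, t + bin)`.
#'
#' @param results list of `window_result` objects, or a numeric vector of
#'   midpoints in seconds since midnight.
#' @param bin bin width, minutes.
#' @return data.frame: `bin_start` (seconds), `bin_start_clock`, `count`.
#' @export
midpoint_histogram <- function(results, bin = 30) {
  mids <- if (is.numeric(results)) results
          else vapply(results, function(r) r$midpoint, numeric(1))
  bw <- bin * 60
  edges <- seq(0, 86400 - bw, by = bw)
  idx <- findInterval(mids, c(edges, 86400))
  counts <- tabulate(idx, nbins = length(edges))
  data.frame(bin_start = edges, bin_start_clock = clock_time(edges),
             count = counts)
}
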