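#' Construct a raw triaxial recording
#'
#' The container every downstream stage consumes: per-sample acceleration in
#' gravitational units (g) on three axes at a fixed sampling rate.
#'
#' @param start_time POSIXct start of the recording (local civil time).
#' @param fs sampling frequency in Hz.
#' @param x,y,z numeric vectors of equal length, acceleration in g.
#' @param device_id free-text device label.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(start_time, fs, x, y, z, device_id = "synthetic") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (length(x) != length(y) || length(y) != length(z)) {
    stop("axis vectors must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || anyNA(z) ||
      !all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop("acceleration samples must be finite", call. = FALSE)
  }
  structure(
    list(start_time = as.POSIXct(start_time, tz = "UTC"), fs = fs,
         x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         device_id = device_id),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s | %g Hz | %d samples (%.2f h) | device %s\n",
              format(x$start_time, "%Y-%m-%d %H:%M:%S"), x$fs,
              length(x$x), length(x$x) / x$fs / 3600, x$device_id))
  invisible(x)
}

#' Per-sample ENMO (Euclidean Norm Minus One)
#'
#' `max(sqrt(x^2 + y^2 + z^2) - 1, 0)`: the vector magnitude of triaxial
#' acceleration corrected for gravity, negatives rounded to zero. Vectorised
#' over samples.
#'
#' @param x,y,z acceleration in g.
#' @return ENMO in g, same length as the inputs.
#' @examples
#' enmo_sample(0, 0, 1)        # 0: resting under gravity
#' enmo_sample(1, 1, 1)        # sqrt(3) - 1
#' @export
enmo_sample <- function(x, y, z) {
  if (anyNA(x) || anyNA(y) || anyNA(z) ||
      !all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop("non-finite input to enmo_sample", call. = FALSE)
  }
  pmax(sqrt(x^2 + y^2 + z^2) - 1, 0)
}

#' Aggregate a raw recording into an ENMO epoch series
#'
#' Per-sample ENMO averaged over fixed epochs (default 5 s). Negative values
#' are truncated per sample before averaging (`truncate_per = "sample"`,
#' the default); the `"epoch"` alternative averages the signed magnitude
#' minus one and truncates the epoch mean. Trailing samples that do not fill
#' a whole epoch are dropped.
#'
#' @param rec a [raw_recording()].
#' @param epoch_length epoch duration in seconds.
#' @param truncate_per `"sample"` or `"epoch"`.
#' @return an `epoch_series`: a data.frame with columns `time` (epoch start,
#'   POSIXct), `enmo` (g), `wear` (logical, all `TRUE` until
#'   [detect_nonwear()] is applied), `sleep` (logical, `NA` until annotated);
#'   attributes `epoch_length` and `fs`.
#' @export
epoch_aggregate <- function(rec, epoch_length = 5, truncate_per = c("sample", "epoch")) {
  stopifnot(inherits(rec, "raw_recording"))
  truncate_per <- match.arg(truncate_per)
  spe <- rec$fs * epoch_length            # samples per epoch
  if (abs(spe - round(spe)) > 1e-9) {
    stop("fs * epoch_length must be an integer number of samples", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  n <- length(rec$x)
  if (n < spe) stop("recording shorter than one epoch", call. = FALSE)
  n_epochs <- n %/% spe
  keep <- seq_len(n_epochs * spe)
  mag1 <- sqrt(rec$x[keep]^2 + rec$y[keep]^2 + rec$z[keep]^2) - 1
  if (truncate_per == "sample") {
    enmo <- colMeans(matrix(pmax(mag1, 0), nrow = spe))
  } else {
    enmo <- pmax(colMeans(matrix(mag1, nrow = spe)), 0)
  }
  epoch_series(
    time = rec$start_time + (seq_len(n_epochs) - 1L) * epoch_length,
    enmo = enmo, epoch_length = epoch_length, fs = rec$fs
  )
}

#' Construct an epoch series directly
#'
#' Mostly used by tests and the synthetic-data module to build epoch-level
#' fixtures without a raw signal.
#'
#' @param time POSIXct epoch start times.
#' @param enmo non-negative ENMO per epoch (g).
#' @param wear logical wear flag per epoch.
#' @param sleep logical sleep flag per epoch (NA = not annotated).
#' @param epoch_length epoch duration in seconds.
#' @param fs originating sampling rate (informational).
#' @return an `epoch_series` data.frame.
#' @export
epoch_series <- function(time, enmo, wear = TRUE, sleep = NA,
                         epoch_length = 5, fs = NA_real_) {
  if (any(enmo < 0)) stop("enmo must be non-negative", call. = FALSE)
  df <- data.frame(time = as.POSIXct(time, tz = "UTC"), enmo = enmo,
                   wear = rep_len(as.logical(wear), length(enmo)),
                   sleep = rep_len(as.logical(sleep), length(enmo)))
  attr(df, "epoch_length") <- epoch_length
  attr(df, "fs") <- fs
  class(df) <- c("epoch_series", "data.frame")
  df
}

epoch_len <- function(epochs) attr(epochs, "epoch_length") %||% 5

#' Detect non-wear periods from raw signal variance
#'
#' A sliding long window (default 60 min, sliding by 15 min) is classified
#' non-wear when at least `min_axes` axes have per-axis standard deviation
#' below `sd_thresh` OR per-axis value range below `range_thresh` (strict
#' inequalities). An epoch is non-wear when any non-wear window covers it.
#' A final window aligned to the end of the recording is always evaluated so
#' the tail is covered.
#'
#' @param rec a [raw_recording()].
#' @param epochs the `epoch_series` from [epoch_aggregate()] to flag.
#' @param window window length, minutes.
#' @param step slide step, minutes.
#' @param sd_thresh per-axis standard deviation threshold, g.
#' @param range_thresh per-axis range (max - min) threshold, g.
#' @param min_axes number of axes that must look static.
#' @return `epochs` with its `wear` column updated (`FALSE` = non-wear).
#' @export
detect_nonwear <- function(rec, epochs, window = 60, step = 15,
                           sd_thresh = 0.013, range_thresh = 0.050,
                           min_axes = 2) {
  stopifnot(inherits(rec, "raw_recording"))
  if (window < step) stop("non-wear window must be >= step", call. = FALSE)
  n <- length(rec$x)
  wlen <- as.integer(round(window * 60 * rec$fs))
  slen <- as.integer(round(step * 60 * rec$fs))
  if (n <= wlen) stop("recording not longer than one non-wear window", call. = FALSE)
  starts <- seq.int(1L, n - wlen + 1L, by = slen)
  if (tail(starts, 1L) != n - wlen + 1L) starts <- c(starts, n - wlen + 1L)

  axes <- list(rec$x, rec$y, rec$z)
  nonwear_mask <- logical(n)
  for (s in starts) {
    idx <- s:(s + wlen - 1L)
    static_axes <- 0L
    for (a in axes) {
      seg <- a[idx]
      if (sd(seg) < sd_thresh || (max(seg) - min(seg)) < range_thresh) {
        static_axes <- static_axes + 1L
      }
    }
    if (static_axes >= min_axes) nonwear_mask[idx] <- TRUE
  }

  spe <- as.integer(round(rec$fs * epoch_len(epochs)))
  n_epochs <- nrow(epochs)
  mask <- nonwear_mask[seq_len(n_epochs * spe)]
  epoch_hit <- colSums(matrix(mask, nrow = spe)) > 0
  epochs$wear <- epochs$wear & !epoch_hit
  epochs
}

#' Simplified gravity-referenced calibration check
#'
#' Stand-in for full accelerometer auto-calibration: static windows (10-s
#' windows with per-axis SD < 0.013 g) are located; if at least
#' `min_windows` exist and span at least two distinct orientations
#' (pairwise angle > 10 degrees), per-axis offset and gain are fitted by
#' iterated least squares so static-window mean vectors approach unit norm,
#' and the corrected recording is returned. Otherwise the recording is
#' returned unchanged with `applied = FALSE`. No temperature compensation.
#'
#' @param rec a [raw_recording()].
#' @param static_sd SD threshold defining a static window, g.
#' @param min_windows minimum static windows required.
#' @param n_iter least-squares refinement passes.
#' @return list with elements `rec` (possibly corrected) and `report`
#'   (offsets, gains, n_static_windows, applied).
#' @export
simple_calibrate <- function(rec, static_sd = 0.013, min_windows = 10, n_iter = 200) {
  stopifnot(inherits(rec, "raw_recording"))
  wlen <- as.integer(round(10 * rec$fs))      # 10-s static windows
  n <- length(rec$x)
  n_win <- n %/% wlen
  report <- list(offset = c(x = 0, y = 0, z = 0), gain = c(x = 1, y = 1, z = 1),
                 n_static_windows = 0L, applied = FALSE)
  if (n_win < min_windows) return(list(rec = rec, report = report))

  dim3 <- function(v) matrix(v[seq_len(n_win * wlen)], nrow = wlen)
  mx <- dim3(rec$x); my <- dim3(rec$y); mz <- dim3(rec$z)
  sds <- cbind(apply(mx, 2, sd), apply(my, 2, sd), apply(mz, 2, sd))
  static <- rowSums(sds < static_sd) == 3L
  report$n_static_windows <- sum(static)
  if (report$n_static_windows < min_windows) return(list(rec = rec, report = report))

  M <- cbind(colMeans(mx)[static], colMeans(my)[static], colMeans(mz)[static])
  # orientation diversity: max pairwise angle among unit mean vectors > 10 deg
  U <- M / sqrt(rowSums(M^2))
  cosmin <- min(tcrossprod(U))
  if (cosmin > cos(10 * pi / 180)) return(list(rec = rec, report = report))

  offset <- c(0, 0, 0); gain <- c(1, 1, 1)
  for (i in seq_len(n_iter)) {
    C <- sweep(sweep(M, 2, gain, `*`), 2, offset, `+`)
    target <- C / sqrt(rowSums(C^2))           # closest points on unit sphere
    for (j in 1:3) {
      fit <- lm.fit(cbind(1, M[, j]), target[, j])
      offset[j] <- fit$coefficients[1]
      gain[j] <- fit$coefficients[2]
    }
  }
  report$offset <- c(x = offset[1], y = offset[2], z = offset[3])
  report$gain <- c(x = gain[1], y = gain[2], z = gain[3])
  report$applied <- TRUE
  rec$x <- rec$x * gain[1] + offset[1]
  rec$y <- rec$y * gain[2] + offset[2]
  rec$z <- rec$z * gain[3] + offset[3]
  list(rec = rec, report = report)
}

#' Peak oxygen uptake from a breath-averaged series
#'
#' Peak VO2 is the highest mean of three consecutive 10-s interval values
#' (a 30-s rolling mean) at any point during the test.
#'
#' @param vo2_series VO2 values at 10-s intervals (mL·kg^-1·min^-1).
#' @return peak VO2 (mL·kg^-1·min^-1).
#' @examples
#' peak_vo2(c(10, 20, 30, 40))  # mean(20, 30, 40) = 30
#' @export
peak_vo2 <- function(vo2_series) {
  if (length(vo2_series) < 3L) stop("need at least 3 values", call. = FALSE)
  if (anyNA(vo2_series)) stop("VO2 series contains missing values", call. = FALSE)
  n <- length(vo2_series)
  cs <- cumsum(c(0, vo2_series))
  max((cs[4:(n + 1)] - cs[1:(n - 2)]) / 3)
}

#' Write / read the documented raw CSV dialect
#'
#' Header `timestamp_iso8601,x_g,y_g,z_g`, one row per sample, local civil
#' time (no timezone arithmetic).
#'
#' @param rec a [raw_recording()].
#' @param path output file.
#' @return `path`, invisibly (writer); a `raw_recording` (reader).
#' @export
write_raw_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  ts <- rec$start_time + (seq_along(rec$x) - 1) / rec$fs
  dt <- data.table::data.table(
    timestamp_iso8601 = format(ts, "%Y-%m-%dT%H:%M:%OS3"),
    x_g = rec$x, y_g = rec$y, z_g = rec$z
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_raw_csv
#' @param fs sampling rate of the file (the dialect stores timestamps, not
#'   fs; supply the known rate, default inferred from the first two rows).
#' @param device_id device label for the returned recording.
#' @export
read_raw_csv <- function(path, fs = NULL, device_id = "csv") {
  dt <- data.table::fread(path)
  need <- c("timestamp_iso8601", "x_g", "y_g", "z_g")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("raw CSV missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  t0 <- as.POSIXct(dt$timestamp_iso8601[1], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (is.null(fs)) {
    t1 <- as.POSIXct(dt$timestamp_iso8601[2], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    fs <- round(1 / as.numeric(difftime(t1, t0, units = "secs")), 6)
  }
  raw_recording(t0, fs, dt$x_g, dt$y_g, dt$z_g, device_id = device_id)
}

#' Write / read the epoch CSV format
#'
#' Columns: `timestamp`, `enmo_g`, `wear`, `sleep`.
#' @param epochs an `epoch_series`.
#' @param path file path.
#' @export
write_epoch_csv <- function(epochs, path) {
  dt <- data.table::data.table(
    timestamp = format(epochs$time, "%Y-%m-%dT%H:%M:%S"),
    enmo_g = epochs$enmo, wear = epochs$wear, sleep = epochs$sleep
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @param epoch_length epoch duration in seconds.
#' @export
read_epoch_csv <- function(path, epoch_length = 5) {
  dt <- data.table::fread(path)
  epoch_series(
    time = as.POSIXct(dt$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    enmo = dt$enmo_g, wear = dt$wear, sleep = dt$sleep,
    epoch_length = epoch_length
  )
}
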