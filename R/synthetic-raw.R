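#' Build a segment schedule for the raw-signal generator
#'
#' The ground-truth script a synthetic recording follows: non-overlapping
#' segments of known kind (`activity`, `nonwear`, `sleep`) and, for activity
#' segments, a target ENMO level that the generated signal attains exactly.
#' Gaps between segments default to quiet wear (target ENMO 0).
#'
#' @param start numeric vector, segment start offsets in seconds from the
#'   recording start.
#' @param duration numeric vector, segment durations in seconds (> 0).
#' @param kind character vector in `c("activity", "nonwear", "sleep")`.
#' @param target_enmo numeric vector, target ENMO in g (>= 0); ignored for
#'   non-activity segments.
#' @param span total recording span in seconds (must cover all segments).
#' @return a `segment_schedule` data.frame, sorted by start.
#' @export
segment_schedule <- function(start = numeric(), duration = numeric(),
                             kind = character(), target_enmo = 0,
                             span = NULL) {
  n <- length(start)
  stopifnot(length(duration) == n, length(kind) == n)
  target_enmo <- rep_len(target_enmo, n)
  if (any(duration <= 0)) stop("segment durations must be > 0", call. = FALSE)
  if (any(target_enmo < 0)) stop("target_enmo must be >= 0", call. = FALSE)
  if (!all(kind %in% c("activity", "nonwear", "sleep"))) {
    stop("kind must be one of activity/nonwear/sleep", call. = FALSE)
  }
  sch <- data.frame(start = start, duration = duration, kind = kind,
                    target_enmo = target_enmo)
  sch <- sch[order(sch$start), , drop = FALSE]
  if (n > 1L && any(sch$start[-1] < (sch$start + sch$duration)[-n] - 1e-9)) {
    stop("segments overlap", call. = FALSE)
  }
  if (is.null(span)) span <- if (n) max(sch$start + sch$duration) else 0
  if (n && span < max(sch$start + sch$duration) - 1e-9) {
    stop("span does not cover the schedule", call. = FALSE)
  }
  attr(sch, "span") <- span
  class(sch) <- c("segment_schedule", "data.frame")
  sch
}

# random unit vectors, n x 3
runit <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Unit directions scattered around gravity: a slow random walk of the gravity
# vector (one small step per minute, well under 1 degree) plus a per-sample
# angular jitter of 3-8 degrees. Norm is 1 exactly, so per-sample ENMO is 0,
# yet at most one axis (the one near-parallel to gravity) can look static --
# wear signal never satisfies a >= 2-axis non-wear criterion.
jittered_gravity <- function(n, fs, g0) {
  n_min <- ceiling(n / (60 * fs))
  gs <- matrix(0, n_min, 3)
  g <- g0
  for (i in seq_len(n_min)) {
    g <- g + 0.01 * rnorm(3)            # ~0.6 degree rms step per minute
    g <- g / sqrt(sum(g^2))
    gs[i, ] <- g
  }
  idx <- pmin(((seq_len(n) - 1L) %/% as.integer(60 * fs)) + 1L, n_min)
  gmat <- gs[idx, , drop = FALSE]
  # orthonormal frame per sample
  ref <- cbind(-gmat[, 2], gmat[, 1], 0)
  degen <- rowSums(ref^2) < 1e-12
  if (any(degen)) ref[degen, ] <- matrix(c(1, 0, 0), sum(degen), 3, byrow = TRUE)
  e1 <- ref / sqrt(rowSums(ref^2))
  e2 <- cbind(gmat[, 2] * e1[, 3] - gmat[, 3] * e1[, 2],
              gmat[, 3] * e1[, 1] - gmat[, 1] * e1[, 3],
              gmat[, 1] * e1[, 2] - gmat[, 2] * e1[, 1])
  theta <- runif(n, 3, 8) * pi / 180
  phi <- runif(n, 0, 2 * pi)
  cos(theta) * gmat + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
}

#' Generate a raw triaxial recording from a segment schedule
#'
#' Construction guarantees, by design rather than approximation:
#' * activity segments: every sample's vector norm is exactly
#'   `1 + target_enmo` (a random unit direction scaled), so per-sample ENMO
#'   equals the target exactly;
#' * quiet wear and sleep segments: unit-norm samples (ENMO 0) whose
#'   direction drifts/jitters enough that wear never looks like non-wear;
#' * non-wear segments: a frozen orientation plus uniform per-axis noise of
#'   ±0.008 g (SD ≈ 0.0046 g, range ≤ 0.016 g), far inside any sensible
#'   static-detection threshold.
#'
#' Deterministic given `seed`.
#'
#' @param schedule a [segment_schedule()].
#' @param fs sampling frequency, Hz.
#' @param seed integer seed (also controls the initial orientation).
#' @param start_time POSIXct recording start (default a Monday midnight).
#' @return list with `rec` (a [raw_recording()]) and `truth` (the schedule).
#' @export
gen_raw_recording <- function(schedule, fs = 50,
                              seed = 1L,
                              start_time = as.POSIXct("2019-03-04 00:00:00", tz = "UTC")) {
  stopifnot(inherits(schedule, "segment_schedule"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  span <- attr(schedule, "span")
  n <- as.integer(round(span * fs))
  if (n < 1L) stop("empty schedule span", call. = FALSE)

  with_seed(seed, {
    target <- numeric(n)                 # per-sample target ENMO
    kind <- rep("wear", n)
    for (i in seq_len(nrow(schedule))) {
      a <- as.integer(round(schedule$start[i] * fs)) + 1L
      b <- min(as.integer(round((schedule$start[i] + schedule$duration[i]) * fs)), n)
      if (a > b) next
      kind[a:b] <- schedule$kind[i]
      if (schedule$kind[i] == "activity") target[a:b] <- schedule$target_enmo[i]
    }

    V <- matrix(0, n, 3)
    g0 <- runit(1)[1, ]
    quiet <- kind %in% c("wear", "sleep") | (kind == "activity" & target == 0)
    if (any(quiet)) V[quiet, ] <- jittered_gravity(sum(quiet), fs, g0)
    act <- kind == "activity" & target > 0
    if (any(act)) V[act, ] <- (1 + target[act]) * runit(sum(act))

    # non-wear blocks: one frozen orientation per block
    r <- rle(kind)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values == "nonwear")) {
      idx <- starts[j]:ends[j]
      ori <- runit(1)[1, ]
      m <- length(idx)
      V[idx, ] <- matrix(ori, m, 3, byrow = TRUE) +
        matrix(runif(3 * m, -0.008, 0.008), m, 3)
    }

    rec <- raw_recording(start_time, fs, V[, 1], V[, 2], V[, 3],
                         device_id = paste0("synthetic-seed", seed))
    truth <- schedule
    attr(truth, "sample_kind") <- NULL
    list(rec = rec, truth = truth, sample_kind = kind)
  })
}

#' Apply ground-truth sleep windows to an epoch series
#'
#' Sleep detection itself is out of scope; sleep windows arrive as
#' annotations (here: the generator's truth schedule) and are projected onto
#' epochs. An epoch is flagged asleep when its start falls inside a sleep
#' segment.
#'
#' @param epochs an `epoch_series`.
#' @param schedule a [segment_schedule()] containing `sleep` segments, or a
#'   data.frame with `start`/`duration` seconds relative to `origin`.
#' @param origin POSIXct the schedule offsets are relative to (default: first
#'   epoch time).
#' @return `epochs` with the `sleep` column filled (logical, no NA).
#' @export
apply_sleep_annotation <- function(epochs, schedule, origin = epochs$time[1]) {
  off <- as.numeric(difftime(epochs$time, origin, units = "secs"))
  sleep <- rep(FALSE, nrow(epochs))
  seg <- schedule[schedule$kind == "sleep", , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    sleep <- sleep | (off >= seg$start[i] & off < seg$start[i] + seg$duration[i])
  }
  epochs$sleep <- sleep
  epochs
}

#' Generate a realistic multi-day subject schedule
#'
#' Convenience builder for end-to-end fixtures: each day has a sleep window
#' (23:00 to 07:00 by default), a handful of activity blocks at mixed ENMO
#' levels (light / moderate / vigorous ranges), optional non-wear blocks on
#' selected days, and quiet wear elsewhere.
#'
#' @param n_days number of days.
#' @param seed integer seed.
#' @param nonwear_days integer vector of day indices that get a 120-min
#'   non-wear block at 13:00.
#' @return a [segment_schedule()] spanning `n_days * 86400` seconds.
#' @export
gen_subject_schedule <- function(n_days = 14, seed = 1L, nonwear_days = integer()) {
  with_seed(seed, {
    start <- numeric(); duration <- numeric(); kind <- character(); enmo <- numeric()
    for (d in seq_len(n_days)) {
      day0 <- (d - 1) * 86400
      # sleep 00:00-07:00 and 23:00-24:00 (civil-day aligned)
      start <- c(start, day0, day0 + 23 * 3600)
      duration <- c(duration, 7 * 3600, 3600)
      kind <- c(kind, "sleep", "sleep")
      enmo <- c(enmo, 0, 0)
      # 4 activity blocks in the morning/afternoon; on non-wear days stop
      # before the 13:00 block so the planted non-wear is never displaced
      t <- day0 + 8 * 3600
      t_max <- day0 + (if (d %in% nonwear_days) 13 else 22.5) * 3600
      for (k in 1:4) {
        gap <- runif(1, 600, 5400)
        dur <- round(runif(1, 1200, 3600) / 5) * 5
        lev <- sample(c(0.05, 0.12, 0.2, 0.45), 1)
        t <- t + gap
        if (t + dur > t_max) break
        start <- c(start, t); duration <- c(duration, dur)
        kind <- c(kind, "activity"); enmo <- c(enmo, lev)
        t <- t + dur
      }
      if (d %in% nonwear_days) {
        start <- c(start, day0 + 13 * 3600); duration <- c(duration, 7200)
        kind <- c(kind, "nonwear"); enmo <- c(enmo, 0)
      }
    }
    sch <- data.frame(start = start, duration = duration, kind = kind,
                      target_enmo = enmo)
    sch <- sch[order(sch$start), , drop = FALSE]
    # drop any accidental overlap with the non-wear insertion
    keep <- rep(TRUE, nrow(sch))
    last_end <- -1
    for (i in seq_len(nrow(sch))) {
      if (sch$start[i] < last_end) keep[i] <- FALSE
      else last_end <- sch$start[i] + sch$duration[i]
    }
    sch <- sch[keep, , drop = FALSE]
    segment_schedule(sch$start, sch$duration, sch$kind, sch$target_enmo,
                     span = n_days * 86400)
  })
}

#' Serialise a truth schedule to JSON
#' @param schedule a [segment_schedule()].
#' @param path output path.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(span = attr(schedule, "span"),
         segments = as.data.frame(schedule)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- obj$segments
  if (is.null(seg) || !NROW(seg)) {
    return(segment_schedule(span = obj$span))
  }
  segment_schedule(seg$start, seg$duration, seg$kind, seg$target_enmo,
                   span = obj$span)
}
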