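dow_levels <- function() c("Monday", "Tuesday", "Wednesday", "Thursday",
                           "Friday", "Saturday", "Sunday")
season_levels <- function() c("Spring", "Summer", "Autumn", "Winter")

#' Intensity cut-off scheme
#'
#' ENMO thresholds separating sedentary time from light, moderate and
#' vigorous activity, with the MET levels each threshold is anchored to.
#' Defaults: 0.03 g (LPA, >= 2 METs), 0.1 g (MPA, >= 3 METs), 0.4 g
#' (VPA, >= 6 METs); everything below 0.03 g is sedentary.
#'
#' @param light,moderate,vigorous cut-offs in g, strictly increasing.
#' @param met_anchors METs each cut-off corresponds to.
#' @return a `cutoff_scheme` list.
#' @export
cutoff_scheme <- function(light = 0.03, moderate = 0.1, vigorous = 0.4,
                          met_anchors = c(light = 2, moderate = 3, vigorous = 6)) {
  if (!(0 < light && light < moderate && moderate < vigorous)) {
    stop("cut-offs must satisfy 0 < light < moderate < vigorous", call. = FALSE)
  }
  structure(list(light = light, moderate = moderate, vigorous = vigorous,
                 met_anchors = met_anchors),
            class = "cutoff_scheme")
}

#' Classify epoch ENMO into an intensity class
#'
#' Boundaries are inclusive upward: an epoch at exactly a cut-off enters the
#' higher class; sedentary is strictly below the light cut-off. Vectorised.
#'
#' @param enmo non-negative epoch ENMO (g).
#' @param scheme a [cutoff_scheme()].
#' @return factor with levels `sedentary, LPA, MPA, VPA`.
#' @examples
#' classify_epoch(c(0.02, 0.03, 0.1, 0.4))
#' @export
classify_epoch <- function(enmo, scheme = cutoff_scheme()) {
  if (any(enmo < 0)) stop("enmo must be non-negative", call. = FALSE)
  cut(enmo, breaks = c(-Inf, scheme$light, scheme$moderate, scheme$vigorous, Inf),
      labels = c("sedentary", "LPA", "MPA", "VPA"), right = FALSE)
}

#' Calendar features for measurement days
#'
#' Day 1 is the first midnight after device receipt; only days 1..`max_days`
#' (default 13) are analysable. Week 1 spans days 1-7, week 2 days 8-13.
#' Weekend = Saturday and Sunday. Seasons: Spring (Mar-May), Summer
#' (Jun-Aug), Autumn (Sep-Nov), Winter (Dec-Feb).
#'
#' @param dates Date vector.
#' @param recording_start Date of measurement day 1.
#' @param max_days last analysable measurement day.
#' @return data.frame with `date, day_of_week, is_weekend, measurement_day,
#'   week_index, season, included`; rows outside days 1..`max_days` have
#'   `included = FALSE` (each exclusion is messaged).
#' @export
calendar_features <- function(dates, recording_start, max_days = 13) {
  dates <- as.Date(dates)
  recording_start <- as.Date(recording_start)
  md <- as.integer(dates - recording_start) + 1L
  dow_num <- as.integer(format(dates, "%u"))          # 1 = Monday .. 7 = Sunday
  month <- as.integer(format(dates, "%m"))
  season <- c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
              "Summer", "Summer", "Autumn", "Autumn", "Autumn", "Winter")[month]
  included <- md >= 1L & md <= max_days
  for (i in which(!included)) {
    message("excluded ", dates[i], ": measurement day ", md[i],
            " outside 1..", max_days)
  }
  data.frame(
    date = dates,
    day_of_week = factor(dow_levels()[dow_num], levels = dow_levels()),
    is_weekend = dow_num >= 6L,
    measurement_day = md,
    week_index = ifelse(md <= 7L, 1L, 2L),
    season = factor(season, levels = season_levels()),
    included = included
  )
}

#' Bouted MVPA minutes
#'
#' Sums the duration of maximal runs of consecutive wear epochs at or above
#' the moderate cut-off whose length reaches `min_bout` minutes. A run is
#' broken by any epoch below the cut-off or flagged non-wear; by default no
#' interruption is tolerated (`tolerance = 0`). With a positive tolerance,
#' runs separated by at most that many consecutive non-MVPA epochs merge
#' into one bout, and only the MVPA epochs inside a qualifying bout are
#' counted.
#'
#' @param epochs an `epoch_series`.
#' @param scheme a [cutoff_scheme()].
#' @param min_bout minimum bout duration, minutes.
#' @param tolerance interruption tolerance, epochs.
#' @return bouted MVPA in minutes.
#' @export
bouted_mvpa <- function(epochs, scheme = cutoff_scheme(), min_bout = 10,
                        tolerance = 0) {
  el <- epoch_len(epochs)
  is_mvpa <- epochs$wear & epochs$enmo >= scheme$moderate
  if (!length(is_mvpa)) return(0)
  r <- rle(is_mvpa)
  if (tolerance > 0) {
    # merge MVPA runs separated by short interruptions
    vals <- r$values
    gap_ok <- !vals & r$lengths <= tolerance
    inner <- seq_along(vals) > 1 & seq_along(vals) < length(vals)
    vals[gap_ok & inner] <- TRUE
    is_merged <- inverse.rle(list(values = vals, lengths = r$lengths))
    r2 <- rle(is_merged)
    min_epochs <- min_bout * 60 / el
    qual <- r2$values & r2$lengths >= min_epochs
    keep <- inverse.rle(list(values = qual, lengths = r2$lengths))
    return(sum(is_mvpa & keep) * el / 60)
  }
  min_epochs <- min_bout * 60 / el
  sum(r$lengths[r$values & r$lengths >= min_epochs]) * el / 60
}

#' Daily sleep minutes from epoch annotations
#'
#' Pass-through of sleep-window annotations: sums flagged sleep epochs.
#' Returns `NA` (with a message) when the series carries no annotation.
#'
#' @param epochs an `epoch_series`.
#' @return minutes, or `NA_real_` if unannotated.
#' @export
sleep_minutes <- function(epochs) {
  if (all(is.na(epochs$sleep))) {
    message("no sleep annotation present; sleep minutes absent")
    return(NA_real_)
  }
  sum(epochs$sleep, na.rm = TRUE) * epoch_len(epochs) / 60
}

#' Summarise one civil day of epochs
#'
#' Counts wear epochs per intensity class (non-wear epochs contribute to no
#' class), converts counts to minutes, computes bouted MVPA and optional
#' sleep minutes, and applies the >= 600 wear-minute validity rule. Epoch
#' counts are also returned so the partition `sedentary + LPA + MPA + VPA =
#' wear` can be checked exactly at epoch resolution.
#'
#' @param epochs `epoch_series` falling within one [midnight, midnight)
#'   interval.
#' @param scheme a [cutoff_scheme()].
#' @param min_bout minimum MVPA bout length, minutes.
#' @param bout_tolerance interruption tolerance, epochs.
#' @param valid_day_minutes wear minutes required for a valid day.
#' @param recording_start optional Date of measurement day 1; fills calendar
#'   fields when supplied.
#' @param max_days last analysable measurement day.
#' @return one-row data.frame (a `DaySummary`).
#' @export
summarize_day <- function(epochs, scheme = cutoff_scheme(), min_bout = 10,
                          bout_tolerance = 0, valid_day_minutes = 600,
                          recording_start = NULL, max_days = 13) {
  dates <- unique(as.Date(epochs$time))
  if (length(dates) != 1L) {
    stop("epochs span more than one civil day", call. = FALSE)
  }
  el <- epoch_len(epochs)
  cls <- classify_epoch(epochs$enmo, scheme)
  wear <- epochs$wear
  counts <- vapply(c("sedentary", "LPA", "MPA", "VPA"),
                   function(k) sum(wear & cls == k), integer(1))
  mins <- counts * el / 60
  wear_minutes <- sum(wear) * el / 60
  out <- data.frame(
    date = dates,
    wear_minutes = wear_minutes,
    sedentary = mins[["sedentary"]], lpa = mins[["LPA"]],
    mpa = mins[["MPA"]], vpa = mins[["VPA"]],
    mvpa = mins[["MPA"]] + mins[["VPA"]],
    tpa = mins[["LPA"]] + mins[["MPA"]] + mins[["VPA"]],
    bouted_mvpa = bouted_mvpa(epochs, scheme, min_bout, bout_tolerance),
    sleep_minutes = suppressMessages(sleep_minutes(epochs)),
    sedentary_epochs = counts[["sedentary"]], lpa_epochs = counts[["LPA"]],
    mpa_epochs = counts[["MPA"]], vpa_epochs = counts[["VPA"]],
    wear_epochs = sum(wear),
    valid = wear_minutes >= valid_day_minutes
  )
  if (!is.null(recording_start)) {
    cal <- calendar_features(dates, recording_start, max_days = max_days)
    out <- cbind(out, cal[, c("day_of_week", "is_weekend", "measurement_day",
                              "week_index", "season", "included")])
  }
  rownames(out) <- NULL
  out
}

#' Summarise a multi-day epoch series into day rows
#'
#' Splits an epoch series at civil midnights, summarises each day, attaches
#' calendar features, and drops days outside measurement days
#' 1..`max_days` (each with a logged reason).
#'
#' @param epochs `epoch_series` covering any number of days.
#' @param recording_start Date of measurement day 1 (default: date of the
#'   first epoch).
#' @param max_days last analysable measurement day.
#' @inheritParams summarize_day
#' @return data.frame of day summaries, one row per analysable day.
#' @export
summarize_days <- function(epochs, scheme = cutoff_scheme(),
                           recording_start = as.Date(epochs$time[1]),
                           max_days = 13, min_bout = 10, bout_tolerance = 0,
                           valid_day_minutes = 600) {
  el <- epoch_len(epochs)
  day <- as.Date(epochs$time)
  pieces <- split(seq_len(nrow(epochs)), day)
  rows <- lapply(pieces, function(idx) {
    sub <- epochs[idx, , drop = FALSE]
    attr(sub, "epoch_length") <- el
    class(sub) <- c("epoch_series", "data.frame")
    summarize_day(sub, scheme, min_bout, bout_tolerance, valid_day_minutes,
                  recording_start = recording_start, max_days = max_days)
  })
  out <- do.call(rbind, rows)
  keep <- out$included
  if (any(!keep)) {
    message(sum(!keep), " day(s) outside measurement days 1..", max_days,
            " excluded")
  }
  out <- out[keep & out$measurement_day <= max_days, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subject-level inclusion by the two-week validity rule
#'
#' A subject is included when week 1 (days 1-7) and week 2 (days 8-13) each
#' contain at least `min_weekdays` valid weekdays and at least
#' `min_weekend` valid weekend days.
#'
#' @param days data.frame of day summaries for one subject with columns
#'   `valid`, `is_weekend`, `week_index`.
#' @param min_weekdays,min_weekend per-week requirements.
#' @return list: per-week valid weekday/weekend counts and `included`.
#' @export
subject_validity <- function(days, min_weekdays = 4, min_weekend = 1) {
  count <- function(w, weekend) {
    sum(days$valid & days$week_index == w & days$is_weekend == weekend)
  }
  res <- list(
    week1_weekdays = count(1, FALSE), week1_weekend = count(1, TRUE),
    week2_weekdays = count(2, FALSE), week2_weekend = count(2, TRUE)
  )
  res$included <- res$week1_weekdays >= min_weekdays &&
    res$week1_weekend >= min_weekend &&
    res$week2_weekdays >= min_weekdays &&
    res$week2_weekend >= min_weekend
  res
}
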