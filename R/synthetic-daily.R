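#' Cohort covariate moments (means, SDs, printed ranges)
#'
#' Defaults describe the two study populations the package's analyses are
#' designed for: heart-failure patients (HEART) and healthy adults (HEALTH).
#' VO2peak: HEART 21.5 +/- 6.4 (10.2-39.5), HEALTH 34.4 +/- 9.9 (14.2-65.1)
#' mL.kg-1.min-1. Age: 66 +/- 13 (26-89) vs 54 +/- 19 (21-91) years. Female
#' proportion 23% vs 51%. Daily wear time ~1434 +/- 44 min.
#' @keywords internal
cohort_moments <- function(group = c("HEART", "HEALTH")) {
  group <- match.arg(group)
  if (group == "HEART") {
    list(vo2 = c(mean = 21.5, sd = 6.4, lo = 10.2, hi = 39.5),
         age = c(mean = 66, sd = 13, lo = 26, hi = 89),
         p_female = 0.23, n = 56,
         wear = c(mean = 1434.2, sd = 44.2))
  } else {
    list(vo2 = c(mean = 34.4, sd = 9.9, lo = 14.2, hi = 65.1),
         age = c(mean = 54, sd = 19, lo = 21, hi = 91),
         p_female = 0.51, n = 299,
         wear = c(mean = 1434.8, sd = 42.4))
  }
}

# truncated-normal draws by rejection; matches a printed mean/SD/range
rtruncnorm_rej <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Draw a VO2peak cohort from the group's published moments
#'
#' Normal draws with the group's mean/SD, rejection-resampled into the
#' printed range.
#'
#' @param group `"HEART"` or `"HEALTH"`.
#' @param n cohort size.
#' @param seed integer seed.
#' @return numeric vector of VO2peak values (mL·kg^-1·min^-1).
#' @export
gen_vo2peak_cohort <- function(group = c("HEART", "HEALTH"), n, seed = 1L) {
  group <- match.arg(group)
  stopifnot(n >= 1)
  m <- cohort_moments(group)$vo2
  with_seed(seed, rtruncnorm_rej(n, m["mean"], m["sd"], m["lo"], m["hi"]))
}

#' Generate a subject table with covariates for both groups
#'
#' @param n_heart,n_health group sizes (defaults: the reference cohort's
#'   56 and 299).
#' @param seed integer seed.
#' @return data.frame: subject_id, group, age, sex, vo2peak.
#' @export
gen_subject_table <- function(n_heart = 56, n_health = 299, seed = 1L) {
  with_seed(seed, {
    one <- function(group, n, id0) {
      if (n < 1) {
        return(data.frame(subject_id = character(), group = character(),
                          age = numeric(), sex = character(),
                          vo2peak = numeric()))
      }
      m <- cohort_moments(group)
      data.frame(
        subject_id = sprintf("%s%03d", substr(group, 1, 2), id0 + seq_len(n)),
        group = group,
        age = round(rtruncnorm_rej(n, m$age["mean"], m$age["sd"],
                                   m$age["lo"], m$age["hi"])),
        sex = ifelse(runif(n) < m$p_female, "female", "male"),
        vo2peak = rtruncnorm_rej(n, m$vo2["mean"], m$vo2["sd"],
                                 m$vo2["lo"], m$vo2["hi"])
      )
    }
    rbind(one("HEART", n_heart, 0L), one("HEALTH", n_health, 1000L))
  })
}

#' Specification of a synthetic daily-summary dataset
#'
#' Declares the data-generating model for per-day activity minutes:
#' `minutes[class] = baseline[class] + day_of_week_effect + season_effect +
#' reactivity_slope * (day - 1) + subject_intercept + residual`, truncated
#' to `[0, wear_minutes]`. The same additive day-of-week / season /
#' reactivity structure (scaled per class by `effect_scale`) applies to every
#' activity class; wear time and sleep have their own small blocks so the
#' wear-trend and sleep-regression analyses have generated outcomes to work
#' on. Because every class receives the effect additively, composite
#' outcomes (MVPA = MPA+VPA, TPA = LPA+MPA+VPA) carry the injected effect
#' once per component class.
#'
#' @param n_subjects subjects per group, named c(HEART = , HEALTH = ).
#' @param baseline_minutes named baseline minutes/day per class
#'   (sedentary, lpa, mpa, vpa).
#' @param day_of_week_effects 7 additive offsets, Monday..Sunday, minutes.
#' @param season_effects 4 additive offsets, Spring/Summer/Autumn/Winter.
#' @param reactivity_slope minutes per measurement day.
#' @param subject_sd between-subject SD, minutes.
#' @param residual_sd within-subject residual SD, minutes.
#' @param wear list(baseline, slope, subject_sd, residual_sd) for daily wear
#'   minutes.
#' @param sleep list(baseline, weekend_shift, residual_sd) for daily sleep
#'   minutes.
#' @return a `daily_effect_spec` list.
#' @export
daily_effect_spec <- function(n_subjects = c(HEART = 56, HEALTH = 299),
                              baseline_minutes = c(sedentary = 600, lpa = 200,
                                                   mpa = 60, vpa = 10),
                              day_of_week_effects = rep(0, 7),
                              season_effects = rep(0, 4),
                              reactivity_slope = 0,
                              subject_sd = 25,
                              residual_sd = 20,
                              wear = list(baseline = 1434, slope = 0,
                                          subject_sd = 20, residual_sd = 30),
                              sleep = list(baseline = 450, weekend_shift = 0,
                                           residual_sd = 35)) {
  stopifnot(length(day_of_week_effects) == 7, length(season_effects) == 4,
            subject_sd >= 0, residual_sd >= 0,
            all(baseline_minutes >= 0))
  structure(
    list(n_subjects = n_subjects, baseline_minutes = baseline_minutes,
         day_of_week_effects = day_of_week_effects,
         season_effects = season_effects,
         reactivity_slope = reactivity_slope,
         subject_sd = subject_sd, residual_sd = residual_sd,
         wear = wear, sleep = sleep),
    class = "daily_effect_spec"
  )
}

#' Generate a daily-summary dataset with known effects
#'
#' One row per subject-day. Deterministic given `seed`. Calendar features
#' (day of week, weekend, season, measurement day, week index) are computed
#' from real dates starting at `start_date`.
#'
#' @param spec a [daily_effect_spec()].
#' @param n_days days per subject (the analyses use 13).
#' @param start_date Date or string, the first measurement day.
#' @param seed integer seed.
#' @param stagger_weeks when > 0, each subject starts a uniformly drawn
#'   0..(stagger_weeks - 1) whole weeks after `start_date` (keeps the
#'   day-of-week layout aligned while spreading measurement across seasons,
#'   as in a rolling-recruitment cohort).
#' @return data.frame with subject covariates, calendar features, and
#'   minutes columns `sedentary, lpa, mpa, vpa, mvpa, tpa, bouted_mvpa,
#'   wear_minutes, sleep_minutes`.
#' @export
gen_daily_dataset <- function(spec, n_days = 13,
                              start_date = as.Date("2019-03-04"), seed = 1L,
                              stagger_weeks = 0) {
  stopifnot(inherits(spec, "daily_effect_spec"), n_days >= 1)
  start_date <- as.Date(start_date)
  subj <- gen_subject_table(n_heart = spec$n_subjects[["HEART"]],
                            n_health = spec$n_subjects[["HEALTH"]],
                            seed = child_seed(seed, 1))
  n_sub <- nrow(subj)

  with_seed(child_seed(seed, 2), {
    classes <- names(spec$baseline_minutes)
    b_subj <- rnorm(n_sub, 0, spec$subject_sd)
    wear_b <- rnorm(n_sub, 0, spec$wear$subject_sd)
    offsets <- if (stagger_weeks > 0) {
      7L * sample.int(stagger_weeks, n_sub, replace = TRUE) - 7L
    } else {
      integer(n_sub)
    }
    rows <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      dates <- start_date + offsets[i] + (seq_len(n_days) - 1L)
      cal <- calendar_features(dates, recording_start = dates[1],
                               max_days = n_days)
      dow_idx <- as.integer(cal$day_of_week)
      sea_idx <- as.integer(cal$season)
      eff_day <- spec$day_of_week_effects[dow_idx] +
        spec$season_effects[sea_idx] +
        spec$reactivity_slope * (cal$measurement_day - 1)
      wear_i <- spec$wear$baseline + wear_b[i] +
        spec$wear$slope * (cal$measurement_day - 1) +
        rnorm(n_days, 0, spec$wear$residual_sd)
      wear_i <- pmin(pmax(wear_i, 0), 1440)
      mins <- vapply(classes, function(cl) {
        v <- spec$baseline_minutes[[cl]] + eff_day + b_subj[i] +
          rnorm(n_days, 0, spec$residual_sd)
        pmin(pmax(v, 0), wear_i)
      }, numeric(n_days))
      if (n_days == 1L) mins <- matrix(mins, nrow = 1, dimnames = list(NULL, classes))
      sleep_i <- spec$sleep$baseline +
        spec$sleep$weekend_shift * cal$is_weekend +
        rnorm(n_days, 0, spec$sleep$residual_sd)
      rows[[i]] <- data.frame(
        subj[i, , drop = FALSE], row.names = NULL,
        date = dates, day_of_week = cal$day_of_week,
        is_weekend = cal$is_weekend, measurement_day = cal$measurement_day,
        week_index = cal$week_index, season = cal$season,
        wear_minutes = wear_i,
        sedentary = mins[, "sedentary"], lpa = mins[, "lpa"],
        mpa = mins[, "mpa"], vpa = mins[, "vpa"],
        sleep_minutes = pmax(sleep_i, 0)
      )
    }
    out <- do.call(rbind, rows)
    out$mvpa <- out$mpa + out$vpa
    out$tpa <- out$lpa + out$mpa + out$vpa
    out$bouted_mvpa <- pmin(out$mvpa, pmax(0, 0.35 * out$mvpa))
    rownames(out) <- NULL
    out
  })
}
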