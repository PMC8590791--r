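test_that("activity segments hit their target ENMO exactly", {
  sch <- segment_schedule(0, 5, "activity", 0.2)
  gr <- gen_raw_recording(sch, fs = 50, seed = 1)
  expect_equal(length(gr$rec$x), 250L)
  e <- enmo_sample(gr$rec$x, gr$rec$y, gr$rec$z)
  expect_equal(e, rep(0.2, 250), tolerance = 1e-12)
})

test_that("non-wear segments stay inside the stated noise envelope", {
  sch <- segment_schedule(0, 2 * 3600, "nonwear")
  gr <- gen_raw_recording(sch, fs = 5, seed = 2)
  wlen <- 3600 * 5
  for (s in c(1L, 1800 * 5, 3600 * 5 + 1L)) {
    idx <- s:(s + wlen - 1)
    for (ax in c("x", "y", "z")) {
      seg <- gr$rec[[ax]][idx]
      expect_lt(sd(seg), 0.013)
      expect_lt(max(seg) - min(seg), 0.050)
    }
  }
})

test_that("generators are deterministic and leave the RNG state alone", {
  sch <- segment_schedule(0, 60, "activity", 0.1)
  a <- gen_raw_recording(sch, fs = 50, seed = 7)
  b <- gen_raw_recording(sch, fs = 50, seed = 7)
  expect_identical(a$rec$x, b$rec$x)
  expect_identical(a$rec$z, b$rec$z)

  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_vo2peak_cohort("HEART", 5, seed = 3))
  expect_identical(runif(1), before)

  expect_identical(gen_vo2peak_cohort("HEART", 1, seed = 9),
                   gen_vo2peak_cohort("HEART", 1, seed = 9))
})

test_that("schedule validation rejects bad input", {
  expect_error(segment_schedule(c(0, 50), c(100, 100),
                                c("activity", "activity"), 0.1), "overlap")
  expect_error(segment_schedule(0, -5, "activity", 0.1), "durations")
  expect_error(segment_schedule(0, 5, "activity", -0.1), "target_enmo")
  expect_error(gen_raw_recording(segment_schedule(0, 5, "activity", 0.1),
                                 fs = -1), "positive")
})

test_that("vo2peak cohorts match the stated moments and ranges", {
  # analytic mean of N(mu, sd) truncated to [lo, hi] -- independent oracle
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  heart <- gen_vo2peak_cohort("HEART", 4000, seed = 5)
  expect_lt(abs(mean(heart) - trunc_mean(21.5, 6.4, 10.2, 39.5)), 0.3)
  expect_true(all(heart >= 10.2 & heart <= 39.5))
  health <- gen_vo2peak_cohort("HEALTH", 4000, seed = 6)
  expect_lt(abs(mean(health) - trunc_mean(34.4, 9.9, 14.2, 65.1)), 0.3)
  # the truncation bias keeps the realised mean near the printed 34.4 / 21.5
  expect_lt(abs(mean(health) - 34.4), 0.75)
  expect_lt(abs(mean(heart) - 21.5), 0.75)
  expect_true(all(health >= 14.2 & health <= 65.1))
})

test_that("degenerate daily spec yields exactly the baseline", {
  spec <- daily_effect_spec(
    n_subjects = c(HEART = 0, HEALTH = 5),
    baseline_minutes = c(sedentary = 300, lpa = 300, mpa = 300, vpa = 300),
    subject_sd = 0, residual_sd = 0,
    wear = list(baseline = 1434, slope = 0, subject_sd = 0, residual_sd = 0),
    sleep = list(baseline = 450, weekend_shift = 0, residual_sd = 0)
  )
  d <- gen_daily_dataset(spec, n_days = 13, seed = 4)
  expect_true(all(d$lpa == 300))
  expect_true(all(d$sedentary == 300))
  expect_true(all(d$wear_minutes == 1434))
})

test_that("injected Sunday effect shows up in raw group means", {
  spec <- daily_effect_spec(
    n_subjects = c(HEART = 0, HEALTH = 500),
    day_of_week_effects = c(0, 0, 0, 0, 0, 0, -20),
    residual_sd = 10, subject_sd = 15
  )
  d <- gen_daily_dataset(spec, n_days = 13, seed = 8)
  diff <- mean(d$lpa[d$day_of_week == "Sunday"]) -
    mean(d$lpa[d$day_of_week == "Monday"])
  expect_lt(abs(diff - (-20)), 1.5)
})

test_that("13 days from a Monday give a 7/6 week split with 3 weekend days", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 1, HEALTH = 0))
  d <- gen_daily_dataset(spec, n_days = 13,
                         start_date = as.Date("2019-03-04"), seed = 1)
  # Mon..Sun then Mon..Sat: one Sunday, two Saturdays
  expect_equal(sum(d$day_of_week == "Sunday"), 1L)
  expect_equal(sum(d$is_weekend), 3L)
  expect_equal(sum(d$week_index == 1), 7L)
  expect_equal(sum(d$week_index == 2), 6L)
  expect_true(all(d$sedentary <= d$wear_minutes))
})

test_that("staggered starts spread subjects across seasons", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = 80))
  d <- gen_daily_dataset(spec, n_days = 13, seed = 3, stagger_weeks = 52)
  expect_gte(length(unique(d$season)), 3L)
  # day-of-week layout still aligned: every subject starts a Monday
  firsts <- tapply(as.character(d$day_of_week), d$subject_id,
                   function(x) x[1])
  expect_true(all(firsts == "Monday"))
})

test_that("truth round-trip: pipeline recovers planted activity minutes", {
  # 8-h span: quiet wear + three activity blocks at known levels
  sch <- segment_schedule(
    start = c(3600, 3 * 3600, 5 * 3600),
    duration = c(1800, 3600, 600),
    kind = rep("activity", 3),
    target_enmo = c(0.05, 0.12, 0.45),
    span = 8 * 3600
  )
  gr <- gen_raw_recording(sch, fs = 5, seed = 77)
  ep <- detect_nonwear(gr$rec, epoch_aggregate(gr$rec, 5))
  cls <- classify_epoch(ep$enmo)
  expect_equal(sum(cls == "LPA" & ep$wear) * 5 / 60, 30)    # 0.05 g block
  expect_equal(sum(cls == "MPA" & ep$wear) * 5 / 60, 60)    # 0.12 g block
  expect_equal(sum(cls == "VPA" & ep$wear) * 5 / 60, 10)    # 0.45 g block
  expect_equal(sum(!ep$wear), 0L)
})

test_that("sleep annotation projects truth windows onto epochs", {
  sch <- segment_schedule(c(0, 4 * 3600), c(2 * 3600, 3600),
                          c("sleep", "activity"), c(0, 0.1),
                          span = 6 * 3600)
  gr <- gen_raw_recording(sch, fs = 5, seed = 12)
  ep <- apply_sleep_annotation(epoch_aggregate(gr$rec, 5), gr$truth)
  expect_equal(sleep_minutes(ep), 120)
})

test_that("schedule JSON round-trips", {
  sch <- gen_subject_schedule(n_days = 2, seed = 3, nonwear_days = 1L)
  p <- tempfile(fileext = ".json")
  write_schedule_json(sch, p)
  back <- read_schedule_json(p)
  expect_equal(as.data.frame(back), as.data.frame(sch), tolerance = 1e-9)
  expect_equal(attr(back, "span"), attr(sch, "span"))
  unlink(p)
})
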