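# Moderate-scale model checks; the heavier calibration simulations live in
# test-acceptance.R.

test_that("fit_mixed recovers an injected day-of-week effect", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = 60),
                            day_of_week_effects = c(0, 0, 0, 0, 0, 0, -20),
                            residual_sd = 15, subject_sd = 20)
  d <- gen_daily_dataset(spec, n_days = 13, seed = 11)
  m <- fit_mixed(d, "lpa", factor = "day_of_week")
  sun <- m$estimates[m$estimates$term == "day_of_weekSunday", ]
  expect_lt(abs(sun$estimate - (-20)), 2 * sun$se)
  expect_lt(m$factor_test$p, 0.01)
  expect_true(m$converged)
  expect_equal(m$factor_test$df, 6L)
  expect_equal(m$n_subjects, 60L)
  # CI construction
  expect_equal(sun$ci_hi - sun$estimate, 1.96 * sun$se, tolerance = 1e-9)
})

test_that("model results are invariant to row order", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = 25),
                            residual_sd = 15, subject_sd = 10)
  d <- gen_daily_dataset(spec, n_days = 13, seed = 21)
  m1 <- fit_mixed(d, "tpa", factor = "day_of_week")
  set.seed(1)
  m2 <- fit_mixed(d[sample(nrow(d)), ], "tpa", factor = "day_of_week")
  expect_equal(m1$estimates$estimate, m2$estimates$estimate, tolerance = 1e-6)
  expect_equal(m1$factor_test$p, m2$factor_test$p, tolerance = 1e-6)
})

test_that("weighted and unweighted fits agree under homoscedasticity", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = 40),
                            day_of_week_effects = c(0, 0, 0, 0, 0, -10, -20),
                            residual_sd = 15, subject_sd = 10)
  d <- gen_daily_dataset(spec, n_days = 13, seed = 31)
  m0 <- fit_mixed(d, "mpa", factor = "day_of_week", weights = "none")
  mw <- fit_mixed(d, "mpa", factor = "day_of_week", weights = "by_factor_level")
  expect_equal(m0$estimates$estimate, mw$estimates$estimate, tolerance = 0.05)
  expect_true(mw$converged)
})

test_that("weekend_week_contrast recovers an injected weekend deficit", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = 80),
                            day_of_week_effects = c(0, 0, 0, 0, 0, -15, -15),
                            residual_sd = 15, subject_sd = 20)
  d <- gen_daily_dataset(spec, n_days = 13, seed = 41)
  m <- weekend_week_contrast(d, "lpa")
  we <- m$estimates[m$estimates$term == "is_weekendTRUE", ]
  expect_lt(abs(we$estimate - (-15)), 2 * we$se)
  wk <- m$estimates[m$estimates$term == "week_index2", ]
  expect_lt(abs(wk$estimate), 3 * wk$se)    # no week effect injected
})

test_that("season model recovers injected summer surplus on staggered starts", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = 80),
                            season_effects = c(0, 25, 0, 0),
                            residual_sd = 15, subject_sd = 20)
  d <- gen_daily_dataset(spec, n_days = 13, seed = 51, stagger_weeks = 52)
  # note: composite outcomes (tpa/mvpa) accumulate the injected per-class
  # effect once per component class, so the check targets a single class
  m <- fit_mixed(d, "lpa", factor = "season")
  su <- m$estimates[m$estimates$term == "seasonSummer", ]
  expect_lt(abs(su$estimate - 25), 2 * su$se)
  expect_lt(m$factor_test$p, 0.01)
})

test_that("reactivity slope on wear time is recovered", {
  spec <- daily_effect_spec(
    n_subjects = c(HEART = 0, HEALTH = 100),
    wear = list(baseline = 1410, slope = -0.5, subject_sd = 20, residual_sd = 30)
  )
  d <- gen_daily_dataset(spec, n_days = 13, seed = 61)
  m <- fit_mixed(d, "wear_minutes", factor = "measurement_day")
  sl <- m$estimates[m$estimates$term == "measurement_day", ]
  expect_lt(abs(sl$estimate - (-0.5)), 2 * sl$se)
  # wear time must not appear as its own covariate
  expect_false("wear_minutes" %in% m$estimates$term)
})

test_that("rank-deficient designs fail loudly, naming the column", {
  spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = 10))
  d <- gen_daily_dataset(spec, n_days = 13, seed = 71)
  d$vo2peak <- d$age * 2          # collinear with age
  expect_error(fit_mixed(d, "tpa", factor = "day_of_week"), "vo2peak")
})

test_that("sleep regression behaves at the null and under a shift", {
  spec <- daily_effect_spec(
    n_subjects = c(HEART = 0, HEALTH = 40),
    sleep = list(baseline = 430, weekend_shift = 28, residual_sd = 35)
  )
  d <- gen_daily_dataset(spec, n_days = 13, seed = 81)
  r <- sleep_weekday_regression(d)
  expect_lt(abs(r$estimate - 28), 2 * r$se)
  expect_lt(r$p, 0.05)

  # constant sleep -> exactly zero difference (perfect-fit warning expected)
  d0 <- d; d0$sleep_minutes <- 450
  expect_equal(suppressWarnings(sleep_weekday_regression(d0)$estimate), 0,
               tolerance = 1e-9)

  d_na <- d; d_na$sleep_minutes <- NA_real_
  expect_error(sleep_weekday_regression(d_na), "sleep")
})

test_that("weartime_rank_test matches exact enumeration and rank invariance", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  got <- weartime_rank_test(a, b, exact = TRUE)
  expect_equal(got$p, oracle_ranksum_p(a, b), tolerance = 1e-12)
  expect_equal(got$p, 0.1, tolerance = 1e-12)   # 2 / choose(6, 3)

  set.seed(3)
  x <- runif(20); y <- runif(25)
  p1 <- weartime_rank_test(x, y)
  p2 <- weartime_rank_test(x + 100, y + 100)
  expect_equal(p1$statistic, p2$statistic)
  expect_equal(p1$p, p2$p)

  same <- weartime_rank_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p, 0.99)
  expect_error(weartime_rank_test(numeric(0), y), "non-empty")
})

test_that("estimator bias shrinks as the cohort grows", {
  bias_at <- function(n) {
    spec <- daily_effect_spec(n_subjects = c(HEART = 0, HEALTH = n),
                              day_of_week_effects = c(0, 0, 0, 0, 0, 0, -20),
                              residual_sd = 15, subject_sd = 20)
    ests <- vapply(1:5, function(r) {
      d <- gen_daily_dataset(spec, n_days = 13, seed = 500 + r)
      m <- fit_mixed(d, "lpa", factor = "day_of_week")
      m$estimates$estimate[m$estimates$term == "day_of_weekSunday"]
    }, numeric(1))
    abs(mean(ests) - (-20))
  }
  expect_lt(bias_at(60), bias_at(10) + 1.5)  # allow Monte-Carlo slack
})
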