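#' Fit a linear mixed model for a daily activity outcome
#'
#' The repeated-measures workhorse: daily outcome minutes modelled as
#' `outcome ~ factor + age + sex + vo2peak (+ wear_minutes) + (1 | subject)`
#' fitted by REML (lme4). Daily wear time enters as a covariate for every
#' physical-activity outcome but is excluded when the outcome is wear time
#' itself. The joint significance of the factor is a likelihood-ratio test
#' against the covariates-only model, both refitted by maximum likelihood.
#' Reference levels: Monday for day of week, Spring for season, male for
#' sex. Optional heteroscedasticity correction: per-factor-level inverse
#' residual variances estimated from an initial unweighted fit, one
#' re-weighting pass.
#'
#' @param data daily-summary data.frame (one row per subject-day) with
#'   columns `subject_id, age, sex, vo2peak, wear_minutes` plus the outcome
#'   and factor columns.
#' @param outcome outcome column name (minutes/day), e.g. `"tpa"`,
#'   `"mvpa"`, `"wear_minutes"`, `"sleep_minutes"`.
#' @param factor one of `"day_of_week"` (7 levels), `"weekend_week"`
#'   (weekend indicator + week 1/2), `"measurement_day"` (numeric 1-13
#'   reactivity trend), `"season"` (4 levels).
#' @param weights `"none"` or `"by_factor_level"`.
#' @param compute_estimates skip the REML estimates fit (LRT only) when
#'   `FALSE`; used by calibration simulations.
#' @return a `model_result` list: `estimates` (term, estimate, se, ci_lo,
#'   ci_hi), `factor_test` (statistic, df, p), variance components, `n_obs`,
#'   `n_subjects`, `converged`, and the spec echo.
#' @export
fit_mixed <- function(data, outcome,
                      factor = c("day_of_week", "weekend_week",
                                 "measurement_day", "season"),
                      weights = c("none", "by_factor_level"),
                      compute_estimates = TRUE) {
  factor <- match.arg(factor)
  weights <- match.arg(weights)
  data <- prep_model_data(data, outcome)
  if (length(unique(data$subject_id)) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }

  factor_terms <- switch(factor,
    day_of_week = "day_of_week",
    weekend_week = "is_weekend + week_index",
    measurement_day = "measurement_day",
    season = "season"
  )
  covars <- c("age", "sex", "vo2peak")
  if (outcome != "wear_minutes" && "wear_minutes" %in% names(data)) {
    covars <- c(covars, "wear_minutes")
  }
  fixed_full <- paste(c(factor_terms, covars), collapse = " + ")
  fixed_null <- paste(covars, collapse = " + ")
  f_full <- as.formula(paste(".outcome ~", fixed_full, "+ (1 | subject_id)"))
  f_null <- as.formula(paste(".outcome ~", fixed_null, "+ (1 | subject_id)"))

  check_full_rank(as.formula(paste("~", fixed_full)), data)

  w <- NULL
  converged <- TRUE
  fit_quiet <- function(formula, reml, w) {
    ok <- TRUE
    fit <- withCallingHandlers(
      lme4::lmer(formula, data = data, REML = reml, weights = w,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(cond) {
        if (grepl("converge", conditionMessage(cond), ignore.case = TRUE)) {
          ok <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(cond) invokeRestart("muffleMessage")
    )
    list(fit = fit, ok = ok)
  }

  if (weights == "by_factor_level") {
    pre <- fit_quiet(f_full, reml = TRUE, w = NULL)
    lev <- factor_level_key(data, factor)
    rv <- tapply(resid(pre$fit), lev, function(r) max(var(r), 1e-8))
    w <- as.numeric(1 / rv[lev])
    data$.w <- w
  }

  full_ml <- fit_quiet(f_full, reml = FALSE, w = w)
  null_ml <- fit_quiet(f_null, reml = FALSE, w = w)
  converged <- full_ml$ok && null_ml$ok
  stat <- max(0, 2 * (as.numeric(logLik(full_ml$fit)) -
                        as.numeric(logLik(null_ml$fit))))
  df <- length(lme4::fixef(full_ml$fit)) - length(lme4::fixef(null_ml$fit))
  p <- pchisq(stat, df = df, lower.tail = FALSE)

  est <- NULL; vc <- c(subject = NA_real_, residual = NA_real_)
  if (compute_estimates) {
    reml <- fit_quiet(f_full, reml = TRUE, w = w)
    converged <- converged && reml$ok
    b <- lme4::fixef(reml$fit)
    se <- sqrt(diag(as.matrix(vcov(reml$fit))))
    est <- data.frame(term = names(b), estimate = as.numeric(b),
                      se = se, ci_lo = b - 1.96 * se, ci_hi = b + 1.96 * se,
                      row.names = NULL)
    v <- as.data.frame(lme4::VarCorr(reml$fit))
    vc <- c(subject = v$vcov[v$grp == "subject_id"][1],
            residual = v$vcov[v$grp == "Residual"][1])
  }

  structure(list(
    outcome = outcome, factor = factor, weights = weights,
    estimates = est,
    factor_test = list(statistic = stat, df = df, p = p),
    var_subject = vc[["subject"]], var_residual = vc[["residual"]],
    n_obs = nrow(data), n_subjects = length(unique(data$subject_id)),
    converged = converged
  ), class = "model_result")
}

# coerce model columns to the conventions every fit expects
prep_model_data <- function(data, outcome) {
  if (!outcome %in% names(data)) {
    stop("outcome column not found: ", outcome, call. = FALSE)
  }
  need <- c("subject_id", "age", "sex", "vo2peak")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data$.outcome <- data[[outcome]]
  data <- data[complete.cases(data[, c(".outcome", need)]), , drop = FALSE]
  data$subject_id <- base::factor(data$subject_id)
  data$sex <- stats::relevel(base::factor(data$sex), ref = "male")
  if ("day_of_week" %in% names(data)) {
    data$day_of_week <- droplevels(base::factor(data$day_of_week,
                                                levels = dow_levels()))
  }
  if ("season" %in% names(data)) {
    data$season <- droplevels(base::factor(as.character(data$season),
                                           levels = season_levels()))
  }
  if ("week_index" %in% names(data)) {
    data$week_index <- base::factor(data$week_index, levels = c(1, 2))
  }
  data
}

factor_level_key <- function(data, factor) {
  switch(factor,
    day_of_week = as.character(data$day_of_week),
    weekend_week = paste(data$is_weekend, data$week_index),
    measurement_day = as.character(data$measurement_day),
    season = as.character(data$season)
  )
}

check_full_rank <- function(formula, data) {
  X <- model.matrix(formula, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s ~ %s (weights: %s)\n", x$outcome, x$factor,
              x$weights))
  cat(sprintf("  n_obs %d, n_subjects %d, converged %s\n", x$n_obs,
              x$n_subjects, x$converged))
  cat(sprintf("  factor LRT: chisq = %.3f, df = %d, p = %.4g\n",
              x$factor_test$statistic, x$factor_test$df, x$factor_test$p))
  if (!is.null(x$estimates)) {
    print(x$estimates, digits = 4)
  }
  invisible(x)
}

#' Weekday/weekend by week contrast
#'
#' Mixed model with fixed effects for weekend (vs weekday) and week 2 (vs
#' week 1), the standard covariate set, and a subject random intercept.
#'
#' @inheritParams fit_mixed
#' @return a `model_result`; the `is_weekendTRUE` and `week_index2` rows of
#'   `estimates` are the contrasts of interest.
#' @export
weekend_week_contrast <- function(data, outcome, weights = "none") {
  fit_mixed(data, outcome, factor = "weekend_week", weights = weights)
}

#' Weekend vs weekday sleep regression
#'
#' Ordinary least squares of daily sleep minutes on a weekend indicator;
#' reports the weekend minus weekday difference with 95% CI and p-value.
#'
#' @param data daily-summary data.frame with `sleep_minutes` and
#'   `is_weekend`.
#' @return list: `estimate`, `se`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
sleep_weekday_regression <- function(data) {
  keep <- !is.na(data$sleep_minutes)
  if (!any(keep)) stop("no sleep minutes available", call. = FALSE)
  d <- data[keep, , drop = FALSE]
  fit <- lm(sleep_minutes ~ is_weekend, data = d)
  sm <- summary(fit)$coefficients
  est <- sm["is_weekendTRUE", "Estimate"]
  se <- sm["is_weekendTRUE", "Std. Error"]
  list(estimate = est, se = se, ci_lo = est - 1.96 * se,
       ci_hi = est + 1.96 * se, p = sm["is_weekendTRUE", "Pr(>|t|)"],
       n = nrow(d))
}

#' Wilcoxon rank-sum comparison of wear time between groups
#'
#' Two-sided rank-sum test of daily wear minutes, group A vs group B.
#'
#' @param group_a,group_b numeric vectors of daily wear minutes.
#' @param exact passed to [stats::wilcox.test()].
#' @return list: `statistic` (W), `p`.
#' @export
weartime_rank_test <- function(group_a, group_b, exact = NULL) {
  if (!length(group_a) || !length(group_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided", exact = exact)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Serialise model results to JSON
#'
#' @param results named list of `model_result` (and/or plain lists).
#' @param path output path.
#' @param config optional config echo.
#' @export
write_model_json <- function(results, path, config = NULL) {
  payload <- list(config = config,
                  results = lapply(results, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null", na = "null")
  invisible(path)
}
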