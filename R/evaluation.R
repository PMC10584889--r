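#' Random train/validation split of a cohort
#'
#' Uniform random partition without replacement: `n_train` ids go to the
#' training set, the complement to validation. Deterministic under `seed`.
#'
#' @param ids Sample ids (or a tibble with `sample_id`).
#' @param n_train Training-set size (< number of ids).
#' @param seed Integer seed.
#' @return List with `train` and `validation` id vectors.
#' @export
split_cohort <- function(ids, n_train, seed) {
  assert_seed(seed)
  if (is.data.frame(ids)) ids <- ids$sample_id
  n_train <- assert_count(n_train, "n_train")
  if (n_train >= length(ids)) abort("`n_train` must be smaller than the cohort")
  train <- withr::with_seed(seed, sample(ids, n_train))
  list(train = train, validation = setdiff(ids, train))
}

#' Rank-based AUC (concordance of predictions with a binary outcome)
#'
#' Equivalent to the Mann-Whitney statistic: the probability that a random
#' case outranks a random control, with ties counted half.
#'
#' @param pred Numeric predictions.
#' @param outcome Binary outcome (0/1).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(pred, outcome) {
  y <- as.integer(outcome)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("AUC needs both cases and controls")
  r <- rank(pred)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a per-SD score-outcome regression model
#'
#' The score is standardized to mean 0, SD 1 over the complete-case fit rows
#' (so the effect is per SD of score), then entered into a logistic
#' (`family = "logistic"`) or linear (`"linear"`) model with the stated
#' covariates. Reports the per-SD effect (odds ratio for logistic, units per
#' SD for linear) with a Wald 95% CI and p-value, plus AUC (rank-based
#' concordance of fitted probabilities) or adjusted R-squared. Complete-case
#' analysis; the number of dropped rows is recorded.
#'
#' @param data Tibble containing the score, outcome and covariates.
#' @param score Name of the score column.
#' @param outcome Name of the outcome column (binary for logistic).
#' @param covariates Character vector of covariate columns (default none).
#' @param family `"logistic"` or `"linear"`.
#' @return A `score_eval` object.
#' @export
fit_score_model <- function(data, score, outcome, covariates = character(),
                            family = c("logistic", "linear")) {
  family <- match.arg(family)
  assert_columns(data, c(score, outcome, covariates), "model data")

  used <- data[c(outcome, score, covariates)]
  cc <- complete.cases(used)
  used <- used[cc, ]
  n <- nrow(used)
  if (n <= length(covariates) + 2) {
    abort("too few complete cases for the requested model")
  }

  s <- used[[score]]
  if (sd(s) == 0) abort("score has zero variance over the fit rows")
  used$.score_std <- (s - mean(s)) / sd(s)

  form <- reformulate(c(".score_std", covariates), response = outcome)

  if (family == "logistic") {
    if (var(used[[outcome]]) == 0) abort("outcome has zero variance")
    fit <- suppressWarnings(glm(form, data = used, family = binomial()))
    beta <- coef(fit)[".score_std"]
    se <- sqrt(diag(stats::vcov(fit)))[".score_std"]
    if (!fit$converged || abs(beta) > 15) {
      abort("logistic fit did not converge (possible separation)")
    }
    est <- exp(beta)
    ci <- exp(beta + c(-1.96, 1.96) * se)
    stat <- rank_auc(fitted(fit), used[[outcome]])
    stat_name <- "auc"
  } else {
    if (var(used[[outcome]]) == 0) abort("outcome has zero variance")
    fit <- lm(form, data = used)
    beta <- coef(fit)[".score_std"]
    se <- sqrt(diag(stats::vcov(fit)))[".score_std"]
    est <- unname(beta)
    ci <- beta + c(-1.96, 1.96) * se
    stat <- summary(fit)$adj.r.squared
    stat_name <- "adj_r_squared"
  }
  zval <- beta / se
  p <- 2 * pnorm(-abs(zval))

  structure(
    list(
      score = score, outcome = outcome, family = family,
      effect_per_sd = unname(est),
      ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
      p_value = unname(p),
      statistic = unname(stat), statistic_name = stat_name,
      n = n, n_dropped = sum(!cc),
      covariates = covariates,
      fit = fit
    ),
    class = "score_eval"
  )
}

#' @export
print.score_eval <- function(x, ...) {
  eff <- if (x$family == "logistic") "OR per SD" else "effect per SD"
  cat(sprintf("<score_eval> %s ~ %s (%s), n = %d\n",
              x$outcome, x$score, x$family, x$n))
  cat(sprintf("  %s = %.3f (95%% CI %.3f-%.3f), p = %.3g; %s = %.4f\n",
              eff, x$effect_per_sd, x$ci_lower, x$ci_upper, x$p_value,
              x$statistic_name, x$statistic))
  invisible(x)
}

#' @method tidy score_eval
#' @export
tidy.score_eval <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4]
  )
}

#' @method glance score_eval
#' @export
glance.score_eval <- function(x, ...) {
  out <- tibble::tibble(
    score = x$score, outcome = x$outcome, family = x$family,
    effect_per_sd = x$effect_per_sd,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    p_value = x$p_value, n = x$n, n_dropped = x$n_dropped
  )
  out[[x$statistic_name]] <- x$statistic
  out
}

#' Select the best-performing candidate score on a training split
#'
#' Fits each candidate score column on the training rows and selects the
#' maximum AUC (logistic) or maximum adjusted R-squared (linear); ties go to
#' the first candidate in input order. The winner is refit on the validation
#' rows. Selection touches only training rows.
#'
#' @param data Tibble with candidate score columns, outcome and covariates.
#' @param candidates Character vector of candidate score columns.
#' @param train_ids,validation_ids Sample-id vectors (matched against
#'   `data$sample_id`).
#' @param outcome,covariates,family As in [fit_score_model()].
#' @return List: `best` (column name), `train_results` tibble (one row per
#'   candidate), `validation` (`score_eval` of the winner on validation).
#' @export
select_best <- function(data, candidates, train_ids, validation_ids,
                        outcome, covariates = character(),
                        family = c("logistic", "linear")) {
  family <- match.arg(family)
  if (length(candidates) < 1) abort("need at least one candidate score")
  assert_columns(data, "sample_id", "data")

  train <- data[data$sample_id %in% train_ids, ]
  valid <- data[data$sample_id %in% validation_ids, ]

  train_results <- purrr::map_dfr(candidates, function(sc) {
    res <- tryCatch(
      fit_score_model(train, sc, outcome, covariates, family),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(score = sc, effect_per_sd = NA_real_,
                            statistic = NA_real_, converged = FALSE))
    }
    tibble::tibble(score = sc, effect_per_sd = res$effect_per_sd,
                   statistic = res$statistic, converged = TRUE)
  })
  if (all(!train_results$converged)) abort("no candidate score could be fit")

  stat <- ifelse(train_results$converged, train_results$statistic, -Inf)
  best <- candidates[which.max(stat)]  # first index on ties

  list(
    best = best,
    train_results = train_results,
    validation = fit_score_model(valid, best, outcome, covariates, family)
  )
}

#' Decile risk stratification against reference-anchored deciles
#'
#' Groups samples by their reference-derived decile and reports per-decile
#' counts with prevalence (binary outcome) or median and IQR (continuous).
#' For binary outcomes the top-versus-bottom-decile odds ratio is computed
#' from the 2x2 table with a Woolf (log-OR normal) 95% CI; it is suppressed
#' when either extreme decile is empty or degenerate.
#'
#' @param data Tibble with a `decile` column (1-10, from [percentile_rank()])
#'   and the outcome.
#' @param outcome Outcome column name.
#' @param type `"binary"` or `"continuous"`.
#' @return A `decile_table` tibble; attributes `top_vs_bottom_or`,
#'   `or_ci_lower`, `or_ci_upper` for binary outcomes.
#' @export
decile_stratify <- function(data, outcome, type = c("binary", "continuous")) {
  type <- match.arg(type)
  assert_columns(data, c("decile", outcome), "data")
  keep <- !is.na(data[[outcome]]) & !is.na(data$decile)
  data <- data[keep, ]

  base <- tibble::tibble(decile = 1:10)
  if (type == "binary") {
    tab <- dplyr::summarise(
      dplyr::group_by(data, .data$decile),
      n = dplyr::n(),
      cases = sum(.data[[outcome]] == 1),
      prevalence = mean(.data[[outcome]] == 1),
      .groups = "drop"
    )
    out <- dplyr::left_join(base, tab, by = "decile")
    out$n[is.na(out$n)] <- 0L
  } else {
    tab <- dplyr::summarise(
      dplyr::group_by(data, .data$decile),
      n = dplyr::n(),
      median = median(.data[[outcome]]),
      q1 = quantile(.data[[outcome]], 0.25),
      q3 = quantile(.data[[outcome]], 0.75),
      .groups = "drop"
    )
    out <- dplyr::left_join(base, tab, by = "decile")
    out$n[is.na(out$n)] <- 0L
  }

  or <- ci <- c(NA_real_, NA_real_, NA_real_)
  if (type == "binary") {
    top <- out[out$decile == 10, ]
    bot <- out[out$decile == 1, ]
    a <- top$cases; b <- top$n - top$cases
    c_ <- bot$cases; d <- bot$n - bot$cases
    if (isTRUE(top$n > 0) && isTRUE(bot$n > 0) &&
        all(c(a, b, c_, d) > 0)) {
      lor <- log((a * d) / (b * c_))
      se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
      or <- c(exp(lor), exp(lor - 1.96 * se), exp(lor + 1.96 * se))
    }
  }

  structure(
    out,
    class = c("decile_table", class(out)),
    outcome = outcome, type = type,
    top_vs_bottom_or = or[1], or_ci_lower = or[2], or_ci_upper = or[3]
  )
}

#' Odds ratio from a 2x2 case/control table with Woolf CI
#'
#' @param cases_high,controls_high Counts in the high-risk group.
#' @param cases_low,controls_low Counts in the low-risk group.
#' @return Tibble `or`, `ci_lower`, `ci_upper`.
#' @export
odds_ratio_2x2 <- function(cases_high, controls_high, cases_low, controls_low) {
  lor <- log((cases_high * controls_low) / (controls_high * cases_low))
  se <- sqrt(1 / cases_high + 1 / controls_high + 1 / cases_low +
               1 / controls_low)
  tibble::tibble(or = exp(lor),
                 ci_lower = exp(lor - 1.96 * se),
                 ci_upper = exp(lor + 1.96 * se))
}

#' Score-by-risk-factor interaction test with stratified effects
#'
#' Fits the outcome on main effects plus a score-by-factor product term and
#' reports the two-sided Wald p-value of the product term. For a binary
#' factor, per-stratum score effects are also fit, with the stratifying
#' variable removed from the covariate list (as for age/sex subgroup models).
#'
#' @param data Tibble with score, factor, outcome and covariates.
#' @param score,outcome,covariates,family As in [fit_score_model()].
#' @param risk_factor Name of the (binary or continuous) risk-factor column.
#' @param stratified Also fit per-stratum models for a binary factor
#'   (default `TRUE`).
#' @return List: `p_interaction`, `interaction_term`, `strata` (tibble of
#'   per-stratum `score_eval` summaries; `NULL` for continuous factors or
#'   `stratified = FALSE`).
#' @export
interaction_test <- function(data, score, risk_factor, outcome,
                             covariates = character(),
                             family = c("logistic", "linear"),
                             stratified = TRUE) {
  family <- match.arg(family)
  assert_columns(data, c(score, risk_factor, outcome, covariates), "data")

  used <- data[c(outcome, score, risk_factor, covariates)]
  used <- used[complete.cases(used), ]
  s <- used[[score]]
  used$.score_std <- (s - mean(s)) / sd(s)

  form <- stats::as.formula(paste(
    outcome, "~ .score_std *", risk_factor,
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""
  ))
  fit <- if (family == "logistic") {
    suppressWarnings(glm(form, data = used, family = binomial()))
  } else {
    lm(form, data = used)
  }
  sm <- summary(fit)$coefficients
  term <- grep(paste0("^\\.score_std:"), rownames(sm), value = TRUE)
  if (length(term) == 0) abort("interaction term missing from the fit")
  zval <- sm[term[1], 1] / sm[term[1], 2]
  p_int <- 2 * pnorm(-abs(zval))

  strata <- NULL
  lev <- unique(stats::na.omit(data[[risk_factor]]))
  if (stratified && length(lev) == 2) {
    strat_cov <- setdiff(covariates, risk_factor)
    strata <- purrr::map_dfr(sort(lev), function(l) {
      sub <- data[!is.na(data[[risk_factor]]) & data[[risk_factor]] == l, ]
      if (nrow(sub) == 0) abort("empty stratum")
      res <- fit_score_model(sub, score, outcome, strat_cov, family)
      dplyr::mutate(glance(res), stratum = paste0(risk_factor, "=", l),
                    .before = 1)
    })
  }

  list(p_interaction = unname(p_int),
       interaction_term = term[1],
       model = fit,
       strata = strata,
       covariates = setdiff(covariates, risk_factor))
}

#' Compare characteristics of high- vs low-genomic-risk extremes
#'
#' Continuous characteristics are compared by Welch's two-sample t-test
#' (Student's optional); binary characteristics by a chi-squared test on the
#' 2x2 table. Output is a long table mirroring the usual
#' supplementary-table layout.
#'
#' @param data Phenotype tibble.
#' @param high,low Logical vectors (or column names) flagging the top and
#'   bottom quintile groups.
#' @param continuous,binary Character vectors of columns to compare.
#' @param test `"welch"` (default) or `"student"` for continuous columns.
#' @return Tibble: `variable`, `type`, `mean_high`/`mean_low` (or
#'   proportions), `statistic`, `p_value`, `test`.
#' @export
compare_extremes <- function(data, high, low,
                             continuous = character(),
                             binary = character(),
                             test = c("welch", "student")) {
  test <- match.arg(test)
  if (is.character(high)) high <- data[[high]]
  if (is.character(low)) low <- data[[low]]
  high <- !is.na(high) & high
  low <- !is.na(low) & low
  if (sum(high) < 2 || sum(low) < 2) {
    abort("both extreme groups need at least 2 samples")
  }

  cont <- purrr::map_dfr(continuous, function(v) {
    xh <- data[[v]][high]
    xl <- data[[v]][low]
    tt <- t.test(xh, xl, var.equal = (test == "student"))
    tibble::tibble(variable = v, type = "continuous",
                   mean_high = mean(xh, na.rm = TRUE),
                   mean_low = mean(xl, na.rm = TRUE),
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   test = if (test == "welch") "Welch t" else "Student t")
  })
  bin <- purrr::map_dfr(binary, function(v) {
    xh <- data[[v]][high]
    xl <- data[[v]][low]
    tab <- rbind(c(sum(xh == 1, na.rm = TRUE), sum(xh == 0, na.rm = TRUE)),
                 c(sum(xl == 1, na.rm = TRUE), sum(xl == 0, na.rm = TRUE)))
    ct <- suppressWarnings(chisq.test(tab))
    tibble::tibble(variable = v, type = "binary",
                   mean_high = mean(xh == 1, na.rm = TRUE),
                   mean_low = mean(xl == 1, na.rm = TRUE),
                   statistic = unname(ct$statistic),
                   p_value = ct$p.value,
                   test = "chi-squared")
  })
  dplyr::bind_rows(cont, bin)
}

#' Score performance over repeated comparator subsets
#'
#' Draws `n_replicates` random subsets of size `subset_size` (see
#' [replicate_subsets()]) and fits the per-SD score model on each, returning
#' the distribution of effects and fit statistics. Fit failures are counted,
#' not fatal.
#'
#' @param data Tibble with `sample_id`, score, outcome and covariates.
#' @param subset_size,n_replicates,seed As in [replicate_subsets()].
#' @param score,outcome,covariates,family As in [fit_score_model()].
#' @return Tibble with one row per successful replicate (`replicate`,
#'   `effect_per_sd`, `statistic`); attributes `summary` (mean and 2.5/97.5
#'   percentiles) and `n_failed`.
#' @export
replicate_performance <- function(data, subset_size, n_replicates, score,
                                  outcome, covariates = character(),
                                  family = c("logistic", "linear"), seed) {
  family <- match.arg(family)
  assert_columns(data, "sample_id", "data")
  subsets <- replicate_subsets(data$sample_id, subset_size, n_replicates, seed)

  rows <- purrr::imap(subsets, function(ids, i) {
    sub <- data[data$sample_id %in% ids, ]
    res <- tryCatch(fit_score_model(sub, score, outcome, covariates, family),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(replicate = i, effect_per_sd = res$effect_per_sd,
                   statistic = res$statistic,
                   statistic_name = res$statistic_name)
  })
  out <- dplyr::bind_rows(rows)
  n_failed <- n_replicates - nrow(out)

  summ <- tibble::tibble(
    mean_effect = mean(out$effect_per_sd),
    effect_q025 = quantile(out$effect_per_sd, 0.025, names = FALSE),
    effect_q975 = quantile(out$effect_per_sd, 0.975, names = FALSE),
    mean_statistic = mean(out$statistic),
    n_replicates = nrow(out), n_failed = n_failed
  )
  attr(out, "summary") <- summ
  attr(out, "n_failed") <- n_failed
  out
}
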