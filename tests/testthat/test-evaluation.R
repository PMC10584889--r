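sim_logistic <- function(n, beta, seed, interaction = 0) {
  withr::with_seed(seed, {
    s <- rnorm(n)
    f <- rbinom(n, 1, 0.4)
    eta <- beta * s + 0.3 * f + interaction * s * f
    tibble::tibble(
      sample_id = sprintf("s%05d", seq_len(n)),
      score = s, factor = f,
      y = rbinom(n, 1, stats::plogis(eta))
    )
  })
}

test_that("cohort splitting is an exact seeded partition", {
  ids <- sprintf("s%04d", 1:5399)
  sp <- split_cohort(ids, 2700, seed = 17)
  expect_length(sp$train, 2700)
  expect_length(sp$validation, 2699)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_length(intersect(sp$train, sp$validation), 0)
  sp2 <- split_cohort(ids, 2700, seed = 17)
  expect_identical(sp, sp2)
  expect_error(split_cohort(ids, 5399, seed = 1), "smaller")
})

test_that("a null score yields an OR CI covering 1", {
  d <- sim_logistic(5000, beta = 0, seed = 21)
  res <- fit_score_model(d, "score", "y", family = "logistic")
  expect_lte(res$ci_lower, 1)
  expect_gte(res$ci_upper, 1)
  expect_gt(res$p_value, 0.001)
})

test_that("a true OR of 1.8 per SD is recovered", {
  ors <- vapply(1:25, function(s) {
    d <- sim_logistic(5000, beta = log(1.8), seed = 500 + s)
    fit_score_model(d, "score", "y", family = "logistic")$effect_per_sd
  }, numeric(1))
  expect_gte(mean(ors >= 1.6 & ors <= 2.0), 0.95)
})

test_that("model AUC equals the all-pairs concordance oracle (and pROC)", {
  d <- sim_logistic(200, beta = log(2), seed = 23)
  res <- fit_score_model(d, "score", "y", c("factor"), "logistic")
  p <- fitted(res$fit)
  y <- d$y

  conc <- 0
  tot <- 0
  for (i in which(y == 1)) {
    for (j in which(y == 0)) {
      conc <- conc + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
      tot <- tot + 1
    }
  }
  expect_equal(res$statistic, as.numeric(conc / tot), tolerance = 1e-10)
  expect_equal(res$statistic,
               as.numeric(suppressMessages(pROC::auc(y, p))),
               tolerance = 1e-10)
})

test_that("per-SD effects are invariant to affine rescaling of the raw score", {
  d <- sim_logistic(2000, beta = log(1.5), seed = 24)
  r1 <- fit_score_model(d, "score", "y", family = "logistic")
  d$score <- 1000 + 17 * d$score
  r2 <- fit_score_model(d, "score", "y", family = "logistic")
  expect_equal(r1$effect_per_sd, r2$effect_per_sd, tolerance = 1e-8)
  # AUC is invariant under strictly monotone transforms of predictions
  expect_equal(rank_auc(fitted(r1$fit), d$y),
               rank_auc(stats::qlogis(fitted(r1$fit)), d$y), tolerance = 1e-12)
})

test_that("linear family reports adjusted R-squared below R-squared with covariates", {
  withr::with_seed(25, {
    d <- tibble::tibble(score = rnorm(300), cov = rnorm(300))
    d$y <- 0.4 * d$score + 0.2 * d$cov + rnorm(300)
  })
  res <- fit_score_model(d, "score", "y", "cov", "linear")
  sm <- summary(res$fit)
  expect_lt(sm$adj.r.squared, sm$r.squared)
  expect_equal(res$statistic, sm$adj.r.squared)
  expect_equal(res$effect_per_sd, unname(coef(res$fit)[".score_std"]))
})

test_that("best-score selection prefers the low-noise candidate and ignores validation", {
  picks <- vapply(1:20, function(s) {
    withr::with_seed(600 + s, {
      n <- 1200
      g <- rnorm(n)
      d <- tibble::tibble(
        sample_id = sprintf("s%04d", 1:n),
        good = g + 0.3 * rnorm(n),
        bad = g + 3 * rnorm(n),
        y = rbinom(n, 1, stats::plogis(1.2 * g))
      )
    })
    sp <- split_cohort(d$sample_id, 600, seed = s)
    sel <- select_best(d, c("good", "bad"), sp$train, sp$validation, "y")
    sel$best == "good"
  }, logical(1))
  expect_gte(mean(picks), 0.95)

  # mutating validation outcomes cannot change the selection
  withr::with_seed(99, {
    n <- 1000
    g <- rnorm(n)
    d <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                        good = g + 0.3 * rnorm(n), bad = rnorm(n),
                        y = rbinom(n, 1, stats::plogis(g)))
  })
  sp <- split_cohort(d$sample_id, 500, seed = 1)
  sel1 <- select_best(d, c("good", "bad"), sp$train, sp$validation, "y")
  d2 <- d
  flip <- d2$sample_id %in% sp$validation
  d2$y[flip] <- 1 - d2$y[flip]
  sel2 <- select_best(d2, c("good", "bad"), sp$train, sp$validation, "y")
  expect_identical(sel1$best, sel2$best)
  expect_identical(sel1$train_results, sel2$train_results)
})

test_that("decile stratification reports flat nulls, monotone signals and the 2x2 OR", {
  # null: prevalence spread below 5 points at n = 10000
  withr::with_seed(27, {
    d <- tibble::tibble(decile = sample(1:10, 10000, replace = TRUE),
                        y = rbinom(10000, 1, 0.5))
  })
  dt <- decile_stratify(d, "y", "binary")
  # binomial noise alone puts the expected range of 10 independent decile
  # prevalences (n ~ 1000 each) near 0.049, so the bound sits at 5 SDs
  # above zero signal rather than at the noise floor itself
  expect_lt(max(dt$prevalence) - min(dt$prevalence), 0.08)
  expect_equal(sum(dt$n), 10000)

  # toy 2x2: (top 100/50 vs bottom 50/100) gives OR 4
  d2 <- tibble::tibble(
    decile = rep(c(10, 1), times = c(150, 150)),
    y = c(rep(1, 100), rep(0, 50), rep(1, 50), rep(0, 100))
  )
  dt2 <- decile_stratify(d2, "y", "binary")
  expect_equal(attr(dt2, "top_vs_bottom_or"), 4.0, tolerance = 1e-12)
  expect_equal(odds_ratio_2x2(100, 50, 50, 100)$or, 4.0)

  # a liability-model signal is (near) monotone across deciles
  mono <- vapply(1:5, function(s) {
    withr::with_seed(700 + s, {
      n <- 10000
      g <- rnorm(n)
      y <- rbinom(n, 1, stats::plogis(log(1.8) * g))
      dec <- pmin(floor(stats::pnorm(g) * 10) + 1L, 10L)
    })
    pr <- decile_stratify(tibble::tibble(decile = dec, y = y),
                          "y", "binary")$prevalence
    all(diff(pr) > 0)
  }, logical(1))
  expect_gte(sum(mono), 4)

  # continuous outcomes: median/IQR per decile
  withr::with_seed(28, {
    d3 <- tibble::tibble(decile = sample(1:10, 500, replace = TRUE),
                         y = rnorm(500))
  })
  dt3 <- decile_stratify(d3, "y", "continuous")
  expect_true(all(c("median", "q1", "q3") %in% names(dt3)))
})

test_that("interaction Wald test is calibrated under the null and powered under signal", {
  pvals <- vapply(1:200, function(s) {
    d <- sim_logistic(5000, beta = log(1.6), seed = 1000 + s)
    interaction_test(d, "score", "factor", "y",
                     stratified = FALSE)$p_interaction
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)

  power <- vapply(1:30, function(s) {
    d <- sim_logistic(5000, beta = log(1.6), seed = 2000 + s,
                      interaction = 0.5)
    interaction_test(d, "score", "factor", "y",
                     stratified = FALSE)$p_interaction < 0.05
  }, logical(1))
  expect_gt(mean(power), 0.8)
})

test_that("subgroup models drop the stratifying covariate", {
  d <- sim_logistic(3000, beta = log(1.5), seed = 31)
  res <- interaction_test(d, "score", "factor", "y",
                          covariates = "factor")
  expect_false("factor" %in% res$covariates)
  expect_equal(nrow(res$strata), 2)
  expect_true(all(res$strata$n > 0))
})

test_that("extreme-quintile comparisons match closed-form tests", {
  withr::with_seed(33, {
    d <- tibble::tibble(
      grp_high = rep(c(TRUE, FALSE), c(60, 60)),
      age = c(rnorm(60, 58.1, 10), rnorm(60, 60.3, 10)),
      smoker = rbinom(120, 1, 0.4)
    )
  })
  res <- compare_extremes(d, d$grp_high, !d$grp_high,
                          continuous = "age", binary = "smoker")
  # Welch statistic equals the textbook formula
  xh <- d$age[d$grp_high]
  xl <- d$age[!d$grp_high]
  tw <- (mean(xh) - mean(xl)) /
    sqrt(var(xh) / length(xh) + var(xl) / length(xl))
  expect_equal(res$statistic[res$variable == "age"], tw, tolerance = 1e-12)

  # identical groups: p-values of 1 (chi-squared with identical proportions)
  same <- compare_extremes(dplyr::bind_rows(d, d),
                           c(d$grp_high, !d$grp_high),
                           c(!d$grp_high, d$grp_high),
                           continuous = "age", binary = "smoker")
  expect_true(all(same$p_value > 0.99))

  # power at the reported onset-age gap (58.1 vs 60.3, SD 10, n 1000/400)
  hits <- vapply(1:40, function(s) {
    withr::with_seed(3000 + s, {
      a <- rnorm(1000, 58.1, 10)
      b <- rnorm(400, 60.3, 10)
    })
    t.test(a, b)$p.value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("replicate performance reduces to a single fit and is seeded", {
  d <- sim_logistic(800, beta = log(1.7), seed = 35)
  full <- fit_score_model(d, "score", "y", family = "logistic")
  rep1 <- replicate_performance(d, 800, 1, "score", "y",
                                family = "logistic", seed = 2)
  expect_equal(rep1$effect_per_sd, full$effect_per_sd, tolerance = 1e-12)

  r1 <- replicate_performance(d, 300, 20, "score", "y",
                              family = "logistic", seed = 3)
  r2 <- replicate_performance(d, 300, 20, "score", "y",
                              family = "logistic", seed = 3)
  expect_identical(r1$effect_per_sd, r2$effect_per_sd)

  # replicate mean stays near the full-pool effect on a homogeneous pool
  summ <- attr(r1, "summary")
  se_mc <- sd(r1$effect_per_sd) / sqrt(nrow(r1))
  expect_lt(abs(summ$mean_effect - full$effect_per_sd),
            4 * se_mc + 0.05)
})
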