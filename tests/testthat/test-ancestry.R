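test_that("LD pruning keeps one of an exact duplicate pair and satisfies its postcondition", {
  cfg <- small_config(seed = 51, n_variants = 200, n_duplicate = 10,
                      cohort_sizes = c(panel = 300, reference = 0,
                                       case_control = 0, biobank = 0))
  d <- simulate_genotypes(cfg)
  kept <- ld_prune(d, window = 100, step = 50, r2_thresh = 0.2)

  dup_ids <- grep("^dup", d$variants$variant_id, value = TRUE)
  for (dup in dup_ids) {
    src_pos <- d$variants$pos[d$variants$variant_id == dup] - 1L
    src <- d$variants$variant_id[d$variants$pos == src_pos]
    expect_equal(sum(c(dup, src) %in% kept), 1, info = dup)
  }

  # brute-force postcondition: no surviving within-window pair reaches r2 = 0.2
  ord <- order(d$variants$pos)
  ids_ord <- d$variants$variant_id[ord]
  keep_idx <- which(ids_ord %in% kept)
  dos <- d$dosages[, ord]
  nv <- length(ids_ord)
  starts <- seq(1, max(1, nv - 99), by = 50)
  for (s in starts) {
    win <- intersect(s:(s + 99), keep_idx)
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(dos[, win]))^2
    diag(r2) <- 0
    expect_lt(max(r2, na.rm = TRUE), 0.2)
  }
})

test_that("independent variants are mostly retained by pruning", {
  withr::with_seed(52, {
    d <- make_dataset(matrix(rbinom(500 * 200, 2, runif(200, 0.1, 0.9)),
                             500, 200, byrow = TRUE))
  })
  kept <- ld_prune(d, window = 100, step = 50, r2_thresh = 0.2)
  expect_gte(length(kept), 0.95 * 200)
  expect_error(ld_prune(d, window = 10, step = 50), "window")
})

test_that("PCA fit is orthonormal and reprojects the panel onto itself", {
  st <- small_study()
  panel <- subset_cohort(st$dataset, "panel")
  m <- st$model

  G <- crossprod(m$loadings)
  expect_equal(G, diag(m$k), tolerance = 1e-8, ignore_attr = TRUE)

  pcs_panel <- project_pcs(m, panel)
  X <- sweep(sweep(panel$dosages[, m$variant_id], 2, m$center),
             2, m$scale, "/")
  expect_equal(unname(prstailor:::pc_matrix(pcs_panel)),
               unname(X %*% m$loadings), tolerance = 1e-8)
  # panel-anchored: panel coordinates are centered
  expect_equal(max(abs(colMeans(prstailor:::pc_matrix(pcs_panel)))), 0,
               tolerance = 1e-8)

  expect_error(fit_pca(panel, m$variant_id, k = 10000), "k")
})

test_that("two simulated populations separate strongly on PC1", {
  st <- small_study()
  panel <- subset_cohort(st$dataset, "panel")
  pcs <- project_pcs(st$model, panel)
  a <- pcs$PC1[panel$samples$population == "POP1"]
  b <- pcs$PC1[panel$samples$population == "POP2"]
  within_sd <- sqrt((var(a) + var(b)) / 2)
  expect_gt(abs(mean(a) - mean(b)), 4 * within_sd)
})

test_that("projection behaves at its fixed points and under variant permutation", {
  st <- small_study()
  m <- st$model

  # a sample sitting exactly at the panel mean projects to the origin
  d0 <- make_dataset(matrix(m$center, 1, length(m$center)))
  d0$variants$variant_id <- m$variant_id
  expect_equal(max(abs(prstailor:::pc_matrix(project_pcs(m, d0)))), 0,
               tolerance = 1e-10)

  # variant order does not matter (matching is by id)
  cc <- subset_cohort(st$dataset, "reference")
  perm <- sample(ncol(cc$dosages))
  cc_perm <- prstailor:::filter_variants(cc, perm)
  expect_equal(project_pcs(m, cc)$PC1, project_pcs(m, cc_perm)$PC1,
               tolerance = 1e-10)
})

test_that("projected target samples land nearest their own population centroid", {
  st <- small_study()
  panel <- subset_cohort(st$dataset, "panel")
  pcs_panel <- project_pcs(st$model, panel)
  cent <- function(pop) {
    colMeans(prstailor:::pc_matrix(
      pcs_panel[panel$samples$population == pop, ]))
  }
  c1 <- cent("POP1")
  c2 <- cent("POP2")

  bio <- subset_cohort(st$dataset, "biobank")
  pcs_bio <- prstailor:::pc_matrix(project_pcs(st$model, bio))
  target <- bio$samples$population == "POP1"
  d1 <- sqrt(rowSums(sweep(pcs_bio[target, ], 2, c1)^2))
  d2 <- sqrt(rowSums(sweep(pcs_bio[target, ], 2, c2)^2))
  expect_gte(mean(d1 < d2), 0.9)
})

test_that("PC adjustment reduces to mean-centering when PCs are zero and is orthogonal to PCs", {
  st <- small_study()
  sc <- compute_raw_scores(harmonize_weights(st$scoring$cand2, st$dataset),
                           st$dataset)

  # all-zero PCs degrade to intercept-only: adjusted = raw - mean(raw)
  zero_pcs <- make_pcs(matrix(0, nrow(sc), 10), ids = sc$sample_id)
  adj0 <- adjust_scores(sc, zero_pcs)
  expect_equal(adj0$adjusted, sc$raw - mean(sc$raw), tolerance = 1e-12)

  # duplicated (collinear) PC columns are an error naming the rank
  dup_pcs <- st$pcs
  dup_pcs$PC10 <- dup_pcs$PC1
  expect_error(adjust_scores(sc, dup_pcs), "rank-deficient")

  adj <- adjust_scores(sc, st$pcs)
  pcm <- prstailor:::pc_matrix(st$pcs, 10)
  for (j in 1:10) {
    expect_lt(abs(cor(adj$adjusted, pcm[, j])), 1e-8)
  }
})

test_that("PC-regression coefficients equal the normal-equations solution", {
  withr::with_seed(53, {
    n <- 50
    pcm <- matrix(rnorm(n * 10), n, 10)
    raw <- rnorm(n)
  })
  pcs <- make_pcs(pcm)
  sc <- tibble::tibble(sample_id = pcs$sample_id, raw = raw)
  adj <- adjust_scores(sc, pcs)

  X <- cbind(1, pcm)
  beta <- solve(t(X) %*% X, t(X) %*% raw)
  expect_equal(adj$adjusted, raw - as.numeric(X %*% beta), tolerance = 1e-10)
})

test_that("adjustment removes population structure from drift-only score differences", {
  shrink <- vapply(1:5, function(s) {
    cfg <- small_config(seed = 300 + s, n_variants = 300, h2 = 0,
                        cohort_sizes = c(panel = 300, reference = 0,
                                         case_control = 0, biobank = 300),
                        biobank_target_fraction = 0.5)
    d <- simulate_genotypes(cfg)
    sf <- simulate_scoring_files(d, cfg, 1, 0)
    sc <- compute_raw_scores(harmonize_weights(attr(sf, "truth"), d), d)
    panel <- subset_cohort(d, "panel")
    m <- fit_pca(panel, ld_prune(panel, 150, 50), k = 10)
    pcs <- project_pcs(m, d)
    adj <- adjust_scores(sc, pcs)

    bio <- d$samples$cohort == "biobank"
    pop <- d$samples$population[bio]
    gap <- function(x) abs(mean(x[pop == "POP1"]) - mean(x[pop == "POP2"]))
    1 - gap(adj$adjusted[bio]) / gap(adj$raw[bio])
  }, numeric(1))
  expect_gte(sum(shrink >= 0.8), 4)
})

test_that("reference calibration stores an honest residual summary", {
  st <- small_study()
  ref_ids <- st$dataset$samples$sample_id[
    st$dataset$samples$cohort == "reference"]
  sc <- compute_raw_scores(harmonize_weights(st$scoring$cand2, st$dataset),
                           st$dataset)
  sc_ref <- sc[sc$sample_id %in% ref_ids, ]
  rd <- calibrate_reference(sc_ref, st$pcs)

  expect_lt(abs(rd$residual_mean), 1e-10 * rd$residual_sd)
  expect_equal(rd$n, length(ref_ids))

  # bootstrap refit (resampling score/PC rows jointly) keeps the SD within 15%
  idx <- withr::with_seed(54, sample(nrow(sc_ref), replace = TRUE))
  boot_ids <- sprintf("boot%04d", seq_along(idx))
  boot <- sc_ref[idx, ]
  boot$sample_id <- boot_ids
  boot_pcs <- st$pcs[match(sc_ref$sample_id[idx], st$pcs$sample_id), ]
  boot_pcs$sample_id <- boot_ids
  rd_b <- calibrate_reference(boot, boot_pcs)
  expect_lt(abs(rd_b$residual_sd - rd$residual_sd) / rd$residual_sd, 0.15)

  # degenerate references are rejected
  flat <- tibble::tibble(sample_id = sc_ref$sample_id,
                         raw = rep(1, nrow(sc_ref)))
  expect_error(suppressWarnings(calibrate_reference(flat, st$pcs)),
               "zero variance")
})

test_that("percentiles are uniform on the reference, monotone, and consistent across modes", {
  withr::with_seed(55, {
    n_ref <- 1000
    pcm <- matrix(rnorm(n_ref * 10), n_ref, 10)
    raw <- as.numeric(pcm %*% rnorm(10)) + rnorm(n_ref)
  })
  pcs <- make_pcs(pcm, ids = sprintf("r%04d", 1:n_ref))
  sc <- tibble::tibble(sample_id = pcs$sample_id, raw = raw)
  rd <- calibrate_reference(sc, pcs)
  pr <- percentile_rank(rd, sc, pcs)

  # KS distance from Uniform(0, 100) below the alpha = 0.01 critical value
  ks <- max(abs(sort(pr$percentile) / 100 - (seq_len(n_ref)) / n_ref))
  expect_lt(ks, 1.63 / sqrt(n_ref))

  # reference deciles hold 10% +/- 1 sample each
  expect_true(all(abs(table(pr$decile) - n_ref / 10) <= 1))

  # the reference median scores at percentile 50 +/- 100/(2n)
  med_resid <- median(rd$sorted_residuals)
  med_raw <- tibble::tibble(sample_id = "x", raw = med_resid)
  med_pcs <- make_pcs(matrix(0, 1, 10), ids = "x")
  # undo the intercept so the residual equals med_resid exactly
  med_raw$raw <- med_resid + rd$coefficients[1]
  pm <- percentile_rank(rd, med_raw, med_pcs)
  expect_lt(abs(pm$percentile - 50), 100 / (2 * n_ref) + 1e-9)

  # strictly larger raw score, same PCs, strictly larger percentile
  probe <- tibble::tibble(sample_id = c("a", "b"),
                          raw = rd$coefficients[1] +
                            quantile(rd$sorted_residuals, c(0.3, 0.31)))
  probe_pcs <- make_pcs(matrix(0, 2, 10), ids = c("a", "b"))
  pp <- percentile_rank(rd, probe, probe_pcs)
  expect_lt(pp$percentile[1], pp$percentile[2])

  # normal-CDF mode agrees with the empirical mode on Gaussian residuals
  pr_n <- percentile_rank(rd, sc, pcs, mode = "normal")
  expect_lt(max(abs(pr_n$percentile - pr$percentile)), 3)

  expect_error(percentile_rank(list(), sc, pcs), "calibrated")
})
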