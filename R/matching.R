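#' Ancestry matching by squared Mahalanobis distance
#'
#' Computes the centroid and sample covariance of the target cohort in PC
#' space, the squared Mahalanobis distance of every candidate from that
#' centroid, and matches candidates whose distance does not exceed the
#' chi-squared critical value at significance level `alpha` with `df` degrees
#' of freedom. The covariance is ridge-regularized (epsilon x trace / k on
#' the diagonal) when its condition number exceeds 1e8.
#'
#' @param candidate_pcs `pc_scores` tibble of candidates (e.g. a biobank).
#' @param target_pcs `pc_scores` tibble of the target cohort.
#' @param alpha Significance level of the boundary (default 0.05).
#' @param df Degrees of freedom; must equal the PC dimension (default 10).
#' @return A `mahalanobis_match`: tibble (`sample_id`, `d2`, `matched`) plus
#'   `centroid`, `covariance`, `cutoff`, `alpha`, `df`.
#' @export
mahalanobis_match <- function(candidate_pcs, target_pcs,
                              alpha = 0.05, df = 10) {
  assert_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  df <- assert_count(df, "df")
  Xc <- pc_matrix(candidate_pcs)
  Xt <- pc_matrix(target_pcs)
  if (ncol(Xt) != df || ncol(Xc) != df) {
    abort(sprintf("df = %d must equal the PC-coordinate dimension (%d)",
                  df, ncol(Xt)))
  }
  if (nrow(Xt) <= df) abort("target cohort must be larger than df")

  mu <- colMeans(Xt)
  S <- cov(Xt)
  if (kappa(S) > 1e8) {
    S <- S + diag(1e-6 * sum(diag(S)) / df, df)
  }
  Sinv <- tryCatch(solve(S), error = function(e) {
    abort("target covariance is singular even after regularization")
  })

  d2 <- mahalanobis(Xc, mu, S)
  cutoff <- qchisq(1 - alpha, df)

  structure(
    list(
      matches = tibble::tibble(
        sample_id = candidate_pcs$sample_id,
        d2 = d2,
        matched = d2 <= cutoff
      ),
      centroid = mu, covariance = S,
      cutoff = cutoff, alpha = alpha, df = df,
      n_target = nrow(Xt)
    ),
    class = "mahalanobis_match"
  )
}

#' @export
print.mahalanobis_match <- function(x, ...) {
  cat(sprintf(
    "<mahalanobis_match> %d / %d candidates within chi-squared cutoff %.3f (alpha %.3g, df %d)\n",
    sum(x$matches$matched), nrow(x$matches), x$cutoff, x$alpha, x$df))
  invisible(x)
}

#' @method tidy mahalanobis_match
#' @export
tidy.mahalanobis_match <- function(x, ...) x$matches

#' @method glance mahalanobis_match
#' @export
glance.mahalanobis_match <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$matches),
    n_matched = sum(x$matches$matched),
    matched_fraction = mean(x$matches$matched),
    cutoff = x$cutoff, alpha = x$alpha, df = x$df,
    n_target = x$n_target
  )
}

standardized_mean_diff <- function(x_case, x_ctrl) {
  s <- sqrt((var(x_case) + var(x_ctrl)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x_case) - mean(x_ctrl)) / s
}

#' 1:1 nearest-neighbor covariate matching
#'
#' Greedy sequential matching without replacement: cases are shuffled in a
#' seed-fixed order; each case is matched to the unused pool member with the
#' smallest Euclidean distance on standardized continuous covariates, with
#' exact matching enforced first on binary covariates. Produces an
#' equal-sized comparator cohort and a covariate balance table (standardized
#' mean differences before and after matching).
#'
#' @param cases,pool Tibbles with a `sample_id` column and the covariates.
#' @param covariates Character vector of covariate columns present in both.
#' @param seed Integer seed fixing the case order.
#' @return A `covariate_match`: `pairs` tibble (`case_id`, `control_id`,
#'   `distance`) and `balance` tibble (`covariate`, `smd_pre`, `smd_post`).
#' @export
nearest_neighbor_match <- function(cases, pool, covariates, seed) {
  assert_seed(seed)
  assert_columns(cases, c("sample_id", covariates), "cases")
  assert_columns(pool, c("sample_id", covariates), "pool")
  if (nrow(pool) < nrow(cases)) abort("pool must be at least as large as cases")

  comb <- dplyr::bind_rows(cases[covariates], pool[covariates])
  is_binary <- vapply(covariates, function(v) {
    length(unique(stats::na.omit(comb[[v]]))) <= 2
  }, logical(1))
  bin_cov <- covariates[is_binary]
  cont_cov <- covariates[!is_binary]

  std <- function(tab) {
    out <- matrix(0, nrow(tab), length(cont_cov))
    for (j in seq_along(cont_cov)) {
      v <- cont_cov[j]
      mu <- mean(comb[[v]], na.rm = TRUE)
      s <- sd(comb[[v]], na.rm = TRUE)
      out[, j] <- if (is.finite(s) && s > 0) (tab[[v]] - mu) / s else 0
    }
    out
  }
  Zc <- std(cases)
  Zp <- std(pool)

  bin_key <- function(tab) {
    if (length(bin_cov) == 0) rep("", nrow(tab))
    else do.call(paste, c(tab[bin_cov], sep = "\r"))
  }
  kc <- bin_key(cases)
  kp <- bin_key(pool)

  ord <- withr::with_seed(seed, sample.int(nrow(cases)))
  used <- rep(FALSE, nrow(pool))
  pair_control <- integer(nrow(cases))
  pair_dist <- numeric(nrow(cases))
  unmatched <- character(0)

  for (i in ord) {
    avail <- which(!used & kp == kc[i])
    if (length(avail) == 0) {
      unmatched <- c(unmatched, cases$sample_id[i])
      next
    }
    if (length(cont_cov) > 0) {
      d <- sqrt(colSums((t(Zp[avail, , drop = FALSE]) - Zc[i, ])^2))
    } else {
      d <- numeric(length(avail))
    }
    j <- avail[which.min(d)]
    used[j] <- TRUE
    pair_control[i] <- j
    pair_dist[i] <- min(d)
  }
  if (length(unmatched) > 0) {
    abort(sprintf("pool exhausted; unmatched cases: %s",
                  paste(sort(unmatched), collapse = ", ")))
  }

  matched_pool <- pool[pair_control, ]
  balance <- purrr::map_dfr(covariates, function(v) {
    tibble::tibble(
      covariate = v,
      smd_pre = abs(standardized_mean_diff(cases[[v]], pool[[v]])),
      smd_post = abs(standardized_mean_diff(cases[[v]], matched_pool[[v]]))
    )
  })

  structure(
    list(
      pairs = tibble::tibble(
        case_id = cases$sample_id,
        control_id = pool$sample_id[pair_control],
        distance = pair_dist
      ),
      balance = balance,
      covariates = covariates, seed = as.integer(seed)
    ),
    class = "covariate_match"
  )
}

#' @export
print.covariate_match <- function(x, ...) {
  cat(sprintf("<covariate_match> %d pairs on %s\n",
              nrow(x$pairs), paste(x$covariates, collapse = ", ")))
  print(x$balance)
  invisible(x)
}

#' @method tidy covariate_match
#' @export
tidy.covariate_match <- function(x, ...) x$pairs

#' Repeated random subsets of a sample pool
#'
#' Draws `n_replicates` independent simple random subsets of `subset_size`
#' without replacement (within each subset), deterministically under `seed`.
#' Used to build comparator-resampling distributions of score performance.
#'
#' @param ids Vector of sample ids (or a tibble with `sample_id`).
#' @param subset_size Size of each subset.
#' @param n_replicates Number of subsets.
#' @param seed Integer seed.
#' @return List of id vectors, length `n_replicates`.
#' @export
replicate_subsets <- function(ids, subset_size, n_replicates, seed) {
  assert_seed(seed)
  if (is.data.frame(ids)) ids <- ids$sample_id
  subset_size <- assert_count(subset_size, "subset_size")
  n_replicates <- assert_count(n_replicates, "n_replicates")
  if (subset_size > length(ids)) {
    abort("`subset_size` exceeds the pool size")
  }
  withr::with_seed(seed, {
    purrr::map(seq_len(n_replicates), function(i) sample(ids, subset_size))
  })
}
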