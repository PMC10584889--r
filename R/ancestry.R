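#' Greedy windowed LD pruning
#'
#' Slides a window of `window` variants by `step` variants along the
#' position-sorted dataset. Within each window, while any pair of surviving
#' variants has squared dosage correlation `r2 >= r2_thresh`, the member with
#' the lower MAF is removed (tie: the later position). On exit no surviving
#' within-window pair reaches the threshold.
#'
#' @param dataset A `genotype_dataset`.
#' @param window Window size in variants (default 1000).
#' @param step Step size in variants (default 50).
#' @param r2_thresh Squared-correlation threshold (default 0.2).
#' @return Character vector of retained variant ids (position order).
#' @export
ld_prune <- function(dataset, window = 1000, step = 50, r2_thresh = 0.2) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  window <- assert_count(window, "window", min = 2L)
  step <- assert_count(step, "step")
  if (window < step) abort("`window` must be >= `step`")
  assert_number(r2_thresh, "r2_thresh", 0, 1, strict_lower = TRUE)

  ord <- order(dataset$variants$chrom, dataset$variants$pos)
  dos <- dataset$dosages[, ord, drop = FALSE]
  ids <- dataset$variants$variant_id[ord]
  nv <- length(ids)

  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, nv)

  starts <- if (nv <= window) 1L else seq(1L, nv - window + 1L, by = step)
  for (s in starts) {
    win <- s:min(s + window - 1L, nv)
    repeat {
      idx <- win[keep[win]]
      if (length(idx) < 2) break
      cc <- suppressWarnings(cor(dos[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      cc[!is.finite(cc)] <- 0
      cc[lower.tri(cc, diag = TRUE)] <- 0
      hit <- which(cc >= r2_thresh, arr.ind = TRUE)
      if (nrow(hit) == 0) break
      i <- idx[hit[1, 1]]
      j <- idx[hit[1, 2]]
      drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
      keep[drop] <- FALSE
    }
  }
  ids[keep]
}

#' Fit a PCA model of ancestry on a reference panel
#'
#' Dosage columns of the pruned variants are standardized with the panel
#' allele frequency: center `2p`, scale `sqrt(2 p (1 - p))` (monomorphic
#' variants excluded). Loadings are the top-`k` right singular vectors of the
#' standardized matrix, with the sign convention that the largest-magnitude
#' loading in each component is positive.
#'
#' @param panel A `genotype_dataset` (the multi-population panel).
#' @param pruned Character vector of variant ids to use (e.g. [ld_prune()]).
#' @param k Number of components (default 10).
#' @return A `pc_model`: variant ids, per-variant `center`/`scale`, and the
#'   `variants x k` loading matrix.
#' @export
fit_pca <- function(panel, pruned, k = 10) {
  stopifnot(inherits(panel, "genotype_dataset"))
  k <- assert_count(k, "k")
  idx <- match(pruned, panel$variants$variant_id)
  if (anyNA(idx)) abort("some pruned variant ids are absent from the panel")
  dos <- panel$dosages[, idx, drop = FALSE]

  p <- colMeans(dos, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  ids <- pruned[poly]

  if (k > min(dim(dos))) {
    abort(sprintf("k = %d exceeds min(samples, variants) = %d",
                  k, min(dim(dos))))
  }

  ctr <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  X <- sweep(sweep(dos, 2, ctr), 2, scl, "/")
  if (anyNA(X)) X[is.na(X)] <- 0  # missing dosage = panel mean after centering

  sv <- svd(X, nu = 0, nv = k)
  if (sv$d[k] < 1e-8 * sv$d[1]) {
    abort(sprintf("k = %d exceeds the numerical rank of the panel", k))
  }
  V <- sv$v
  for (j in seq_len(k)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- ids

  structure(list(variant_id = ids, center = ctr, scale = scl,
                 loadings = V, k = k,
                 singular_values = sv$d[seq_len(k)]),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d variants, k = %d\n", length(x$variant_id), x$k))
  invisible(x)
}

#' Project samples onto a fitted PC space
#'
#' Dosages are standardized with the model's (panel-derived) centering and
#' scaling and multiplied by the loadings, anchoring all cohorts in the panel
#' coordinate system. Missing dosages are mean-imputed with the panel
#' frequency (i.e. contribute zero after centering). More than 20% of model
#' variants absent from `dataset` is an error.
#'
#' @param model A `pc_model`.
#' @param dataset A `genotype_dataset`.
#' @return Tibble `sample_id`, `PC1` ... `PCk` (class `pc_scores`).
#' @export
project_pcs <- function(model, dataset) {
  stopifnot(inherits(model, "pc_model"),
            inherits(dataset, "genotype_dataset"))
  idx <- match(model$variant_id, dataset$variants$variant_id)
  absent <- is.na(idx)
  if (mean(absent) > 0.2) {
    abort(sprintf("%.0f%% of model variants absent from dataset; projection untrustworthy",
                  100 * mean(absent)))
  }
  nv <- length(model$variant_id)
  X <- matrix(0, nrow(dataset$dosages), nv)
  pres <- which(!absent)
  X[, pres] <- dataset$dosages[, idx[pres], drop = FALSE]
  X[, pres] <- sweep(X[, pres, drop = FALSE], 2, model$center[pres])
  X[is.na(X)] <- 0
  if (any(absent)) X[, absent] <- 0
  X <- sweep(X, 2, model$scale, "/")

  coords <- X %*% model$loadings
  colnames(coords) <- pc_cols(model$k)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = dataset$samples$sample_id),
    tibble::as_tibble(coords)
  )
  class(out) <- c("pc_scores", class(out))
  out
}

pc_matrix <- function(pcs, k = NULL) {
  cols <- grep("^PC\\d+$", names(pcs), value = TRUE)
  cols <- cols[order(as.integer(sub("PC", "", cols)))]
  if (!is.null(k)) cols <- cols[seq_len(k)]
  as.matrix(pcs[cols])
}

# least-squares fit of y on PCs; constant PC columns carry no ancestry signal
# and drop to the intercept; genuinely collinear PCs are an error
fit_pc_regression <- function(y, pcmat) {
  keep <- apply(pcmat, 2, function(col) var(col) > 0)
  X <- cbind(`(Intercept)` = 1, pcmat[, keep, drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    abort(sprintf("PC design matrix is rank-deficient (rank %d < %d): collinear PCs",
                  qr_x$rank, ncol(X)))
  }
  coefs <- setNames(numeric(ncol(pcmat) + 1),
                    c("(Intercept)", colnames(pcmat)))
  coefs[c(TRUE, keep)] <- qr.coef(qr_x, y)
  coefs
}

#' Ancestry-adjust raw polygenic scores with PC residuals
#'
#' Fits `raw ~ PC1 + ... + PCk` by least squares over the fit cohort and
#' returns the residual (raw minus predicted) for every sample, including
#' samples outside the fit cohort, using the fitted coefficients.
#'
#' @param scores Tibble with `sample_id` and `raw` (e.g.
#'   [compute_raw_scores()] output).
#' @param pcs A `pc_scores` tibble covering all samples in `scores`.
#' @param fit_ids Sample ids defining the fit cohort (default: all samples in
#'   `scores`).
#' @param k Number of PCs used (default 10).
#' @return `scores` with an `adjusted` column appended.
#' @export
adjust_scores <- function(scores, pcs, fit_ids = NULL, k = 10) {
  assert_columns(scores, c("sample_id", "raw"), "scores")
  fit_ids <- fit_ids %||% scores$sample_id
  if (length(fit_ids) == 0) abort("fit cohort is empty")

  m <- match(scores$sample_id, pcs$sample_id)
  if (anyNA(m)) abort("PC scores missing for some samples")
  pcmat <- pc_matrix(pcs, k)[m, , drop = FALSE]

  in_fit <- scores$sample_id %in% fit_ids
  if (!any(in_fit)) abort("fit cohort is empty")
  coefs <- fit_pc_regression(scores$raw[in_fit], pcmat[in_fit, , drop = FALSE])
  pred <- as.numeric(cbind(1, pcmat) %*% coefs)
  dplyr::mutate(scores, adjusted = .data$raw - pred)
}

#' Calibrate a reference distribution for percentile reporting
#'
#' Fits the PC-regression of raw scores on the reference cohort and stores the
#' coefficients, the residual mean and SD, and the sorted residual vector for
#' empirical percentile lookup.
#'
#' @param scores_ref Tibble with `sample_id`, `raw` for the reference cohort.
#' @param pcs_ref `pc_scores` for the reference cohort.
#' @param k Number of PCs (default 10).
#' @return A `reference_distribution`.
#' @export
calibrate_reference <- function(scores_ref, pcs_ref, k = 10) {
  assert_columns(scores_ref, c("sample_id", "raw"), "scores_ref")
  n <- nrow(scores_ref)
  if (n < 50) warn(sprintf("reference cohort has only %d samples (< 50)", n))

  m <- match(scores_ref$sample_id, pcs_ref$sample_id)
  if (anyNA(m)) abort("PC scores missing for some reference samples")
  pcmat <- pc_matrix(pcs_ref, k)[m, , drop = FALSE]

  coefs <- fit_pc_regression(scores_ref$raw, pcmat)
  resid <- scores_ref$raw - as.numeric(cbind(1, pcmat) %*% coefs)
  s <- sd(resid)
  # tolerance absorbs float noise when the scores are exactly collinear
  # with the PCs (e.g. a constant reference)
  if (!is.finite(s) || s <= 1e-12 * max(abs(scores_ref$raw), 1)) {
    abort("reference residuals have zero variance; cannot calibrate")
  }

  structure(
    list(coefficients = coefs, k = k,
         residual_mean = mean(resid), residual_sd = s,
         sorted_residuals = sort(resid),
         n = n, reference_ids = scores_ref$sample_id),
    class = "reference_distribution"
  )
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("<reference_distribution> n = %d, residual SD = %.4g, k = %d\n",
              x$n, x$residual_sd, x$k))
  invisible(x)
}

#' Percentile, z-score, decile and quintile against a reference distribution
#'
#' Each sample's residual (raw score minus the reference PC-regression
#' prediction) is standardized with the reference residual mean/SD to give
#' `z`, and ranked against the sorted reference residuals. The default
#' `empirical` mode interpolates mid-rank plotting positions
#' `100 (i - 0.5) / n`; values outside the observed reference range clamp to
#' `100 / (2n)` and `100 - 100 / (2n)`, keeping percentiles in (0, 100). Mode
#' `normal` uses `100 * pnorm(z)`. Deciles/quintiles use right-open bins on
#' the percentile (`[0, 10), ..., [90, 100]`).
#'
#' @param refdist A [calibrate_reference()] result.
#' @param scores Tibble with `sample_id`, `raw`.
#' @param pcs `pc_scores` covering those samples.
#' @param mode `"empirical"` (default) or `"normal"`.
#' @return Tibble `sample_id`, `residual`, `z`, `percentile`, `decile`,
#'   `quintile`; attribute `percentile_mode` records the mode.
#' @export
percentile_rank <- function(refdist, scores, pcs,
                            mode = c("empirical", "normal")) {
  if (!inherits(refdist, "reference_distribution")) {
    abort("`refdist` must be a calibrated reference_distribution")
  }
  mode <- match.arg(mode)
  assert_columns(scores, c("sample_id", "raw"), "scores")

  m <- match(scores$sample_id, pcs$sample_id)
  if (anyNA(m)) abort("PC scores missing for some samples")
  pcmat <- pc_matrix(pcs, refdist$k)[m, , drop = FALSE]

  resid <- scores$raw - as.numeric(cbind(1, pcmat) %*% refdist$coefficients)
  z <- (resid - refdist$residual_mean) / refdist$residual_sd

  if (mode == "empirical") {
    sr <- refdist$sorted_residuals
    n <- length(sr)
    pp <- 100 * (seq_len(n) - 0.5) / n
    pct <- suppressWarnings(
      approx(sr, pp, xout = resid, rule = 2, ties = mean)$y
    )
  } else {
    pct <- 100 * pnorm(z)
  }
  pct <- pmin(pmax(pct, 1e-9), 100 - 1e-9)

  out <- tibble::tibble(
    sample_id = scores$sample_id,
    residual = resid,
    z = z,
    percentile = pct,
    decile = pmin(floor(pct / 10) + 1L, 10L),
    quintile = pmin(floor(pct / 20) + 1L, 5L)
  )
  attr(out, "percentile_mode") <- mode
  out
}

#' Serialize / restore a reference distribution as JSON
#'
#' @param refdist A `reference_distribution`.
#' @param path JSON path.
#' @return `path` (write) / a `reference_distribution` (read).
#' @export
write_reference_distribution <- function(refdist, path) {
  stopifnot(inherits(refdist, "reference_distribution"))
  jsonlite::write_json(
    list(coefficients = as.list(refdist$coefficients), k = refdist$k,
         residual_mean = refdist$residual_mean,
         residual_sd = refdist$residual_sd,
         sorted_residuals = refdist$sorted_residuals,
         n = refdist$n, reference_ids = refdist$reference_ids),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_reference_distribution
#' @export
read_reference_distribution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coefficients = unlist(x$coefficients), k = x$k,
         residual_mean = x$residual_mean, residual_sd = x$residual_sd,
         sorted_residuals = x$sorted_residuals,
         n = x$n, reference_ids = x$reference_ids),
    class = "reference_distribution"
  )
}

#' Write PC model / PC scores in eigenvec-style TSV layouts
#'
#' @param model A `pc_model`; `pcs` a `pc_scores` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pc_model <- function(model, path) {
  stopifnot(inherits(model, "pc_model"))
  tab <- dplyr::bind_cols(
    tibble::tibble(variant_id = model$variant_id,
                   center = model$center, scale = model$scale),
    tibble::as_tibble(model$loadings, .name_repair = ~paste0("loading_", seq_along(.)))
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pc_model
#' @param pcs A `pc_scores` tibble.
#' @export
write_pc_scores <- function(pcs, path) {
  readr::write_tsv(tibble::as_tibble(pcs), path, progress = FALSE)
  invisible(path)
}
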