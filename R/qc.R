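new_qc_report <- function(stage, n_samples_in, n_samples_out,
                          n_variants_in, n_variants_out, filters,
                          sample_stats = NULL, variant_stats = NULL) {
  structure(
    list(stage = stage,
         n_samples_in = n_samples_in, n_samples_out = n_samples_out,
         n_variants_in = n_variants_in, n_variants_out = n_variants_out,
         filters = filters,
         sample_stats = sample_stats, variant_stats = variant_stats),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> stage %s: samples %d -> %d, variants %d -> %d\n",
              x$stage, x$n_samples_in, x$n_samples_out,
              x$n_variants_in, x$n_variants_out))
  print(x$filters)
  invisible(x)
}

#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$filters

hard_calls <- function(dosages) {
  g <- round(dosages)
  g[g < 0] <- 0
  g[g > 2] <- 2
  g
}

#' Sample-level quality control
#'
#' Removes samples with dosage missingness above `miss_thresh`, then samples
#' whose heterozygosity rate (fraction of heterozygous hard calls among
#' non-missing variants, PLINK convention) exceeds the mean by more than
#' `het_sd` standard deviations. Mean and SD are computed over the samples
#' surviving the missingness filter, in that order.
#'
#' @param dataset A `genotype_dataset`.
#' @param miss_thresh Missingness threshold (default 0.05; removal is strict
#'   `> miss_thresh`).
#' @param het_sd Heterozygosity SD multiplier (default 5).
#' @return List with elements `dataset` (filtered) and `report` (`qc_report`
#'   including per-sample missingness/heterozygosity).
#' @export
sample_qc <- function(dataset, miss_thresh = 0.05, het_sd = 5) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (nrow(dataset$dosages) == 0) abort("dataset has no samples")
  assert_number(miss_thresh, "miss_thresh", 0, 1, strict_lower = TRUE)
  assert_number(het_sd, "het_sd", 0, Inf, strict_lower = TRUE)

  dos <- dataset$dosages
  miss <- rowMeans(is.na(dos))
  keep1 <- miss <= miss_thresh
  n_miss_removed <- sum(!keep1)

  g <- hard_calls(dos)
  het <- rowMeans(g == 1, na.rm = TRUE)
  het_surv <- het[keep1]
  if (length(het_surv) == 0) abort("all samples removed by missingness filter")
  cutoff <- mean(het_surv) + het_sd * sd(het_surv)
  if (!is.finite(cutoff)) cutoff <- Inf  # single survivor: SD undefined
  keep2 <- keep1 & het <= cutoff
  n_het_removed <- sum(keep1) - sum(keep2)

  if (!any(keep2)) abort("all samples removed by sample QC")

  report <- new_qc_report(
    "sample_qc",
    n_samples_in = nrow(dos), n_samples_out = sum(keep2),
    n_variants_in = ncol(dos), n_variants_out = ncol(dos),
    filters = tibble::tibble(
      filter = c("missingness", "heterozygosity"),
      threshold = c(miss_thresh, cutoff),
      removed = c(n_miss_removed, n_het_removed)
    ),
    sample_stats = tibble::tibble(
      sample_id = dataset$samples$sample_id,
      missingness = miss, heterozygosity = het, kept = keep2
    )
  )
  list(dataset = filter_samples(dataset, keep2), report = report)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided p-value for the observed heterozygote count given the
#' genotype margins, via the standard enumeration recurrence over all possible
#' heterozygote counts. For very large samples (`n > 5000`) a 1-df chi-squared
#' approximation is used.
#'
#' @param n_het,n_hom1,n_hom2 Genotype counts (heterozygotes and the two
#'   homozygote classes).
#' @return The p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (rare == 0) return(1)

  if (n > 5000) {
    p <- (2 * n_hom1 + n_het) / (2 * n)
    e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    o <- c(n_hom1, n_het, n_hom2)
    if (any(e == 0)) return(1)
    return(unname(pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)))
  }

  probs <- numeric(rare + 1)  # probs[h + 1] = P(het = h), parity of `rare` only
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  probs[mid + 1] <- 1

  h <- mid
  hom_r <- (rare - mid) / 2
  hom_c <- n - h - hom_r
  while (h >= 2) {
    probs[h - 1] <- probs[h + 1] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    h <- h - 2
    hom_r <- hom_r + 1
    hom_c <- hom_c + 1
  }
  h <- mid
  hom_r <- (rare - mid) / 2
  hom_c <- n - h - hom_r
  while (h <= rare - 2) {
    probs[h + 3] <- probs[h + 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    h <- h + 2
    hom_r <- hom_r - 1
    hom_c <- hom_c - 1
  }
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[n_het + 1] * (1 + 1e-12)]))
}

variant_summaries <- function(dosages) {
  g <- hard_calls(dosages)
  n_nonmiss <- colSums(!is.na(dosages))
  call_rate <- n_nonmiss / nrow(dosages)
  p <- colSums(dosages, na.rm = TRUE) / (2 * pmax(n_nonmiss, 1))
  maf <- pmin(p, 1 - p)
  maf[n_nonmiss == 0] <- NA_real_
  n_hom2 <- colSums(g == 2, na.rm = TRUE)   # counted-allele homozygote
  n_het <- colSums(g == 1, na.rm = TRUE)
  n_hom0 <- colSums(g == 0, na.rm = TRUE)
  hwe_p <- vapply(seq_along(n_het), function(j) {
    if (n_nonmiss[j] == 0) return(NA_real_)
    hwe_exact_test(n_het[j], n_hom2[j], n_hom0[j])
  }, numeric(1))
  tibble::tibble(call_rate = call_rate, maf = maf, hwe_p = hwe_p)
}

#' Variant-level quality control
#'
#' Removes variants with call rate below `call_thresh`, minor allele frequency
#' below `maf_thresh` (from observed allele counts), or an exact
#' Hardy-Weinberg p-value (on rounded hard calls) below `hwe_thresh`. All
#' thresholds are strict (`<`), matching the conventional filter spellings.
#' A variant with every call missing is removed by the call-rate filter.
#'
#' @param dataset A `genotype_dataset`.
#' @param call_thresh Call-rate threshold (default 0.98).
#' @param maf_thresh MAF threshold (default 0.01).
#' @param hwe_thresh HWE p-value threshold (default 1e-6).
#' @return List with `dataset` (filtered) and `report` (`qc_report` including
#'   per-variant call rate, MAF and HWE p).
#' @export
variant_qc <- function(dataset, call_thresh = 0.98, maf_thresh = 0.01,
                       hwe_thresh = 1e-6) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (ncol(dataset$dosages) == 0) abort("dataset has no variants")
  vs <- variant_summaries(dataset$dosages)

  fail_call <- vs$call_rate < call_thresh
  fail_maf <- !fail_call & (is.na(vs$maf) | vs$maf < maf_thresh)
  fail_hwe <- !fail_call & !fail_maf &
    (!is.na(vs$hwe_p) & vs$hwe_p < hwe_thresh)
  keep <- !(fail_call | fail_maf | fail_hwe)
  if (!any(keep)) abort("all variants removed by variant QC")

  report <- new_qc_report(
    "variant_qc",
    n_samples_in = nrow(dataset$dosages),
    n_samples_out = nrow(dataset$dosages),
    n_variants_in = ncol(dataset$dosages), n_variants_out = sum(keep),
    filters = tibble::tibble(
      filter = c("call_rate", "maf", "hwe"),
      threshold = c(call_thresh, maf_thresh, hwe_thresh),
      removed = c(sum(fail_call), sum(fail_maf), sum(fail_hwe))
    ),
    variant_stats = dplyr::bind_cols(
      tibble::tibble(variant_id = dataset$variants$variant_id), vs,
      tibble::tibble(kept = keep)
    )
  )
  list(dataset = filter_variants(dataset, keep), report = report)
}

#' Post-imputation INFO / MAF filter
#'
#' Removes variants with imputation quality `INFO < info_thresh` or
#' `MAF < maf_thresh` (strict inequalities). Variants without an INFO value
#' are retained by the INFO criterion and their count is logged in the report.
#'
#' @param dataset A `genotype_dataset` (uses the `info` variant column).
#' @param info_thresh INFO threshold (default 0.3).
#' @param maf_thresh MAF threshold (default 0.01).
#' @return List with `dataset` and `report`.
#' @export
info_filter <- function(dataset, info_thresh = 0.3, maf_thresh = 0.01) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  info <- dataset$variants$info
  vs <- variant_summaries(dataset$dosages)

  fail_info <- !is.na(info) & info < info_thresh
  fail_maf <- !fail_info & (is.na(vs$maf) | vs$maf < maf_thresh)
  keep <- !(fail_info | fail_maf)
  if (!any(keep)) abort("all variants removed by INFO/MAF filter")

  report <- new_qc_report(
    "info_filter",
    n_samples_in = nrow(dataset$dosages),
    n_samples_out = nrow(dataset$dosages),
    n_variants_in = ncol(dataset$dosages), n_variants_out = sum(keep),
    filters = tibble::tibble(
      filter = c("info", "maf", "info_absent_retained"),
      threshold = c(info_thresh, maf_thresh, NA_real_),
      removed = c(sum(fail_info), sum(fail_maf), 0L)
    )
  )
  report$n_info_missing <- sum(is.na(info))
  list(dataset = filter_variants(dataset, keep), report = report)
}

#' Write a QC report as TSV (filter table) and JSON (full summary)
#'
#' @param report A `qc_report`.
#' @param path Base path; writes `<path>.tsv` and `<path>.json`.
#' @return Base path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  readr::write_tsv(report$filters, paste0(path, ".tsv"), progress = FALSE)
  jsonlite::write_json(
    list(stage = report$stage,
         n_samples_in = report$n_samples_in,
         n_samples_out = report$n_samples_out,
         n_variants_in = report$n_variants_in,
         n_variants_out = report$n_variants_out,
         filters = report$filters),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
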