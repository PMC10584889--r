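#' Read a PGS Catalog-format scoring file
#'
#' Parses the standard layout: `#`-prefixed `key=value` metadata lines, a
#' header row, then tab-separated records with columns `chr_name`,
#' `chr_position`, `effect_allele`, `other_allele`, `effect_weight`.
#' Row order is preserved.
#'
#' @param path Path to the scoring file.
#' @return A `scoring_file` tibble with metadata attributes `score_id`,
#'   `trait`, `genome_build`.
#' @export
read_scoring_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("scoring file not found: %s", path))
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#+\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      meta[[key]] <- sub("^[^=]*=", "", kv)
    }
  }
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  body <- body[nzchar(body)]
  if (length(body) < 2) abort("scoring file has no data rows")

  tab <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("chr_name", "chr_position", "effect_allele",
                "other_allele", "effect_weight")
  for (col in required) {
    if (!col %in% names(tab)) abort(sprintf("missing column %s", col))
  }

  w <- suppressWarnings(as.numeric(tab$effect_weight))
  bad <- which(is.na(w) & !is.na(tab$effect_weight))
  if (length(bad)) {
    # +1 header line plus any metadata lines precede the first data row
    abort(sprintf("non-numeric effect_weight at line %d",
                  length(meta_idx) + 1L + bad[1]))
  }

  new_scoring_file(
    tibble::tibble(
      chr_name = tab$chr_name,
      chr_position = as.integer(tab$chr_position),
      effect_allele = tab$effect_allele,
      other_allele = tab$other_allele,
      effect_weight = w
    ),
    score_id = meta$pgs_id %||% sub("\\.txt$|\\.tsv$", "", basename(path)),
    trait = meta$trait_reported %||% "unknown",
    genome_build = meta$genome_build %||% "unknown"
  )
}

#' Write a scoring file in PGS Catalog layout
#'
#' @param scoring A `scoring_file`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(scoring, path) {
  stopifnot(inherits(scoring, "scoring_file"))
  meta <- c(
    sprintf("#pgs_id=%s", attr(scoring, "score_id")),
    sprintf("#trait_reported=%s", attr(scoring, "trait")),
    sprintf("#genome_build=%s", attr(scoring, "genome_build"))
  )
  body <- tibble::as_tibble(unclass(scoring)[
    c("chr_name", "chr_position", "effect_allele",
      "other_allele", "effect_weight")
  ])
  writeLines(meta, path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Harmonize scoring-file alleles against a genotype dataset
#'
#' Records are matched to dataset variants on (chromosome, position). A record
#' is `direct` when its effect allele equals the dataset's counted allele
#' (`allele1`) and the other allele equals `allele2`; `swapped` when reversed.
#' Strand-ambiguous (palindromic) allele pairs A/T and C/G are always dropped;
#' anything else is unmatched.
#'
#' @param scoring A `scoring_file`.
#' @param dataset A `genotype_dataset`.
#' @return A `harmonized_weights` tibble (`variant_id`, `index`, `weight`,
#'   `orientation`) with count attributes `n_matched`, `n_swapped`,
#'   `n_palindromic_dropped`, `n_unmatched`, plus `score_id`.
#' @export
harmonize_weights <- function(scoring, dataset) {
  stopifnot(inherits(scoring, "scoring_file"),
            inherits(dataset, "genotype_dataset"))
  n_rec <- nrow(scoring)

  palin <- is_palindromic(scoring$effect_allele, scoring$other_allele)

  vkey <- paste(dataset$variants$chrom, dataset$variants$pos)
  rkey <- paste(scoring$chr_name, scoring$chr_position)
  idx <- match(rkey, vkey)

  a1 <- dataset$variants$allele1[idx]
  a2 <- dataset$variants$allele2[idx]
  direct <- !is.na(idx) & scoring$effect_allele == a1 &
    scoring$other_allele == a2
  swapped <- !is.na(idx) & scoring$effect_allele == a2 &
    scoring$other_allele == a1

  use <- !palin & (direct | swapped)
  res <- tibble::tibble(
    variant_id = dataset$variants$variant_id[idx[use]],
    index = idx[use],
    weight = scoring$effect_weight[use],
    orientation = ifelse(direct[use], "direct", "swapped")
  )

  n_matched <- nrow(res)
  n_pal <- sum(palin)
  n_unmatched <- n_rec - n_matched - n_pal
  if (n_matched == 0) {
    abort("no scoring-file records matched the dataset (build or format mismatch?)")
  }

  structure(res,
            class = c("harmonized_weights", class(res)),
            score_id = attr(scoring, "score_id"),
            n_matched = n_matched,
            n_swapped = sum(res$orientation == "swapped"),
            n_palindromic_dropped = n_pal,
            n_unmatched = n_unmatched)
}

#' @export
print.harmonized_weights <- function(x, ...) {
  cat(sprintf(
    "<harmonized_weights> %s: %d matched (%d swapped), %d palindromic dropped, %d unmatched\n",
    attr(x, "score_id"), attr(x, "n_matched"), attr(x, "n_swapped"),
    attr(x, "n_palindromic_dropped"), attr(x, "n_unmatched")))
  NextMethod()
}

#' Compute raw and normalized polygenic scores
#'
#' Per-sample score is the weighted dosage sum over harmonized variants, with
#' swapped-orientation dosages counted as `2 - dosage`. Missing dosages are
#' replaced by the variant's mean (oriented) dosage over non-missing samples
#' (PLINK `--score` convention); variants with every dosage missing are
#' excluded with a warning. Normalized scores are z-scores against the stated
#' normalization cohort (mean 0, SD 1 over that cohort).
#'
#' @param weights A `harmonized_weights`.
#' @param dataset A `genotype_dataset`.
#' @param normalization_cohort Cohort role used for normalization (default:
#'   all samples).
#' @return Tibble (`sample_id`, `score_id`, `raw`, `normalized`) with
#'   attribute `normalization_cohort`.
#' @export
compute_raw_scores <- function(weights, dataset, normalization_cohort = NULL) {
  stopifnot(inherits(weights, "harmonized_weights"),
            inherits(dataset, "genotype_dataset"))
  if (nrow(weights) == 0) abort("harmonized weights are empty")

  D <- dataset$dosages[, weights$index, drop = FALSE]
  sw <- weights$orientation == "swapped"
  if (any(sw)) D[, sw] <- 2 - D[, sw, drop = FALSE]

  cm <- colMeans(D, na.rm = TRUE)
  all_missing <- !is.finite(cm)
  if (any(all_missing)) {
    warn(sprintf("%d variant(s) with all dosages missing excluded from score",
                 sum(all_missing)))
    D <- D[, !all_missing, drop = FALSE]
    cm <- cm[!all_missing]
  }
  w <- weights$weight[if (any(all_missing)) !all_missing else TRUE]

  if (anyNA(D)) {
    for (j in seq_len(ncol(D))) {
      miss <- is.na(D[, j])
      if (any(miss)) D[miss, j] <- cm[j]
    }
  }
  raw <- as.numeric(D %*% w)

  in_cohort <- if (is.null(normalization_cohort)) {
    rep(TRUE, nrow(dataset$samples))
  } else {
    dataset$samples$cohort %in% normalization_cohort
  }
  if (!any(in_cohort)) abort("normalization cohort has no samples")
  mu <- mean(raw[in_cohort])
  s <- sd(raw[in_cohort])
  normalized <- if (s > 0) (raw - mu) / s else raw - mu

  out <- tibble::tibble(
    sample_id = dataset$samples$sample_id,
    score_id = attr(weights, "score_id"),
    raw = raw,
    normalized = normalized
  )
  attr(out, "normalization_cohort") <- normalization_cohort %||% "all"
  out
}
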