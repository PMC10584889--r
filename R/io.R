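# genotype / phenotype / config I/O

#' Write a genotype dataset as VCF with GT and DS fields
#'
#' Plain-text VCF 4.2: hard genotype calls (rounded dosage) in GT and the
#' dosage itself in DS; missing dosages become `./.:.`. The imputation
#' quality, when present, is written as `INFO=<value>` in the INFO column.
#' Cohort/population labels are not part of VCF; persist `dataset$samples`
#' separately (see [write_sample_table()]).
#'
#' @param dataset A `genotype_dataset`.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  v <- dataset$variants
  dos <- dataset$dosages
  g <- hard_calls(dos)

  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of counted allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples$sample_id), collapse = "\t")
  )

  gt_str <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(nrow(v)), function(j) {
    gj <- g[, j]
    dj <- dos[, j]
    cell <- ifelse(is.na(dj), "./.:.",
                   paste0(gt_str[gj + 1L], ":", formatC(dj, format = "g")))
    info <- if (is.na(v$info[j])) "." else sprintf("INFO=%g", v$info[j])
    # counted allele (allele1) written as ALT so DS counts ALT copies
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$allele2[j], v$allele1[j],
            ".", "PASS", info, "GT:DS", cell), collapse = "\t")
  }, character(1))

  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a GT/DS VCF into a genotype dataset
#'
#' Uses `vcfR` for parsing. The ALT allele is taken as the counted allele
#' (`allele1`); dosages come from DS when present, otherwise from GT allele
#' counts. Sample cohort/population labels are taken from `samples` when
#' supplied (matched on `sample_id`), otherwise set `NA`.
#'
#' @param path VCF path.
#' @param samples Optional tibble (`sample_id`, `population`, `cohort`).
#' @return A `genotype_dataset`.
#' @export
read_genotype_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))

  ds <- tryCatch(
    vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
    error = function(e) NULL
  )
  if (is.null(ds)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    ds[gt %in% c("0/0", "0|0")] <- 0
    ds[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    ds[gt %in% c("1/1", "1|1")] <- 2
  }

  info_raw <- vcfR::extract.info(v, element = "INFO")
  info <- suppressWarnings(as.numeric(info_raw))

  sample_ids <- colnames(ds)
  smp <- tibble::tibble(sample_id = sample_ids,
                        population = NA_character_,
                        cohort = NA_character_)
  if (!is.null(samples)) {
    assert_columns(samples, c("sample_id", "population", "cohort"), "samples")
    m <- match(sample_ids, samples$sample_id)
    smp$population <- samples$population[m]
    smp$cohort <- samples$cohort[m]
  }

  variants <- tibble::tibble(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    allele1 = fix$ALT,
    allele2 = fix$REF,
    info = info
  )
  new_genotype_dataset(t(ds), smp, variants)
}

#' Write / read a dosage matrix as TSV
#'
#' Layout: one row per variant with metadata columns (`variant_id`, `chrom`,
#' `pos`, `allele1`, `allele2`, `info`) followed by one dosage column per
#' sample.
#'
#' @param dataset A `genotype_dataset`.
#' @param path Output path.
#' @return `path` (write) / a `genotype_dataset` (read).
#' @export
write_dosage_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  tab <- dplyr::bind_cols(
    dataset$variants,
    tibble::as_tibble(t(dataset$dosages))
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param samples Optional sample table with `sample_id`, `population`,
#'   `cohort` (as in [read_genotype_vcf()]).
#' @export
read_dosage_tsv <- function(path, samples = NULL) {
  if (!file.exists(path)) abort(sprintf("dosage TSV not found: %s", path))
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "allele1", "allele2", "info")
  assert_columns(tab, meta_cols, "dosage TSV")
  variants <- tab[meta_cols]
  variants$chrom <- as.character(variants$chrom)
  dos <- t(as.matrix(tab[setdiff(names(tab), meta_cols)]))
  sample_ids <- rownames(dos)
  smp <- tibble::tibble(sample_id = sample_ids,
                        population = NA_character_,
                        cohort = NA_character_)
  if (!is.null(samples)) {
    m <- match(sample_ids, samples$sample_id)
    smp$population <- samples$population[m]
    smp$cohort <- samples$cohort[m]
  }
  new_genotype_dataset(dos, smp, variants)
}

#' Persist the sample table (cohort and population labels)
#'
#' @param dataset A `genotype_dataset` (or a sample tibble).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(dataset, path) {
  smp <- if (inherits(dataset, "genotype_dataset")) dataset$samples else dataset
  readr::write_tsv(smp, path, progress = FALSE)
  invisible(path)
}

#' Write / read a simulation config as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML path.
#' @return `path` (write) / a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$cohort_sizes <- as.list(x$cohort_sizes)  # keep role names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) abort("config YAML must carry a `seed`")
  do.call(sim_config, c(
    x[c("n_populations", "fst", "n_variants", "n_causal", "h2", "prevalence",
        "biobank_target_fraction", "missing_rate", "info_fraction",
        "n_duplicate", "prevalence_t2d", "prevalence_cmp", "seed")],
    list(cohort_sizes = unlist(x$cohort_sizes),
         med_assign = lapply(x$med_assign, unlist))
  ))
}
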