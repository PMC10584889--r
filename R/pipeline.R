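#' Configure an end-to-end pipeline run
#'
#' Bundles inputs, thresholds and the master seed for [run_pgs_pipeline()].
#' Every threshold defaults to the framework's standard value (sample
#' missingness 0.05, heterozygosity 5 SD, call rate 0.98, MAF 0.01, HWE 1e-6,
#' INFO 0.3, LD pruning 1000/50/0.2, k = 10 PCs, ancestry boundary alpha 0.05
#' with df 10).
#'
#' @param genotypes A `genotype_dataset`, or a path to a VCF / dosage TSV.
#' @param phenotypes A phenotype tibble, or a TSV path.
#' @param scoring_files List of `scoring_file` objects or paths.
#' @param out_dir Output directory for stage artifacts.
#' @param samples Optional sample table (needed when `genotypes` is a path,
#'   to carry cohort/population labels): tibble or TSV path.
#' @param outcome Outcome column for selection/evaluation (default `"cad"`).
#' @param covariates Covariates for evaluation models.
#' @param n_train Training-set size (default: half the case-control cohort).
#' @param mind,het_sd,geno,maf,hwe,info QC thresholds.
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters.
#' @param k Number of ancestry PCs.
#' @param alpha,df Ancestry-match boundary parameters.
#' @param percentile_mode `"empirical"` or `"normal"`.
#' @param seed Mandatory master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes, phenotypes, scoring_files, out_dir,
                            samples = NULL,
                            outcome = "cad",
                            covariates = c("age", "sex", "array_version"),
                            n_train = NULL,
                            mind = 0.05, het_sd = 5,
                            geno = 0.98, maf = 0.01, hwe = 1e-6, info = 0.3,
                            ld_window = 1000, ld_step = 50, ld_r2 = 0.2,
                            k = 10, alpha = 0.05, df = 10,
                            percentile_mode = "empirical",
                            seed) {
  assert_seed(seed)
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes,
         scoring_files = scoring_files, out_dir = out_dir,
         samples = samples, outcome = outcome, covariates = covariates,
         n_train = n_train,
         mind = mind, het_sd = het_sd, geno = geno, maf = maf,
         hwe = hwe, info = info,
         ld_window = ld_window, ld_step = ld_step, ld_r2 = ld_r2,
         k = k, alpha = alpha, df = df,
         percentile_mode = percentile_mode,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

load_pipeline_genotypes <- function(config) {
  g <- config$genotypes
  if (inherits(g, "genotype_dataset")) return(g)
  if (!is.character(g) || !file.exists(g)) {
    abort(sprintf("genotype input not found: %s", as.character(g)))
  }
  samples <- config$samples
  if (is.character(samples)) {
    samples <- readr::read_tsv(samples, progress = FALSE,
                               show_col_types = FALSE)
  }
  if (grepl("\\.vcf$", g)) read_genotype_vcf(g, samples)
  else read_dosage_tsv(g, samples)
}

load_pipeline_scoring <- function(config) {
  purrr::map(config$scoring_files, function(sf) {
    if (inherits(sf, "scoring_file")) return(sf)
    if (!is.character(sf) || !file.exists(sf)) {
      abort(sprintf("scoring file not found: %s", as.character(sf)))
    }
    read_scoring_file(sf)
  })
}

#' Run the four-step score-optimization pipeline end to end
#'
#' Stage order: `qc` (sample QC, variant QC, INFO filter) -> `score`
#' (harmonize each scoring file and compute raw scores, normalized against
#' the reference cohort) -> `ancestry` (LD-prune the panel, fit PCA, project
#' all samples) -> `calibrate` (reference distribution per score) ->
#' `select` (train/validation split of the case-control cohort, best score
#' by AUC or adjusted R-squared) -> `stratify` (reference-anchored deciles of
#' the best score, decile table on validation) -> `match` (Mahalanobis
#' ancestry matching of the biobank cohort against the reference cohort) ->
#' `evaluate` (per-SD model of the best score on validation). Each stage
#' writes its artifacts under `out_dir`; any error halts with the stage name.
#' A `manifest.json` hash-stamps inputs and outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of stage results.
#' @export
run_pgs_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  art <- function(...) file.path(out, ...)
  results <- list()

  dataset <- run_stage("load", load_pipeline_genotypes(config))
  pheno <- run_stage("load", {
    p <- config$phenotypes
    if (is.character(p)) {
      readr::read_tsv(p, progress = FALSE, show_col_types = FALSE)
    } else {
      tibble::as_tibble(p)
    }
  })

  # --- qc -------------------------------------------------------------
  results$qc <- run_stage("qc", {
    sq <- sample_qc(dataset, config$mind, config$het_sd)
    vq <- variant_qc(sq$dataset, config$geno, config$maf, config$hwe)
    iq <- info_filter(vq$dataset, config$info, config$maf)
    write_qc_report(sq$report, art("qc_sample"))
    write_qc_report(vq$report, art("qc_variant"))
    write_qc_report(iq$report, art("qc_info"))
    dataset <- iq$dataset
    list(dataset = iq$dataset,
         sample = sq$report, variant = vq$report, info = iq$report)
  })
  dataset <- results$qc$dataset

  # --- score ----------------------------------------------------------
  results$score <- run_stage("score", {
    scoring <- load_pipeline_scoring(config)
    scores <- purrr::map(scoring, function(sf) {
      hw <- harmonize_weights(sf, dataset)
      compute_raw_scores(hw, dataset, normalization_cohort = "reference")
    })
    long <- dplyr::bind_rows(scores)
    readr::write_tsv(long, art("raw_scores.tsv"), progress = FALSE)
    scores
  })
  score_ids <- purrr::map_chr(results$score, ~ .x$score_id[1])

  # --- ancestry -------------------------------------------------------
  results$ancestry <- run_stage("ancestry", {
    panel <- subset_cohort(dataset, "panel")
    pruned <- ld_prune(panel, config$ld_window, config$ld_step, config$ld_r2)
    model <- fit_pca(panel, pruned, config$k)
    pcs <- project_pcs(model, dataset)
    write_pc_model(model, art("pc_model.tsv"))
    write_pc_scores(pcs, art("pc_scores.tsv"))
    list(model = model, pcs = pcs, pruned = pruned)
  })
  pcs <- results$ancestry$pcs

  # --- calibrate ------------------------------------------------------
  ref_ids <- dataset$samples$sample_id[dataset$samples$cohort == "reference"]
  results$calibrate <- run_stage("calibrate", {
    refdists <- purrr::map(results$score, function(sc) {
      ref_sc <- sc[sc$sample_id %in% ref_ids, ]
      calibrate_reference(ref_sc, pcs, k = config$k)
    })
    names(refdists) <- score_ids
    purrr::iwalk(refdists, function(rd, id) {
      write_reference_distribution(rd, art(sprintf("refdist_%s.json", id)))
    })
    refdists
  })

  # --- select ---------------------------------------------------------
  cc_ids <- dataset$samples$sample_id[dataset$samples$cohort == "case_control"]
  results$select <- run_stage("select", {
    wide <- Reduce(function(a, b) {
      dplyr::left_join(a, b, by = "sample_id")
    }, purrr::map(results$score, function(sc) {
      setNames(sc[c("sample_id", "normalized")],
               c("sample_id", sc$score_id[1]))
    }))
    model_data <- dplyr::inner_join(
      dplyr::left_join(wide, pheno, by = "sample_id"),
      tibble::tibble(sample_id = cc_ids), by = "sample_id"
    )
    n_train <- config$n_train %||% floor(length(cc_ids) / 2)
    split <- split_cohort(model_data$sample_id, n_train, config$seed)
    sel <- select_best(model_data, score_ids, split$train, split$validation,
                       config$outcome, config$covariates, "logistic")
    readr::write_tsv(sel$train_results, art("selection.tsv"),
                     progress = FALSE)
    writeLines(split$train, art("train_ids.txt"))
    writeLines(split$validation, art("validation_ids.txt"))
    c(sel, list(split = split, model_data = model_data))
  })
  best <- results$select$best

  # --- stratify -------------------------------------------------------
  results$stratify <- run_stage("stratify", {
    best_scores <- results$score[[which(score_ids == best)]]
    pr <- percentile_rank(results$calibrate[[best]],
                          best_scores[best_scores$sample_id %in% cc_ids, ],
                          pcs, mode = config$percentile_mode)
    strat_data <- dplyr::inner_join(
      pr, pheno[c("sample_id", config$outcome)], by = "sample_id"
    )
    valid <- strat_data[strat_data$sample_id %in%
                          results$select$split$validation, ]
    dt <- decile_stratify(valid, config$outcome, "binary")
    readr::write_tsv(tibble::as_tibble(dt), art("decile_table.tsv"),
                     progress = FALSE)
    readr::write_tsv(pr, art("percentiles.tsv"), progress = FALSE)
    list(percentiles = pr, decile_table = dt)
  })

  # --- match ----------------------------------------------------------
  results$match <- run_stage("match", {
    bb_ids <- dataset$samples$sample_id[dataset$samples$cohort == "biobank"]
    if (length(bb_ids) == 0) {
      NULL
    } else {
      mm <- mahalanobis_match(pcs[pcs$sample_id %in% bb_ids, ],
                              pcs[pcs$sample_id %in% ref_ids, ],
                              config$alpha, config$df)
      writeLines(mm$matches$sample_id[mm$matches$matched],
                 art("matched_ids.txt"))
      readr::write_tsv(mm$matches, art("match_distances.tsv"),
                       progress = FALSE)
      mm
    }
  })

  # --- evaluate -------------------------------------------------------
  results$evaluate <- run_stage("evaluate", {
    valid_data <- results$select$model_data[
      results$select$model_data$sample_id %in%
        results$select$split$validation, ]
    ev <- fit_score_model(valid_data, best, config$outcome,
                          config$covariates, "logistic")
    jsonlite::write_json(as.list(glance(ev)), art("evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    ev
  })

  # --- manifest -------------------------------------------------------
  run_stage("manifest", {
    files <- sort(list.files(out, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    jsonlite::write_json(
      list(seed = config$seed,
           best_score = best,
           thresholds = config[c("mind", "het_sd", "geno", "maf", "hwe",
                                 "info", "ld_window", "ld_step", "ld_r2",
                                 "k", "alpha", "df")],
           artifacts = as.list(setNames(
             unname(tools::md5sum(files)), basename(files)))),
      art("manifest.json"), auto_unbox = TRUE, digits = NA
    )
  })

  invisible(results)
}
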