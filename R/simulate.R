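#' Configure a synthetic multi-cohort genotype study
#'
#' Bundles every knob of the synthetic-data generator into a validated object.
#' Defaults describe the study design the package targets: a multi-population
#' reference panel, a target-ancestry population reference cohort, a
#' case-control cohort from the target population, and a mixed-ancestry
#' biobank containing a planted target-ancestry subset. Binary disease is
#' generated under an additive liability-threshold model; population structure
#' follows the Balding-Nichols model parameterized by Fst.
#'
#' @param n_populations Number of distinct populations (>= 1). Population 1 is
#'   the target population.
#' @param fst Balding-Nichols differentiation in `[0, 1)`; 0 means all
#'   populations share the ancestral allele frequencies exactly.
#' @param n_variants Number of independent biallelic variants.
#' @param n_causal Number of causal variants (`<= n_variants`).
#' @param h2 Liability-scale (binary) / trait-scale (continuous) heritability
#'   in `[0, 1]`.
#' @param prevalence Case fraction of the primary disease (CAD) in `(0, 1)`.
#' @param cohort_sizes Named integer vector with roles `panel`, `reference`,
#'   `case_control`, `biobank`. A role may be 0 only if it is not used
#'   downstream of the stage being exercised.
#' @param biobank_target_fraction Fraction of biobank samples drawn from the
#'   target population.
#' @param missing_rate Fraction of dosage entries set missing (QC exercise).
#' @param info_fraction Fraction of variants carrying an imputation-quality
#'   INFO value drawn Uniform(0, 1); the rest have no INFO.
#' @param n_duplicate Number of variants duplicated at adjacent positions to
#'   create perfect LD (exercises LD pruning). Default 0.
#' @param prevalence_t2d,prevalence_cmp Case fractions for the secondary
#'   binary traits (type 2 diabetes, cardiomyopathy).
#' @param med_assign Named list of `c(intercept, slope)` logistic coefficients
#'   (on the standardized untreated trait) governing medication assignment for
#'   `statin`, `ezetimibe`, `fibrate`, `antihypertensive`.
#' @param seed Mandatory integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_populations = 2,
                       fst = 0.1,
                       n_variants = 2000,
                       n_causal = 200,
                       h2 = 0.5,
                       prevalence = 0.65,
                       cohort_sizes = c(panel = 2481, reference = 1017,
                                        case_control = 5399, biobank = 2000),
                       biobank_target_fraction = 0.25,
                       missing_rate = 0,
                       info_fraction = 0,
                       n_duplicate = 0,
                       prevalence_t2d = 0.556,
                       prevalence_cmp = 0.093,
                       med_assign = list(
                         statin = c(-0.2, 1.2),
                         ezetimibe = c(-2.3, 0.8),
                         fibrate = c(-2.2, 1.0),
                         antihypertensive = c(0.3, 1.5)
                       ),
                       seed) {
  assert_seed(seed)
  n_populations <- assert_count(n_populations, "n_populations")
  assert_number(fst, "fst", 0, 1, strict_upper = TRUE)
  n_variants <- assert_count(n_variants, "n_variants")
  n_causal <- assert_count(n_causal, "n_causal", min = 1L)
  if (n_causal > n_variants) abort("`n_causal` must be <= `n_variants`")
  assert_number(h2, "h2", 0, 1)
  assert_number(prevalence, "prevalence", 0, 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(biobank_target_fraction, "biobank_target_fraction", 0, 1)
  assert_number(missing_rate, "missing_rate", 0, 1, strict_upper = TRUE)
  assert_number(info_fraction, "info_fraction", 0, 1)
  n_duplicate <- assert_count(n_duplicate, "n_duplicate", min = 0L)
  roles <- c("panel", "reference", "case_control", "biobank")
  if (!all(roles %in% names(cohort_sizes))) {
    abort(sprintf("`cohort_sizes` must name roles: %s",
                  paste(roles, collapse = ", ")))
  }
  cohort_sizes <- vapply(cohort_sizes[roles], assert_count,
                         integer(1), name = "cohort_sizes", min = 0L)
  if (sum(cohort_sizes) == 0) abort("all cohort sizes are zero")

  structure(
    list(
      n_populations = n_populations, fst = fst,
      n_variants = n_variants, n_causal = n_causal,
      h2 = h2, prevalence = prevalence,
      prevalence_t2d = prevalence_t2d, prevalence_cmp = prevalence_cmp,
      cohort_sizes = cohort_sizes,
      biobank_target_fraction = biobank_target_fraction,
      missing_rate = missing_rate, info_fraction = info_fraction,
      n_duplicate = n_duplicate,
      med_assign = med_assign,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  populations: %d (Fst %.3g), variants: %d (%d causal)\n",
              x$n_populations, x$fst, x$n_variants, x$n_causal))
  cat(sprintf("  h2: %.2f, prevalence (CAD/T2D/CMP): %.3f/%.3f/%.3f\n",
              x$h2, x$prevalence, x$prevalence_t2d, x$prevalence_cmp))
  cat(sprintf("  cohorts: %s\n",
              paste(names(x$cohort_sizes), x$cohort_sizes,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

new_genotype_dataset <- function(dosages, samples, variants) {
  stopifnot(nrow(dosages) == nrow(samples), ncol(dosages) == nrow(variants))
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages,
                 samples = tibble::as_tibble(samples),
                 variants = tibble::as_tibble(variants)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  print(dplyr::count(x$samples, .data$population, .data$cohort))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

# role/population assignment for every simulated sample
assign_cohorts <- function(config) {
  pops <- paste0("POP", seq_len(config$n_populations))
  out <- purrr::imap(as.list(config$cohort_sizes), function(n, role) {
    if (n == 0) return(NULL)
    pop <- switch(role,
      panel = pops[((seq_len(n) - 1L) %% length(pops)) + 1L],
      reference = rep(pops[1], n),
      case_control = rep(pops[1], n),
      biobank = {
        n_target <- round(config$biobank_target_fraction * n)
        others <- if (length(pops) > 1) pops[-1] else pops
        c(rep(pops[1], n_target),
          others[((seq_len(n - n_target) - 1L) %% length(others)) + 1L])
      }
    )
    tibble::tibble(
      sample_id = sprintf("%s_%05d", role, seq_len(n)),
      population = pop,
      cohort = role
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate genotype dosages with Balding-Nichols population structure
#'
#' Draws ancestral allele frequencies Uniform(0.05, 0.95); each population's
#' frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral value
#' (copied exactly when `fst = 0`), and genotypes are Binomial(2, p_pop).
#' Variants sit on a single chromosome at strictly increasing positions.
#' Optional uniform missingness and a partial INFO column exercise QC, and
#' `n_duplicate` exact-copy variants exercise LD pruning.
#'
#' @param config A [sim_config()].
#' @return A `genotype_dataset`: list of `dosages` (samples x variants matrix,
#'   entries in `[0, 2]` or `NA`), `samples` tibble (`sample_id`, `population`,
#'   `cohort`) and `variants` tibble (`variant_id`, `chrom`, `pos`, `allele1`
#'   = counted allele, `allele2`, `info`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    K <- config$n_populations
    V <- config$n_variants
    F_ <- config$fst

    p_anc <- runif(V, 0.05, 0.95)
    pop_freq <- matrix(NA_real_, K, V)
    for (k in seq_len(K)) {
      pop_freq[k, ] <- if (F_ == 0) p_anc else {
        rbeta(V, p_anc * (1 - F_) / F_, (1 - p_anc) * (1 - F_) / F_)
      }
    }

    samples <- assign_cohorts(config)
    n <- nrow(samples)
    pops <- paste0("POP", seq_len(K))

    dos <- matrix(NA_real_, n, V)
    for (k in seq_len(K)) {
      rows <- which(samples$population == pops[k])
      if (length(rows) == 0) next
      nr <- length(rows)
      dos[rows, ] <- matrix(
        rbinom(nr * V, 2L, rep(pop_freq[k, ], each = nr)), nr, V
      )
    }

    # alleles chosen to never be strand-ambiguous (palindromic pairs are
    # exercised with crafted records, not generator output)
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, V, replace = TRUE)
    a2 <- vapply(a1, function(b) {
      sample(setdiff(bases, c(b, BASE_COMPLEMENT[[b]])), 1L)
    }, character(1))

    pos <- sort(sample.int(V * 100L, V))
    variants <- tibble::tibble(
      variant_id = sprintf("var%06d", seq_len(V)),
      chrom = "1",
      pos = pos,
      allele1 = a1,
      allele2 = unname(a2),
      info = NA_real_
    )

    if (config$info_fraction > 0) {
      n_info <- round(config$info_fraction * V)
      idx <- sample.int(V, n_info)
      variants$info[idx] <- runif(n_info)
    }

    if (config$n_duplicate > 0) {
      src <- sample.int(V, min(config$n_duplicate, V))
      dup_var <- variants[src, ]
      dup_var$variant_id <- sprintf("dup%06d", seq_along(src))
      dup_var$pos <- dup_var$pos + 1L   # adjacent, keeps ordering usable
      dos <- cbind(dos, dos[, src, drop = FALSE])
      variants <- dplyr::bind_rows(variants, dup_var)
      ord <- order(variants$pos, variants$variant_id)
      variants <- variants[ord, ]
      dos <- dos[, ord, drop = FALSE]
    }

    if (config$missing_rate > 0) {
      mask <- runif(length(dos)) < config$missing_rate
      dos[mask] <- NA_real_
    }

    out <- new_genotype_dataset(dos, samples, variants)
    # simulation truth, for validation only (never used by the pipeline)
    attr(out, "frequencies") <- list(ancestral = p_anc, population = pop_freq)
    out
  })
}

new_scoring_file <- function(records, score_id, trait = "simulated",
                             genome_build = "GRCh38") {
  records <- tibble::as_tibble(records)
  assert_columns(records, c("chr_name", "chr_position", "effect_allele",
                            "other_allele", "effect_weight"), "scoring file")
  if (any(!is.finite(records$effect_weight))) {
    abort("scoring-file weights must all be finite")
  }
  bad <- !(records$effect_allele %in% names(BASE_COMPLEMENT)) |
    !(records$other_allele %in% names(BASE_COMPLEMENT))
  if (any(bad)) abort("scoring-file alleles must be A/C/G/T")
  key <- paste(records$chr_name, records$chr_position, records$effect_allele)
  if (anyDuplicated(key)) {
    abort("duplicate (chromosome, position, effect_allele) in scoring file")
  }
  structure(records,
            class = c("scoring_file", class(records)),
            score_id = score_id, trait = trait, genome_build = genome_build)
}

#' @export
print.scoring_file <- function(x, ...) {
  cat(sprintf("<scoring_file> %s (%s, build %s), %d variants\n",
              attr(x, "score_id"), attr(x, "trait"),
              attr(x, "genome_build"), nrow(x)))
  NextMethod()
}

#' Simulate candidate PRS scoring files of graded quality
#'
#' Creates one true causal weight vector (standard-normal weights on
#' `n_causal` variants of the dataset) and `n_candidates` scoring files whose
#' weights are the truth plus independent Gaussian noise scaled by
#' `noise_levels[i] * sd(true weights)`. A noise level of 0 reproduces the
#' truth exactly. This emulates a panel of candidate scores of varying quality
#' (e.g. different derivation methods) for best-score selection.
#'
#' @param dataset A `genotype_dataset`.
#' @param config The [sim_config()] used to build `dataset`.
#' @param n_candidates Number of candidate files (>= 1).
#' @param noise_levels Nonnegative noise multipliers, one per candidate.
#' @return A named list of `scoring_file` objects (`cand1`, `cand2`, ...),
#'   with the true-weight scoring file attached as attribute `truth`.
#' @export
simulate_scoring_files <- function(dataset, config, n_candidates = 5,
                                   noise_levels = c(0, 0.25, 0.5, 1, 2)) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "sim_config"))
  n_candidates <- assert_count(n_candidates, "n_candidates")
  if (length(noise_levels) != n_candidates) {
    abort("`noise_levels` must have length `n_candidates`")
  }
  if (any(noise_levels < 0)) abort("`noise_levels` must be nonnegative")

  withr::with_seed(config$seed + 1L, {
    real <- !startsWith(dataset$variants$variant_id, "dup")
    pool <- which(real)
    causal <- sort(sample(pool, min(config$n_causal, length(pool))))
    w_true <- rnorm(length(causal))
    s <- sd(w_true)

    base <- dataset$variants[causal, ]
    mk <- function(w, id) {
      new_scoring_file(
        tibble::tibble(
          chr_name = base$chrom,
          chr_position = base$pos,
          effect_allele = base$allele1,
          other_allele = base$allele2,
          effect_weight = w
        ),
        score_id = id
      )
    }

    out <- purrr::map(seq_len(n_candidates), function(i) {
      w <- w_true + noise_levels[i] * s * rnorm(length(w_true))
      mk(w, sprintf("SIM%03d", i))
    })
    names(out) <- paste0("cand", seq_len(n_candidates))
    attr(out, "truth") <- mk(w_true, "SIM_TRUE")
    attr(out, "noise_levels") <- noise_levels
    out
  })
}

# Table-1-style trait roster: mean/SD of the *untreated* trait values
SIM_TRAITS <- tibble::tribble(
  ~trait, ~mean, ~sd,
  "ldl", 135.82, 53.38,
  "hdl", 45.20, 13.24,
  "tg", 165.73, 111.87,
  "sbp", 146.61, 23.92,
  "dbp", 83.06, 13.34,
  "bmi", 29.31, 6.05,
  "height", 1.61, 0.09
)

#' Simulate a clinical phenotype table from genotypes
#'
#' The genetic value `g` is the standardized weighted dosage sum under the true
#' weights. Binary diseases follow the liability-threshold model: liability =
#' sqrt(h2) g + sqrt(1 - h2) e with e ~ N(0,1), case iff liability exceeds the
#' (1 - prevalence) normal quantile. Continuous traits are mean + sd *
#' (sqrt(h2) g + sqrt(1 - h2) e) with trait-specific independent noise,
#' truncated below at a small positive value so measured quantities stay
#' nonnegative. Medication flags are logistic in the standardized untreated
#' trait; measured lipids/BP then have the forward treatment effect applied
#' (statin: LDL x0.70, TG x0.85; ezetimibe: LDL x0.80; fibrate: LDL x0.90;
#' antihypertensive: SBP -15, DBP -10), so the medication-adjustment
#' operations can recover the untreated values. Per-vessel coronary stenosis
#' is generated for cases, increasing in liability.
#'
#' @param dataset A `genotype_dataset`.
#' @param true_weights The true `scoring_file` (attribute `truth` of
#'   [simulate_scoring_files()]).
#' @param config The [sim_config()] used throughout.
#' @return A tibble with one row per sample (demographics, disease flags,
#'   per-vessel stenosis, measured traits, medication and smoking flags).
#'   Attribute `untreated` holds the simulation truth (genetic value,
#'   liabilities, untreated trait values) for validation.
#' @export
simulate_phenotypes <- function(dataset, true_weights, config) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "sim_config"))
  if (is.null(true_weights) || !inherits(true_weights, "scoring_file")) {
    abort("`true_weights` must be the true scoring_file")
  }

  hw <- harmonize_weights(true_weights, dataset)
  raw <- compute_raw_scores(hw, dataset)$raw
  g <- as.numeric(scale(raw))
  n <- length(g)
  h2 <- config$h2

  withr::with_seed(config$seed + 2L, {
    liab <- function(prev) {
      l <- sqrt(h2) * g + sqrt(1 - h2) * rnorm(n)
      list(liability = l, case = as.integer(l > qnorm(1 - prev)))
    }
    cad <- liab(config$prevalence)
    t2d <- liab(config$prevalence_t2d)
    cmp <- liab(config$prevalence_cmp)

    cont <- purrr::pmap(SIM_TRAITS, function(trait, mean, sd) {
      pmax(mean + sd * (sqrt(h2) * g + sqrt(1 - h2) * rnorm(n)), 0.01)
    })
    names(cont) <- SIM_TRAITS$trait

    # stenosis increasing in CAD liability for cases, zero otherwise
    excess <- cad$liability - qnorm(1 - config$prevalence)
    sten <- function(base, slope, noise) {
      s <- ifelse(cad$case == 1L,
                  base + slope * excess + rnorm(n, 0, noise), 0)
      pmin(pmax(s, 0), 100)
    }
    mi_history <- as.integer(cad$case == 1L & runif(n) < 0.3)

    zt <- function(x, trait) {
      row <- SIM_TRAITS[SIM_TRAITS$trait == trait, ]
      (x - row$mean) / row$sd
    }
    med <- function(coefs, z) {
      as.integer(runif(n) < stats::plogis(coefs[1] + coefs[2] * z))
    }
    ma <- config$med_assign
    statin <- med(ma$statin, zt(cont$ldl, "ldl"))
    ezetimibe <- med(ma$ezetimibe, zt(cont$ldl, "ldl"))
    fibrate <- med(ma$fibrate, zt(cont$tg, "tg"))
    antihtn <- med(ma$antihypertensive, zt(cont$sbp, "sbp"))

    pheno <- tibble::tibble(
      sample_id = dataset$samples$sample_id,
      cohort = dataset$samples$cohort,
      population = dataset$samples$population,
      age = pmax(18, rnorm(n, 54.83, 14.82)),
      sex = rbinom(n, 1L, 0.643),
      array_version = sample(c("na29", "na32"), n, replace = TRUE),
      cad = cad$case,
      t2d = t2d$case,
      cardiomyopathy = cmp$case,
      mi_history = mi_history,
      sten_lm = sten(15, 12, 15),
      sten_lad = sten(45, 22, 20),
      sten_lcx = sten(40, 22, 20),
      sten_rca = sten(40, 22, 20),
      ldl = cont$ldl * (1 - 0.30 * statin) * (1 - 0.20 * ezetimibe) *
        (1 - 0.10 * fibrate),
      hdl = cont$hdl,
      tg = cont$tg * (1 - 0.15 * statin),
      sbp = cont$sbp - 15 * antihtn,
      dbp = cont$dbp - 10 * antihtn,
      bmi = cont$bmi,
      height = cont$height,
      statin = statin,
      ezetimibe = ezetimibe,
      fibrate = fibrate,
      antihypertensive = antihtn,
      smoking = rbinom(n, 1L, 0.383)
    )

    attr(pheno, "untreated") <- tibble::tibble(
      sample_id = pheno$sample_id,
      g = g,
      liability_cad = cad$liability,
      liability_t2d = t2d$liability,
      !!!cont
    )
    pheno
  })
}

# dataset subsetting helpers used throughout qc/scoring/ancestry ------------

filter_samples <- function(dataset, keep) {
  new_genotype_dataset(dataset$dosages[keep, , drop = FALSE],
                       dataset$samples[keep, ], dataset$variants)
}

filter_variants <- function(dataset, keep) {
  new_genotype_dataset(dataset$dosages[, keep, drop = FALSE],
                       dataset$samples, dataset$variants[keep, ])
}

#' Subset a genotype dataset to one or more cohort roles
#'
#' @param dataset A `genotype_dataset`.
#' @param roles Character vector of cohort roles (e.g. `"panel"`).
#' @return A `genotype_dataset` containing only those samples.
#' @export
subset_cohort <- function(dataset, roles) {
  keep <- dataset$samples$cohort %in% roles
  if (!any(keep)) abort(sprintf("no samples with cohort role %s",
                                paste(roles, collapse = "/")))
  filter_samples(dataset, keep)
}
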