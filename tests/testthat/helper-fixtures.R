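# shared fixtures: everything is generated in code, cached per session

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small two-population study used by most integration-style tests
small_config <- function(seed = 42, ...) {
  args <- list(
    seed = seed, n_populations = 2, fst = 0.1,
    n_variants = 300, n_causal = 50, h2 = 0.5, prevalence = 0.5,
    cohort_sizes = c(panel = 300, reference = 200,
                     case_control = 500, biobank = 200),
    biobank_target_fraction = 0.25
  )
  override <- list(...)
  do.call(sim_config, utils::modifyList(args, override))
}

small_study <- function() {
  cached("small_study", function() {
    cfg <- small_config()
    dataset <- simulate_genotypes(cfg)
    scoring <- simulate_scoring_files(dataset, cfg, 3, c(0, 0.5, 2))
    pheno <- simulate_phenotypes(dataset, attr(scoring, "truth"), cfg)
    panel <- subset_cohort(dataset, "panel")
    model <- fit_pca(panel, ld_prune(panel, window = 150, step = 50), k = 10)
    pcs <- project_pcs(model, dataset)
    list(config = cfg, dataset = dataset, scoring = scoring,
         pheno = pheno, model = model, pcs = pcs)
  })
}

# hand-built genotype dataset from a dosage matrix
make_dataset <- function(dos, population = NULL, cohort = NULL,
                         allele1 = NULL, allele2 = NULL, info = NULL,
                         pos = NULL) {
  n <- nrow(dos)
  v <- ncol(dos)
  samples <- tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n)),
    population = population %||% rep("POP1", n),
    cohort = cohort %||% rep("case_control", n)
  )
  variants <- tibble::tibble(
    variant_id = sprintf("v%04d", seq_len(v)),
    chrom = "1",
    pos = pos %||% (seq_len(v) * 10L),
    allele1 = allele1 %||% rep("G", v),
    allele2 = allele2 %||% rep("A", v),
    info = info %||% rep(NA_real_, v)
  )
  prstailor:::new_genotype_dataset(dos, samples, variants)
}

make_pcs <- function(mat, ids = NULL) {
  colnames(mat) <- paste0("PC", seq_len(ncol(mat)))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids %||% sprintf("s%04d", seq_len(nrow(mat)))),
    tibble::as_tibble(mat)
  )
  class(out) <- c("pc_scores", class(out))
  out
}

# Hudson Fst estimator (ratio of averages) from two vectors of sample
# allele frequencies and their haploid sample sizes -- independent oracle
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# brute-force exact HWE p-value by full enumeration of heterozygote counts
hwe_brute <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  nA <- 2 * n_hom1 + n_het
  if (min(nA, 2 * n - nA) == 0) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    na <- (nA - h) / 2
    nb <- n - h - na
    lfactorial(n) - lfactorial(na) - lfactorial(h) - lfactorial(nb) +
      h * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}
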