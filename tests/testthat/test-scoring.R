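toy_scoring <- function(records, id = "TOY") {
  prstailor:::new_scoring_file(records, score_id = id)
}

test_that("the parser reads PGS Catalog layout and reports format errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "#pgs_id=PGS_TOY", "#trait_reported=toy", "#genome_build=GRCh38",
    "chr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    "1\t100\tG\tA\t0.1",
    "1\t200\tC\tA\t-0.2",
    "1\t300\tT\tG\t0.05"
  ), path)
  sf <- read_scoring_file(path)
  expect_s3_class(sf, "scoring_file")
  expect_equal(sf$effect_weight, c(0.1, -0.2, 0.05))
  expect_equal(sf$chr_position, c(100L, 200L, 300L))
  expect_identical(attr(sf, "score_id"), "PGS_TOY")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "chr_name\tchr_position\tother_allele\teffect_weight",
    "1\t100\tA\t0.1"
  ), bad)
  expect_error(read_scoring_file(bad), "missing column effect_allele")

  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "#pgs_id=X",
    "chr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    "1\t100\tG\tA\t0.1",
    "1\t200\tC\tA\tnot_a_number"
  ), bad2)
  expect_error(read_scoring_file(bad2), "non-numeric effect_weight at line 4")
})

test_that("harmonization classifies direct, swapped, palindromic and unmatched records", {
  d <- make_dataset(matrix(1, 4, 3),
                    allele1 = c("G", "G", "C"),
                    allele2 = c("A", "A", "T"),
                    pos = c(100L, 200L, 300L))
  sf <- toy_scoring(tibble::tibble(
    chr_name = "1",
    chr_position = c(100L, 200L, 300L, 999L),
    effect_allele = c("G", "A", "A", "G"),
    other_allele = c("A", "G", "T", "A"),
    effect_weight = c(1, 2, 3, 4)
  ))
  hw <- harmonize_weights(sf, d)
  expect_equal(hw$orientation, c("direct", "swapped"))
  expect_equal(attr(hw, "n_matched"), 2)
  expect_equal(attr(hw, "n_swapped"), 1)
  expect_equal(attr(hw, "n_palindromic_dropped"), 1)  # A/T record
  expect_equal(attr(hw, "n_unmatched"), 1)            # position 999
  expect_equal(attr(hw, "n_matched") + attr(hw, "n_palindromic_dropped") +
                 attr(hw, "n_unmatched"), nrow(sf))

  # zero matches signal a build/format mismatch
  far <- toy_scoring(tibble::tibble(
    chr_name = "1", chr_position = 12345L,
    effect_allele = "G", other_allele = "A", effect_weight = 1
  ))
  expect_error(harmonize_weights(far, d), "build or format mismatch")
})

test_that("raw scores match trivial closed forms", {
  withr::with_seed(1, {
    d <- make_dataset(matrix(rbinom(30, 2, 0.5), 10, 3))
  })
  zero <- toy_scoring(tibble::tibble(
    chr_name = "1", chr_position = c(10L, 20L, 30L),
    effect_allele = "G", other_allele = "A", effect_weight = 0
  ))
  expect_equal(compute_raw_scores(harmonize_weights(zero, d), d)$raw,
               rep(0, 10))

  d1 <- make_dataset(matrix(c(0, 1, 2), 3, 1))
  one <- toy_scoring(tibble::tibble(
    chr_name = "1", chr_position = 10L,
    effect_allele = "G", other_allele = "A", effect_weight = 1
  ))
  expect_equal(compute_raw_scores(harmonize_weights(one, d1), d1)$raw,
               c(0, 1, 2))
})

test_that("the scoring engine equals a per-sample double-loop oracle", {
  withr::with_seed(2, {
    dos <- matrix(rbinom(50, 2, 0.4), 5, 10)
    dos[cbind(c(1, 3, 5), c(2, 7, 7))] <- NA   # exercise mean imputation
    d <- make_dataset(dos,
                      allele1 = rep(c("G", "C"), 5),
                      allele2 = rep(c("A", "T"), 5))
    w <- rnorm(10)
  })
  # swap the allele labels on half the records so both orientations occur
  swap <- seq(2, 10, by = 2)
  sf <- toy_scoring(tibble::tibble(
    chr_name = "1",
    chr_position = d$variants$pos,
    effect_allele = ifelse(seq_len(10) %in% swap,
                           d$variants$allele2, d$variants$allele1),
    other_allele = ifelse(seq_len(10) %in% swap,
                          d$variants$allele1, d$variants$allele2),
    effect_weight = w
  ))
  hw <- harmonize_weights(sf, d)
  got <- compute_raw_scores(hw, d)$raw

  oracle <- numeric(5)
  for (i in 1:5) {
    acc <- 0
    for (j in 1:10) {
      dj <- d$dosages[, j]
      if (j %in% swap) dj <- 2 - dj
      x <- if (is.na(dj[i])) mean(dj, na.rm = TRUE) else dj[i]
      acc <- acc + w[j] * x
    }
    oracle[i] <- acc
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("flipping a variant's allele labels leaves scores unchanged", {
  withr::with_seed(3, {
    d <- make_dataset(matrix(rbinom(200, 2, 0.3), 20, 10))
    w <- rnorm(10)
  })
  sf <- toy_scoring(tibble::tibble(
    chr_name = "1", chr_position = d$variants$pos,
    effect_allele = d$variants$allele1, other_allele = d$variants$allele2,
    effect_weight = w
  ))
  s1 <- compute_raw_scores(harmonize_weights(sf, d), d)$raw

  flipped <- d
  flipped$variants$allele1[4] <- d$variants$allele2[4]
  flipped$variants$allele2[4] <- d$variants$allele1[4]
  flipped$dosages[, 4] <- 2 - d$dosages[, 4]
  hw2 <- harmonize_weights(sf, flipped)
  expect_equal(hw2$orientation[4], "swapped")
  s2 <- compute_raw_scores(hw2, flipped)$raw
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("permuting sample order permutes scores identically", {
  withr::with_seed(4, {
    d <- make_dataset(matrix(rbinom(200, 2, 0.5), 20, 10))
    w <- rnorm(10)
  })
  sf <- toy_scoring(tibble::tibble(
    chr_name = "1", chr_position = d$variants$pos,
    effect_allele = d$variants$allele1, other_allele = d$variants$allele2,
    effect_weight = w
  ))
  s1 <- compute_raw_scores(harmonize_weights(sf, d), d)

  perm <- sample(20)
  dp <- prstailor:::filter_samples(d, perm)
  s2 <- compute_raw_scores(harmonize_weights(sf, dp), dp)
  m <- match(s1$sample_id, s2$sample_id)
  expect_equal(s1$raw, s2$raw[m])
})

test_that("mean imputation keeps a missing sample's contribution inside the observed envelope", {
  withr::with_seed(5, {
    d <- make_dataset(matrix(rbinom(40, 2, 0.5), 20, 2))
  })
  sf <- toy_scoring(tibble::tibble(
    chr_name = "1", chr_position = d$variants$pos,
    effect_allele = d$variants$allele1, other_allele = d$variants$allele2,
    effect_weight = c(1.5, -0.7)
  ))
  d$dosages[3, 1] <- NA
  s <- compute_raw_scores(harmonize_weights(sf, d), d)$raw
  contrib3_v1 <- s[3] - (-0.7) * d$dosages[3, 2]
  obs <- 1.5 * d$dosages[-3, 1]
  expect_gte(contrib3_v1, min(obs))
  expect_lte(contrib3_v1, max(obs))

  # normalization cohort contract: mean 0, SD 1 over that cohort
  st <- small_study()
  sc <- compute_raw_scores(harmonize_weights(st$scoring$cand2, st$dataset),
                           st$dataset, normalization_cohort = "reference")
  ref <- sc$normalized[st$dataset$samples$cohort == "reference"]
  expect_equal(mean(ref), 0, tolerance = 1e-12)
  expect_equal(sd(ref), 1, tolerance = 1e-12)
})
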