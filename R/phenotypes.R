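#' Medication-adjustment rules
#'
#' Fractions by which lipid-lowering drugs reduce measured lipids and
#' additive offsets removed by antihypertensives. Defaults: statins reduce
#' LDL by 30% and TG by 15%; ezetimibe reduces LDL by 20%; fibrate reduces
#' LDL by 10%; antihypertensives are assumed to have lowered SBP by 15 mmHg
#' and DBP by 10 mmHg. Fibrate effects on TG and HDL have no established
#' default here and stay unset (`NA`): samples needing them are flagged
#' rather than silently adjusted.
#'
#' @param statin_ldl_frac,statin_tg_frac,ezetimibe_ldl_frac,fibrate_ldl_frac
#'   Fractional reductions in `[0, 1)`.
#' @param sbp_add,dbp_add Additive mmHg offsets (>= 0).
#' @param fibrate_tg_frac,fibrate_hdl_frac Optional fractions, default `NA`.
#' @return A `medication_rules` list.
#' @export
medication_rules <- function(statin_ldl_frac = 0.30,
                             statin_tg_frac = 0.15,
                             ezetimibe_ldl_frac = 0.20,
                             fibrate_ldl_frac = 0.10,
                             sbp_add = 15,
                             dbp_add = 10,
                             fibrate_tg_frac = NA_real_,
                             fibrate_hdl_frac = NA_real_) {
  for (f in c(statin_ldl_frac, statin_tg_frac, ezetimibe_ldl_frac,
              fibrate_ldl_frac)) {
    assert_number(f, "medication fraction", 0, 1, strict_upper = TRUE)
  }
  assert_number(sbp_add, "sbp_add", 0, Inf)
  assert_number(dbp_add, "dbp_add", 0, Inf)
  structure(
    list(statin_ldl_frac = statin_ldl_frac,
         statin_tg_frac = statin_tg_frac,
         ezetimibe_ldl_frac = ezetimibe_ldl_frac,
         fibrate_ldl_frac = fibrate_ldl_frac,
         sbp_add = sbp_add, dbp_add = dbp_add,
         fibrate_tg_frac = fibrate_tg_frac,
         fibrate_hdl_frac = fibrate_hdl_frac),
    class = "medication_rules"
  )
}

#' Estimate untreated lipid levels from measured values and medication flags
#'
#' Multiplicative back-adjustment: the estimated untreated value is the
#' measured value divided by the product of `(1 - fraction)` over the active
#' medications affecting that lipid, so combination therapy composes
#' multiplicatively and the adjustment is order-invariant. LDL is adjusted
#' for statin/ezetimibe/fibrate; TG for statin (plus fibrate when
#' `fibrate_tg_frac` is set); HDL only when `fibrate_hdl_frac` is set.
#' Samples on fibrate whose TG/HDL fractions are unset are flagged in
#' `tg_needs_fibrate_adjustment` / `hdl_needs_fibrate_adjustment`.
#'
#' @param data Tibble with columns `ldl`, `hdl`, `tg` (mg/dL) and binary
#'   flags `statin`, `ezetimibe`, `fibrate`.
#' @param rules A [medication_rules()].
#' @return `data` with adjusted lipids, a `lipids_adjusted` provenance column
#'   and the fibrate flags above. Calling twice is an error.
#' @export
adjust_lipids <- function(data, rules = medication_rules()) {
  assert_columns(data, c("ldl", "hdl", "tg", "statin", "ezetimibe", "fibrate"),
                 "phenotype data")
  if ("lipids_adjusted" %in% names(data) && any(data$lipids_adjusted)) {
    abort("lipids are already medication-adjusted")
  }
  bad <- c(data$ldl, data$hdl, data$tg)
  if (any(bad < 0, na.rm = TRUE)) abort("lipid values must be nonnegative")

  ldl_fac <- (1 - rules$statin_ldl_frac)^data$statin *
    (1 - rules$ezetimibe_ldl_frac)^data$ezetimibe *
    (1 - rules$fibrate_ldl_frac)^data$fibrate
  tg_fac <- (1 - rules$statin_tg_frac)^data$statin
  if (!is.na(rules$fibrate_tg_frac)) {
    tg_fac <- tg_fac * (1 - rules$fibrate_tg_frac)^data$fibrate
  }
  hdl_fac <- rep(1, nrow(data))
  if (!is.na(rules$fibrate_hdl_frac)) {
    hdl_fac <- (1 - rules$fibrate_hdl_frac)^data$fibrate
  }

  dplyr::mutate(
    data,
    ldl = .data$ldl / ldl_fac,
    tg = .data$tg / tg_fac,
    hdl = .data$hdl / hdl_fac,
    lipids_adjusted = TRUE,
    tg_needs_fibrate_adjustment =
      is.na(rules$fibrate_tg_frac) & .data$fibrate == 1,
    hdl_needs_fibrate_adjustment =
      is.na(rules$fibrate_hdl_frac) & .data$fibrate == 1
  )
}

#' Estimate untreated blood pressure from measured values and treatment flag
#'
#' Treated samples get `sbp + 15` and `dbp + 10` (rule-configurable);
#' untreated samples are unchanged. A `bp_adjusted` provenance column guards
#' against double application.
#'
#' @param data Tibble with `sbp`, `dbp` (mmHg) and binary `antihypertensive`.
#' @param rules A [medication_rules()].
#' @return `data` with adjusted pressures and `bp_adjusted = TRUE`.
#' @export
adjust_bp <- function(data, rules = medication_rules()) {
  assert_columns(data, c("sbp", "dbp", "antihypertensive"), "phenotype data")
  if ("bp_adjusted" %in% names(data) && any(data$bp_adjusted)) {
    abort("blood pressure is already medication-adjusted")
  }
  if (any(c(data$sbp, data$dbp) < 0, na.rm = TRUE)) {
    abort("blood pressure values must be nonnegative")
  }
  dplyr::mutate(
    data,
    sbp = .data$sbp + rules$sbp_add * .data$antihypertensive,
    dbp = .data$dbp + rules$dbp_add * .data$antihypertensive,
    bp_adjusted = TRUE
  )
}

#' Classify coronary artery disease status and severity from angiography
#'
#' A vessel is obstructive at >= 70% stenosis for the left anterior
#' descending (LAD), left circumflex (LCx) and right coronary artery (RCA),
#' and at >= 50% for the left main (LM). `any_cad` is any nonzero stenosis or
#' a myocardial-infarction history. Severity (`n_obstructive_vessels`) counts
#' obstructive vessels among LAD/LCx/RCA only; LM carries its own flag.
#'
#' @param data Tibble with stenosis percents `sten_lm`, `sten_lad`,
#'   `sten_lcx`, `sten_rca` in `[0, 100]` and binary `mi_history`.
#' @return `data` with `lm_obstructive`, `lad_obstructive`, `lcx_obstructive`,
#'   `rca_obstructive`, `n_obstructive_vessels`, `obstructive_cad`, `any_cad`.
#' @export
classify_cad <- function(data) {
  cols <- c("sten_lm", "sten_lad", "sten_lcx", "sten_rca")
  assert_columns(data, c(cols, "mi_history"), "phenotype data")
  sten <- as.matrix(data[cols])
  if (any(sten < 0 | sten > 100, na.rm = TRUE)) {
    abort("stenosis percents must be in [0, 100]")
  }
  dplyr::mutate(
    data,
    lm_obstructive = .data$sten_lm >= 50,
    lad_obstructive = .data$sten_lad >= 70,
    lcx_obstructive = .data$sten_lcx >= 70,
    rca_obstructive = .data$sten_rca >= 70,
    n_obstructive_vessels = as.integer(.data$lad_obstructive) +
      as.integer(.data$lcx_obstructive) + as.integer(.data$rca_obstructive),
    obstructive_cad = .data$lm_obstructive | .data$lad_obstructive |
      .data$lcx_obstructive | .data$rca_obstructive,
    any_cad = .data$sten_lm > 0 | .data$sten_lad > 0 | .data$sten_lcx > 0 |
      .data$sten_rca > 0 | .data$mi_history == 1
  )
}

#' Derive conventional risk-factor flags
#'
#' Obesity is BMI >= 30 kg/m2 (inclusive). Hypertension is SBP >= 140 or
#' DBP >= 90 mmHg or antihypertensive use. Smoking and diabetes pass through
#' existing columns. When `percentiles` is supplied (a [percentile_rank()]
#' result), top/bottom-quintile flags of genomic risk are added (top:
#' percentile in `[80, 100]`; bottom: `[0, 20)`). Missing inputs yield
#' missing flags.
#'
#' @param data Phenotype tibble.
#' @param percentiles Optional percentile tibble (`sample_id`, `percentile`).
#' @return `data` with `obesity`, `hypertension`, and (when available)
#'   `high_genomic_risk` / `low_genomic_risk`.
#' @export
derive_risk_factors <- function(data, percentiles = NULL) {
  out <- data
  if ("bmi" %in% names(out)) {
    out <- dplyr::mutate(out, obesity = .data$bmi >= 30)
  }
  if (all(c("sbp", "dbp") %in% names(out))) {
    med <- if ("antihypertensive" %in% names(out)) {
      out$antihypertensive == 1
    } else {
      FALSE
    }
    out <- dplyr::mutate(out,
                         hypertension = .data$sbp >= 140 | .data$dbp >= 90 | med)
  }
  if (!is.null(percentiles)) {
    m <- match(out$sample_id, percentiles$sample_id)
    pct <- percentiles$percentile[m]
    out <- dplyr::mutate(out,
                         high_genomic_risk = pct >= 80,
                         low_genomic_risk = pct < 20)
  }
  out
}
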