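#' Plot a decile stratification table
#'
#' Binary outcomes: per-decile prevalence bars. Continuous outcomes:
#' per-decile median with IQR error bars.
#'
#' @param object A [decile_stratify()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decile_table
#' @export
autoplot.decile_table <- function(object, ...) {
  type <- attr(object, "type")
  outcome <- attr(object, "outcome")
  df <- tibble::as_tibble(object)
  if (type == "binary") {
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$decile),
                                     y = .data$prevalence)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "Polygenic score decile (reference-anchored)",
                    y = paste("Prevalence of", outcome)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$decile),
                                     y = .data$median)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1,
                                            ymax = .data$q3)) +
      ggplot2::labs(x = "Polygenic score decile (reference-anchored)",
                    y = paste("Median", outcome, "(IQR)")) +
      ggplot2::theme_minimal()
  }
}

#' Plot the Mahalanobis distance distribution with the match boundary
#'
#' @param object A [mahalanobis_match()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mahalanobis_match
#' @export
autoplot.mahalanobis_match <- function(object, ...) {
  df <- object$matches
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d2)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Squared Mahalanobis distance from target centroid",
                  y = "Candidates",
                  subtitle = sprintf("chi-squared cutoff %.2f (alpha %.3g, df %d)",
                                     object$cutoff, object$alpha, object$df)) +
    ggplot2::theme_minimal()
}

#' Scatter the first two ancestry PCs, coloured by population or cohort
#'
#' @param pcs A `pc_scores` tibble.
#' @param samples Sample tibble (`sample_id` plus the colour column).
#' @param colour Column of `samples` to colour by (default `"population"`).
#' @return A ggplot object.
#' @export
plot_pc_scores <- function(pcs, samples, colour = "population") {
  df <- dplyr::left_join(tibble::as_tibble(pcs), samples, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of subgroup score effects
#'
#' Takes a long table (`stratum`/`subgroup`, `effect_per_sd`, `ci_lower`,
#' `ci_upper`) such as the `strata` element of [interaction_test()].
#'
#' @param results Long-format tibble of subgroup effects.
#' @param label Column naming each subgroup (default `"stratum"`).
#' @return A ggplot object.
#' @export
plot_subgroup_effects <- function(results, label = "stratum") {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$effect_per_sd,
                               y = .data[[label]])) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "OR per SD (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
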