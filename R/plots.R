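#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_boxplot
#'   geom_histogram geom_vline geom_hline labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot the search trace of a weight search
#'
#' Best-so-far objective per generation, one line per restart.
#'
#' @param object A `wcvr_search` from [ga_search()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wcvr_search <- function(object, ...) {
  ggplot(object$traces,
         aes(x = .data$generation, y = .data$best_objective,
             colour = factor(.data$restart))) +
    geom_line() +
    labs(x = "Generation", y = paste0("Best objective (", object$objective, ")"),
         colour = "Restart",
         title = paste0("Weight search trace: ", object$best_spec$name)) +
    theme_minimal()
}

#' Plot bootstrap weight distributions
#'
#' Boxplots of the signed normalized peptide weights across bootstrap
#' replicates: positive weights place a peptide in the numerator, negative
#' in the denominator.
#'
#' @param object A `wcvr_weight_distribution` from
#'   [bootstrap_weight_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wcvr_weight_distribution <- function(object, ...) {
  ggplot(object$weights, aes(x = .data$peptide, y = .data$weight_pct)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_boxplot() +
    labs(x = NULL, y = "Signed weight (%)",
         title = paste0("Bootstrapped weights (objective ", object$objective, ")")) +
    theme_minimal()
}

#' Deviation of case samples from the control mean
#'
#' Histograms of harmonized case values per peptide, with the control mean
#' (1 on the harmonized scale) marked. Shorter peptides typically fall
#' below 1, longer above.
#'
#' @param panel A harmonized (non-rescaled) panel tibble.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_deviation_profile <- function(panel, bins = 30) {
  validate_panel(panel)
  long <- tidyr::pivot_longer(panel[panel$group == "case", ],
                              dplyr::all_of(ab_peptides()),
                              names_to = "peptide", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    geom_histogram(bins = bins, fill = "grey40") +
    geom_vline(xintercept = 1, colour = "red", linetype = 2) +
    facet_wrap(~peptide, scales = "free") +
    labs(x = "Harmonized value (control mean = 1)", y = "Case samples") +
    theme_minimal()
}

#' Performance landscape of ratio biomarkers
#'
#' Scatter of age-at-onset \eqn{R^2} against control-class PR AUC, one
#' point per biomarker; named biomarkers (benchmarks, searched wCVRs) can
#' be highlighted over the cloud of enumerated unweighted ratios.
#'
#' @param enumeration A tibble with columns `biomarker`, `pr_auc_controls`,
#'   `r_squared` (e.g. the `enumeration` element of [run_pipeline()]).
#' @param highlight Optional tibble of the same shape drawn as labelled
#'   points.
#' @return A ggplot.
#' @export
plot_performance_map <- function(enumeration, highlight = NULL) {
  p <- ggplot(enumeration, aes(x = .data$pr_auc_controls, y = .data$r_squared)) +
    geom_point(shape = 1, colour = "grey50") +
    labs(x = "PR AUC (controls)", y = expression(R^2 ~ "(age at onset)")) +
    theme_minimal()
  if (!is.null(highlight)) {
    p <- p + geom_point(data = highlight, aes(colour = .data$biomarker), size = 3)
  }
  p
}
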