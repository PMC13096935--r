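check_labels <- function(labels) {
  if (!all(labels %in% c("control", "case"))) {
    abort("`labels` must contain only 'control' and 'case'.")
  }
  labels
}

#' Resolve the abnormal direction of a biomarker
#'
#' The abnormal direction is the sign of (case median - control median) of
#' the scores: `"higher"` when cases score above controls, `"lower"`
#' otherwise. Classification metrics and the cross-validation threshold rule
#' operate on scores oriented so that higher means more abnormal.
#'
#' @param scores Numeric biomarker scores.
#' @param labels Character vector of `"control"` / `"case"`.
#' @return `"higher"` or `"lower"`.
#' @export
resolve_orientation <- function(scores, labels) {
  check_labels(labels)
  d <- median(scores[labels == "case"]) - median(scores[labels == "control"])
  if (d >= 0) "higher" else "lower"
}

orient_scores <- function(scores, labels, orientation = "auto") {
  orientation <- rlang::arg_match(orientation, c("auto", "higher", "lower"))
  if (orientation == "auto") orientation <- resolve_orientation(scores, labels)
  if (orientation == "lower") -scores else scores
}

#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) formulation: the fraction of
#' (case, control) pairs in which the case scores higher, ties counted one
#' half. Scores are first oriented so that higher means abnormal (see
#' [resolve_orientation()]); with `orientation = "auto"` the direction is
#' resolved on the supplied data.
#'
#' @param scores Numeric biomarker scores.
#' @param labels `"control"` / `"case"` per score.
#' @param orientation `"auto"`, `"higher"`, or `"lower"` (abnormal direction).
#' @return The ROC AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(1, 3, 2, 4), c("control", "control", "case", "case"))
roc_auc <- function(scores, labels, orientation = "auto") {
  check_labels(labels)
  if (length(unique(labels)) < 2) abort("ROC AUC needs both classes present.")
  s <- orient_scores(scores, labels, orientation)
  r <- rank(s)
  n1 <- sum(labels == "case")
  n0 <- sum(labels == "control")
  (sum(r[labels == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (right-continuous) precision-recall AUC, avoiding the
#' optimistic linear interpolation of the trapezoid rule. For the minority
#' control class (`positive = "control"`, the default of
#' [pr_auc_controls()]) the curve plots control precision TN/(TN + FN)
#' against control recall TN/(TN + FP): a sample is called control when its
#' abnormality-oriented score falls at or below the threshold.
#'
#' @inheritParams roc_auc
#' @param positive Which class is treated as the positive class.
#' @return The PR AUC in \[0, 1\]; for uninformative scores it approaches
#'   the positive-class prevalence.
#' @export
pr_auc <- function(scores, labels, positive = c("control", "case"),
                   orientation = "auto") {
  positive <- rlang::arg_match(positive)
  check_labels(labels)
  if (sum(labels == positive) == 0) {
    abort(paste0("PR AUC needs at least one '", positive, "' sample."))
  }
  s <- orient_scores(scores, labels, orientation)
  # orient so the positive class is the high-scoring one
  if (positive == "control") s <- -s
  ord <- order(s, decreasing = TRUE)
  y <- labels[ord] == positive
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # collapse tied scores: keep the last index of each tied block
  keep <- c(diff(s[ord]) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' @rdname pr_auc
#' @export
pr_auc_controls <- function(scores, labels, orientation = "auto") {
  pr_auc(scores, labels, positive = "control", orientation = orientation)
}

#' Squared Pearson correlation between scores and age at onset
#'
#' The coefficient of determination \eqn{R^2} used for the regression
#' objective: the square of the Pearson correlation between biomarker score
#' and age at onset, computed over mutation carriers only (rows with a
#' non-missing `aao`).
#'
#' @param scores Numeric biomarker scores.
#' @param aao Age at onset in years; `NA` for controls.
#' @return \eqn{R^2} in \[0, 1\]; 0 (with a warning) when either variable is
#'   constant.
#' @export
pearson_r2_vs_aao <- function(scores, aao) {
  keep <- !is.na(aao)
  s <- scores[keep]; a <- aao[keep]
  if (length(s) < 3) abort("R^2 vs age at onset needs at least 3 carriers with AAO.")
  if (sd(s) == 0 || sd(a) == 0) {
    warn("Zero variance in scores or AAO; R^2 reported as 0.")
    return(0)
  }
  cor(s, a)^2
}

#' Bootstrap confidence interval for a metric
#'
#' Resamples the rows of `data` with replacement (within each stratum when
#' `strata` is given, preserving class counts under heavy imbalance) and
#' reports the bootstrap median and 2.5/97.5 percentiles of
#' `metric_fn(data)`. Replicates on which the metric fails or is
#' non-finite are redrawn up to `max_retries` times, then skipped.
#'
#' @param data A data frame of per-sample rows.
#' @param metric_fn Function of a data frame returning a scalar.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param strata Optional vector (length `nrow(data)`) of stratum labels for
#'   stratified resampling, e.g. the case/control group.
#' @param seed Integer seed; the RNG state is restored afterwards.
#' @param metric Name reported in the output.
#' @param point `"median"` (bootstrap median, the default) or `"plugin"`
#'   (the metric on the original data).
#' @param conf Confidence level (default 0.95).
#' @param max_retries Redraw attempts per failed replicate.
#' @return A one-row tibble: `metric`, `estimate`, `conf.low`, `conf.high`,
#'   `n_boot`, `stratified`.
#' @export
bootstrap_ci <- function(data, metric_fn, n_boot = 2000, strata = NULL,
                         seed = 1L, metric = "metric",
                         point = c("median", "plugin"), conf = 0.95,
                         max_retries = 10) {
  point <- rlang::arg_match(point)
  n <- nrow(data)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  draw <- function() {
    unlist(lapply(idx_by_stratum, function(ix) ix[sample.int(length(ix), length(ix), replace = TRUE)]),
           use.names = FALSE)
  }
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (attempt in seq_len(max_retries)) {
        v <- tryCatch(metric_fn(data[draw(), , drop = FALSE]),
                      error = function(e) NA_real_, warning = function(w) NA_real_)
        if (is.finite(v)) return(v)
      }
      NA_real_
    }, numeric(1))
  })
  n_failed <- sum(is.na(vals))
  if (n_failed > 0) {
    warn(paste0(n_failed, " bootstrap replicate(s) skipped (metric undefined after retries)."))
    vals <- vals[!is.na(vals)]
  }
  alpha <- (1 - conf) / 2
  est <- if (point == "median") median(vals) else metric_fn(data)
  tibble::tibble(
    metric = metric,
    estimate = est,
    conf.low = unname(quantile(vals, alpha, type = 7)),
    conf.high = unname(quantile(vals, 1 - alpha, type = 7)),
    n_boot = n_boot,
    stratified = !is.null(strata)
  )
}

#' Evaluate biomarkers with bootstrap confidence intervals
#'
#' Scores each biomarker on the panel and reports ROC AUC, control-class PR
#' AUC, case-class PR AUC, and \eqn{R^2} versus age at onset, each with a
#' 95% bootstrap CI (2000 replicates by default; stratified by group for
#' the classification metrics to respect the heavy class imbalance). The
#' abnormal direction of each biomarker is resolved once on the full panel
#' and held fixed across bootstrap replicates.
#'
#' @param panel A harmonized (and, for additive specs, reference-rescaled)
#'   panel tibble.
#' @param specs A list of [ratio_spec()] objects (default [benchmark_specs()]).
#' @param n_boot Bootstrap replicates per metric.
#' @param seed Integer seed.
#' @param point Passed to [bootstrap_ci()].
#' @return A tibble with one row per (biomarker, metric).
#' @export
#' @examples
#' \donttest{
#' panel <- harmonize_panel(simulate_cohorts(sim_config(seed = 2)))
#' evaluate_biomarkers(panel, benchmark_specs()["Ab42/40"], n_boot = 200)
#' }
evaluate_biomarkers <- function(panel, specs = benchmark_specs(), n_boot = 2000,
                                seed = 1L, point = "median") {
  if (inherits(specs, "ratio_spec")) specs <- list(specs)
  purrr::imap_dfr(specs, function(spec, nm) {
    sc <- compute_ratio(panel, spec)
    orientation <- resolve_orientation(sc$score, sc$group)
    cls <- list(
      roc_auc = function(d) roc_auc(d$score, d$group, orientation),
      pr_auc_controls = function(d) pr_auc_controls(d$score, d$group, orientation),
      pr_auc_cases = function(d) pr_auc(d$score, d$group, "case", orientation)
    )
    out <- purrr::imap_dfr(cls, function(f, mnm) {
      bootstrap_ci(sc, f, n_boot = n_boot, strata = sc$group,
                   seed = seed, metric = mnm, point = point)
    })
    carriers <- sc[!is.na(sc$aao_years), , drop = FALSE]
    if (nrow(carriers) >= 3) {
      out <- dplyr::bind_rows(out, bootstrap_ci(
        carriers, function(d) pearson_r2_vs_aao(d$score, d$aao_years),
        n_boot = n_boot, seed = seed, metric = "r_squared", point = point))
    }
    dplyr::mutate(out, biomarker = spec$name, orientation = orientation,
                  .before = 1)
  })
}
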