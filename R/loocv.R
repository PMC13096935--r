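f1_score <- function(predicted_case, is_case) {
  tp <- sum(predicted_case & is_case)
  fp <- sum(predicted_case & !is_case)
  fn <- sum(!predicted_case & is_case)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Leave-one-out cross-validation of biomarkers
#'
#' Evaluates each biomarker by leave-one-out cross-validation over all
#' samples (carriers and controls). In each fold the held-out sample is
#' scored with a spec derived from the training fold only:
#'
#' * **Classification.** The abnormal direction is resolved on the training
#'   fold and the decision threshold is set at the most extreme training
#'   control score in that direction (prioritizing specificity for the
#'   small control group); the held-out sample is called a case only if its
#'   score lies strictly beyond the threshold. By construction no training
#'   control is ever misclassified.
#' * **Regression.** An ordinary least-squares line of age at onset on
#'   score is fitted on the training carriers; a held-out carrier receives
#'   the fitted prediction.
#'
#' A fixed [ratio_spec()] is applied as-is; a [search_config()] re-runs the
#' weight search inside every training fold (no information leakage from
#' the held-out sample).
#'
#' @param panel A harmonized, reference-rescaled panel with one row per
#'   sample (replicates already averaged).
#' @param specs A [ratio_spec()], [search_config()], or (possibly named)
#'   list of either.
#' @param n_boot Bootstrap replicates for the MAE and F1 confidence
#'   intervals (default 2000).
#' @param seed Integer seed (bootstrap, and per-fold searches).
#' @return A named list of `wcvr_loocv` objects, each with per-sample
#'   held-out `predictions`, `mae` (years, over carriers), `f1` (case as
#'   the positive class), and bootstrap CIs.
#' @export
#' @examples
#' \donttest{
#' panel <- harmonize_panel(simulate_cohorts(sim_config(
#'   n_cohorts = 1, n_controls = 4, n_cases = 20, seed = 5)))
#' rep <- loocv_evaluate(panel, benchmark_specs()["Ab42/40"], n_boot = 200)
#' glance(rep[["Ab42/40"]])
#' }
loocv_evaluate <- function(panel, specs, n_boot = 2000, seed = 1L) {
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  if (inherits(specs, "ratio_spec") || inherits(specs, "search_config")) specs <- list(specs)
  if (is.null(names(specs))) {
    names(specs) <- purrr::map_chr(specs, function(s) {
      if (inherits(s, "ratio_spec")) s$name else paste0("wCVR-", s$objective)
    })
  }
  if (sum(panel$group == "control") < 2 || sum(panel$group == "case") < 2) {
    abort("LOOCV needs at least 2 controls and 2 cases.")
  }
  out <- purrr::imap(specs, function(sp, nm) loocv_one(panel, sp, nm, n_boot, seed))
  out
}

loocv_one <- function(panel, spec, name, n_boot, seed) {
  n <- nrow(panel)
  X <- peptide_matrix(panel)
  preds <- purrr::map_dfr(seq_len(n), function(i) {
    train <- panel[-i, , drop = FALSE]
    if (sum(train$group == "control") == 0) {
      warn(paste0("Fold ", i, " has no training controls; fold skipped."))
      return(NULL)
    }
    fold_spec <- if (inherits(spec, "search_config")) {
      cfg <- spec
      cfg$seed <- spec$seed + i
      ga_search(train, cfg)$best_spec
    } else {
      spec
    }
    s_train <- score_matrix(peptide_matrix(train), fold_spec)
    s_test <- score_matrix(X[i, , drop = FALSE], fold_spec)
    orientation <- resolve_orientation(s_train, train$group)
    o_train <- if (orientation == "lower") -s_train else s_train
    o_test <- if (orientation == "lower") -s_test else s_test
    threshold <- max(o_train[train$group == "control"])
    predicted_class <- if (o_test > threshold) "case" else "control"
    predicted_aao <- NA_real_
    if (!is.na(panel$aao_years[i])) {
      carriers <- !is.na(train$aao_years)
      fit <- lm(aao ~ score,
                data = data.frame(aao = train$aao_years[carriers], score = s_train[carriers]))
      predicted_aao <- unname(predict(fit, data.frame(score = s_test)))
    }
    tibble::tibble(
      sample_id = panel$sample_id[i], cohort = panel$cohort[i],
      group = panel$group[i], aao_years = panel$aao_years[i],
      score = as.numeric(s_test), orientation = orientation,
      threshold = if (orientation == "lower") -threshold else threshold,
      predicted_class = predicted_class, predicted_aao = predicted_aao,
      abs_error = abs(predicted_aao - panel$aao_years[i])
    )
  })
  mae <- mean(preds$abs_error, na.rm = TRUE)
  f1 <- f1_score(preds$predicted_class == "case", preds$group == "case")
  ci <- dplyr::bind_rows(
    bootstrap_ci(preds[!is.na(preds$abs_error), ],
                 function(d) mean(d$abs_error), n_boot = n_boot,
                 seed = seed, metric = "mae", point = "plugin"),
    bootstrap_ci(preds, function(d) f1_score(d$predicted_class == "case", d$group == "case"),
                 n_boot = n_boot, strata = preds$group, seed = seed,
                 metric = "f1", point = "plugin")
  )
  structure(list(biomarker = name, predictions = preds, mae = mae, f1 = f1,
                 estimates = ci, n_boot = n_boot, seed = seed),
            class = "wcvr_loocv")
}

#' @export
print.wcvr_loocv <- function(x, ...) {
  cat("<wcvr_loocv> ", x$biomarker, ": F1 = ", format(x$f1, digits = 4),
      ", MAE = ", format(x$mae, digits = 4), " years (",
      nrow(x$predictions), " held-out samples)\n", sep = "")
  invisible(x)
}

# Paired Wilcoxon signed-rank on per-sample differences; zero differences
# dropped (signed-rank convention), exact null for small samples without
# ties, normal approximation with continuity correction otherwise.
paired_wilcoxon_p <- function(a, b, exact_max = 25) {
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0) return(1)
  exact_ok <- length(d) <= exact_max && !any(duplicated(abs(d)))
  suppressWarnings(wilcox.test(d, exact = exact_ok, correct = TRUE)$p.value)
}

#' Paired comparisons between cross-validated biomarkers
#'
#' Pairwise comparisons of [loocv_evaluate()] reports built on identical
#' holdout sets. Regression differences (per-carrier absolute errors) are
#' tested with the paired Wilcoxon signed-rank test; classification (F1)
#' differences with an empirical two-sided p-value from a paired bootstrap
#' over samples, `p = 2 * min(P(diff <= 0), P(diff >= 0))` capped at 1.
#' All p-values from the run form one family for Benjamini-Hochberg
#' adjustment at the given false discovery rate.
#'
#' @param reports A named list of `wcvr_loocv` objects.
#' @param n_boot Paired-bootstrap replicates for the F1 test.
#' @param fdr Significance threshold on the BH-adjusted p-values.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble with one row per (pair, test): the difference estimate
#'   (first minus second), raw and BH-adjusted p-values, and a significance
#'   flag.
#' @export
paired_comparisons <- function(reports, n_boot = 2000, fdr = 0.05, seed = 1L) {
  if (length(reports) < 2) abort("Need at least two LOOCV reports to compare.")
  ids <- lapply(reports, function(r) r$predictions$sample_id)
  if (length(unique(lapply(ids, sort))) != 1) {
    abort("LOOCV reports were built on different holdout sets; comparisons must be paired.")
  }
  nms <- names(reports)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- reports[[pr[1]]]$predictions
    b <- reports[[pr[2]]]$predictions[match(a$sample_id, reports[[pr[2]]]$predictions$sample_id), ]
    p_mae <- paired_wilcoxon_p(a$abs_error, b$abs_error)
    is_case <- a$group == "case"
    f1_diff_obs <- f1_score(a$predicted_class == "case", is_case) -
      f1_score(b$predicted_class == "case", is_case)
    diffs <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(k) {
        ix <- sample.int(nrow(a), nrow(a), replace = TRUE)
        f1_score(a$predicted_class[ix] == "case", is_case[ix]) -
          f1_score(b$predicted_class[ix] == "case", is_case[ix])
      }, numeric(1))
    })
    p_f1 <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
    tibble::tibble(
      biomarker_1 = pr[1], biomarker_2 = pr[2],
      test = c("mae_wilcoxon", "f1_bootstrap"),
      estimate = c(mean(a$abs_error, na.rm = TRUE) - mean(b$abs_error, na.rm = TRUE),
                   f1_diff_obs),
      p.value = c(p_mae, p_f1)
    )
  })
  rows$p.adjusted <- p.adjust(rows$p.value, method = "BH")
  rows$significant <- rows$p.adjusted < fdr
  rows
}
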