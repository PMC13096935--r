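#' Per-peptide correlations with age at onset
#'
#' For every peptide, the Pearson correlation (with Fisher-z 95% CI) and
#' Kendall tau-b (two-sided p) between the peptide's relative abundance and
#' age at onset over mutation carriers. Per-cohort rows use each cohort's
#' total-normalized (pre-harmonization) relative values; the pooled `"all"`
#' row uses the harmonized (post-transformation) values, so abundances are
#' always relative to the five-peptide sum.
#'
#' @param panel A raw wide peptide panel (replicates allowed; zeros are
#'   filtered and replicates averaged internally).
#' @param min_carriers Cohort rows with fewer carriers are skipped.
#' @return A tibble: `cohort` (cohort ID or `"all"`), `peptide`, `pearson_r`,
#'   `pearson_p`, `conf.low`, `conf.high`, `kendall_tau`, `kendall_p`, `n`.
#' @export
peptide_aao_correlations <- function(panel, min_carriers = 3) {
  validate_panel(panel)
  base <- average_replicates(filter_zero_samples(panel, quiet = TRUE))
  relative <- normalize_to_total(base)
  harmonized <- scale_by_control_means(relative)
  one_scope <- function(dat, label) {
    carriers <- dat[!is.na(dat$aao_years), , drop = FALSE]
    if (nrow(carriers) < min_carriers) return(NULL)
    purrr::map_dfr(ab_peptides(), function(pep) {
      x <- carriers[[pep]]; y <- carriers$aao_years
      pe <- suppressWarnings(cor.test(x, y, method = "pearson"))
      ke <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
      tibble::tibble(
        cohort = label, peptide = pep,
        pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
        conf.low = if (!is.null(pe$conf.int)) pe$conf.int[1] else NA_real_,
        conf.high = if (!is.null(pe$conf.int)) pe$conf.int[2] else NA_real_,
        kendall_tau = unname(ke$estimate), kendall_p = ke$p.value,
        n = length(x))
    })
  }
  per_cohort <- purrr::map_dfr(unique(relative$cohort),
                               function(co) one_scope(relative[relative$cohort == co, ], co))
  dplyr::bind_rows(per_cohort, one_scope(harmonized, "all"))
}

#' Fraction of case samples deviating from the control mean
#'
#' On the harmonized scale the control mean of every peptide is 1; this
#' summarizes, per peptide, the fraction of case samples strictly below and
#' strictly above the per-peptide control mean. Values exactly at the mean
#' count in neither strict fraction (reported as `frac_at`). In familial
#' Alzheimer's disease panels the shorter peptides (Ab37/38/40) fall mostly
#' below and the longer (Ab42/43) mostly above.
#'
#' @param panel A harmonized panel (not reference-rescaled; control means
#'   are recomputed from the panel's own controls, pooled across cohorts).
#' @return A tibble: `peptide`, `n_cases`, `frac_below`, `frac_above`,
#'   `frac_at`.
#' @export
deviation_proportions <- function(panel) {
  validate_panel(panel)
  if (sum(panel$group == "case") == 0) abort("No case samples in panel.")
  ctrl_mean <- colMeans(peptide_matrix(panel[panel$group == "control", , drop = FALSE]))
  cases <- peptide_matrix(panel[panel$group == "case", , drop = FALSE])
  purrr::map_dfr(seq_along(ab_peptides()), function(j) {
    v <- cases[, j]
    tibble::tibble(
      peptide = ab_peptides()[j], n_cases = length(v),
      frac_below = mean(v < ctrl_mean[j]),
      frac_above = mean(v > ctrl_mean[j]),
      frac_at = mean(v == ctrl_mean[j]))
  })
}

#' Association of mutation position with onset and Ab42/40
#'
#' Tests whether the codon position of the mutation is associated with age
#' at onset or with the Ab42/40 biomarker across mutation carriers, using
#' Kendall's tau-b (normal approximation, reporting z) and the Pearson
#' correlation (t test with degrees of freedom). Rows without a codon are
#' excluded.
#'
#' @param panel A harmonized panel with `codon` annotations on carriers.
#' @return A tibble with one row per outcome (`aao_years`, `Ab42/40`):
#'   `kendall_tau`, `kendall_z`, `kendall_p`, `pearson_r`, `pearson_t`,
#'   `df`, `pearson_p`, `n`.
#' @export
mutation_position_association <- function(panel) {
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  carriers <- panel[panel$group == "case" & !is.na(panel$codon), , drop = FALSE]
  n_dropped <- sum(panel$group == "case") - nrow(carriers)
  if (n_dropped > 0) inform(paste0(n_dropped, " carrier(s) without codon excluded."))
  if (nrow(carriers) < 3) abort("Need at least 3 carriers with codon positions.")
  if (length(unique(carriers$codon)) < 2) {
    abort("Codon position is constant across carriers; association is undefined.")
  }
  ab4240 <- score_matrix(peptide_matrix(carriers), ratio_spec("Ab42", "Ab40"))
  outcomes <- list("aao_years" = carriers$aao_years, "Ab42/40" = ab4240)
  purrr::imap_dfr(outcomes, function(y, nm) {
    keep <- !is.na(y)
    x <- carriers$codon[keep]; yy <- y[keep]
    ke <- suppressWarnings(cor.test(x, yy, method = "kendall", exact = FALSE))
    pe <- suppressWarnings(cor.test(x, yy, method = "pearson"))
    tibble::tibble(
      outcome = nm,
      kendall_tau = unname(ke$estimate), kendall_z = unname(ke$statistic),
      kendall_p = ke$p.value,
      pearson_r = unname(pe$estimate), pearson_t = unname(pe$statistic),
      df = unname(pe$parameter), pearson_p = pe$p.value, n = sum(keep))
  })
}

#' Bootstrap distribution of searched peptide weights
#'
#' Resamples the panel (stratified by group), reruns the weight search with
#' several random restarts on each replicate, and records the best spec's
#' signed normalized weights. The spread of weights across replicates shows
#' how stable each peptide's contribution and side assignment are.
#'
#' @param panel A harmonized, reference-rescaled panel.
#' @param config A [search_config()]; `n_restarts` is overridden by
#'   `restarts`.
#' @param n_boot Bootstrap replicates (default 200).
#' @param restarts Search restarts per replicate (default 3).
#' @param seed Integer seed.
#' @return A `wcvr_weight_distribution` object: `weights` (tibble of
#'   replicate, peptide, signed `weight_pct`), `summary` (per-peptide
#'   quartiles and sign consistency), and the objective.
#' @export
bootstrap_weight_distribution <- function(panel, config = search_config(),
                                          n_boot = 200, restarts = 3, seed = 1L) {
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  idx_by_group <- split(seq_len(nrow(panel)), panel$group)
  rows <- purrr::map_dfr(seq_len(n_boot), function(b) {
    ix <- withr::with_seed(seed + b, {
      unlist(lapply(idx_by_group,
                    function(i) i[sample.int(length(i), length(i), replace = TRUE)]),
             use.names = FALSE)
    })
    cfg <- config
    cfg$n_restarts <- as.integer(restarts)
    cfg$seed <- as.integer(seed + 7919L * b)
    res <- tryCatch(ga_search(panel[ix, , drop = FALSE], cfg), error = function(e) NULL)
    if (is.null(res)) {
      warn(paste0("Search failed on bootstrap replicate ", b, "; replicate skipped."))
      return(NULL)
    }
    w <- spec_signed_weights(res$best_spec)
    tibble::tibble(replicate = b, peptide = names(w), weight_pct = unname(w),
                   objective_value = res$best_objective)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(rows, .data$peptide),
    q25 = quantile(.data$weight_pct, 0.25), median = median(.data$weight_pct),
    q75 = quantile(.data$weight_pct, 0.75),
    frac_numerator = mean(.data$weight_pct > 0),
    frac_denominator = mean(.data$weight_pct < 0),
    .groups = "drop")
  structure(list(weights = rows, summary = summary, objective = config$objective,
                 n_boot = n_boot, restarts = restarts),
            class = "wcvr_weight_distribution")
}

#' @export
print.wcvr_weight_distribution <- function(x, ...) {
  cat("<wcvr_weight_distribution> objective ", x$objective, ", ",
      length(unique(x$weights$replicate)), " replicate(s) x ", x$restarts,
      " restart(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Grid search of weights around a baseline ratio
#'
#' Fixes a baseline two-peptide ratio at unit weights (Ab42/40 for the
#' regression objective, Ab37/42 for the control-class PR objective) and
#' sweeps the weights of the remaining peptides from 0 to 1 in steps of
#' `step`, on either side of the ratio (a peptide sits in the numerator or
#' the denominator at any grid point, never both). `mode = "marginal"`
#' varies one peptide at a time (others at 0); `mode = "joint"` evaluates
#' the full cartesian grid of the free peptides.
#'
#' @param panel A harmonized, reference-rescaled panel.
#' @param objective `"R"` or `"P"` (chooses the default baseline).
#' @param baseline A [ratio_spec()] overriding the default baseline.
#' @param step Grid step in weight units (default 0.02; 51 points per side).
#' @param mode `"marginal"` or `"joint"`.
#' @param chunk Grid points evaluated per block in joint mode.
#' @return A tibble with one signed-weight column per free peptide
#'   (positive = numerator) and a `value` column with the objective; the
#'   all-zero row reproduces the baseline ratio's metric exactly.
#' @export
grid_search_weights <- function(panel, objective = c("R", "P"), baseline = NULL,
                                step = 0.02, mode = c("marginal", "joint"),
                                chunk = 20000) {
  objective <- rlang::arg_match(objective)
  mode <- rlang::arg_match(mode)
  if (step <= 0) abort("`step` must be positive.")
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  if (is.null(baseline)) {
    baseline <- if (objective == "R") ratio_spec("Ab42", "Ab40", name = "Ab42/40")
                else ratio_spec("Ab37", "Ab42", name = "Ab37/42")
  }
  fixed <- spec_signed_weights(baseline)
  free <- names(fixed)[fixed == 0]
  grid_1d <- sort(unique(c(-seq(0, 1, by = step), seq(0, 1, by = step))))
  X <- peptide_matrix(panel)
  group <- panel$group
  aao <- panel$aao_years
  if (mode == "marginal") {
    rows <- purrr::map_dfr(free, function(pep) {
      W <- matrix(fixed, length(fixed), length(grid_1d),
                  dimnames = list(names(fixed), NULL))
      W[pep, ] <- grid_1d
      vals <- genome_fitness_matrix(W, X, group, aao, objective)
      out <- tibble::as_tibble(setNames(as.data.frame(t(W[free, , drop = FALSE])), free))
      out$value <- vals
      out
    })
  } else {
    combos <- expand.grid(rep(list(grid_1d), length(free)))
    names(combos) <- free
    combos <- as.matrix(combos)
    vals <- numeric(nrow(combos))
    for (start in seq(1, nrow(combos), by = chunk)) {
      ix <- start:min(start + chunk - 1, nrow(combos))
      W <- matrix(fixed, length(fixed), length(ix), dimnames = list(names(fixed), NULL))
      W[free, ] <- t(combos[ix, , drop = FALSE])
      vals[ix] <- genome_fitness_matrix(W, X, group, aao, objective)
    }
    rows <- tibble::as_tibble(as.data.frame(combos))
    rows$value <- vals
  }
  rows <- dplyr::distinct(rows)
  attr(rows, "baseline") <- baseline
  attr(rows, "objective") <- objective
  rows
}

#' Permutation feature importance of peptides
#'
#' Measures how much each peptide contributes to a biomarker's performance:
#' the peptide's values are permuted across samples `n_perm` times, scores
#' and metrics recomputed, and importance reported as the baseline metric
#' minus the mean permuted metric. Peptides with zero weight in the spec
#' have importance exactly 0. The abnormal direction is resolved on the
#' unpermuted scores and held fixed.
#'
#' @param panel A harmonized, reference-rescaled panel.
#' @param spec A [ratio_spec()].
#' @param metrics Metrics to report (subset of `"roc_auc"`,
#'   `"pr_auc_controls"`, `"r_squared"`).
#' @param n_perm Permutations per peptide (default 100).
#' @param seed Integer seed.
#' @return A tibble: `peptide`, `metric`, `baseline`, `importance`.
#' @export
permutation_importance <- function(panel, spec,
                                   metrics = c("roc_auc", "pr_auc_controls", "r_squared"),
                                   n_perm = 100, seed = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  X <- peptide_matrix(panel)
  group <- panel$group
  aao <- panel$aao_years
  base_scores <- score_matrix(X, spec)
  orientation <- resolve_orientation(base_scores, group)
  metric_fns <- list(
    roc_auc = function(s) roc_auc(s, group, orientation),
    pr_auc_controls = function(s) pr_auc_controls(s, group, orientation),
    r_squared = function(s) suppressWarnings(pearson_r2_vs_aao(s, aao))
  )[metrics]
  baseline <- purrr::map_dbl(metric_fns, function(f) f(base_scores))
  active <- names(which(spec_signed_weights(spec) != 0))
  withr::with_seed(seed, {
    purrr::map_dfr(ab_peptides(), function(pep) {
      if (!pep %in% active) {
        return(tibble::tibble(peptide = pep, metric = metrics,
                              baseline = unname(baseline), importance = 0))
      }
      perm_vals <- vapply(seq_len(n_perm), function(k) {
        Xp <- X
        Xp[, pep] <- X[sample.int(nrow(X)), pep]
        s <- score_matrix(Xp, spec)
        purrr::map_dbl(metric_fns, function(f) f(s))
      }, numeric(length(metrics)))
      perm_vals <- matrix(perm_vals, nrow = length(metrics))
      tibble::tibble(peptide = pep, metric = metrics, baseline = unname(baseline),
                     importance = unname(baseline) - rowMeans(perm_vals))
    })
  })
}
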