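# Independent oracles and hand-built fixtures used across the suite.

# ROC AUC as the fraction of (case, control) pairs the case wins, ties 1/2.
# Assumes scores are already oriented higher-is-abnormal.
oracle_roc_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  wins <- 0
  for (a in cs) for (b in ct) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(cs) * length(ct))
}

# PR AUC for the control class by exhaustive threshold sweep over the
# distinct score values, using the TN/FN/FP confusion-count definitions of
# control precision and recall, with step-wise summation.
oracle_pr_auc_controls <- function(scores, labels) {
  # oriented higher-is-abnormal: call control when score <= threshold
  thresholds <- sort(unique(scores))
  prev_recall <- 0
  auc <- 0
  n_controls <- sum(labels == "control")
  for (t in thresholds) {
    called_control <- scores <= t
    tn <- sum(called_control & labels == "control")
    fn <- sum(called_control & labels == "case")
    fp <- sum(!called_control & labels == "control")
    precision <- if (tn + fn > 0) tn / (tn + fn) else 1
    recall <- tn / n_controls  # TN/(TN+FP): every control is either TN or FP
    auc <- auc + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  auc
}

# Kendall tau-b from explicit concordant/discordant pair counts with tie
# correction.
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Brute-force enumeration of ordered pairs of disjoint non-empty subsets,
# via bitmasks (independent of the package's ternary construction).
oracle_n_partition_ratios <- function(n) {
  count <- 0
  for (num in 1:(2^n - 1)) for (den in 1:(2^n - 1)) {
    if (bitwAnd(num, den) == 0) count <- count + 1
  }
  count
}

# A panel whose Ab42/40 ratio equals `score` per sample; other peptides 1.
panel_with_scores <- function(score, group, aao = NULL, cohort = "c1") {
  n <- length(score)
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)), cohort = cohort, replicate = "r1",
    group = group, mutation = NA_character_, codon = NA_real_,
    aao_years = if (is.null(aao)) rep(NA_real_, n) else aao,
    Ab37 = 1, Ab38 = 1, Ab40 = 1, Ab42 = score, Ab43 = 1
  )
}

# A small strictly positive random panel with both groups.
random_panel <- function(n_control = 3, n_case = 7, seed = 1, cohort = "c1") {
  withr::with_seed(seed, {
    n <- n_control + n_case
    tibble::tibble(
      sample_id = sprintf("%s_s%02d", cohort, seq_len(n)), cohort = cohort,
      replicate = "r1",
      group = rep(c("control", "case"), c(n_control, n_case)),
      mutation = NA_character_, codon = NA_real_,
      aao_years = c(rep(NA_real_, n_control), runif(n_case, 30, 60)),
      Ab37 = runif(n, 0.5, 2), Ab38 = runif(n, 0.5, 2), Ab40 = runif(n, 2, 8),
      Ab42 = runif(n, 0.1, 1), Ab43 = runif(n, 0.05, 0.5)
    )
  })
}

# Generator config for the fully noise-free limit (unit bias, no
# biological or measurement variation).
noise_free_config <- function(..., n_cohorts = 1, line_cv = 0) {
  sim_config(..., n_cohorts = n_cohorts,
             assay_bias = matrix(1, n_cohorts, 5),
             noise_cv = 0, line_cv = line_cv, loading_cv = 0, zero_rate = 0,
             aao_noise_sd = 0)
}
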