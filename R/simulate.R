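#' Configure the synthetic multi-cohort peptide study
#'
#' Builds a validated configuration for [simulate_cohorts()]. The defaults
#' describe a multi-assay familial Alzheimer's disease cell-model study:
#' four cohorts with very few controls (3/1/3/1) and many mutation-carrier
#' lines (10/26/131/161) measured in triplicate; an Ab40-dominant control
#' abundance profile; per-cohort multiplicative assay biases; a
#' case-specific multiplicative effect that depletes the shorter peptides
#' (Ab37/38/40) and raises the longer ones (Ab42/43); and an age at onset
#' that is linear (plus Gaussian noise) in a planted short/long-type ratio.
#'
#' @param n_cohorts Number of cohorts (assays).
#' @param n_controls,n_cases Per-cohort sample counts; scalars are recycled.
#' @param n_replicates Technical replicates per sample (scalar).
#' @param control_abundance_profile Named 5-vector of positive fractions
#'   summing to 1: expected relative abundance of each peptide in controls.
#' @param assay_bias Per-cohort multiplicative bias on each peptide: a
#'   `n_cohorts x 5` matrix, or `NULL` to draw lognormal biases (sdlog
#'   `bias_sdlog`) from the config seed.
#' @param bias_sdlog Spread of auto-generated assay biases on the log scale.
#' @param effect_profile Named 5-vector of positive multipliers applied to
#'   case samples (values < 1 deplete, > 1 enrich) at severity 1.
#' @param severity_range Per-case severity exponent is drawn uniformly from
#'   this interval; the case effect is `effect_profile ^ severity`.
#' @param planted_spec [ratio_spec()] whose value on the noise-free,
#'   bias-free case peptide vector determines age at onset.
#' @param aao_intercept,aao_slope Linear map from planted ratio to age at
#'   onset, in years.
#' @param aao_noise_sd Gaussian noise on age at onset, in years.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise per individual measurement.
#' @param line_cv Coefficient of variation of per-line biological
#'   variability: a lognormal factor per (line, peptide), shared across that
#'   line's replicates. Applies to control and case lines alike and is what
#'   makes control compositions heterogeneous within a cohort.
#' @param loading_cv Coefficient of variation of the per-replicate total
#'   loading factor (a common scalar across the five peptides), removed by
#'   total-abundance normalization downstream.
#' @param zero_rate Probability that a single measurement is recorded as 0
#'   (detection failure); exercises the zero-removal filter.
#' @param seed Integer seed; the same config yields an identical panel.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 4,
                       n_controls = c(3, 1, 3, 1),
                       n_cases = c(10, 26, 131, 161),
                       n_replicates = 3,
                       control_abundance_profile = c(
                         Ab37 = 0.16, Ab38 = 0.16, Ab40 = 0.60,
                         Ab42 = 0.07, Ab43 = 0.01),
                       assay_bias = NULL,
                       bias_sdlog = 0.4,
                       effect_profile = c(
                         Ab37 = 0.55, Ab38 = 0.70, Ab40 = 0.85,
                         Ab42 = 2.00, Ab43 = 2.60),
                       severity_range = c(0.4, 1.6),
                       planted_spec = benchmark_specs()[["short/long"]],
                       aao_intercept = 12,
                       aao_slope = 6,
                       aao_noise_sd = 3,
                       noise_cv = 0.1,
                       line_cv = 0.25,
                       loading_cv = 0.2,
                       zero_rate = 0.0125,
                       seed = 1L) {
  stopifnot(length(n_cohorts) == 1, length(n_replicates) == 1, length(seed) == 1)
  n_cohorts <- as.integer(n_cohorts)
  if (is.na(n_cohorts) || n_cohorts < 1) abort("`n_cohorts` must be a positive integer.")
  n_controls <- as.integer(rep_len(n_controls, n_cohorts))
  n_cases <- as.integer(rep_len(n_cases, n_cohorts))
  if (any(n_controls < 1) || any(n_cases < 1) || n_replicates < 1) {
    abort("Sample and replicate counts must be positive integers.")
  }
  p <- control_abundance_profile[ab_peptides()]
  if (anyNA(p) || any(p <= 0)) {
    abort("`control_abundance_profile` needs a strictly positive entry per peptide.")
  }
  if (abs(sum(p) - 1) > 1e-12) abort("`control_abundance_profile` must sum to 1 (within 1e-12).")
  e <- effect_profile[ab_peptides()]
  if (anyNA(e) || any(e <= 0)) abort("`effect_profile` needs a strictly positive entry per peptide.")
  if (!is.null(assay_bias)) {
    assay_bias <- as.matrix(assay_bias)
    if (!all(dim(assay_bias) == c(n_cohorts, 5)) || any(assay_bias <= 0)) {
      abort("`assay_bias` must be a positive n_cohorts x 5 matrix.")
    }
    colnames(assay_bias) <- ab_peptides()
  }
  if (noise_cv < 0 || line_cv < 0 || loading_cv < 0 || aao_noise_sd < 0 || bias_sdlog < 0) {
    abort("Noise parameters must be non-negative.")
  }
  if (zero_rate < 0 || zero_rate >= 1) abort("`zero_rate` must lie in [0, 1).")
  if (length(severity_range) != 2 || severity_range[1] > severity_range[2] ||
      severity_range[1] < 0) {
    abort("`severity_range` must be an ordered non-negative interval.")
  }
  stopifnot(inherits(planted_spec, "ratio_spec"))
  structure(list(
    n_cohorts = n_cohorts, n_controls = n_controls, n_cases = n_cases,
    n_replicates = as.integer(n_replicates),
    control_abundance_profile = p, assay_bias = assay_bias,
    bias_sdlog = bias_sdlog, effect_profile = e,
    severity_range = severity_range, planted_spec = planted_spec,
    aao_intercept = aao_intercept, aao_slope = aao_slope,
    aao_noise_sd = aao_noise_sd, noise_cv = noise_cv, line_cv = line_cv,
    loading_cv = loading_cv,
    zero_rate = zero_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a multi-cohort peptide panel
#'
#' Draws a synthetic case-control peptide panel with the structure the
#' downstream analysis assumes. Control measurements are the control
#' abundance profile times the cohort's assay bias, a per-replicate loading
#' scalar, and multiplicative lognormal noise. Case lines additionally carry
#' `effect_profile ^ severity` with a per-line severity drawn uniformly from
#' `severity_range`. Each case's age at onset is
#' `aao_intercept + aao_slope * v + N(0, aao_noise_sd)` where `v` is the
#' planted spec's ratio on the line's noise-free, bias-free peptide vector
#' (`profile * effect^severity`), so that the planted ratio recovered from
#' harmonized data is exactly linear in age at onset in the noise-free
#' limit. Individual measurements are zeroed with probability `zero_rate`.
#' Each case line gets a mutation label and a codon position drawn
#' independently of everything else (a null mutation-position association).
#'
#' @param config A [sim_config()].
#' @return A wide peptide panel tibble: one row per replicate measurement
#'   with columns `sample_id`, `cohort`, `replicate`, `group`, `mutation`,
#'   `codon`, `aao_years` and the five peptide columns. The per-line
#'   severity and planted ratio are attached as the `truth` attribute.
#' @export
#' @examples
#' panel <- simulate_cohorts(sim_config(n_cohorts = 1, n_controls = 3,
#'                                      n_cases = 10, seed = 7))
#' dplyr::count(panel, group)
simulate_cohorts <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  withr::with_seed(config$seed, simulate_cohorts_impl(config))
}

simulate_cohorts_impl <- function(cfg) {
  p <- cfg$control_abundance_profile
  bias <- cfg$assay_bias
  if (is.null(bias)) {
    bias <- matrix(rlnorm(cfg$n_cohorts * 5, 0, cfg$bias_sdlog), cfg$n_cohorts, 5,
                   dimnames = list(NULL, ab_peptides()))
  }
  rows <- vector("list", cfg$n_cohorts)
  truth <- vector("list", cfg$n_cohorts)
  for (co in seq_len(cfg$n_cohorts)) {
    cohort_id <- paste0("cohort", co)
    n_ctrl <- cfg$n_controls[co]
    n_case <- cfg$n_cases[co]
    ids <- c(sprintf("%s_ctrl%02d", cohort_id, seq_len(n_ctrl)),
             sprintf("%s_case%03d", cohort_id, seq_len(n_case)))
    grp <- rep(c("control", "case"), c(n_ctrl, n_case))
    severity <- ifelse(grp == "case",
                       runif(n_ctrl + n_case, cfg$severity_range[1], cfg$severity_range[2]),
                       NA_real_)
    # per-line true (measurement-noise-free, bias-free) peptide vector:
    # control profile, case effect at the line's severity, and the line's
    # biological composition factor; the planted ratio and hence AAO are
    # functions of this true biology
    eff <- t(vapply(seq_along(ids), function(i) {
      if (grp[i] == "case") p * cfg$effect_profile^severity[i] else p
    }, numeric(5)))
    bio <- matrix(rlnorm_cv(length(ids) * 5, cfg$line_cv), length(ids), 5)
    true_vec <- eff * bio
    colnames(true_vec) <- ab_peptides()
    planted_value <- score_matrix(true_vec, cfg$planted_spec)
    aao <- ifelse(grp == "case",
                  cfg$aao_intercept + cfg$aao_slope * planted_value +
                    rnorm(length(ids), 0, cfg$aao_noise_sd),
                  NA_real_)
    mutation <- ifelse(grp == "case",
                       sprintf("%s_M%03d", cohort_id, cumsum(grp == "case")),
                       NA_character_)
    codon <- ifelse(grp == "case", sample(50:450, length(ids), replace = TRUE), NA_real_)
    line <- tibble::tibble(
      sample_id = ids, cohort = cohort_id, group = grp,
      mutation = mutation, codon = codon, aao_years = aao
    )
    rep_rows <- line[rep(seq_len(nrow(line)), each = cfg$n_replicates), ]
    rep_rows$replicate <- rep(sprintf("r%d", seq_len(cfg$n_replicates)), nrow(line))
    base <- true_vec[rep(seq_len(nrow(line)), each = cfg$n_replicates), , drop = FALSE]
    base <- sweep(base, 2, bias[co, ], `*`)
    loading <- rlnorm_cv(nrow(base), cfg$loading_cv)
    noise <- matrix(rlnorm_cv(length(base), cfg$noise_cv), nrow(base), 5)
    vals <- base * loading * noise
    if (cfg$zero_rate > 0) {
      vals[matrix(runif(length(vals)) < cfg$zero_rate, nrow(vals), 5)] <- 0
    }
    colnames(vals) <- ab_peptides()
    rows[[co]] <- dplyr::bind_cols(rep_rows, tibble::as_tibble(vals))
    truth[[co]] <- dplyr::mutate(line[c("sample_id", "cohort", "group")],
                                 severity = severity, planted_value = planted_value)
  }
  out <- complete_panel_cols(dplyr::bind_rows(rows))
  attr(out, "truth") <- dplyr::bind_rows(truth)
  attr(out, "assay_bias") <- bias
  validate_panel(out)
  out
}
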