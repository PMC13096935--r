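#' Remove samples with any zero peptide measurement
#'
#' Measurements of exactly zero (assay detection failures) make a peptide
#' unusable as a ratio denominator, so any row carrying at least one zero is
#' dropped before harmonization. The number of removed rows is attached as
#' the `n_zero_removed` attribute and reported per cohort.
#'
#' @param panel A wide peptide panel tibble.
#' @param quiet Suppress the per-cohort removal message.
#' @return The filtered panel; `attr(., "n_zero_removed")` holds the count.
#' @export
filter_zero_samples <- function(panel, quiet = FALSE) {
  validate_panel(panel)
  has_zero <- rowSums(peptide_matrix(panel) == 0) > 0
  out <- panel[!has_zero, , drop = FALSE]
  if (!quiet && any(has_zero)) {
    per_cohort <- table(panel$cohort[has_zero])
    inform(paste0("Removed ", sum(has_zero), " of ", nrow(panel),
                  " rows with zero measurements (",
                  paste(names(per_cohort), per_cohort, sep = ": ", collapse = "; "), ")."))
  }
  if (nrow(out) == 0) warn("All rows carried zero measurements; the filtered panel is empty.")
  attr(out, "n_zero_removed") <- sum(has_zero)
  out
}

#' Average technical replicates within each line
#'
#' Collapses the panel to one row per (cohort, sample) by taking the
#' arithmetic mean of each peptide over the sample's replicates, before any
#' ratio is formed. Group, mutation, codon and age-at-onset annotations must
#' be constant within a sample and are carried through.
#'
#' @param panel A wide peptide panel tibble (zero-filtered).
#' @return A panel with one row per (cohort, sample_id).
#' @export
average_replicates <- function(panel) {
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  ann <- dplyr::summarise(
    dplyr::group_by(panel, .data$cohort, .data$sample_id),
    dplyr::across(dplyr::all_of(c("group", "mutation", "codon", "aao_years")),
                  dplyr::n_distinct),
    .groups = "drop")
  bad <- dplyr::filter(ann, dplyr::if_any(dplyr::all_of(c("group", "mutation", "codon", "aao_years")), ~ .x > 1))
  if (nrow(bad) > 0) {
    abort(paste0("Conflicting annotations within sample(s): ",
                 paste(head(bad$sample_id, 5), collapse = ", ")))
  }
  out <- dplyr::summarise(
    dplyr::group_by(panel, .data$cohort, .data$sample_id),
    dplyr::across(dplyr::all_of(c("group", "mutation")), dplyr::first),
    dplyr::across(dplyr::all_of(c("codon", "aao_years")), ~ .x[1]),
    dplyr::across(dplyr::all_of(ab_peptides()), mean),
    .groups = "drop")
  out$replicate <- "mean"
  complete_panel_cols(out)
}

#' Normalize each sample to its total peptide abundance
#'
#' Divides every measurement by the sample's five-peptide sum, converting to
#' relative (compositional) abundances and removing per-sample loading
#' differences. Row sums of the result equal 1.
#'
#' @param panel A wide peptide panel tibble with strictly positive values.
#' @return The panel with each row's peptide values summing to 1.
#' @export
normalize_to_total <- function(panel) {
  validate_panel(panel)
  m <- peptide_matrix(panel)
  tot <- rowSums(m)
  if (any(tot <= 0)) abort("A sample has non-positive total abundance; run filter_zero_samples() first.")
  panel[ab_peptides()] <- m / tot
  panel
}

#' Scale each peptide by its per-cohort control mean
#'
#' Within each cohort, divides every peptide column by the arithmetic mean
#' of that peptide over the cohort's control rows. This corrects
#' assay-specific systematic biases and places all cohorts on a common
#' dimensionless scale in which the control mean of every peptide is exactly
#' 1. The per-cohort control means are attached as the `control_means`
#' attribute.
#'
#' @param panel A total-normalized wide panel; every cohort must contain at
#'   least one control row.
#' @return The harmonized panel (control-relative values).
#' @export
scale_by_control_means <- function(panel) {
  validate_panel(panel)
  no_ctrl <- setdiff(unique(panel$cohort), unique(panel$cohort[panel$group == "control"]))
  if (length(no_ctrl) > 0) {
    abort(paste0("Cohort(s) without control samples: ", paste(no_ctrl, collapse = ", "),
                 ". Control-mean scaling is undefined."))
  }
  zero_removed <- attr(panel, "n_zero_removed")
  scaled <- dplyr::mutate(
    dplyr::group_by(panel, .data$cohort),
    dplyr::across(dplyr::all_of(ab_peptides()), ~ .x / mean(.x[group == "control"])))
  cm <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(panel, .data$group == "control"), .data$cohort),
    dplyr::across(dplyr::all_of(ab_peptides()), mean), .groups = "drop")
  out <- dplyr::ungroup(scaled)
  attr(out, "control_means") <- cm
  attr(out, "n_zero_removed") <- zero_removed
  out
}

#' Reference control proportions for additive biomarkers
#'
#' Returns the relative control abundance of each peptide, used to scale
#' harmonized (control-relative) values back to a natural abundance scale
#' before peptides are added in composite biomarkers. By default the
#' proportions are estimated from the panel's own control rows
#' (total-normalized, then averaged); alternatively pass a single reference
#' cohort to mirror designating one assay as the reference, or supply a
#' named vector of proportions directly via [as_reference_proportions()].
#'
#' @param panel A wide peptide panel containing control rows.
#' @param cohort Optional cohort ID to use as the reference; default pools
#'   all control rows.
#' @return A `reference_proportions` object: a named 5-vector of positive
#'   fractions summing to 1, with a `source` attribute.
#' @export
reference_proportions <- function(panel, cohort = NULL) {
  validate_panel(panel)
  if (!is.null(cohort)) {
    if (!cohort %in% panel$cohort) abort(paste0("Cohort '", cohort, "' not present in panel."))
    panel <- panel[panel$cohort == cohort, , drop = FALSE]
    src <- paste0("controls of cohort ", cohort)
  } else {
    src <- "pooled panel controls"
  }
  ctrl <- panel[panel$group == "control", , drop = FALSE]
  if (nrow(ctrl) == 0) abort("No control rows available to estimate reference proportions.")
  m <- peptide_matrix(ctrl)
  if (any(m <= 0)) abort("Control rows contain zeros; run filter_zero_samples() first.")
  p <- colMeans(m / rowSums(m))
  as_reference_proportions(p / sum(p), source = src)
}

#' @rdname reference_proportions
#' @param x Named numeric vector of positive proportions (one per peptide).
#' @param source Label describing where the proportions came from.
#' @export
as_reference_proportions <- function(x, source = "user-supplied") {
  x <- x[ab_peptides()]
  if (anyNA(x) || any(x <= 0)) {
    abort("Reference proportions need a strictly positive entry for each of the five peptides.")
  }
  if (abs(sum(x) - 1) > 1e-12) abort("Reference proportions must sum to 1 (within 1e-12).")
  structure(x, source = source, class = c("reference_proportions", "numeric"))
}

#' Rescale harmonized values to reference control proportions
#'
#' Multiplies each peptide's harmonized (control-relative) values by its
#' reference control proportion. Required before evaluating biomarkers that
#' add peptides (short/long, enumerated combinations, weighted composite
#' ratios): peptide abundances differ by orders of magnitude, and additive
#' biomarkers are designed around those natural proportions. For
#' single-peptide-per-side ratios the step only multiplies scores by a
#' constant and leaves every evaluation metric unchanged.
#'
#' @param panel A harmonized wide panel.
#' @param ref A [reference_proportions()] object (or named 5-vector).
#' @return The rescaled panel.
#' @export
rescale_to_reference <- function(panel, ref) {
  validate_panel(panel)
  if (!inherits(ref, "reference_proportions")) ref <- as_reference_proportions(ref)
  m <- sweep(peptide_matrix(panel), 2, as.numeric(ref), `*`)
  panel[ab_peptides()] <- m
  attr(panel, "reference") <- ref
  panel
}

#' Harmonize a multi-assay peptide panel
#'
#' Runs the full harmonization pipeline: zero-sample removal, replicate
#' averaging, per-sample total-abundance normalization, per-cohort
#' control-mean scaling, and (optionally) rescaling to reference control
#' proportions for additive biomarkers. After control-mean scaling, values
#' are dimensionless and control-relative: within every cohort the mean of
#' each peptide over controls is exactly 1.
#'
#' @param panel A raw wide peptide panel tibble.
#' @param ref Reference proportions for the final rescaling step; default
#'   [reference_proportions()] estimated from the panel's controls. Pass
#'   `NULL` together with `rescale = FALSE` to stop at control-relative values.
#' @param rescale Apply [rescale_to_reference()] (default `TRUE`).
#' @param average Average technical replicates first (default `TRUE`).
#' @param quiet Suppress messages.
#' @return The harmonized panel tibble, with provenance attributes
#'   (`control_means`, `n_zero_removed`, `reference`); see
#'   [harmonization_provenance()].
#' @export
#' @examples
#' panel <- simulate_cohorts(sim_config(seed = 42))
#' h <- harmonize_panel(panel)
#' harmonization_provenance(h)$n_zero_removed
harmonize_panel <- function(panel, ref = NULL, rescale = TRUE, average = TRUE,
                            quiet = FALSE) {
  out <- filter_zero_samples(panel, quiet = quiet)
  n_removed <- attr(out, "n_zero_removed")
  if (average) out <- average_replicates(out)
  if (rescale && is.null(ref)) ref <- reference_proportions(out)
  out <- normalize_to_total(out)
  out <- scale_by_control_means(out)
  if (rescale) out <- rescale_to_reference(out, ref)
  attr(out, "n_zero_removed") <- n_removed
  out
}

#' @rdname harmonize_panel
#' @export
harmonization_provenance <- function(panel) {
  list(
    control_means = attr(panel, "control_means"),
    n_zero_removed = attr(panel, "n_zero_removed"),
    reference = attr(panel, "reference")
  )
}
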