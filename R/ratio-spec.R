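#' Define a composite value ratio of peptides
#'
#' A ratio specification assigns peptides to a numerator set and a disjoint
#' denominator set, each with non-negative weights. The biomarker score of a
#' sample is the weighted sum of its numerator peptides divided by the
#' weighted sum of its denominator peptides (the weighted composite value
#' ratio, wCVR):
#' \deqn{\mathrm{wCVR} = \frac{\sum_{i \in X_1} k_i x_i}{\sum_{j \in X_2} k_j x_j}}
#' where \eqn{X_1, X_2} are non-overlapping, non-empty peptide sets and
#' \eqn{k} are the per-peptide weights.
#'
#' @param numerator,denominator Either a character vector of peptide names
#'   (unit weights) or a named numeric vector of non-negative weights.
#' @param name Optional label for the spec.
#' @return An object of class `ratio_spec` with elements `numerator`,
#'   `denominator` (named non-negative weights) and `name`.
#' @seealso [benchmark_specs()], [enumerate_ratio_specs()], [compute_ratio()]
#' @export
#' @examples
#' ratio_spec(c(Ab37 = 21, Ab38 = 10, Ab40 = 69), c(Ab42 = 94, Ab43 = 6), "wCVR-RP")
#' ratio_spec("Ab42", "Ab40")  # the classic Ab42/40 ratio
ratio_spec <- function(numerator, denominator, name = NULL) {
  num <- as_weights(numerator, "numerator")
  den <- as_weights(denominator, "denominator")
  if (length(intersect(names(num), names(den))) > 0) {
    abort("Numerator and denominator peptide sets must be disjoint.")
  }
  if (sum(num) <= 0 || sum(den) <= 0) {
    abort("Each side needs at least one strictly positive weight.")
  }
  if (is.null(name)) {
    name <- paste0(paste(names(num), collapse = "+"), "/",
                   paste(names(den), collapse = "+"))
  }
  structure(list(numerator = num, denominator = den, name = name),
            class = "ratio_spec")
}

as_weights <- function(x, side) {
  if (is.character(x)) x <- setNames(rep(1, length(x)), x)
  if (length(x) == 0) abort(paste0("The ", side, " must contain at least one peptide."))
  if (is.null(names(x)) || any(names(x) == "")) {
    abort(paste0("Weights for the ", side, " must be named by peptide."))
  }
  bad <- setdiff(names(x), ab_peptides())
  if (length(bad) > 0) {
    abort(paste0("Unknown peptide(s) in ", side, ": ", paste(bad, collapse = ", "),
                 ". Expected ", paste(ab_peptides(), collapse = ", "), "."))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(paste0("Weights for the ", side, " must be finite and non-negative."))
  }
  x <- x[x > 0]
  if (length(x) == 0) abort(paste0("The ", side, " has no strictly positive weight."))
  x[order(match(names(x), ab_peptides()))]
}

#' @export
print.ratio_spec <- function(x, ...) {
  fmt <- function(w) paste(sprintf("%.3g*%s", unname(w), names(w)), collapse = " + ")
  cat("<ratio_spec> ", x$name, "\n  (", fmt(x$numerator), ") / (", fmt(x$denominator), ")\n",
      sep = "")
  invisible(x)
}

#' Normalize a ratio spec to the percent convention
#'
#' Rescales each side's weights to sum to 100 so that specs are comparable
#' across searches. Biomarker scores from the normalized spec are a fixed
#' positive multiple of the original scores, so every rank-based or
#' correlation-based evaluation metric is unchanged.
#'
#' @param spec A [ratio_spec()].
#' @return A `ratio_spec` whose sides each sum to 100.
#' @export
#' @examples
#' normalize_spec(ratio_spec(c(Ab40 = 0.69, Ab37 = 0.21, Ab38 = 0.10),
#'                           c(Ab42 = 0.94, Ab43 = 0.06)))
normalize_spec <- function(spec) {
  stopifnot(inherits(spec, "ratio_spec"))
  spec$numerator <- 100 * spec$numerator / sum(spec$numerator)
  spec$denominator <- 100 * spec$denominator / sum(spec$denominator)
  spec
}

# Signed weight vector over the canonical peptide order: numerator weights
# positive, denominator weights negative, inactive peptides 0.
spec_signed_weights <- function(spec, peptides = ab_peptides()) {
  w <- setNames(numeric(length(peptides)), peptides)
  w[names(spec$numerator)] <- spec$numerator
  w[names(spec$denominator)] <- -spec$denominator
  w
}

# Inverse of spec_signed_weights(); returns NULL when a side is empty.
spec_from_signed_weights <- function(w, name = NULL) {
  w <- w[w != 0]
  num <- w[w > 0]
  den <- -w[w < 0]
  if (length(num) == 0 || length(den) == 0) return(NULL)
  ratio_spec(num, den, name = name)
}

# Score a numeric matrix (samples x 5 peptides, canonical column order).
score_matrix <- function(m, spec) {
  w <- spec_signed_weights(spec, colnames(m) %||% ab_peptides())
  num <- as.vector(m %*% pmax(w, 0))
  den <- as.vector(m %*% pmax(-w, 0))
  if (any(den <= 0)) abort("Denominator sum is non-positive; panel values must be strictly positive.")
  num / den
}

#' Compute biomarker scores for a panel
#'
#' Applies a ratio spec to a peptide panel, returning one score per row.
#' For additive specs (more than one peptide on a side) the panel should be
#' harmonized and rescaled to reference control proportions first (see
#' [harmonize_panel()]), so that weights act on the natural abundance scale.
#'
#' @param panel A peptide panel tibble (wide, one column per peptide).
#' @param spec A [ratio_spec()].
#' @return The panel's metadata columns plus a `score` column; the spec name
#'   is carried in the `biomarker` column.
#' @export
#' @examples
#' panel <- simulate_cohorts(sim_config(n_cohorts = 1, n_cases = 5, seed = 1))
#' compute_ratio(harmonize_panel(panel), ratio_spec("Ab42", "Ab40"))
compute_ratio <- function(panel, spec) {
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  dplyr::bind_cols(
    panel[intersect(panel_meta_cols(), names(panel))],
    tibble::tibble(biomarker = spec$name, score = score_matrix(peptide_matrix(panel), spec))
  )
}

#' Reference ratio biomarkers from the literature
#'
#' The fixed comparator ratios: `Ab42/40`, `Ab40/42`, `Ab37/42`, and the
#' `short/long` ratio Ab(37+38+40)/(42+43). `short/long` carries equal unit
#' weights: applied to reference-rescaled data this reproduces
#' natural-abundance weighting of the peptides.
#'
#' @return A named list of [ratio_spec()] objects.
#' @export
benchmark_specs <- function() {
  specs <- list(
    ratio_spec("Ab42", "Ab40", name = "Ab42/40"),
    ratio_spec("Ab40", "Ab42", name = "Ab40/42"),
    ratio_spec("Ab37", "Ab42", name = "Ab37/42"),
    ratio_spec(c("Ab37", "Ab38", "Ab40"), c("Ab42", "Ab43"), name = "short/long")
  )
  setNames(specs, purrr::map_chr(specs, "name"))
}

#' Enumerate all unweighted peptide-partition ratios
#'
#' Generates every ratio whose numerator and denominator are disjoint,
#' non-empty subsets of the peptide set (no peptide repeated), with unit
#' weights per peptide. For \eqn{n} peptides there are
#' \eqn{3^n - 2\cdot 2^n + 1} such ratios: 180 for the five amyloid-beta
#' peptides. Intended to be evaluated on reference-rescaled data so unit
#' weights correspond to natural control abundances.
#'
#' @param peptides Character vector of at least two distinct peptide names.
#' @return A named list of [ratio_spec()] objects.
#' @export
#' @examples
#' length(enumerate_ratio_specs(ab_peptides()))  # 180
enumerate_ratio_specs <- function(peptides = ab_peptides()) {
  peptides <- unique(peptides)
  n <- length(peptides)
  if (n < 2) abort("Need at least two distinct peptides to form a ratio.")
  assign_side <- expand.grid(rep(list(0:2), n))  # 0 unused, 1 numerator, 2 denominator
  specs <- list()
  for (i in seq_len(nrow(assign_side))) {
    a <- as.integer(assign_side[i, ])
    num <- peptides[a == 1]
    den <- peptides[a == 2]
    if (length(num) == 0 || length(den) == 0) next
    specs[[length(specs) + 1]] <- ratio_spec(num, den)
  }
  setNames(specs, purrr::map_chr(specs, "name"))
}

#' Tidy a ratio spec into a per-peptide weight table
#'
#' @param x A [ratio_spec()].
#' @param ... Unused.
#' @return A tibble with one row per peptide: side and signed normalized
#'   weight in percent (denominator negative, the printed convention).
#' @export
tidy.ratio_spec <- function(x, ...) {
  w <- spec_signed_weights(normalize_spec(x))
  tibble::tibble(
    biomarker = x$name,
    peptide = names(w),
    side = dplyr::case_when(w > 0 ~ "numerator", w < 0 ~ "denominator", TRUE ~ "inactive"),
    weight_pct = unname(w)
  )
}
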