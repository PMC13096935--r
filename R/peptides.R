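#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median sd cor cor.test lm predict quantile rnorm runif
#'   rlnorm rbinom p.adjust wilcox.test optim setNames coef complete.cases
#' @importFrom utils head
NULL

#' Canonical amyloid-beta peptide names
#'
#' The five C-terminal-length amyloid-beta species the package analyses, in
#' canonical order: `Ab37`, `Ab38`, `Ab40`, `Ab42`, `Ab43`. Shorter species
#' (Ab37, Ab38, Ab40) typically fall below control levels in familial
#' Alzheimer's disease models while the longer, aggregation-prone species
#' (Ab42, Ab43) rise above them.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' ab_peptides()
ab_peptides <- function() {
  c("Ab37", "Ab38", "Ab40", "Ab42", "Ab43")
}

# Map assorted spellings (Abeta42, AB42, "Ab 42", unicode beta) onto the
# canonical names; unknown names are returned NA so callers can report them.
canonical_peptide <- function(x) {
  key <- gsub("[^0-9]", "", x)
  out <- ifelse(key %in% c("37", "38", "40", "42", "43"), paste0("Ab", key), NA_character_)
  # guard against e.g. "Ab39" or strings with stray digits like "peptide1_42"
  plausible <- grepl("^(a|A)(b|B|beta|BETA|β)?[ _-]?[0-9]{2}$", x) | x %in% ab_peptides()
  out[!plausible] <- NA_character_
  out
}

panel_meta_cols <- function() {
  c("sample_id", "cohort", "replicate", "group", "mutation", "codon", "aao_years")
}

# Validate a wide peptide panel tibble: required columns, group levels,
# non-negative finite measurements, AAO only on cases.
validate_panel <- function(panel, call = rlang::caller_env()) {
  need <- c("sample_id", "cohort", "group", ab_peptides())
  missing <- setdiff(need, names(panel))
  if (length(missing) > 0) {
    abort(paste0("Panel is missing required column(s): ", paste(missing, collapse = ", ")),
          call = call)
  }
  if (!all(panel$group %in% c("control", "case"))) {
    bad <- unique(setdiff(panel$group, c("control", "case")))
    abort(paste0("`group` must be 'control' or 'case'; found: ", paste(bad, collapse = ", ")),
          call = call)
  }
  vals <- as.matrix(panel[ab_peptides()])
  if (anyNA(vals)) {
    abort("Peptide measurements contain missing values; all five peptides are required per row.",
          call = call)
  }
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rows <- which(apply(vals, 1, function(r) any(!is.finite(r)) || any(r < 0)))
    abort(paste0("Peptide measurements must be finite and non-negative (rows: ",
                 paste(head(rows, 5), collapse = ", "), ")."), call = call)
  }
  if ("aao_years" %in% names(panel)) {
    if (any(panel$group == "control" & !is.na(panel$aao_years))) {
      abort("Controls must not carry `aao_years` (age at onset applies to mutation carriers).",
            call = call)
    }
  }
  invisible(panel)
}

# Ensure optional metadata columns exist so downstream code can rely on them.
complete_panel_cols <- function(panel) {
  if (!"replicate" %in% names(panel)) panel$replicate <- "r1"
  if (!"mutation" %in% names(panel)) panel$mutation <- NA_character_
  if (!"codon" %in% names(panel)) panel$codon <- NA_real_
  if (!"aao_years" %in% names(panel)) panel$aao_years <- NA_real_
  dplyr::relocate(panel, dplyr::any_of(panel_meta_cols()))
}

peptide_matrix <- function(panel) {
  m <- as.matrix(panel[ab_peptides()])
  rownames(m) <- NULL
  m
}
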