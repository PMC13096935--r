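#' Read a peptide panel from CSV
#'
#' Accepts the documented long format (columns `sample_id`, `cohort`,
#' `replicate`, `group`, `mutation`, `codon`, `aao_years`, `peptide`,
#' `value`) or a wide format with one column per peptide. Peptide names are
#' canonicalized to `Ab37`, `Ab38`, `Ab40`, `Ab42`, `Ab43` at the boundary
#' (spellings such as `Abeta42` or `AB42` are accepted); any other peptide
#' column, for example Ab39, is rejected — this is a five-peptide analysis
#' and unknown species must be removed upstream. Rows missing any of the
#' five peptides or carrying negative values fail with row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated wide peptide panel tibble.
#' @export
read_peptide_panel <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("peptide", "value") %in% names(raw))) {
    canon <- canonical_peptide(raw$peptide)
    if (anyNA(canon)) {
      bad <- unique(raw$peptide[is.na(canon)])
      abort(paste0("Unknown peptide name(s): ", paste(bad, collapse = ", "),
                   ". This is a five-peptide analysis (",
                   paste(ab_peptides(), collapse = ", "),
                   "); drop other species before loading."))
    }
    raw$peptide <- canon
    panel <- tidyr::pivot_wider(raw, names_from = "peptide", values_from = "value")
  } else {
    known_meta <- names(raw) %in% panel_meta_cols()
    canon <- canonical_peptide(names(raw))
    if (any(!known_meta & is.na(canon))) {
      bad <- names(raw)[!known_meta & is.na(canon)]
      abort(paste0("Unrecognized column(s): ", paste(bad, collapse = ", "),
                   ". Expected panel metadata plus peptide columns ",
                   paste(ab_peptides(), collapse = ", "), "."))
    }
    names(raw)[!known_meta] <- canon[!known_meta]
    panel <- raw
  }
  missing_pep <- setdiff(ab_peptides(), names(panel))
  if (length(missing_pep) > 0) {
    abort(paste0("Panel lacks peptide(s): ", paste(missing_pep, collapse = ", "), "."))
  }
  panel <- complete_panel_cols(tibble::as_tibble(panel))
  m <- as.matrix(panel[ab_peptides()])
  if (anyNA(m)) {
    abort(paste0("Missing peptide measurements in row(s): ",
                 paste(head(which(rowSums(is.na(m)) > 0), 5), collapse = ", "),
                 "; all five peptides are required per sample."))
  }
  if (any(m < 0)) {
    abort(paste0("Negative concentrations in row(s): ",
                 paste(head(which(rowSums(m < 0) > 0), 5), collapse = ", "),
                 "; assays report non-negative values."))
  }
  validate_panel(panel)
  inform(paste0("Loaded ", nrow(panel), " rows; ",
                paste(vapply(split(panel$sample_id, panel$cohort),
                             function(x) length(unique(x)), integer(1)),
                      "samples in", names(split(panel$sample_id, panel$cohort)),
                      collapse = "; "), "."))
  panel
}

#' Write a peptide panel to CSV
#'
#' @param panel A wide peptide panel tibble.
#' @param path Output CSV path.
#' @param format `"long"` (default; one row per measurement) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_peptide_panel <- function(panel, path, format = c("long", "wide")) {
  format <- rlang::arg_match(format)
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  out <- if (format == "long") {
    tidyr::pivot_longer(panel, dplyr::all_of(ab_peptides()),
                        names_to = "peptide", values_to = "value")
  } else {
    panel
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write ratio specs as JSON
#'
#' Serializes a [ratio_spec()] using the signed-percentage convention: one
#' weight per active peptide, numerator weights positive, denominator
#' weights negative.
#'
#' @param spec A [ratio_spec()].
#' @param path JSON file path.
#' @return `write_ratio_spec()` returns `path` invisibly;
#'   `read_ratio_spec()` the deserialized [ratio_spec()].
#' @export
write_ratio_spec <- function(spec, path) {
  w <- spec_signed_weights(normalize_spec(spec))
  jsonlite::write_json(list(name = spec$name, weights = as.list(w[w != 0])),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ratio_spec
#' @export
read_ratio_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(obj$weights)
  spec <- spec_from_signed_weights(w, name = obj$name)
  if (is.null(spec)) abort("Spec JSON must have at least one positive and one negative weight.")
  spec
}

#' Read and write simulation configs as JSON
#'
#' @param config A [sim_config()].
#' @param path JSON file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` the deserialized [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  obj$control_abundance_profile <- as.list(config$control_abundance_profile)
  obj$effect_profile <- as.list(config$effect_profile)
  w <- spec_signed_weights(config$planted_spec)
  obj$planted_spec <- list(name = config$planted_spec$name, weights = as.list(w[w != 0]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted <- spec_from_signed_weights(unlist(obj$planted_spec$weights),
                                      name = obj$planted_spec$name)
  bias <- obj$assay_bias
  if (!is.null(bias)) bias <- matrix(unlist(bias), nrow = obj$n_cohorts)
  sim_config(
    n_cohorts = obj$n_cohorts, n_controls = obj$n_controls, n_cases = obj$n_cases,
    n_replicates = obj$n_replicates,
    control_abundance_profile = unlist(obj$control_abundance_profile),
    assay_bias = bias, bias_sdlog = obj$bias_sdlog,
    effect_profile = unlist(obj$effect_profile),
    severity_range = unlist(obj$severity_range), planted_spec = planted,
    aao_intercept = obj$aao_intercept, aao_slope = obj$aao_slope,
    aao_noise_sd = obj$aao_noise_sd, noise_cv = obj$noise_cv,
    line_cv = obj$line_cv, loading_cv = obj$loading_cv,
    zero_rate = obj$zero_rate, seed = obj$seed
  )
}
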