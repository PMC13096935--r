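#' Run the full biomarker analysis pipeline
#'
#' Orchestrates the analysis end to end on a supplied or simulated panel:
#' harmonization, benchmark and enumerated ratio evaluation, the weight
#' search per objective, leave-one-out cross-validation with paired
#' comparisons, per-peptide onset correlations, deviation proportions, and
#' the mutation-position association. All tabular results are written as
#' TSV/CSV with a JSON manifest; reruns with the same inputs and seed are
#' reproducible.
#'
#' @param panel A raw wide peptide panel, or `NULL` to simulate one.
#' @param sim A [sim_config()] used when `panel` is `NULL`.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing and just return results.
#' @param biomarkers Stages to evaluate: any of `"benchmarks"`,
#'   `"enumeration"`, `"wcvr"`. Omitting `"wcvr"` skips the search
#'   entirely.
#' @param search A [search_config()] for the wCVR stages.
#' @param n_boot Bootstrap replicates for metric CIs.
#' @param loocv Run leave-one-out cross-validation of the benchmark and
#'   searched specs (fixed weights from the full-data search; set
#'   `loocv_research = TRUE` to re-search per fold instead).
#' @param loocv_research Re-run the weight search inside every training
#'   fold (leakage-safe but much slower).
#' @param seed Global seed; propagated to every stochastic stage.
#' @return Invisibly, a named list with the harmonized panel, metric
#'   tables, search results, LOOCV reports, comparisons and association
#'   tables.
#' @export
run_pipeline <- function(panel = NULL, sim = sim_config(), out_dir = NULL,
                         biomarkers = c("benchmarks", "enumeration", "wcvr"),
                         search = search_config(),
                         n_boot = 2000, loocv = TRUE, loocv_research = FALSE,
                         seed = 1L) {
  biomarkers <- match.arg(biomarkers, several.ok = TRUE)
  if (is.null(panel)) {
    sim$seed <- as.integer(seed)
    panel <- simulate_cohorts(sim)
  }
  harmonized <- harmonize_panel(panel, quiet = TRUE)
  results <- list(panel = panel, harmonized = harmonized,
                  provenance = harmonization_provenance(harmonized))

  specs <- list()
  if ("benchmarks" %in% biomarkers) specs <- c(specs, benchmark_specs())
  searches <- NULL
  if ("wcvr" %in% biomarkers) {
    cfg <- search
    cfg$seed <- as.integer(seed)
    searches <- run_configurations(harmonized, cfg)
    specs <- c(specs, purrr::map(searches, "best_spec"))
    results$searches <- searches
    results$weights <- purrr::map_dfr(searches, tidy)
  }
  if (length(specs) > 0) {
    results$metrics <- evaluate_biomarkers(harmonized, specs, n_boot = n_boot,
                                           seed = seed)
  }
  if ("enumeration" %in% biomarkers) {
    enum <- enumerate_ratio_specs()
    results$enumeration <- purrr::imap_dfr(enum, function(sp, nm) {
      sc <- compute_ratio(harmonized, sp)
      tibble::tibble(
        biomarker = nm,
        pr_auc_controls = pr_auc_controls(sc$score, sc$group),
        r_squared = suppressWarnings(pearson_r2_vs_aao(sc$score, sc$aao_years)))
    })
  }
  if (loocv && length(specs) > 0) {
    loocv_specs <- specs
    if (loocv_research && !is.null(searches)) {
      for (nm in names(searches)) {
        cfg <- search
        cfg$objective <- searches[[nm]]$objective
        loocv_specs[[nm]] <- cfg
      }
    }
    results$loocv <- loocv_evaluate(harmonized, loocv_specs, n_boot = n_boot,
                                    seed = seed)
    results$loocv_summary <- purrr::map_dfr(results$loocv, glance)
    results$comparisons <- paired_comparisons(results$loocv, n_boot = n_boot,
                                              seed = seed)
  }
  results$correlations <- peptide_aao_correlations(panel)
  no_rescale <- harmonize_panel(panel, rescale = FALSE, quiet = TRUE)
  results$deviations <- deviation_proportions(no_rescale)
  results$mutation_position <- tryCatch(mutation_position_association(no_rescale),
                                        error = function(e) NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_outputs(results, out_dir, seed)
  }
  invisible(results)
}

write_pipeline_outputs <- function(results, out_dir, seed) {
  p <- function(...) file.path(out_dir, ...)
  write_peptide_panel(results$panel, p("panel.csv"))
  readr::write_csv(results$harmonized, p("harmonized_panel.csv"), progress = FALSE)
  prov <- results$provenance
  jsonlite::write_json(list(
    n_zero_removed = prov$n_zero_removed,
    control_means = prov$control_means,
    reference = as.list(unclass(prov$reference)),
    reference_source = attr(prov$reference, "source")
  ), p("provenance.json"), auto_unbox = TRUE, digits = NA)
  tsv <- function(x, name) if (!is.null(x)) readr::write_tsv(x, p(name), progress = FALSE)
  tsv(results$metrics, "metrics.tsv")
  tsv(results$weights, "weights.tsv")
  tsv(results$enumeration, "enumeration.tsv")
  tsv(results$loocv_summary, "loocv_summary.tsv")
  tsv(results$comparisons, "loocv_comparisons.tsv")
  tsv(results$correlations, "correlations.tsv")
  tsv(results$deviations, "deviations.tsv")
  tsv(results$mutation_position, "mutation_position.tsv")
  if (!is.null(results$searches)) {
    for (nm in names(results$searches)) {
      write_ratio_spec(results$searches[[nm]]$best_spec,
                       p(paste0("spec_", gsub("[^A-Za-z0-9]+", "_", nm), ".json")))
    }
  }
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("wcvr")),
    r_version = R.version.string,
    seed = seed,
    files = list.files(out_dir)
  ), p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
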