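#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize search results
#'
#' `tidy()` returns the best spec's per-peptide signed weights (rounded to
#' the config's reporting resolution); `glance()` a one-row summary of the
#' run.
#'
#' @param x A `wcvr_search` from [ga_search()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wcvr_search <- function(x, ...) {
  out <- tidy(x$best_spec)
  out$weight_pct <- round(out$weight_pct / x$config$weight_resolution) * x$config$weight_resolution
  out
}

#' @rdname tidy.wcvr_search
#' @export
glance.wcvr_search <- function(x, ...) {
  tibble::tibble(
    biomarker = x$best_spec$name,
    objective = x$objective,
    best_objective = x$best_objective,
    n_restarts = x$config$n_restarts,
    generations = x$config$generations,
    population_size = x$config$population_size,
    n_samples = x$n_samples
  )
}

#' Tidy and summarize cross-validation reports
#'
#' `tidy()` returns the per-sample held-out predictions; `glance()` a
#' one-row summary with MAE, F1 and their bootstrap CIs.
#'
#' @param x A `wcvr_loocv` from [loocv_evaluate()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wcvr_loocv <- function(x, ...) {
  dplyr::mutate(x$predictions, biomarker = x$biomarker, .before = 1)
}

#' @rdname tidy.wcvr_loocv
#' @export
glance.wcvr_loocv <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    biomarker = x$biomarker,
    mae = x$mae,
    mae_low = est$conf.low[est$metric == "mae"],
    mae_high = est$conf.high[est$metric == "mae"],
    f1 = x$f1,
    f1_low = est$conf.low[est$metric == "f1"],
    f1_high = est$conf.high[est$metric == "f1"],
    n = nrow(x$predictions),
    n_boot = x$n_boot
  )
}
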