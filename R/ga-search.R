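#' Configure the genetic-algorithm weight search
#'
#' Settings for [ga_search()]: a real-coded genetic algorithm over signed
#' peptide weights (sign selects numerator vs denominator, magnitude the
#' weight) with tournament selection, blend crossover, Gaussian mutation,
#' elitism, multi-restart, and an optional Nelder-Mead polish of the best
#' genome. Benchmark ratios can be seeded into the initial population so the
#' search provably dominates them on training data.
#'
#' @param objective `"R"` (squared Pearson correlation of scores with age at
#'   onset over carriers), `"P"` (control-class PR AUC), or `"RP"` (their
#'   product).
#' @param population_size Even positive integer (default 100).
#' @param generations Generations per restart (default 120).
#' @param crossover_rate,mutation_rate Per-pair / per-gene probabilities.
#' @param mutation_sd Standard deviation of Gaussian gene mutation.
#' @param n_restarts Independent restarts; the best result is kept.
#' @param elitism Number of top genomes copied unchanged each generation.
#' @param seed_benchmarks Inject [benchmark_specs()] into each initial
#'   population (default `TRUE`).
#' @param polish Refine the best genome by Nelder-Mead (default `TRUE`);
#'   mainly sharpens the smooth `R` objective.
#' @param weight_resolution Reporting resolution of normalized weights, in
#'   percentage points (default 0.1, matching one printed decimal).
#' @param seed Integer seed; results are deterministic given the config.
#' @return A list of class `search_config`.
#' @export
search_config <- function(objective = c("RP", "R", "P"),
                          population_size = 100,
                          generations = 120,
                          crossover_rate = 0.9,
                          mutation_rate = 0.25,
                          mutation_sd = 0.15,
                          n_restarts = 3,
                          elitism = 1,
                          seed_benchmarks = TRUE,
                          polish = TRUE,
                          weight_resolution = 0.1,
                          seed = 1L) {
  objective <- rlang::arg_match(objective)
  population_size <- as.integer(population_size)
  if (population_size < 4 || population_size %% 2 != 0) {
    abort("`population_size` must be an even integer >= 4.")
  }
  if (crossover_rate < 0 || crossover_rate > 1 || mutation_rate < 0 || mutation_rate > 1) {
    abort("Rates must be probabilities in [0, 1].")
  }
  if (generations < 1 || n_restarts < 1) abort("`generations` and `n_restarts` must be positive.")
  if (weight_resolution <= 0) abort("`weight_resolution` must be positive.")
  structure(list(
    objective = objective, population_size = population_size,
    generations = as.integer(generations), crossover_rate = crossover_rate,
    mutation_rate = mutation_rate, mutation_sd = mutation_sd,
    n_restarts = as.integer(n_restarts), elitism = as.integer(elitism),
    seed_benchmarks = isTRUE(seed_benchmarks), polish = isTRUE(polish),
    weight_resolution = weight_resolution, seed = as.integer(seed)
  ), class = "search_config")
}

#' Objective value of a ratio spec on a panel
#'
#' Evaluates the search objective for a spec: `"R"` is the squared Pearson
#' correlation between biomarker scores and age at onset over mutation
#' carriers, `"P"` the control-class PR AUC, and `"RP"` their product.
#'
#' @param panel A harmonized (and reference-rescaled) panel tibble.
#' @param spec A [ratio_spec()].
#' @param objective `"R"`, `"P"`, or `"RP"`.
#' @return A scalar in \[0, 1\].
#' @export
objective_value <- function(panel, spec, objective = c("RP", "R", "P")) {
  objective <- rlang::arg_match(objective)
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  check_objective_data(panel$group, panel$aao_years, objective)
  eval_objective(score_matrix(peptide_matrix(panel), spec),
                 panel$group, panel$aao_years, objective)
}

check_objective_data <- function(group, aao, objective) {
  if (objective %in% c("R", "RP") && sum(!is.na(aao)) < 2) {
    abort("Objective R needs at least 2 carriers with age at onset.")
  }
  if (objective %in% c("P", "RP")) {
    if (sum(group == "control") < 1) abort("Objective P needs at least 1 control.")
    if (sum(group == "case") < 2) abort("Objective P needs at least 2 cases.")
  }
  invisible(NULL)
}

eval_objective <- function(scores, group, aao, objective) {
  r2 <- function() {
    keep <- !is.na(aao)
    s <- scores[keep]
    if (sd(s) == 0 || sd(aao[keep]) == 0) return(0)
    cor(s, aao[keep])^2
  }
  p <- function() pr_auc_controls(scores, group)
  switch(objective, R = r2(), P = p(), RP = r2() * p())
}

# --- genome helpers -------------------------------------------------------
# A genome is a signed weight per peptide in [-1, 1]; sign = side.

repair_genome <- function(w) {
  if (all(w == 0)) w <- runif(length(w), -1, 1)
  if (all(w >= 0) || all(w <= 0)) {
    k <- which.max(abs(w))
    w[k] <- -w[k]
    if (w[k] == 0) w[k] <- sample(c(-0.5, 0.5), 1)
  }
  w
}

genome_fitness_matrix <- function(W, X, group, aao, objective) {
  num <- X %*% pmax(W, 0)
  den <- X %*% pmax(-W, 0)
  S <- num / den
  carriers <- !is.na(aao)
  r2 <- NULL
  if (objective %in% c("R", "RP")) {
    A <- S[carriers, , drop = FALSE]
    y <- aao[carriers] - mean(aao[carriers])
    A0 <- sweep(A, 2, colMeans(A))
    denom <- sqrt(colSums(A0^2)) * sqrt(sum(y^2))
    r2 <- ifelse(denom > 0, (as.vector(crossprod(A0, y)) / denom)^2, 0)
  }
  pv <- NULL
  if (objective %in% c("P", "RP")) {
    pv <- vapply(seq_len(ncol(S)), function(j) pr_auc_controls(S[, j], group), numeric(1))
  }
  switch(objective, R = r2, P = pv, RP = r2 * pv)
}

# Prefer higher fitness; break exact ties by fewer active peptides, then by
# lexicographic order of the signed weight vector.
better_genome <- function(f1, w1, f2, w2) {
  if (is.null(f2)) return(TRUE)
  if (f1 != f2) return(f1 > f2)
  a1 <- sum(w1 != 0); a2 <- sum(w2 != 0)
  if (a1 != a2) return(a1 < a2)
  isTRUE(all(w1 <= w2)) && any(w1 < w2)
}

#' Search for a weighted composite value ratio
#'
#' Runs a multi-restart real-coded genetic algorithm over signed peptide
#' weights to maximize the configured objective on the supplied panel. Each
#' genome is a signed weight per peptide; invalid genomes (an empty
#' numerator or denominator) are repaired by flipping the
#' largest-magnitude weight to the empty side. With
#' `seed_benchmarks = TRUE` the benchmark ratios join the initial
#' population, so (with elitism) the final objective can never fall below
#' any benchmark's objective on the training data.
#'
#' For the pure classification objective (`"P"`), whose metrics are
#' invariant under taking the reciprocal of the ratio, the returned spec is
#' canonically oriented with the control-enriched side in the numerator
#' (cases score low), the convention used for short/long-type ratios. The
#' regression objectives are not reciprocal-invariant, so their specs are
#' reported as found.
#'
#' @param panel A harmonized, reference-rescaled panel tibble.
#' @param config A [search_config()].
#' @param peptides Peptides the search may use (default all five); useful
#'   for restricted searches that can be verified exhaustively.
#' @return A `wcvr_search` object: `best_spec` (normalized
#'   [ratio_spec()]), `best_objective`, `objective`, `traces` (a tibble of
#'   the best-so-far objective per generation per restart), `config`.
#' @export
#' @examples
#' \donttest{
#' panel <- harmonize_panel(simulate_cohorts(sim_config(seed = 3)))
#' fit <- ga_search(panel, search_config("R", population_size = 40,
#'                                       generations = 30, n_restarts = 1))
#' tidy(fit)
#' }
ga_search <- function(panel, config = search_config(), peptides = ab_peptides()) {
  if (!inherits(config, "search_config")) abort("`config` must come from search_config().")
  peptides <- match.arg(peptides, ab_peptides(), several.ok = TRUE)
  if (length(peptides) < 2) abort("The search needs at least two peptides.")
  validate_panel(panel)
  panel <- complete_panel_cols(panel)
  X <- peptide_matrix(panel)[, peptides, drop = FALSE]
  if (any(X <= 0)) abort("Panel values must be strictly positive (harmonize first).")
  group <- panel$group
  aao <- panel$aao_years
  check_objective_data(group, aao, config$objective)
  withr::with_seed(config$seed, ga_search_impl(X, group, aao, config, panel$sample_id))
}

ga_search_impl <- function(X, group, aao, cfg, sample_ids) {
  npep <- ncol(X)
  pop_n <- cfg$population_size
  fitness <- function(W) genome_fitness_matrix(W, X, group, aao, cfg$objective)
  bench_W <- NULL
  if (cfg$seed_benchmarks) {
    usable <- purrr::keep(benchmark_specs(), function(s) {
      all(c(names(s$numerator), names(s$denominator)) %in% colnames(X))
    })
    if (length(usable) > 0) {
      bench_W <- vapply(usable, function(s) {
        w <- spec_signed_weights(s, colnames(X))
        w / max(abs(w))
      }, numeric(npep))
    }
  }
  best_w <- NULL; best_f <- NULL
  traces <- list()
  for (restart in seq_len(cfg$n_restarts)) {
    W <- matrix(runif(npep * pop_n, -1, 1), npep, pop_n)
    if (!is.null(bench_W)) W[, seq_len(ncol(bench_W))] <- bench_W
    W <- apply(W, 2, repair_genome)
    trace <- numeric(cfg$generations)
    r_best_w <- NULL; r_best_f <- NULL
    for (gen in seq_len(cfg$generations)) {
      f <- fitness(W)
      gi <- which.max(f)
      if (better_genome(f[gi], W[, gi], r_best_f, r_best_w)) {
        r_best_f <- f[gi]; r_best_w <- W[, gi]
      }
      trace[gen] <- r_best_f
      if (gen == cfg$generations) break
      # tournament selection (size 3)
      pick <- function() {
        cand <- sample.int(pop_n, 3)
        cand[which.max(f[cand])]
      }
      children <- matrix(0, npep, pop_n)
      for (k in seq(1, pop_n, by = 2)) {
        p1 <- W[, pick()]; p2 <- W[, pick()]
        if (runif(1) < cfg$crossover_rate) {
          # blend (BLX-alpha 0.5) crossover
          lo <- pmin(p1, p2); hi <- pmax(p1, p2); d <- hi - lo
          c1 <- runif(npep, lo - 0.5 * d, hi + 0.5 * d)
          c2 <- runif(npep, lo - 0.5 * d, hi + 0.5 * d)
        } else {
          c1 <- p1; c2 <- p2
        }
        children[, k] <- c1
        children[, k + 1] <- c2
      }
      mut <- matrix(runif(npep * pop_n) < cfg$mutation_rate, npep, pop_n)
      children[mut] <- children[mut] + rnorm(sum(mut), 0, cfg$mutation_sd)
      children <- pmin(pmax(children, -1), 1)
      children <- apply(children, 2, repair_genome)
      if (cfg$elitism > 0) {
        elite <- order(f, decreasing = TRUE)[seq_len(cfg$elitism)]
        children[, seq_len(cfg$elitism)] <- W[, elite]
      }
      W <- children
    }
    traces[[restart]] <- tibble::tibble(restart = restart,
                                        generation = seq_len(cfg$generations),
                                        best_objective = trace)
    if (better_genome(r_best_f, r_best_w, best_f, best_w)) {
      best_f <- r_best_f; best_w <- r_best_w
    }
  }
  if (cfg$polish) {
    pen_fit <- function(w) {
      if (all(w >= 0) || all(w <= 0)) return(-1)
      as.numeric(fitness(matrix(w, ncol = 1)))
    }
    pol <- tryCatch(
      optim(best_w, function(w) -pen_fit(w), method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(pol) && -pol$value > best_f) {
      best_f <- -pol$value
      best_w <- pol$par
    }
  }
  if (cfg$objective == "P") {
    # PR/ROC metrics are reciprocal-invariant: report with the
    # control-enriched side on top (cases score low)
    s <- as.vector((X %*% pmax(best_w, 0)) / (X %*% pmax(-best_w, 0)))
    if (median(s[group == "case"]) > median(s[group == "control"])) best_w <- -best_w
  }
  best_spec <- normalize_spec(spec_from_signed_weights(
    setNames(best_w, colnames(X)), name = paste0("wCVR-", cfg$objective)))
  structure(list(
    best_spec = best_spec,
    best_objective = best_f,
    objective = cfg$objective,
    traces = dplyr::bind_rows(traces),
    config = cfg,
    n_samples = nrow(X)
  ), class = "wcvr_search")
}

#' @export
print.wcvr_search <- function(x, ...) {
  cat("<wcvr_search> objective ", x$objective, " = ", format(x$best_objective, digits = 6),
      " (", max(x$traces$restart), " restart(s), ", x$n_samples, " samples)\n", sep = "")
  print(x$best_spec)
  invisible(x)
}

#' Run the weight search under each objective
#'
#' Convenience wrapper running [ga_search()] once per objective (`R`, `P`,
#' `RP`) with per-objective seeds derived from the base config.
#'
#' @param panel A harmonized, reference-rescaled panel tibble.
#' @param config A [search_config()]; its `objective` field is overridden.
#' @return A named list of `wcvr_search` results
#'   (`wCVR-R`, `wCVR-P`, `wCVR-RP`).
#' @export
run_configurations <- function(panel, config = search_config()) {
  objectives <- c("R", "P", "RP")
  out <- lapply(seq_along(objectives), function(i) {
    cfg <- config
    cfg$objective <- objectives[i]
    cfg$seed <- config$seed + i - 1L
    ga_search(panel, cfg)
  })
  setNames(out, paste0("wCVR-", objectives))
}
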