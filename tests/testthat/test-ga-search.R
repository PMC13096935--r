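small_search <- function(objective, seed = 9, ...) {
  search_config(objective, population_size = 40, generations = 40,
                n_restarts = 1, seed = seed, ...)
}

test_that("objective values reduce to their component metrics", {
  panel <- harmonize_panel(random_panel(n_control = 3, n_case = 10, seed = 4),
                           quiet = TRUE)
  spec <- benchmark_specs()[["short/long"]]
  sc <- compute_ratio(panel, spec)
  r <- pearson_r2_vs_aao(sc$score, sc$aao_years)
  p <- pr_auc_controls(sc$score, sc$group)
  expect_equal(objective_value(panel, spec, "R"), r)
  expect_equal(objective_value(panel, spec, "P"), p)
  expect_equal(objective_value(panel, spec, "RP"), r * p)

  # exact limits: affine scores give R = 1; separated groups give P = 1
  lin <- panel_with_scores(c(1, 2, 3, 4, 10, 11),
                           c(rep("case", 4), "control", "control"),
                           aao = c(40, 45, 50, 55, NA, NA))
  expect_equal(objective_value(lin, ratio_spec("Ab42", "Ab40"), "R"), 1)
  expect_equal(objective_value(lin, ratio_spec("Ab42", "Ab40"), "P"), 1)
  expect_equal(objective_value(lin, ratio_spec("Ab42", "Ab40"), "RP"), 1)
})

test_that("search is deterministic given the seed", {
  panel <- harmonize_panel(simulate_cohorts(sim_config(
    n_cohorts = 1, n_controls = 4, n_cases = 20, seed = 3)), quiet = TRUE)
  r1 <- ga_search(panel, small_search("R"))
  r2 <- ga_search(panel, small_search("R"))
  expect_identical(r1$best_spec, r2$best_spec)
  expect_identical(r1$traces, r2$traces)
  r3 <- ga_search(panel, small_search("R", seed = 10))
  expect_s3_class(r3$best_spec, "ratio_spec")
})

test_that("best-so-far traces are monotone non-decreasing within restarts", {
  panel <- harmonize_panel(simulate_cohorts(sim_config(
    n_cohorts = 1, n_controls = 4, n_cases = 20, seed = 5)), quiet = TRUE)
  res <- ga_search(panel, search_config("RP", population_size = 30,
                                        generations = 25, n_restarts = 2, seed = 2))
  for (tr in split(res$traces, res$traces$restart)) {
    expect_true(all(diff(tr$best_objective) >= 0))
  }
  expect_gte(res$best_objective, max(res$traces$best_objective) - 1e-12)
})

test_that("search recovers a planted spec on measurement-noise-free data", {
  planted <- ratio_spec(c(Ab37 = 0.2, Ab38 = 0.2, Ab40 = 0.6),
                        c(Ab42 = 0.8, Ab43 = 0.2), "planted")
  cfg <- noise_free_config(n_controls = 10, n_cases = 60, n_replicates = 1,
                           planted_spec = planted, seed = 5)
  cfg$line_cv <- 0.1  # biological line diversity carries the signal
  h <- harmonize_panel(simulate_cohorts(cfg), quiet = TRUE)
  res <- ga_search(h, search_config("R", seed = 3))
  expect_gte(res$best_objective, 0.999)
  w <- tidy(res)$weight_pct
  wp <- tidy(normalize_spec(planted))$weight_pct
  expect_lt(max(abs(w - wp)), 2)
})

test_that("search matches or beats an exhaustive 3-peptide grid", {
  brute_best <- function(h, peps, grid = seq(0.05, 1, by = 0.05)) {
    X <- as.matrix(h[peps]); grp <- h$group
    best <- 0
    assigns <- expand.grid(rep(list(0:2), length(peps)))
    for (i in seq_len(nrow(assigns))) {
      a <- as.integer(assigns[i, ])
      if (!any(a == 1) || !any(a == 2)) next
      act <- which(a > 0)
      combos <- as.matrix(expand.grid(rep(list(grid), length(act))))
      for (r in seq_len(nrow(combos))) {
        w <- numeric(length(peps))
        w[act] <- combos[r, ] * ifelse(a[act] == 1, 1, -1)
        s <- as.vector((X %*% pmax(w, 0)) / (X %*% pmax(-w, 0)))
        best <- max(best, pr_auc_controls(s, grp))
      }
    }
    best
  }
  peps <- c("Ab37", "Ab40", "Ab42")
  for (sd in c(8, 21)) {
    panel <- simulate_cohorts(sim_config(n_cohorts = 1, n_controls = 6,
                                         n_cases = 18, n_replicates = 1,
                                         line_cv = 0.5, seed = sd))
    h <- harmonize_panel(panel, quiet = TRUE)
    b <- brute_best(h, peps)
    res <- ga_search(h, search_config("P", population_size = 60, generations = 80,
                                      n_restarts = 2, seed = 9), peptides = peps)
    # the continuous search must never fall below the discrete grid optimum
    expect_gte(res$best_objective, b - 1e-6)
    expect_setequal(c(names(res$best_spec$numerator), names(res$best_spec$denominator)),
                    intersect(peps, c(names(res$best_spec$numerator),
                                      names(res$best_spec$denominator))))
  }
})

test_that("seeded benchmarks guarantee dominance over reference ratios", {
  panel <- harmonize_panel(simulate_cohorts(sim_config(
    n_cohorts = 2, n_controls = 3, n_cases = 30, seed = 17)), quiet = TRUE)
  results <- run_configurations(panel, small_search("RP"))
  expect_setequal(names(results), c("wCVR-R", "wCVR-P", "wCVR-RP"))
  for (res in results) {
    bench_vals <- vapply(benchmark_specs(),
                         function(s) objective_value(panel, s, res$objective),
                         numeric(1))
    expect_gte(res$best_objective, max(bench_vals) - 1e-9)
  }
})

test_that("degenerate inputs surface errors", {
  one_case <- panel_with_scores(c(1, 2, 5), c("control", "control", "case"),
                                aao = c(NA, NA, 40))
  expect_error(ga_search(one_case, small_search("P")), "2 cases")
  expect_error(ga_search(one_case, small_search("R")), "2 carriers")
  expect_error(search_config("R", population_size = 7), "even")
  expect_error(search_config("R", mutation_rate = 2), "probabilities")
  panel <- harmonize_panel(random_panel(seed = 2), quiet = TRUE)
  expect_error(ga_search(panel, small_search("R"), peptides = "Ab42"), "two peptides")
})
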