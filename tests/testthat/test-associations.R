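test_that("peptide-onset correlations hit exact limits and match the tau oracle", {
  # one peptide exactly affine increasing in AAO
  n <- 8
  aao <- seq(40, 68, length.out = n)
  panel <- panel_with_scores(rep(1, n + 2), c(rep("case", n), "control", "control"),
                             aao = c(aao, NA, NA))
  panel$sample_id <- sprintf("s%02d", seq_len(n + 2))
  panel$Ab42 <- c(0.02 + 0.001 * aao, 0.05, 0.06)
  tab <- peptide_aao_correlations(panel)
  row <- tab[tab$cohort == "c1" & tab$peptide == "Ab42", ]
  # relative abundance of Ab42 is monotone in its raw value here (other
  # peptides constant), so tau = 1; Pearson on the composition is high
  expect_equal(row$kendall_tau, 1)
  expect_gt(row$pearson_r, 0.99)
  expect_true(row$conf.low <= row$pearson_r && row$pearson_r <= row$conf.high)

  # reversed ranking gives tau = -1
  panel2 <- panel
  panel2$Ab42[seq_len(n)] <- rev(panel2$Ab42[seq_len(n)])
  tab2 <- peptide_aao_correlations(panel2)
  expect_equal(tab2$kendall_tau[tab2$cohort == "c1" & tab2$peptide == "Ab42"], -1)

  # 5-point fixture against explicit concordant/discordant pair counting
  x <- c(1.2, 3.4, 2.2, 5.5, 4.1)
  y <- c(10, 30, 20, 50, 40)
  expect_equal(unname(cor(x, y, method = "kendall")), oracle_kendall_tau_b(x, y))
  xt <- c(1, 1, 2, 3, 3)  # ties on both sides
  yt <- c(2, 1, 1, 3, 3)
  expect_equal(unname(cor(xt, yt, method = "kendall")), oracle_kendall_tau_b(xt, yt))
})

test_that("correlation table covers per-cohort and pooled scopes", {
  panel <- simulate_cohorts(sim_config(n_cohorts = 2, n_controls = 3,
                                       n_cases = 15, seed = 9))
  tab <- peptide_aao_correlations(panel)
  expect_setequal(unique(tab$cohort), c("cohort1", "cohort2", "all"))
  expect_equal(sum(tab$cohort == "all"), 5)
  expect_true(all(abs(tab$kendall_tau) <= 1))
  expect_true(all(tab$conf.low <= tab$conf.high))
})

test_that("deviation fractions partition the case samples", {
  panel <- panel_with_scores(c(1, 1, 0.5, 0.7, 1, 1.3),
                             c("control", "control", rep("case", 4)),
                             aao = c(NA, NA, 40, 45, 50, 55))
  dev <- deviation_proportions(panel)
  expect_equal(dev$frac_below + dev$frac_above + dev$frac_at, rep(1, 5))
  ab42 <- dev[dev$peptide == "Ab42", ]
  expect_equal(ab42$frac_below, 2 / 4)
  expect_equal(ab42$frac_above, 1 / 4)
  expect_equal(ab42$frac_at, 1 / 4)  # value exactly at the control mean
  other <- dev[dev$peptide == "Ab37", ]
  expect_equal(other$frac_at, 1)
  expect_error(deviation_proportions(panel[panel$group == "control", ]), "case")
})

test_that("mutation-position association handles monotone and degenerate codons", {
  panel <- simulate_cohorts(sim_config(n_cohorts = 1, n_controls = 3,
                                       n_cases = 20, seed = 13))
  h <- harmonize_panel(panel, rescale = FALSE, quiet = TRUE)
  mono <- h
  carriers <- mono$group == "case"
  mono$codon[carriers] <- rank(mono$aao_years[carriers])  # monotone map
  tab <- mutation_position_association(mono)
  expect_equal(tab$kendall_tau[tab$outcome == "aao_years"], 1)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("kendall_z", "pearson_t", "df") %in% names(tab)))

  flat <- h
  flat$codon[flat$group == "case"] <- 180
  expect_error(mutation_position_association(flat), "constant")
})

test_that("bootstrapped weight distributions respect spec invariants", {
  cfg <- noise_free_config(n_controls = 8, n_cases = 30, n_replicates = 1, seed = 3)
  cfg$line_cv <- 0.1
  h <- harmonize_panel(simulate_cohorts(cfg), quiet = TRUE)
  wd <- bootstrap_weight_distribution(
    h, search_config("R", population_size = 30, generations = 20, n_restarts = 1),
    n_boot = 5, restarts = 2, seed = 11)
  expect_equal(nrow(wd$weights), 5 * 5)
  for (rep_w in split(wd$weights, wd$weights$replicate)) {
    expect_equal(sum(rep_w$weight_pct[rep_w$weight_pct > 0]), 100, tolerance = 1e-6)
    expect_equal(sum(rep_w$weight_pct[rep_w$weight_pct < 0]), -100, tolerance = 1e-6)
  }
  expect_equal(nrow(wd$summary), 5)
  # planted denominator peptide lands in the denominator across replicates
  ab42 <- wd$weights$weight_pct[wd$weights$peptide == "Ab42"]
  expect_true(all(ab42 < 0))
})

test_that("grid search reduces to the baseline and has the documented axis", {
  h <- harmonize_panel(simulate_cohorts(sim_config(
    n_cohorts = 1, n_controls = 4, n_cases = 15, seed = 6)), quiet = TRUE)
  g <- grid_search_weights(h, "R", step = 0.1, mode = "marginal")
  base_val <- objective_value(h, ratio_spec("Ab42", "Ab40"), "R")
  zero_rows <- g[rowSums(abs(as.matrix(g[setdiff(names(g), "value")]))) == 0, ]
  expect_equal(unique(zero_rows$value), base_val)
  # default step: 51 weights per peptide-side (0 to 1 by 0.02)
  g2 <- grid_search_weights(h, "P", step = 0.02, mode = "marginal")
  expect_setequal(setdiff(names(g2), "value"), c("Ab38", "Ab40", "Ab43"))
  w38 <- sort(unique(g2$Ab38))
  expect_length(w38[w38 >= 0], 51)
  expect_length(w38[w38 <= 0], 51)
  expect_error(grid_search_weights(h, "R", step = 0), "positive")

  # joint mode at a coarse step covers the cartesian grid
  gj <- grid_search_weights(h, "R", step = 0.5, mode = "joint")
  expect_equal(nrow(gj), 5^3)
  expect_equal(unique(gj$value[rowSums(abs(as.matrix(gj[1:3]))) == 0]), base_val)
})

test_that("permutation importance is zero for inactive peptides and ranks drivers", {
  # planted signal only in Ab42: cases shifted there, other peptides pure noise
  withr::with_seed(8, {
    n <- 40
    panel <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:n), cohort = "c1", replicate = "r1",
      group = rep(c("control", "case"), c(8, 32)),
      mutation = NA_character_, codon = NA_real_,
      aao_years = c(rep(NA, 8), runif(32, 35, 60)),
      Ab37 = rlnorm(n, 0, 0.3), Ab38 = rlnorm(n, 0, 0.3),
      Ab40 = rlnorm(n, 1, 0.3),
      Ab42 = rlnorm(n, 0, 0.1) * rep(c(1, 3), c(8, 32)),
      Ab43 = rlnorm(n, -1, 0.3))
    panel$aao_years[panel$group == "case"] <- 70 - 5 * panel$Ab42[panel$group == "case"]
  })
  spec <- ratio_spec(c(Ab40 = 1), c(Ab42 = 1, Ab43 = 0.2))
  imp <- permutation_importance(panel, spec, n_perm = 30, seed = 2)
  inactive <- imp[imp$peptide %in% c("Ab37", "Ab38"), ]
  expect_true(all(inactive$importance == 0))
  roc_imp <- imp[imp$metric == "roc_auc", ]
  expect_equal(roc_imp$peptide[which.max(roc_imp$importance)], "Ab42")
  expect_true(all(is.finite(imp$importance)))
})
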