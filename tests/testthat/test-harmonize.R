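test_that("zero filtering removes exactly the affected rows", {
  clean <- random_panel(n_control = 3, n_case = 7)
  expect_equal(filter_zero_samples(clean, quiet = TRUE)[names(clean)], clean,
               ignore_attr = TRUE)
  expect_equal(attr(filter_zero_samples(clean, quiet = TRUE), "n_zero_removed"), 0)

  # a 230-row panel with exactly 14 zero-bearing rows
  big <- random_panel(n_control = 30, n_case = 200, seed = 3)
  zero_rows <- c(5, 17, 23, 48, 51, 77, 90, 101, 115, 140, 160, 188, 201, 230)
  big$Ab43[zero_rows[1:10]] <- 0
  big$Ab37[zero_rows[11:13]] <- 0
  big[zero_rows[14], ab_peptides()] <- 0  # fully-zero row counts once
  out <- filter_zero_samples(big, quiet = TRUE)
  expect_equal(nrow(out), 216)
  expect_equal(attr(out, "n_zero_removed"), 14)
})

test_that("replicate averaging is the arithmetic mean and preserves annotations", {
  p <- panel_with_scores(c(1, 1), c("case", "case"), aao = c(40, 40))
  p$sample_id <- "s01"
  p$replicate <- c("r1", "r2")
  p$Ab40 <- c(10, 20)
  avg <- average_replicates(p)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$Ab40, 15)
  expect_equal(avg$aao_years, 40)

  single <- random_panel()
  avg1 <- average_replicates(single)
  expect_equal(avg1[c("sample_id", ab_peptides())][order(avg1$sample_id), ],
               single[c("sample_id", ab_peptides())][order(single$sample_id), ])

  panel <- simulate_cohorts(sim_config(n_cohorts = 1, n_controls = 3, n_cases = 10,
                                       n_replicates = 3, zero_rate = 0, seed = 2))
  expect_equal(nrow(average_replicates(panel)), 13)

  bad <- p
  bad$aao_years <- c(40, 45)  # conflicting annotation within a sample
  expect_error(average_replicates(bad), "Conflicting")
})

test_that("total normalization yields compositions and is scale-invariant", {
  p <- panel_with_scores(1, "case", aao = 40)
  p[ab_peptides()] <- as.list(c(1, 1, 2, 4, 2))
  out <- normalize_to_total(p)
  expect_equal(unlist(out[ab_peptides()]), c(.1, .1, .2, .4, .2),
               ignore_attr = TRUE)

  r <- random_panel(seed = 7)
  scaled <- r
  scaled[ab_peptides()] <- scaled[ab_peptides()] * 7.3  # per-row positive scaling
  expect_equal(normalize_to_total(r)[ab_peptides()],
               normalize_to_total(scaled)[ab_peptides()])
  expect_equal(rowSums(as.matrix(normalize_to_total(r)[ab_peptides()])),
               rep(1, nrow(r)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("control-mean scaling sets control means to exactly 1 and is idempotent", {
  r <- normalize_to_total(random_panel(n_control = 4, n_case = 9, seed = 11))
  h <- scale_by_control_means(r)
  cm <- colMeans(as.matrix(h[h$group == "control", ab_peptides()]))
  expect_equal(unname(cm), rep(1, 5), tolerance = 1e-12)
  h2 <- scale_by_control_means(h)
  expect_equal(h2[ab_peptides()], h[ab_peptides()], tolerance = 1e-12,
               ignore_attr = TRUE)

  # a case measurement equal to the control mean maps to 1.0
  p <- random_panel(n_control = 2, n_case = 1, seed = 5)
  p$Ab42[3] <- mean(p$Ab42[1:2])
  hp <- scale_by_control_means(p)
  expect_equal(hp$Ab42[3], 1)

  no_ctrl <- random_panel()
  no_ctrl$group <- "case"
  no_ctrl$aao_years <- 40 + seq_len(nrow(no_ctrl))
  expect_error(scale_by_control_means(no_ctrl), "without control")
})

test_that("reference rescaling restores natural proportions for additive ratios", {
  ref <- as_reference_proportions(
    c(Ab37 = 0.16, Ab38 = 0.16, Ab40 = 0.60, Ab42 = 0.07, Ab43 = 0.01))
  ones <- panel_with_scores(1, "case", aao = 40)
  out <- rescale_to_reference(ones, ref)
  expect_equal(unlist(out[ab_peptides()]), as.numeric(ref), ignore_attr = TRUE)

  # uniform reference is a global scalar: every ratio biomarker unchanged
  r <- harmonize_panel(random_panel(n_control = 3, n_case = 9, seed = 13),
                       rescale = FALSE, quiet = TRUE)
  unif <- rescale_to_reference(r, as_reference_proportions(
    setNames(rep(0.2, 5), ab_peptides())))
  sl <- benchmark_specs()[["short/long"]]
  expect_equal(compute_ratio(unif, sl)$score, compute_ratio(r, sl)$score,
               tolerance = 1e-12)
  # a non-uniform reference changes additive ratios
  nonunif <- rescale_to_reference(r, ref)
  expect_false(isTRUE(all.equal(compute_ratio(nonunif, sl)$score,
                                compute_ratio(r, sl)$score)))
  # ... but leaves single-peptide ratios unchanged up to a constant factor
  s1 <- compute_ratio(nonunif, benchmark_specs()[["Ab42/40"]])$score
  s2 <- compute_ratio(r, benchmark_specs()[["Ab42/40"]])$score
  expect_equal(s1 / s2, rep(s1[1] / s2[1], length(s1)), tolerance = 1e-12)
})

test_that("per-cohort assay bias cancels in biomarker scores", {
  # two cohorts with matched underlying biology, homogeneous controls,
  # differing only by a per-peptide multiplicative assay bias
  base <- simulate_cohorts(noise_free_config(
    n_controls = 4, n_cases = 15, n_replicates = 1, line_cv = 0, seed = 21))
  biased <- base
  bias <- c(Ab37 = 2.5, Ab38 = 0.4, Ab40 = 1.7, Ab42 = 0.8, Ab43 = 3.1)
  biased[ab_peptides()] <- sweep(as.matrix(base[ab_peptides()]), 2, bias, `*`)
  biased$cohort <- "c_biased"
  biased$sample_id <- paste0("b_", biased$sample_id)

  h_base <- harmonize_panel(base, rescale = FALSE, quiet = TRUE)
  h_biased <- harmonize_panel(biased, rescale = FALSE, quiet = TRUE)
  for (spec in benchmark_specs()) {
    expect_equal(compute_ratio(h_biased, spec)$score,
                 compute_ratio(h_base, spec)$score, tolerance = 1e-12)
  }
  # value-level: bias alters each row only by a common scalar
  ratio <- as.matrix(h_biased[ab_peptides()]) / as.matrix(h_base[ab_peptides()])
  expect_lt(max(apply(ratio, 1, function(x) diff(range(x)))), 1e-12)
})

test_that("harmonization provenance records the pipeline's inputs", {
  panel <- simulate_cohorts(sim_config(seed = 6))
  h <- harmonize_panel(panel, quiet = TRUE)
  prov <- harmonization_provenance(h)
  expect_gt(prov$n_zero_removed, 0)
  expect_equal(nrow(prov$control_means), 4)
  expect_s3_class(prov$reference, "reference_proportions")
  expect_equal(sum(as.numeric(prov$reference)), 1, tolerance = 1e-12)
})
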