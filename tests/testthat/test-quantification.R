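# Trapezoidal integration, log2 normalization, protein roll-up.

quant_entry <- function(frag_mz = c(300, 400, 500), ordinals = 3:5) {
  e <- make_entries("PEPQK", 2L, 500, 2, FALSE, 300, frag_mz,
                    ordinal = ordinals)
  e$quant_flag <- "quant"
  e
}

test_that("a Gaussian peak integrates to its closed-form area within 1%", {
  tr <- gaussian_trace("r1", "urine", "PEPQK", 2L, "y", 3L, 1L,
                       apex = 300, sigma = 5, amplitude = 100, step = 0.5)
  e <- quant_entry(300, 3L)
  area <- integrate_peptide(tr, e, c(300 - 20, 300 + 20))
  expect_equal(area, 100 * 5 * sqrt(2 * pi), tolerance = 0.01)

  # linear in amplitude, stable under grid refinement
  tr2 <- tr; tr2$intensity <- tr$intensity * 3.5
  expect_equal(integrate_peptide(tr2, e, c(280, 320)), 3.5 * area,
               tolerance = 1e-9)
  fine <- gaussian_trace("r1", "urine", "PEPQK", 2L, "y", 3L, 1L,
                         apex = 300, sigma = 5, amplitude = 100,
                         step = 0.1)
  expect_equal(integrate_peptide(fine, e, c(280, 320)), area,
               tolerance = 0.01)
})

test_that("integration handles zero traces, additivity and missing ions", {
  tr3 <- gaussian_trace("r1", "urine", "PEPQK", 2L, "y", 3L, 1L, 300)
  tr4 <- gaussian_trace("r1", "urine", "PEPQK", 2L, "y", 4L, 1L, 300)
  e2 <- quant_entry(c(300, 400), 3:4)
  single <- integrate_peptide(tr3, quant_entry(300, 3L), c(276, 324))
  both <- integrate_peptide(rbind(tr3, tr4), e2, c(276, 324))
  expect_equal(both, 2 * single, tolerance = 1e-12)

  zero <- tr3; zero$intensity <- 0
  expect_equal(integrate_peptide(zero, quant_entry(300, 3L), c(276, 324)),
               0)

  # quant ion lacking a trace contributes nothing
  expect_equal(integrate_peptide(tr3, e2, c(276, 324)), single)

  # no quant-flagged ions: missing, not zero
  e_none <- quant_entry(300, 3L); e_none$quant_flag <- "detection_only"
  expect_true(is.na(integrate_peptide(tr3, e_none, c(276, 324))))

  expect_error(integrate_peptide(tr3, e2, c(324, 276)), "boundary")
})

test_that("log2 normalization removes run-level scale and is idempotent", {
  vals <- matrix(2^matrix(rnorm(40, 10), 10, 4), 10, 4,
                 dimnames = list(sprintf("p%02d", 1:10),
                                 sprintf("r%d", 1:4)))
  meta <- data.frame(run_id = sprintf("r%d", 1:4), matrix_id = "urine")
  qt <- quant_table(vals, meta)

  scaled <- vals; scaled[, 2] <- vals[, 1] * 2; scaled[, 1] <- vals[, 1]
  qt2 <- quant_table(scaled, meta)
  n2 <- normalize_log2(qt2)
  expect_equal(n2$values[, 1], n2$values[, 2], tolerance = 1e-9,
               ignore_attr = TRUE)

  n1 <- normalize_log2(qt)
  # complete-case run means all equal after normalization
  expect_lt(diff(range(colMeans(n1$values))), 1e-9)
  # renormalizing the already-centered table changes nothing
  again <- normalize_log2(quant_table(2^n1$values, meta))
  expect_equal(again$values, n1$values, tolerance = 1e-9)
  # within-run rank order preserved
  for (j in 1:4) {
    expect_equal(order(n1$values[, j]), order(vals[, j]))
  }
})

test_that("normalization requires complete cases and positive values", {
  vals <- matrix(c(1, NA, NA, 4), 2, 2,
                 dimnames = list(c("a", "b"), c("r1", "r2")))
  meta <- data.frame(run_id = c("r1", "r2"), matrix_id = "urine")
  expect_error(normalize_log2(quant_table(vals, meta)), "complete-case")
  vals2 <- matrix(c(0, 1, 2, 3), 2, 2,
                  dimnames = list(c("a", "b"), c("r1", "r2")))
  expect_error(normalize_log2(quant_table(vals2, meta)), "non-positive")
})

test_that("protein roll-up sums unique peptides and drops shared ones", {
  vals <- matrix(c(10, 20, 30, 40, 5, 6), 3, 2, byrow = FALSE,
                 dimnames = list(c("pepA", "pepB", "pepC"),
                                 c("r1", "r2")))
  meta <- data.frame(run_id = c("r1", "r2"), matrix_id = "urine")
  qt <- quant_table(vals, meta)
  pmap <- data.frame(peptide = c("pepA", "pepB", "pepC", "pepC"),
                     protein = c("PR1", "PR1", "PR1", "PR2"))
  pt <- rollup_protein(qt, pmap)
  # pepC shared between PR1 and PR2: contributes to neither
  expect_equal(rownames(pt$values), "PR1")
  expect_equal(unname(pt$values["PR1", ]), c(10 + 20, 40 + 5))

  pmap3 <- data.frame(peptide = c("pepA", "pepB", "pepC"),
                      protein = "PR1")
  pt3 <- rollup_protein(qt, pmap3)
  expect_equal(unname(pt3$values["PR1", ]), c(60, 51))
  # total protein signal never exceeds total peptide signal
  expect_lte(sum(pt3$values), sum(vals))

  expect_error(rollup_protein(qt, pmap[0, ]), "config error")
})

test_that("quantified simulation recovers spiked two-fold protein changes", {
  cfg <- simulation_config(n_true_peptides = 120L, n_false_targets = 20L,
                           n_decoys = 120L, n_interference_pairs = 0L,
                           runs_per_matrix = 6L, fraction_spiked = 0.1,
                           detection_probability = c(urine = 1,
                                                     plasma = 1,
                                                     serum = 1),
                           seed = 19L)
  sim <- simulate_experiment(cfg)
  # +1 estimator floor: 120 true peptides sit near the 1% limit; use 5%
  pcfg <- pipeline_config(fdr_alpha = 0.05)
  h <- harmonize(sim$libraries, sim$chromatograms, pcfg)
  qt <- quantify_experiment(sim$chromatograms, h$harmonized,
                            sim$run_meta)
  pt <- rollup_protein(qt, sim$truth$protein_map)
  pn <- normalize_log2(pt)
  grp <- pn$meta$group
  delta <- rowMeans(pn$values[, grp == "B", drop = FALSE], na.rm = TRUE) -
    rowMeans(pn$values[, grp == "A", drop = FALSE], na.rm = TRUE)
  spiked <- names(which(sim$truth$spiked))
  spiked <- intersect(spiked, rownames(pn$values))
  expect_gt(length(spiked), 2)
  expect_lte(median(abs(delta[spiked] - 1)), 0.2)
  unspiked <- setdiff(rownames(pn$values), spiked)
  expect_lte(median(abs(delta[unspiked])), 0.2)
})
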