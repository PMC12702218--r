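# The synthetic experiment generator: mass arithmetic, determinism, score
# mixtures, warps, and the injected-interference ground truth.

test_that("fragment masses follow the monoisotopic ladder", {
  lad <- fragment_ladder("PEPTIDEK")
  y1 <- lad$mz[lad$ion_series == "y" & lad$ordinal == 1]
  expect_equal(y1, 147.1128, tolerance = 0.001)

  # b(n-1) + y(1) = neutral mass + 2 protons (ladder conservation)
  set.seed(5)
  for (i in 1:25) {
    pep <- make_peptide()
    n <- nrow(pep$ladder) / 2 + 1
    b_last <- pep$ladder$mz[pep$ladder$ion_series == "b" &
                              pep$ladder$ordinal == n - 1]
    y1 <- pep$ladder$mz[pep$ladder$ion_series == "y" &
                          pep$ladder$ordinal == 1]
    expect_equal(b_last + y1,
                 peptide_neutral_mass(pep$peptide) + 2 * 1.00727646688,
                 tolerance = 0.001)
  }
})

test_that("generated peptides are tryptic-like", {
  set.seed(9)
  for (i in 1:2000) {
    p <- make_peptide()$peptide
    plain <- gsub("\\[[^]]*\\]", "", p)
    expect_match(substr(plain, nchar(plain), nchar(plain)), "[KR]")
    expect_true(nchar(plain) >= 7 && nchar(plain) <= 25)
  }
})

test_that("full detection probability puts every true peptide in every library", {
  cfg <- simulation_config(
    n_true_peptides = 100L, n_false_targets = 20L, n_decoys = 40L,
    detection_probability = c(urine = 1, plasma = 1, serum = 1),
    n_interference_pairs = 0L, runs_per_matrix = 2L, seed = 1L)
  sim <- simulate_experiment(cfg, with_chromatograms = FALSE)
  for (m in names(sim$libraries)) {
    expect_true(all(sim$truth$true_peptides %in%
                      sim$libraries[[m]]$entries$peptide))
  }
})

test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  cfg <- simulation_config(n_true_peptides = 40L, n_false_targets = 20L,
                           n_decoys = 40L, n_interference_pairs = 4L,
                           runs_per_matrix = 2L, seed = 7L)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$libraries, b$libraries)
  expect_identical(a$chromatograms, b$chromatograms)

  cfg2 <- cfg; cfg2$seed <- 8L
  c <- simulate_experiment(cfg2, with_chromatograms = FALSE)
  expect_false(identical(a$libraries$urine$entries$score,
                         c$libraries$urine$entries$score))
})

test_that("injected interference pairs satisfy the co-isolation, co-elution and ppm invariants", {
  pcfg <- pipeline_config()
  cfg <- simulation_config(n_true_peptides = 60L, n_false_targets = 10L,
                           n_decoys = 20L, n_interference_pairs = 20L,
                           runs_per_matrix = 2L, seed = 7L)
  sim <- simulate_experiment(cfg, pcfg, with_chromatograms = FALSE)
  pairs <- sim$truth$interference_pairs
  expect_equal(nrow(pairs), 20L)
  roles <- sim$truth$roles
  for (k in seq_len(nrow(pairs))) {
    a_mz <- roles$precursor_mz[roles$peptide == pairs$analyte_peptide[k]]
    b_mz <- roles$precursor_mz[roles$peptide == pairs$interferer_peptide[k]]
    expect_true(coisolated(pcfg$wide_scheme, a_mz, b_mz, "union"))
    drt <- abs(sim$truth$rt_matrix[pairs$analyte_peptide[k], ] -
                 sim$truth$rt_matrix[pairs$interferer_peptide[k], ])
    expect_true(any(drt <= pcfg$coelution_tolerance))
    ppm <- abs(pairs$interferer_fragment_mz[k] -
                 pairs$analyte_fragment_mz[k]) /
      pairs$analyte_fragment_mz[k] * 1e6
    expect_lte(ppm, pcfg$ppm_tolerance)
  }
})

test_that("score mixtures match their configured components", {
  sc <- simulate_scored_peptides(n_targets = 10000L, true_fraction = 0.3,
                                 n_decoys = 10000L,
                                 matrices = "urine",
                                 detection_probability = c(urine = 1),
                                 seed = 4L)
  s <- sc$scores
  dec <- s$score[s$is_decoy]
  tru <- s$score[s$peptide %in% sc$truth$peptide[sc$truth$is_true]]
  expect_gt(suppressWarnings(stats::ks.test(dec, "pnorm", 0, 1))$p.value,
            0.001)
  expect_gt(suppressWarnings(stats::ks.test(tru, "pnorm", 3, 1))$p.value,
            0.001)
})

test_that("library retention times inverse-warp back to reference times", {
  cfg <- simulation_config(n_true_peptides = 80L, n_false_targets = 0L,
                           n_decoys = 10L, n_interference_pairs = 0L,
                           runs_per_matrix = 2L, seed = 12L)
  sim <- simulate_experiment(cfg, with_chromatograms = FALSE)
  roles <- sim$truth$roles
  for (m in cfg$matrices) {
    e <- sim$libraries[[m]]$entries
    e <- e[!e$is_decoy & !duplicated(e$peptide), , drop = FALSE]
    ref <- roles$ref_rt[match(e$peptide, roles$peptide)]
    inv <- harmolib:::warp_invert(cfg$warp_params[[m]], e$rt_seconds)
    expect_lte(median(abs(inv - ref)), 2 * cfg$rt_jitter_sd)
  }
})

test_that("inconsistent simulation configs are rejected", {
  expect_error(simulation_config(n_true_peptides = 10L,
                                 n_interference_pairs = 8L),
               class = "harmolib_config_error")
  expect_error(
    simulation_config(detection_probability = c(urine = 0, plasma = 1,
                                                serum = 1)),
    class = "harmolib_config_error")
})
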