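# Interference screening under wide windows, peak-shape correlation, and
# quantitative-ion selection.

test_that("a constructed co-isolating, co-eluting pair is flagged and an RT-shifted one is not", {
  cfg <- pipeline_config()
  analyte <- make_entries("ANALYTEK", 2L, 500.25, 2, FALSE, 1000,
                          c(700.350, 820.4, 930.5))
  interferer <- make_entries("INTERFK", 2L, 505.10, 1.5, FALSE, 1010,
                             c(700.352, 611.3, 450.2))
  lib <- spectral_library(rbind(analyte, interferer))
  rep1 <- find_cofragmenting(analyte, lib, cfg$wide_scheme, cfg)
  hit <- rep1[rep1$fragment_mz == 700.350, ]
  expect_true(hit$flagged)
  expect_equal(hit$interferers[[1]]$peptide, "INTERFK")
  expect_lt(hit$interferers[[1]]$ppm_distance, 10)
  expect_false(any(rep1$flagged[rep1$fragment_mz != 700.350]))

  far <- interferer; far$rt_seconds <- 1120  # 120 s away
  lib2 <- spectral_library(rbind(analyte, far))
  rep2 <- find_cofragmenting(analyte, lib2, cfg$wide_scheme, cfg)
  expect_false(any(rep2$flagged))
})

test_that("an analyte alone in its library has no flags", {
  cfg <- pipeline_config()
  analyte <- make_entries("LONELYK", 2L, 500.25, 2, FALSE, 1000,
                          c(700.350, 820.4))
  lib <- spectral_library(analyte)
  rep <- find_cofragmenting(analyte, lib, cfg$wide_scheme, cfg)
  expect_false(any(rep$flagged))
  expect_equal(rep$n_interferers, c(0L, 0L))
})

test_that("library-wide flagging equals the brute-force all-pairs oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    lib <- random_library(120)
    for (rule in c("union", "demultiplexed")) {
      cfg <- pipeline_config(cofragmentation_rule = rule)
      fast <- flagged_set(flag_library_interference(lib, cfg$wide_scheme,
                                                    cfg))
      brute <- oracle_interference(lib, cfg$wide_scheme, cfg)
      expect_setequal(fast, brute)
    }
  }
})

test_that("find_cofragmenting agrees with the library-wide sweep per precursor", {
  set.seed(77)
  lib <- random_library(60)
  cfg <- pipeline_config()
  sweep <- flag_library_interference(lib, cfg$wide_scheme, cfg)
  e <- lib$entries
  for (p in unique(e$peptide)[1:10]) {
    an <- e[e$peptide == p, , drop = FALSE]
    rep <- find_cofragmenting(an, lib, cfg$wide_scheme, cfg)
    expect_equal(rep$flagged, sweep$flagged[sweep$peptide == p])
  }
})

test_that("the union rule flags a superset of the demultiplexed rule", {
  set.seed(55)
  lib <- random_library(200)
  cfg_u <- pipeline_config(cofragmentation_rule = "union")
  cfg_d <- pipeline_config(cofragmentation_rule = "demultiplexed")
  fu <- flagged_set(flag_library_interference(lib, cfg_u$wide_scheme,
                                              cfg_u))
  fd <- flagged_set(flag_library_interference(lib, cfg_d$wide_scheme,
                                              cfg_d))
  expect_true(all(fd %in% fu))
})

test_that("peak-shape correlation scores identical, shifted and dead traces correctly", {
  mk <- function(ordinal, apex) {
    gaussian_trace("r1", "urine", "PEPK", 2L, "y", ordinal, 1L,
                   apex = apex)
  }
  identical4 <- rbind(mk(3, 300), mk(4, 300), mk(5, 300), mk(6, 300))
  r <- peak_shape_correlation(identical4)
  expect_equal(r$correlation, rep(1, 4), tolerance = 1e-9)

  shifted <- rbind(mk(3, 300), mk(4, 300), mk(5, 300), mk(6, 318))
  r2 <- peak_shape_correlation(shifted)
  expect_equal(which.min(r2$correlation), which(r2$fragment_ordinal == 6))
  expect_lt(r2$correlation[r2$fragment_ordinal == 6],
            min(r2$correlation[r2$fragment_ordinal != 6]))

  dead <- rbind(mk(3, 300), mk(4, 300))
  dead$intensity[dead$fragment_ordinal == 4] <- 0
  r3 <- peak_shape_correlation(dead)
  expect_equal(r3$correlation[r3$fragment_ordinal == 4], 0)

  expect_error(peak_shape_correlation(mk(3, 300)), "insufficient")
})

test_that("quant-ion selection obeys the 5/3 rule and deterministic tie-breaks", {
  cfg <- pipeline_config()
  frag8 <- data.frame(ion_series = "y", fragment_ordinal = 2:9,
                      fragment_charge = 1L,
                      fragment_mz = seq(300, 1000, length.out = 8),
                      library_intensity = 8:1 * 10)
  sel <- select_quant_ions(frag8, rep(FALSE, 8), NULL, cfg)
  expect_true(sel$quantifiable)
  expect_equal(sum(sel$decision$quant_flag == "quant"), 5L)
  # flags partition the fragment list
  expect_setequal(sel$decision$quant_flag, c("quant", "detection_only"))

  sel2 <- select_quant_ions(frag8, c(rep(TRUE, 6), FALSE, FALSE), NULL,
                            cfg)
  expect_false(sel2$quantifiable)
  expect_true(all(sel2$decision$quant_flag == "detection_only"))

  # equal correlations and intensities: ascending m/z decides
  frag3 <- data.frame(ion_series = "y", fragment_ordinal = 2:4,
                      fragment_charge = 1L,
                      fragment_mz = c(900, 300, 600),
                      library_intensity = c(50, 50, 50))
  sel3 <- select_quant_ions(frag3, rep(FALSE, 3), NULL, cfg)
  expect_true(all(sel3$decision$quant_flag == "quant"))
  frag10 <- data.frame(ion_series = "y", fragment_ordinal = 2:11,
                       fragment_charge = 1L,
                       fragment_mz = c(900, 300, 600, 150, 450, 750,
                                       1050, 200, 500, 800),
                       library_intensity = 50)
  sel10a <- select_quant_ions(frag10, rep(FALSE, 10), NULL, cfg)
  sel10b <- select_quant_ions(frag10, rep(FALSE, 10), NULL, cfg)
  expect_identical(sel10a, sel10b)
  taken <- sort(frag10$fragment_mz[sel10a$decision$quant_flag == "quant"])
  expect_equal(taken, sort(frag10$fragment_mz)[1:5])
})

test_that("correlation ranking prefers clean ions over the interfered one", {
  cfg <- pipeline_config()
  frag <- data.frame(ion_series = "y", fragment_ordinal = 3:8,
                     fragment_charge = 1L,
                     fragment_mz = seq(300, 800, by = 100),
                     library_intensity = 60)
  corr <- data.frame(matrix_id = rep(c("urine", "serum"), each = 6),
                     ion_series = "y", fragment_ordinal = rep(3:8, 2),
                     fragment_charge = 1L,
                     correlation = c(rep(0.99, 6),
                                     c(0.98, 0.99, 0.3, 0.97, 0.99,
                                       0.96)))
  sel <- select_quant_ions(frag, rep(FALSE, 6), corr, cfg)
  expect_equal(
    sel$decision$quant_flag[sel$decision$fragment_ordinal == 5],
    "detection_only")
  expect_equal(sum(sel$decision$quant_flag == "quant"), 5L)
})

test_that("injected interferers are flagged and clean fragments mostly are not", {
  sim <- tiny_sim()
  h <- harmonize(sim$libraries, chromatograms = NULL)
  ion <- h$ion_decisions
  pairs <- sim$truth$interference_pairs
  acc <- h$accepted$peptide
  rel <- pairs[pairs$analyte_peptide %in% acc &
                 pairs$interferer_peptide %in% acc, , drop = FALSE]
  expect_gte(nrow(rel), 5)
  key <- paste(ion$peptide, fragment_key(ion$ion_series,
                                         ion$fragment_ordinal,
                                         ion$fragment_charge))
  pair_key <- paste(rel$analyte_peptide,
                    fragment_key(rel$analyte_ion_series,
                                 rel$analyte_fragment_ordinal,
                                 rel$analyte_fragment_charge))
  flagged <- ion$flagged[match(pair_key, key)]
  expect_gte(mean(flagged, na.rm = TRUE), 0.95)
  clean <- !(key %in% pair_key)
  expect_lte(mean(ion$flagged[clean]), 0.05)
})
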