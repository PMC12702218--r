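# Domain types, file formats, isolation-window arithmetic.

test_that("library TSV round-trips bit-for-bit, including quant flags", {
  sim <- tiny_sim()
  lib <- sim$libraries$urine
  lib$entries$quant_flag[seq_len(10)] <- "quant"
  lib$entries$quant_flag[11:20] <- "detection_only"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(back$matrix_id, lib$matrix_id)
  expect_equal(back$entries, lib$entries, tolerance = 0)
})

test_that("reading rejects malformed transition lists with precise errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  e <- make_entries("AAAAK", 2L, 450.1, 1.5, FALSE, 100,
                    c(300.1, 400.2, 500.3))
  # missing mandatory column
  utils::write.table(e[, -match("fragment_mz", names(e))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_library(path), "fragment_mz")
  # empty value in a numeric column, reported with its line number
  e2 <- e
  e2$fragment_mz <- as.character(e2$fragment_mz)
  e2$fragment_mz[2] <- ""
  utils::write.table(e2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_library(path), "line 3.*fragment_mz")
  # conflicting scores for one precursor
  e3 <- rbind(e, e)
  e3$score[4:6] <- 9
  utils::write.table(e3, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_library(path), "integrity")
})

test_that("header-only library file yields an empty library", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(library_columns(), collapse = "\t"), path)
  lib <- read_library(path)
  expect_s3_class(lib, "spectral_library")
  expect_equal(nrow(lib$entries), 0L)
})

test_that("staggered windows resolve precursors to the expected intervals", {
  sch <- isolation_scheme(400, 1000, 16, staggered = TRUE)
  win <- scheme_windows(sch)
  idx <- windows_for_precursor(sch, 417.0)
  expect_length(idx, 2L)
  got <- win[idx, c("start", "end")]
  expect_setequal(got$start, c(416, 408))
  expect_setequal(got$end, c(432, 424))

  plain <- isolation_scheme(400, 1000, 16, staggered = FALSE)
  idx2 <- windows_for_precursor(plain, 416.0)  # boundary: higher window only
  expect_length(idx2, 1L)
  expect_equal(scheme_windows(plain)$start[idx2], 416)

  expect_error(windows_for_precursor(sch, 399.0), "outside")
})

test_that("window lookup agrees with a brute-force interval scan", {
  set.seed(42)
  for (rep in 1:20) {
    width <- sample(c(4, 8, 12, 16, 24), 1)
    stag <- sample(c(TRUE, FALSE), 1)
    sch <- isolation_scheme(400, 400 + width * sample(10:40, 1), width,
                            stag)
    win <- scheme_windows(sch)
    mz <- runif(20, sch$start_mz, sch$end_mz - 1e-6)
    for (x in mz) {
      brute <- which(win$start <= x & x < win$end)
      expect_identical(windows_for_precursor(sch, x), brute)
      if (stag && x >= sch$start_mz + width / 2 &&
          x < sch$end_mz - width / 2) {
        expect_length(brute, 2L)
      }
    }
  }
})

test_that("scheme and config JSON round-trip", {
  sch <- isolation_scheme(396.43, 1004.7, 4, staggered = TRUE)
  p1 <- withr::local_tempfile(fileext = ".json")
  write_scheme(sch, p1)
  expect_equal(read_scheme(p1), sch)

  cfg <- pipeline_config(fdr_alpha = 0.05, ppm_tolerance = 5,
                         cofragmentation_rule = "demultiplexed")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, p2)
  expect_equal(read_config(p2), cfg)
})

test_that("invalid configurations are rejected as config errors", {
  expect_error(pipeline_config(min_quant_ions = 6, max_quant_ions = 5),
               class = "harmolib_config_error")
  expect_error(pipeline_config(fdr_alpha = 0), "fdr_alpha",
               class = "harmolib_config_error")
  expect_error(pipeline_config(ppm_tolerance = -1),
               class = "harmolib_config_error")
})

test_that("chromatogram CSV and quant report round-trip", {
  tr <- rbind(
    gaussian_trace("r1", "urine", "AAAK", 2L, "y", 3L, 1L, apex = 300),
    gaussian_trace("r1", "urine", "AAAK", 2L, "y", 4L, 1L, apex = 300))
  p <- withr::local_tempfile(fileext = ".csv")
  write_chromatograms(tr, p)
  back <- read_chromatograms(p)
  expect_equal(back, tr, tolerance = 0)

  vals <- matrix(c(1.5, NA, 3.25, 4, 5, 6), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("r1", "r2")))
  meta <- data.frame(run_id = c("r1", "r2"), matrix_id = "urine",
                     group = c("A", "B"))
  qt <- quant_table(vals, meta)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(qt, p2)
  back2 <- read_quant_table(p2)
  expect_equal(back2$values, qt$values, tolerance = 0)
  expect_equal(back2$meta$group, qt$meta$group)
})

test_that("quant tables refuse inconsistent metadata and negative values", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("r1", "r2")))
  meta <- data.frame(run_id = c("r2", "r1"), matrix_id = "urine")
  expect_error(quant_table(vals, meta), "match")
  vals2 <- matrix(c(-1, 1, 1, 1), 2, 2,
                  dimnames = list(c("a", "b"), c("r1", "r2")))
  meta2 <- data.frame(run_id = c("r1", "r2"), matrix_id = "urine")
  expect_error(quant_table(vals2, meta2), "non-negative")
})
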