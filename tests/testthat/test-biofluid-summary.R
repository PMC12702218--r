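# CATalog-style summaries: top-biofluid rule, Venn partition, deltas,
# paired fold changes, pooled t test.

test_that("the 50% top-biofluid rule is inclusive and scale-invariant", {
  m <- c(urine = 100, plasma = 50, serum = 49.9)
  expect_setequal(top_biofluids(m), c("urine", "plasma"))
  expect_setequal(top_biofluids(m * 7.3), c("urine", "plasma"))
  expect_setequal(top_biofluids(c(urine = 3, plasma = 3, serum = 3)),
                  c("urine", "plasma", "serum"))
  expect_equal(top_biofluids(c(urine = NA, plasma = 12, serum = NA)),
               "plasma")
  expect_error(top_biofluids(c(urine = NA_real_)), "missing")
  # argmax always included
  set.seed(61)
  for (i in 1:50) {
    v <- stats::setNames(runif(3, 1, 100), c("u", "p", "s"))
    expect_true(names(v)[which.max(v)] %in% top_biofluids(v))
  }
})

test_that("the three-set overlap partition matches hand enumeration and conserves the union", {
  out <- overlap_partition(c("a", "b", "c"), c("b", "c", "d"),
                           c("c", "d", "e"))
  expect_equal(unname(out), c(1L, 0L, 1L, 1L, 0L, 1L, 1L))

  same <- overlap_partition(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(unname(same), c(0L, 0L, 0L, 0L, 0L, 0L, 5L))

  disj <- overlap_partition(c("a", "b"), c("c"), c("d", "e", "f"))
  expect_equal(unname(disj), c(2L, 1L, 3L, 0L, 0L, 0L, 0L))

  set.seed(62)
  for (i in 1:20) {
    u <- sample(letters, sample(5:20, 1))
    p <- sample(letters, sample(5:20, 1))
    s <- sample(letters, sample(5:20, 1))
    expect_equal(sum(overlap_partition(u, p, s)),
                 length(union(u, union(p, s))))
  }
})

paired_table <- function(vals, fluids, subjects, groups = NULL) {
  runs <- sprintf("%s_r%d", fluids, subjects)
  colnames(vals) <- runs
  meta <- data.frame(run_id = runs, matrix_id = fluids,
                     subject = subjects,
                     group = if (is.null(groups)) NA_character_ else
                       groups)
  quant_table(vals, meta, scale = "linear")
}

test_that("paired fold changes recover exact ratios", {
  vals <- matrix(c(8, 16, 8, 16, 32, 32, 8, 8), 2, 4, byrow = TRUE,
                 dimnames = list(c("PRa", "PRb"), NULL))
  qt <- paired_table(vals, c("urine", "urine", "serum", "serum"),
                     c(1, 2, 1, 2))
  lg <- quant_table(log2(qt$values), qt$meta, scale = "log2")
  fc <- fold_change_table(lg, "urine", "serum")
  expect_equal(fc$delta_log2[fc$row_id == "PRa"], 0)    # identical columns
  expect_equal(fc$delta_log2[fc$row_id == "PRb"], 2)    # urine = 4 x serum
  expect_equal(fc$n_pairs, c(2L, 2L))
  expect_warning(fold_change_table(
    quant_table(matrix(NA_real_, 1, 4,
                       dimnames = list("PRa", colnames(qt$values))),
                qt$meta, scale = "log2"), "urine", "serum"),
    "no proteins")
})

test_that("deltas are per-subject absolute differences with the right row count", {
  vals <- matrix(c(8, 10, 3, 7,
                   5, 5, 5, 5), 2, 4, byrow = TRUE,
                 dimnames = list(c("PRa", "PRb"), NULL))
  qt <- paired_table(vals, c("urine", "urine", "serum", "serum"),
                     c(1, 2, 1, 2))
  d <- compute_deltas(qt)
  expect_equal(d$delta[d$row_id == "PRa" & d$subject == 1], 5)  # |8 - 3|
  expect_true(all(d$delta[d$row_id == "PRb"] == 0))
  # counting oracle: proteins x complete pairs x fluid pairs
  set.seed(63)
  vals2 <- matrix(runif(3 * 6, 1, 10), 3, 6,
                  dimnames = list(c("x", "y", "z"), NULL))
  vals2[1, 2] <- NA
  qt2 <- paired_table(vals2, rep(c("urine", "plasma", "serum"),
                                 each = 2), rep(1:2, 3))
  d2 <- compute_deltas(qt2)
  brute <- 0L
  for (p in rownames(vals2)) {
    for (fp in list(c(1, 3), c(1, 5), c(3, 5))) {
      for (s in 0:1) {
        a <- vals2[p, fp[1] + s]; b <- vals2[p, fp[2] + s]
        if (!is.na(a) && !is.na(b)) brute <- brute + 1L
      }
    }
  }
  expect_equal(nrow(d2), brute)
})

test_that("the pooled t test matches the hand-worked example and flips under swap", {
  tt <- two_group_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.2247, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.288, tolerance = 1e-3)

  sw <- two_group_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(sw$t, -tt$t, tolerance = 1e-12)
  expect_equal(sw$p_value, tt$p_value, tolerance = 1e-12)

  same <- two_group_ttest(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  flat <- two_group_ttest(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
  expect_warning(deg <- two_group_ttest(c(2, 2), c(3, 3)),
                 "zero pooled variance")
  expect_equal(deg$p_value, 0)
})

test_that("the pooled t test matches the reference implementation on random inputs", {
  set.seed(64)
  for (i in 1:300) {
    a <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    mine <- two_group_ttest(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("protein summaries and per-protein group tests work end to end", {
  vals <- matrix(c(100, 120, 50, 55, 20, 22,
                   10, 11, 40, 44, 80, 88), 2, 6, byrow = TRUE,
                 dimnames = list(c("PRa", "PRb"), NULL))
  qt <- paired_table(vals, rep(c("urine", "plasma", "serum"), each = 2),
                     rep(1:2, 3), groups = rep(c("A", "B"), 3))
  s <- protein_summary(qt)
  expect_equal(s$top_fluids[s$row_id == "PRa"], "urine")  # 52.5 < 55
  expect_equal(s$top_fluids[s$row_id == "PRb"], "plasma;serum")
  tt <- group_ttest_table(quant_table(log2(qt$values), qt$meta,
                                      scale = "log2"))
  expect_equal(nrow(tt), 2L)
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
})
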