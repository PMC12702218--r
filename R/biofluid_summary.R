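# Biofluid comparison summaries: per-protein top-biofluid marking (50%
# rule), three-set overlap partition, paired between-fluid fold changes and
# deltas, and the pooled two-group t test.

#' Top biofluids of a protein
#'
#' A fluid is "top" when its average signal is within 50% of the most
#' intense fluid's signal, i.e. mean(f) >= 0.5 * max over fluids
#' (inclusive). Fluids with missing means are excluded. Invariant to
#' uniform positive scaling of the means.
#'
#' @param means Named numeric vector of per-fluid mean intensities
#'   (linear scale by default usage; the rule itself is scale-free).
#' @return Character vector of top fluid labels (always contains the
#'   argmax fluid).
#' @export
top_biofluids <- function(means) {
  keep <- !is.na(means)
  if (!any(keep)) stop("all fluid means are missing", call. = FALSE)
  m <- means[keep]
  names(m)[m >= 0.5 * max(m)]
}

#' Three-set overlap partition
#'
#' Counts of the seven exclusive regions of a three-set Venn diagram of
#' detected-protein sets.
#'
#' @param a,b,c Character vectors (detected identifiers per fluid).
#' @param labels Fluid labels used in the region names.
#' @return Named integer vector: `<A>_only`, `<B>_only`, `<C>_only`,
#'   `<A>_<B>`, `<A>_<C>`, `<B>_<C>`, `all_three`; sums to the size of the
#'   union.
#' @export
overlap_partition <- function(a, b, c, labels = c("urine", "plasma",
                                                  "serum")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(a, union(b, c))
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  counts <- c(
    sum(in_a & !in_b & !in_c),
    sum(!in_a & in_b & !in_c),
    sum(!in_a & !in_b & in_c),
    sum(in_a & in_b & !in_c),
    sum(in_a & !in_b & in_c),
    sum(!in_a & in_b & in_c),
    sum(in_a & in_b & in_c))
  names(counts) <- c(paste0(labels[1], "_only"), paste0(labels[2], "_only"),
                     paste0(labels[3], "_only"),
                     paste(labels[1], labels[2], sep = "_"),
                     paste(labels[1], labels[3], sep = "_"),
                     paste(labels[2], labels[3], sep = "_"),
                     "all_three")
  counts
}

#' Paired between-fluid fold changes
#'
#' For each protein quantified in both fluids, the mean over subjects of
#' the per-subject difference in (log2) intensity between the two fluids.
#' Requires subject pairing in the table's run metadata.
#'
#' @param qt A log2-scale [quant_table()] whose `meta` carries a `subject`
#'   column pairing runs across matrices.
#' @param fluid_a,fluid_b Matrix labels; the result is fluid_a - fluid_b.
#' @return Data frame: row_id, delta_log2, n_pairs. Proteins with no
#'   complete pair are omitted (empty table with a warning when none
#'   remain).
#' @export
fold_change_table <- function(qt, fluid_a, fluid_b) {
  stopifnot(inherits(qt, "quant_table"))
  if (qt$scale != "log2") stop("fold changes expect a log2 table",
                               call. = FALSE)
  if (is.null(qt$meta$subject)) {
    stop("run metadata lacks a 'subject' pairing column", call. = FALSE)
  }
  ma <- qt$meta$matrix_id == fluid_a
  mb <- qt$meta$matrix_id == fluid_b
  subj <- intersect(qt$meta$subject[ma], qt$meta$subject[mb])
  cols_a <- colnames(qt$values)[ma][match(subj, qt$meta$subject[ma])]
  cols_b <- colnames(qt$values)[mb][match(subj, qt$meta$subject[mb])]
  diffs <- qt$values[, cols_a, drop = FALSE] -
    qt$values[, cols_b, drop = FALSE]
  n_pairs <- rowSums(!is.na(diffs))
  out <- data.frame(row_id = rownames(qt$values),
                    delta_log2 = rowMeans(diffs, na.rm = TRUE),
                    n_pairs = n_pairs, stringsAsFactors = FALSE)
  out <- out[out$n_pairs > 0L, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no proteins shared between '", fluid_a,
                               "' and '", fluid_b, "'")
  out
}

#' Per-subject between-fluid absolute differences ("deltas")
#'
#' For every protein, fluid pair and subject with intensities in both
#' fluids, the absolute difference of the two intensities.
#'
#' @param qt A [quant_table()] whose `meta` carries a `subject` column.
#' @return Data frame: row_id, fluid_a, fluid_b, subject, delta.
#' @export
compute_deltas <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  if (is.null(qt$meta$subject)) {
    stop("run metadata lacks a 'subject' pairing column", call. = FALSE)
  }
  fluids <- sort(unique(qt$meta$matrix_id))
  parts <- list()
  if (length(fluids) >= 2L) {
    combs <- utils::combn(fluids, 2L)
    for (k in seq_len(ncol(combs))) {
      fa <- combs[1L, k]; fb <- combs[2L, k]
      ma <- qt$meta$matrix_id == fa
      mb <- qt$meta$matrix_id == fb
      subj <- intersect(qt$meta$subject[ma], qt$meta$subject[mb])
      for (s in subj) {
        ca <- colnames(qt$values)[ma][qt$meta$subject[ma] == s]
        cb <- colnames(qt$values)[mb][qt$meta$subject[mb] == s]
        va <- qt$values[, ca[1L]]; vb <- qt$values[, cb[1L]]
        ok <- !is.na(va) & !is.na(vb)
        if (!any(ok)) next
        parts[[length(parts) + 1L]] <- data.frame(
          row_id = rownames(qt$values)[ok], fluid_a = fa, fluid_b = fb,
          subject = s, delta = abs(va[ok] - vb[ok]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(parts) == 0L) {
    return(data.frame(row_id = character(0), fluid_a = character(0),
                      fluid_b = character(0), subject = integer(0),
                      delta = numeric(0)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Pooled two-sample t test
#'
#' Two-sided Student t test assuming equal variances, with
#' n_A + n_B - 2 degrees of freedom. Degenerate inputs follow fixed
#' conventions: zero pooled variance with equal means gives p = 1; zero
#' pooled variance with unequal means gives p = 0 (with a warning).
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p_value`.
#' @export
two_group_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff == 0) return(list(t = 0, df = df, p_value = 1))
    warning("zero pooled variance with unequal means")
    return(list(t = sign(diff) * Inf, df = df, p_value = 0))
  }
  tstat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df = df))
}

#' Per-protein biofluid summary
#'
#' Per-fluid mean intensities (over that fluid's runs, linear scale) plus
#' the top-biofluid marking, for every row of a quant table.
#'
#' @param qt A linear-scale [quant_table()].
#' @return Data frame: row_id, one `mean_<fluid>` column per fluid,
#'   top_fluids (semicolon-joined labels).
#' @export
protein_summary <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  fluids <- unique(qt$meta$matrix_id)
  means <- sapply(fluids, function(m) {
    rowMeans(qt$values[, qt$meta$matrix_id == m, drop = FALSE],
             na.rm = TRUE)
  })
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(
                                             rownames(qt$values), fluids))
  means[is.nan(means)] <- NA_real_
  top <- apply(means, 1L, function(v) {
    if (all(is.na(v))) return(NA_character_)
    paste(top_biofluids(v), collapse = ";")
  })
  out <- data.frame(row_id = rownames(qt$values), means,
                    top_fluids = top, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out)[seq_along(fluids) + 1L] <- paste0("mean_", fluids)
  rownames(out) <- NULL
  out
}

#' Per-protein two-group comparison
#'
#' Runs [two_group_ttest()] on every row of a quant table using its
#' `group` metadata.
#'
#' @param qt A [quant_table()] with a `group` column naming two groups.
#' @return Data frame: row_id, t, df, p_value (rows with fewer than two
#'   values per group are skipped).
#' @export
group_ttest_table <- function(qt) {
  groups <- sort(unique(stats::na.omit(qt$meta$group)))
  if (length(groups) != 2L) {
    stop("group metadata must define exactly two groups", call. = FALSE)
  }
  ga <- qt$meta$group == groups[1L]
  gb <- qt$meta$group == groups[2L]
  rows <- lapply(seq_len(nrow(qt$values)), function(i) {
    a <- stats::na.omit(qt$values[i, ga])
    b <- stats::na.omit(qt$values[i, gb])
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    tt <- two_group_ttest(a, b)
    data.frame(row_id = rownames(qt$values)[i], t = tt$t, df = tt$df,
               p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(row_id = character(0), t = numeric(0),
                      df = numeric(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
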