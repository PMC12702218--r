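# Peptide and protein quantification from extracted fragment
# chromatograms: trapezoidal integration of quant-flagged ions inside fixed
# peak boundaries, normalization to the average log2 intensity, and
# unique-peptide protein roll-up.

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' Integrate one peptide in one run
#'
#' Sum of trapezoidal areas of the quant-flagged fragment traces inside
#' the peak boundary. A quant ion with no trace in the run contributes 0;
#' a peptide with no quant-flagged ions yields `NA` (missing, never zero).
#'
#' @param run_traces Long chromatogram data frame restricted to one run.
#' @param entry Harmonized fragment rows of the peptide (library layout
#'   with quant_flag set).
#' @param boundary Numeric `c(start, end)` in seconds.
#' @return Linear intensity (scalar) or `NA`.
#' @export
integrate_peptide <- function(run_traces, entry, boundary) {
  stopifnot(length(boundary) == 2L)
  if (boundary[1L] >= boundary[2L]) {
    stop("boundary error: start must precede end", call. = FALSE)
  }
  quant <- entry[entry$quant_flag == "quant", , drop = FALSE]
  if (nrow(quant) == 0L) return(NA_real_)
  sel <- run_traces[run_traces$peptide == quant$peptide[1L] &
                      run_traces$precursor_charge ==
                      quant$precursor_charge[1L], , drop = FALSE]
  qkeys <- fragment_key(quant$ion_series, quant$fragment_ordinal,
                        quant$fragment_charge)
  tkeys <- fragment_key(sel$ion_series, sel$fragment_ordinal,
                        sel$fragment_charge)
  total <- 0
  for (k in qkeys) {
    idx <- which(tkeys == k)
    if (length(idx) == 0L) next  # missing trace contributes 0
    tt <- sel$time_sec[idx]; yy <- sel$intensity[idx]
    inside <- tt >= boundary[1L] & tt <= boundary[2L]
    total <- total + trapz(tt[inside], yy[inside])
  }
  total
}

#' Quantify all peptides of a harmonized experiment
#'
#' Integrates every quantifiable harmonized peptide in every run of every
#' matrix, each run against its own matrix's harmonized library. Peak
#' boundaries are the harmonized (observed or imputed) retention time
#' +/- `boundary_halfwidth` seconds.
#'
#' @param chrom Long chromatogram data frame (all runs).
#' @param harmonized Named list of harmonized [spectral_library()] (from
#'   [harmonize()]).
#' @param run_meta Data frame: run_id, matrix_id, group (and optionally
#'   subject).
#' @param boundary_halfwidth Half-width of the integration window in
#'   seconds (default 18 = 3 x a 6 s peak sigma).
#' @return A linear-scale [quant_table()] (peptides x runs; `NA` where a
#'   peptide has no quant ions or no signal window in a run).
#' @export
quantify_experiment <- function(chrom, harmonized, run_meta,
                                boundary_halfwidth = 18) {
  peptides <- sort(unique(unlist(lapply(harmonized, function(h)
    unique(h$entries$peptide[h$entries$quant_flag == "quant"])))))
  runs <- run_meta$run_id
  vals <- matrix(NA_real_, length(peptides), length(runs),
                 dimnames = list(peptides, runs))
  if (length(peptides) == 0L) {
    return(quant_table(vals, run_meta, row_type = "peptide",
                       scale = "linear"))
  }
  tr_key <- paste(chrom$run_id, chrom$peptide, chrom$ion_series,
                  chrom$fragment_ordinal, chrom$fragment_charge, sep = "\r")
  idx_by_key <- split(seq_len(nrow(chrom)), tr_key)
  for (m in names(harmonized)) {
    e <- harmonized[[m]]$entries
    q <- e[e$quant_flag == "quant" & e$peptide %in% peptides, ,
           drop = FALSE]
    if (nrow(q) == 0L) next
    m_runs <- run_meta$run_id[run_meta$matrix_id == m]
    for (r in m_runs) {
      keys <- paste(r, q$peptide, q$ion_series, q$fragment_ordinal,
                    q$fragment_charge, sep = "\r")
      for (p in unique(q$peptide)) {
        rows_q <- which(q$peptide == p)
        lo <- q$rt_seconds[rows_q[1L]] - boundary_halfwidth
        hi <- q$rt_seconds[rows_q[1L]] + boundary_halfwidth
        total <- NA_real_
        for (i in rows_q) {
          idx <- idx_by_key[[keys[i]]]
          if (is.null(idx)) next
          tt <- chrom$time_sec[idx]
          ord <- order(tt)
          tt <- tt[ord]
          inside <- tt >= lo & tt <= hi
          a <- trapz(tt[inside], chrom$intensity[idx][ord][inside])
          total <- if (is.na(total)) a else total + a
        }
        vals[p, r] <- total
      }
    }
  }
  quant_table(vals, run_meta, row_type = "peptide", scale = "linear")
}

#' Normalize a quant table to the average log2 intensity
#'
#' Each run's log2 intensities are shifted so that every run has the same
#' mean log2 intensity over complete-case rows (rows quantified in every
#' run); the common mean is the grand mean of the per-run means, so the
#' overall intensity scale is preserved. Missing values stay missing.
#'
#' @param qt A linear-scale [quant_table()] with positive values where
#'   present.
#' @return A log2-scale [quant_table()].
#' @export
normalize_log2 <- function(qt) {
  stopifnot(inherits(qt, "quant_table"))
  if (qt$scale != "linear") stop("expected a linear-scale table",
                                 call. = FALSE)
  v <- qt$values
  if (any(v <= 0, na.rm = TRUE)) {
    stop("normalization error: non-positive linear intensities",
         call. = FALSE)
  }
  lg <- log2(v)
  complete <- stats::complete.cases(lg)
  if (!any(complete)) {
    stop("normalization error: no complete-case rows", call. = FALSE)
  }
  m_j <- colMeans(lg[complete, , drop = FALSE])
  M <- mean(m_j)
  out <- sweep(lg, 2L, m_j - M, "-")
  quant_table(out, qt$meta, row_type = qt$row_type, scale = "log2")
}

#' Roll peptide quantities up to proteins
#'
#' Peptide uniqueness is enforced at the protein level: a peptide mapping
#' to more than one protein contributes to none. A protein's linear
#' intensity per run is the sum of its unique peptides' intensities over
#' the peptides quantified in that run; proteins with no unique quantified
#' peptide are absent.
#'
#' @param qt A linear-scale peptide [quant_table()].
#' @param protein_map Data frame with columns peptide, protein (a peptide
#'   may appear on several rows if shared).
#' @return A linear-scale protein [quant_table()].
#' @export
rollup_protein <- function(qt, protein_map) {
  stopifnot(inherits(qt, "quant_table"))
  if (is.null(protein_map) || nrow(protein_map) == 0L) {
    stop("config error: empty protein map", call. = FALSE)
  }
  if (qt$scale != "linear") stop("roll-up expects linear intensities",
                                 call. = FALSE)
  map <- unique(protein_map[, c("peptide", "protein")])
  n_prot <- table(map$peptide)
  unique_pep <- names(n_prot)[n_prot == 1L]
  map <- map[map$peptide %in% unique_pep, , drop = FALSE]
  map <- map[map$peptide %in% rownames(qt$values), , drop = FALSE]
  if (nrow(map) == 0L) {
    vals <- matrix(NA_real_, 0L, ncol(qt$values),
                   dimnames = list(character(0), colnames(qt$values)))
    return(quant_table(vals, qt$meta, row_type = "protein",
                       scale = "linear"))
  }
  sub <- qt$values[map$peptide, , drop = FALSE]
  has <- !is.na(sub)
  sub[!has] <- 0
  sums <- rowsum(sub, group = map$protein)
  counts <- rowsum(has + 0, group = map$protein)
  sums[counts == 0] <- NA_real_
  keep <- rowSums(counts) > 0
  quant_table(sums[keep, , drop = FALSE], qt$meta, row_type = "protein",
              scale = "linear")
}
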