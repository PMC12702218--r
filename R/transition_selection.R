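# Quantitative-transition selection: flag fragment ions at risk of
# co-fragmentation interference under the wide-window scheme, score
# candidate ions by cross-matrix peak-shape correlation, and pick the
# harmonized quantitative-ion set (max 5, min 3).

#' Find co-fragmenting interferers for one precursor
#'
#' A fragment of the analyte is flagged when some other library precursor
#' (i) shares a wide-scheme isolation window with the analyte under the
#' configured co-fragmentation rule, (ii) elutes within the co-elution
#' tolerance of the analyte, and (iii) has a fragment within the ppm
#' tolerance of the analyte fragment's m/z.
#'
#' @param analyte One-precursor data frame (fragment rows of a single
#'   peptide/charge in library layout) or a [spectral_library()] holding
#'   exactly one precursor.
#' @param library A [spectral_library()] of the same matrix (candidate
#'   interferers; the analyte itself is ignored).
#' @param scheme The wide-window [isolation_scheme()].
#' @param cfg A [pipeline_config()] (ppm/co-elution tolerances, rule).
#' @return Data frame with one row per analyte fragment: ion_series,
#'   fragment_ordinal, fragment_charge, fragment_mz, flagged, n_interferers,
#'   plus an `interferers` list-column of per-fragment data frames
#'   (interferer peptide, charge, fragment key, shared window, ppm
#'   distance, delta RT).
#' @export
find_cofragmenting <- function(analyte, library, scheme = cfg$wide_scheme,
                               cfg = pipeline_config()) {
  if (inherits(analyte, "spectral_library")) analyte <- analyte$entries
  stopifnot(is.data.frame(analyte), inherits(library, "spectral_library"))
  if (is.null(scheme)) stop("config error: no wide scheme", call. = FALSE)
  key <- unique(paste(analyte$peptide, analyte$precursor_charge))
  if (length(key) != 1L) {
    stop("analyte must contain exactly one precursor", call. = FALSE)
  }
  a_mz <- analyte$precursor_mz[1L]
  a_rt <- analyte$rt_seconds[1L]
  e <- library$entries
  e <- e[!(e$peptide == analyte$peptide[1L] &
             e$precursor_charge == analyte$precursor_charge[1L]), ,
         drop = FALSE]

  out <- analyte[, c("ion_series", "fragment_ordinal", "fragment_charge",
                     "fragment_mz"), drop = FALSE]
  rownames(out) <- NULL
  out$flagged <- FALSE
  out$n_interferers <- 0L
  out$interferers <- rep(list(empty_interferers()), nrow(out))
  if (nrow(e) == 0L) return(out)

  # candidate precursors: co-isolated and co-eluting
  prec <- e[!duplicated(paste(e$peptide, e$precursor_charge, sep = "\r")),
            c("peptide", "precursor_charge", "precursor_mz", "rt_seconds"),
            drop = FALSE]
  in_range <- prec$precursor_mz >= scheme$start_mz &
    prec$precursor_mz < scheme$end_mz
  coiso <- vapply(seq_len(nrow(prec)), function(i) {
    in_range[i] && coisolated(scheme, a_mz, prec$precursor_mz[i],
                              cfg$cofragmentation_rule)
  }, logical(1))
  coelute <- abs(prec$rt_seconds - a_rt) <= cfg$coelution_tolerance
  cand <- prec[coiso & coelute, , drop = FALSE]
  if (nrow(cand) == 0L) return(out)

  cand_key <- paste(cand$peptide, cand$precursor_charge, sep = "\r")
  e_key <- paste(e$peptide, e$precursor_charge, sep = "\r")
  ef <- e[e_key %in% cand_key, , drop = FALSE]

  a_win <- windows_for_precursor(scheme, a_mz)
  win <- scheme_windows(scheme)
  for (j in seq_len(nrow(out))) {
    ppm <- abs(ef$fragment_mz - out$fragment_mz[j]) /
      out$fragment_mz[j] * 1e6
    hits <- which(ppm <= cfg$ppm_tolerance)
    if (length(hits) == 0L) next
    hit_rows <- ef[hits, , drop = FALSE]
    shared_win <- vapply(hit_rows$precursor_mz, function(mz) {
      intersect(a_win, windows_for_precursor(scheme, mz))[1L]
    }, numeric(1))
    out$interferers[[j]] <- data.frame(
      peptide = hit_rows$peptide,
      precursor_charge = hit_rows$precursor_charge,
      ion_series = hit_rows$ion_series,
      fragment_ordinal = hit_rows$fragment_ordinal,
      fragment_charge = hit_rows$fragment_charge,
      shared_window = as.integer(shared_win),
      ppm_distance = ppm[hits],
      delta_rt = hit_rows$rt_seconds - a_rt,
      stringsAsFactors = FALSE)
    out$flagged[j] <- TRUE
    out$n_interferers[j] <- length(hits)
  }
  out
}

empty_interferers <- function() {
  data.frame(peptide = character(0), precursor_charge = integer(0),
             ion_series = character(0), fragment_ordinal = integer(0),
             fragment_charge = integer(0), shared_window = integer(0),
             ppm_distance = numeric(0), delta_rt = numeric(0),
             stringsAsFactors = FALSE)
}

#' Interference flags for every precursor of a library
#'
#' Vectorized sweep of [find_cofragmenting()]'s rule over a whole library:
#' for each fragment, is there any other co-isolated, co-eluting precursor
#' with a fragment within the ppm tolerance?
#'
#' @param library A [spectral_library()].
#' @inheritParams find_cofragmenting
#' @return Data frame with peptide, precursor_charge, ion_series,
#'   fragment_ordinal, fragment_charge, flagged.
#' @export
flag_library_interference <- function(library, scheme = cfg$wide_scheme,
                                      cfg = pipeline_config()) {
  e <- library$entries
  out <- e[, c("peptide", "precursor_charge", "ion_series",
               "fragment_ordinal", "fragment_charge"), drop = FALSE]
  rownames(out) <- NULL
  out$flagged <- FALSE
  if (nrow(e) == 0L) return(out)
  prec_key <- paste(e$peptide, e$precursor_charge, sep = "\r")
  prec <- e[!duplicated(prec_key), , drop = FALSE]
  pk <- prec_key[!duplicated(prec_key)]
  in_range <- prec$precursor_mz >= scheme$start_mz &
    prec$precursor_mz < scheme$end_mz
  # window memberships (up to two per precursor)
  w1 <- w2 <- rep(NA_integer_, nrow(prec))
  for (i in which(in_range)) {
    w <- windows_for_precursor(scheme, prec$precursor_mz[i])
    w1[i] <- w[1L]
    if (length(w) > 1L) w2[i] <- w[2L]
  }
  half <- ifelse(in_range,
                 half_window_index(scheme, prec$precursor_mz),
                 NA_integer_)
  # fragment m/z ordered lookup for ppm neighbourhood queries
  ord <- order(e$fragment_mz)
  fmz_sorted <- e$fragment_mz[ord]
  fprec_sorted <- match(prec_key, pk)[ord]

  tol <- cfg$ppm_tolerance * 1e-6
  for (j in seq_len(nrow(e))) {
    mz <- e$fragment_mz[j]
    lo <- findInterval(mz * (1 - tol) * (1 - 1e-12), fmz_sorted) + 1L
    hi <- findInterval(mz * (1 + tol) * (1 + 1e-12), fmz_sorted)
    if (hi < lo) next
    sel <- (lo:hi)[abs(fmz_sorted[lo:hi] - mz) / mz * 1e6 <=
                     cfg$ppm_tolerance]
    if (length(sel) == 0L) next
    cand_prec <- fprec_sorted[sel]
    self <- match(prec_key[j], pk)
    cand_prec <- unique(cand_prec[cand_prec != self])
    if (length(cand_prec) == 0L) next
    if (!in_range[self]) next
    ok_rt <- abs(prec$rt_seconds[cand_prec] - e$rt_seconds[j]) <=
      cfg$coelution_tolerance
    if (cfg$cofragmentation_rule == "demultiplexed" && scheme$staggered) {
      ok_win <- !is.na(half[cand_prec]) & half[cand_prec] == half[self]
    } else {
      ok_win <- (!is.na(w1[cand_prec]) &
                   (w1[cand_prec] %in% c(w1[self], w2[self]))) |
        (!is.na(w2[cand_prec]) & (w2[cand_prec] %in% c(w1[self], w2[self])))
    }
    out$flagged[j] <- any(ok_rt & ok_win, na.rm = TRUE)
  }
  out
}

# Resample one trace onto a uniform grid (linear interpolation, zero
# outside the observed range).
resample_trace <- function(times, intensities, grid) {
  y <- stats::approx(times, intensities, xout = grid, rule = 1,
                     ties = mean)$y
  y[is.na(y)] <- 0
  y
}

#' Peak-shape correlation of fragment traces
#'
#' Scores how well each fragment trace of one precursor in one matrix
#' tracks the precursor's overall elution profile. All traces are
#' resampled to a shared uniform grid; the reference shape for a fragment
#' is the pointwise sum of the other fragments (leave-one-out, so a
#' dominant interfered ion cannot validate itself), and the score is the
#' Pearson correlation between the fragment and that reference.
#' Zero-variance traces score 0.
#'
#' @param traces Long data frame (chromatogram layout) holding >= 2
#'   fragment traces of a single precursor in a single run or matrix.
#' @param grid_step Resampling step in seconds (default 0.5).
#' @return Data frame: ion_series, fragment_ordinal, fragment_charge,
#'   correlation.
#' @export
peak_shape_correlation <- function(traces, grid_step = 0.5) {
  fkey <- fragment_key(traces$ion_series, traces$fragment_ordinal,
                       traces$fragment_charge)
  ukeys <- unique(fkey)
  if (length(ukeys) < 2L) {
    stop("insufficient traces: need >= 2 fragments", call. = FALSE)
  }
  grid <- seq(min(traces$time_sec), max(traces$time_sec), by = grid_step)
  mat <- vapply(ukeys, function(k) {
    idx <- fkey == k
    resample_trace(traces$time_sec[idx], traces$intensity[idx], grid)
  }, numeric(length(grid)))
  total <- rowSums(mat)
  corr <- vapply(seq_along(ukeys), function(j) {
    ref <- total - mat[, j]
    if (stats::sd(mat[, j]) == 0 || stats::sd(ref) == 0) return(0)
    stats::cor(mat[, j], ref)
  }, numeric(1))
  info <- traces[match(ukeys, fkey),
                 c("ion_series", "fragment_ordinal", "fragment_charge"),
                 drop = FALSE]
  rownames(info) <- NULL
  info$correlation <- corr
  info
}

#' Per-matrix fragment correlations for one precursor
#'
#' Averages [peak_shape_correlation()] over the runs of each matrix in
#' which the precursor has traces.
#'
#' @param chrom Long chromatogram data frame (all runs).
#' @param peptide,precursor_charge Precursor identity.
#' @param grid_step Resampling step (seconds).
#' @return Data frame: matrix_id, ion_series, fragment_ordinal,
#'   fragment_charge, correlation (mean over runs).
#' @export
matrix_fragment_correlations <- function(chrom, peptide, precursor_charge,
                                         grid_step = 0.5) {
  sel <- chrom[chrom$peptide == peptide &
                 chrom$precursor_charge == precursor_charge, , drop = FALSE]
  if (nrow(sel) == 0L) return(NULL)
  parts <- list()
  for (m in unique(sel$matrix_id)) {
    sm <- sel[sel$matrix_id == m, , drop = FALSE]
    per_run <- lapply(split(sm, sm$run_id), function(tr) {
      if (length(unique(fragment_key(tr$ion_series, tr$fragment_ordinal,
                                     tr$fragment_charge))) < 2L) return(NULL)
      peak_shape_correlation(tr, grid_step)
    })
    per_run <- Filter(Negate(is.null), per_run)
    if (length(per_run) == 0L) next
    allr <- do.call(rbind, per_run)
    agg <- stats::aggregate(
      correlation ~ ion_series + fragment_ordinal + fragment_charge,
      data = allr, FUN = mean)
    agg$matrix_id <- m
    parts[[m]] <- agg
  }
  if (length(parts) == 0L) return(NULL)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[, c("matrix_id", "ion_series", "fragment_ordinal", "fragment_charge",
          "correlation")]
}

#' Select the harmonized quantitative-ion set for one peptide
#'
#' Candidates are the fragments flagged in no matrix. They are ranked by
#' the aggregated cross-matrix peak-shape correlation (min over matrices by
#' default — the strictest reading of "interference-free in all matrices"),
#' ties broken by library intensity (descending) then fragment m/z
#' (ascending). The top `max_quant_ions` become quantitative; if fewer than
#' `min_quant_ions` candidates exist the peptide is not quantifiable and
#' every ion is detection-only.
#'
#' @param fragments Data frame of the peptide's template fragments:
#'   ion_series, fragment_ordinal, fragment_charge, fragment_mz,
#'   library_intensity.
#' @param flagged_any Logical vector (per fragment): flagged in at least
#'   one matrix.
#' @param correlations Data frame from [matrix_fragment_correlations()]
#'   (may be NULL: correlation 0 everywhere).
#' @param cfg A [pipeline_config()].
#' @return List: `decision` (data frame with quant_flag, aggregate
#'   correlation, flagged) and `quantifiable` (logical).
#' @export
select_quant_ions <- function(fragments, flagged_any, correlations = NULL,
                              cfg = pipeline_config()) {
  stopifnot(nrow(fragments) == length(flagged_any))
  fk <- fragment_key(fragments$ion_series, fragments$fragment_ordinal,
                     fragments$fragment_charge)
  aggfun <- if (cfg$correlation_aggregation == "min") min else mean
  aggr <- rep(0, nrow(fragments))
  if (!is.null(correlations) && nrow(correlations) > 0L) {
    ck <- fragment_key(correlations$ion_series,
                       correlations$fragment_ordinal,
                       correlations$fragment_charge)
    agg_by <- tapply(correlations$correlation, ck, aggfun)
    hit <- match(fk, names(agg_by))
    aggr[!is.na(hit)] <- unname(agg_by[hit[!is.na(hit)]])
  }
  cand <- which(!flagged_any)
  decision <- data.frame(fragments,
                         aggregate_correlation = aggr,
                         flagged = flagged_any,
                         quant_flag = "detection_only",
                         stringsAsFactors = FALSE)
  quantifiable <- length(cand) >= cfg$min_quant_ions
  if (quantifiable) {
    ord <- cand[order(-aggr[cand], -fragments$library_intensity[cand],
                      fragments$fragment_mz[cand])]
    take <- utils::head(ord, cfg$max_quant_ions)
    decision$quant_flag[take] <- "quant"
  }
  list(decision = decision, quantifiable = quantifiable)
}

#' Re-flag harmonized libraries with the naive intensity baseline
#'
#' Replaces every peptide's quant flags with the
#' [select_top_intensity_ions()] choice (most intense library fragments,
#' interference ignored). Used to benchmark the harmonized selection
#' against the conventional top-N-by-intensity rule.
#'
#' @param harmonized Named list of harmonized [spectral_library()].
#' @param cfg A [pipeline_config()].
#' @return The same list with quant flags reassigned.
#' @export
apply_naive_flags <- function(harmonized, cfg = pipeline_config()) {
  lapply(harmonized, function(lib) {
    e <- lib$entries
    for (p in unique(e$peptide)) {
      idx <- which(e$peptide == p)
      sel <- select_top_intensity_ions(e[idx, , drop = FALSE], cfg)
      e$quant_flag[idx] <- sel$decision$quant_flag
    }
    spectral_library(e, matrix_id = lib$matrix_id,
                     provenance = "naive-top-intensity", validate = FALSE)
  })
}

#' Naive intensity-based ion selection
#'
#' Baseline selector that ignores interference flags and correlations and
#' simply takes the `max_quant_ions` most intense library fragments. Used
#' to benchmark the harmonized selection.
#'
#' @inheritParams select_quant_ions
#' @return Same shape as [select_quant_ions()].
#' @export
select_top_intensity_ions <- function(fragments, cfg = pipeline_config()) {
  decision <- data.frame(fragments,
                         aggregate_correlation = NA_real_,
                         flagged = NA,
                         quant_flag = "detection_only",
                         stringsAsFactors = FALSE)
  ord <- order(-fragments$library_intensity, fragments$fragment_mz)
  take <- utils::head(ord, cfg$max_quant_ions)
  decision$quant_flag[take] <- "quant"
  list(decision = decision,
       quantifiable = nrow(fragments) >= cfg$min_quant_ions)
}
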