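# Assembly of the harmonized per-matrix libraries: one globally accepted
# peptide set, one fragmentation template per peptide (best-scoring
# matrix), matrix-specific retention times, shared quant/detection-only
# ion flags.

# Template fragment rows for one accepted peptide: the fragment rows of
# its best-scoring matrix, best-scoring charge state (ties: lowest charge).
extract_template <- function(library, peptide) {
  e <- library$entries[library$entries$peptide == peptide, , drop = FALSE]
  if (nrow(e) == 0L) return(NULL)
  prec <- e[!duplicated(e$precursor_charge),
            c("precursor_charge", "score"), drop = FALSE]
  z <- prec$precursor_charge[order(-prec$score, prec$precursor_charge)][1L]
  t <- e[e$precursor_charge == z, , drop = FALSE]
  t[order(t$fragment_mz), , drop = FALSE]
}

#' Run the complete harmonization stage
#'
#' Chains global FDR filtering, warp fitting, match-between-runs RT
#' imputation, cross-matrix interference flagging under the wide-window
#' scheme, peak-shape-correlation scoring (when chromatograms are given)
#' and quantitative-ion selection, then assembles one harmonized library
#' per matrix.
#'
#' @param libraries Named list of per-matrix [spectral_library()].
#' @param chromatograms Optional long chromatogram data frame used for
#'   peak-shape correlations; without it candidate ions are ranked by
#'   library intensity alone.
#' @param cfg A [pipeline_config()].
#' @param warps Optional precomputed warp table from [fit_all_warps()]
#'   (fitted on the fly when NULL).
#' @return List: `harmonized` (named list of harmonized
#'   [spectral_library()], each with a `template_source` attribute),
#'   `scored`, `accepted`, `warps`, `rt_assignments`, `ion_decisions`,
#'   `report`.
#' @export
harmonize <- function(libraries, chromatograms = NULL,
                      cfg = pipeline_config(), warps = NULL) {
  stopifnot(length(libraries) >= 1L, !is.null(names(libraries)))
  fdr <- detection_fdr(libraries, alpha = cfg$fdr_alpha)
  accepted <- fdr$accepted
  if (is.null(warps)) warps <- fit_all_warps(libraries)
  if (nrow(accepted) == 0L) {
    empty <- lapply(libraries, function(lib) {
      sl <- spectral_library(lib$entries[0L, , drop = FALSE],
                             matrix_id = lib$matrix_id,
                             provenance = "harmonized", validate = FALSE)
      attr(sl, "template_source") <- character(0)
      sl
    })
    return(list(harmonized = empty, scored = fdr$scored,
                accepted = accepted, warps = warps,
                rt_assignments = NULL, ion_decisions = NULL,
                report = harmonization_report(libraries, empty)))
  }
  rt_assign <- impute_missing_rts(accepted, libraries, warps)

  templates <- stats::setNames(
    lapply(seq_len(nrow(accepted)), function(i) {
      t <- extract_template(libraries[[accepted$best_matrix[i]]],
                            accepted$peptide[i])
      if (is.null(t)) {
        stop("integrity error: accepted peptide '", accepted$peptide[i],
             "' has no template in matrix '", accepted$best_matrix[i], "'",
             call. = FALSE)
      }
      t
    }), accepted$peptide)

  # per-matrix interference flags on the harmonized candidate libraries
  # (template fragments + matrix-specific, possibly imputed, RTs)
  flagged_keys <- character(0)
  cand_libs <- list()
  for (m in names(libraries)) {
    rt_m <- rt_assign[rt_assign$matrix_id == m, , drop = FALSE]
    rows <- do.call(rbind, lapply(accepted$peptide, function(p) {
      t <- templates[[p]]
      t$matrix_id <- m
      t$rt_seconds <- rt_m$rt_seconds[match(p, rt_m$peptide)]
      t$rt_origin <- rt_m$rt_origin[match(p, rt_m$peptide)]
      t
    }))
    cand <- spectral_library(rows, matrix_id = m, validate = FALSE)
    cand_libs[[m]] <- cand
    fl <- flag_library_interference(cand, cfg$wide_scheme, cfg)
    bad <- fl[fl$flagged, , drop = FALSE]
    flagged_keys <- union(flagged_keys,
                          paste(bad$peptide, bad$precursor_charge,
                                fragment_key(bad$ion_series,
                                             bad$fragment_ordinal,
                                             bad$fragment_charge)))
  }

  # ion decisions per peptide
  decisions <- vector("list", nrow(accepted))
  for (i in seq_len(nrow(accepted))) {
    p <- accepted$peptide[i]
    t <- templates[[p]]
    keys <- paste(t$peptide, t$precursor_charge,
                  fragment_key(t$ion_series, t$fragment_ordinal,
                               t$fragment_charge))
    corr <- if (!is.null(chromatograms)) {
      matrix_fragment_correlations(chromatograms, p,
                                   t$precursor_charge[1L])
    } else NULL
    sel <- select_quant_ions(
      t[, c("ion_series", "fragment_ordinal", "fragment_charge",
            "fragment_mz", "library_intensity")],
      flagged_any = keys %in% flagged_keys,
      correlations = corr, cfg = cfg)
    d <- sel$decision
    d$peptide <- p
    d$precursor_charge <- t$precursor_charge[1L]
    d$quantifiable <- sel$quantifiable
    decisions[[i]] <- d
  }
  ion_decisions <- do.call(rbind, decisions)
  rownames(ion_decisions) <- NULL

  # assemble the harmonized libraries
  dec_key <- paste(ion_decisions$peptide,
                   fragment_key(ion_decisions$ion_series,
                                ion_decisions$fragment_ordinal,
                                ion_decisions$fragment_charge))
  harmonized <- stats::setNames(vector("list", length(libraries)),
                                names(libraries))
  for (m in names(libraries)) {
    rows <- cand_libs[[m]]$entries
    rk <- paste(rows$peptide, fragment_key(rows$ion_series,
                                           rows$fragment_ordinal,
                                           rows$fragment_charge))
    rows$quant_flag <- ion_decisions$quant_flag[match(rk, dec_key)]
    rows$is_decoy <- FALSE
    rows <- rows[order(rows$peptide, rows$precursor_charge,
                       rows$fragment_mz), , drop = FALSE]
    rownames(rows) <- NULL
    sl <- spectral_library(rows, matrix_id = m, provenance = "harmonized",
                           validate = FALSE)
    attr(sl, "template_source") <- stats::setNames(accepted$best_matrix,
                                                   accepted$peptide)
    harmonized[[m]] <- sl
  }
  list(harmonized = harmonized, scored = fdr$scored, accepted = accepted,
       warps = warps, rt_assignments = rt_assign,
       ion_decisions = ion_decisions,
       report = harmonization_report(libraries, harmonized))
}

#' Build harmonized libraries from precomputed stage outputs
#'
#' Lower-level assembly entry point mirroring the pipeline contract:
#' given accepted peptides, fitted warps and ion decisions, produce the
#' per-matrix harmonized libraries. [harmonize()] wraps this together with
#' the upstream stages.
#'
#' @param libraries Named list of input [spectral_library()].
#' @param accepted Accepted peptides ([global_filter()] output).
#' @param warps Warp table ([fit_all_warps()]).
#' @param ion_decisions Ion decision table (as produced by [harmonize()]);
#'   NULL leaves quant flags "unset".
#' @param cfg A [pipeline_config()].
#' @return Named list of harmonized [spectral_library()].
#' @export
build_harmonized_libraries <- function(libraries, accepted, warps,
                                       ion_decisions = NULL,
                                       cfg = pipeline_config()) {
  rt_assign <- impute_missing_rts(accepted, libraries, warps)
  out <- stats::setNames(vector("list", length(libraries)),
                         names(libraries))
  dec_key <- NULL
  if (!is.null(ion_decisions)) {
    dec_key <- paste(ion_decisions$peptide,
                     fragment_key(ion_decisions$ion_series,
                                  ion_decisions$fragment_ordinal,
                                  ion_decisions$fragment_charge))
  }
  for (m in names(libraries)) {
    rt_m <- rt_assign[rt_assign$matrix_id == m, , drop = FALSE]
    rows <- do.call(rbind, lapply(seq_len(nrow(accepted)), function(i) {
      p <- accepted$peptide[i]
      t <- extract_template(libraries[[accepted$best_matrix[i]]], p)
      if (is.null(t)) {
        stop("integrity error: accepted peptide '", p,
             "' lacks a template", call. = FALSE)
      }
      t$matrix_id <- m
      t$rt_seconds <- rt_m$rt_seconds[match(p, rt_m$peptide)]
      t$rt_origin <- rt_m$rt_origin[match(p, rt_m$peptide)]
      t$is_decoy <- FALSE
      if (!is.null(dec_key)) {
        rk <- paste(t$peptide, fragment_key(t$ion_series,
                                            t$fragment_ordinal,
                                            t$fragment_charge))
        t$quant_flag <- ion_decisions$quant_flag[match(rk, dec_key)]
      }
      t
    }))
    rows <- rows[order(rows$peptide, rows$precursor_charge,
                       rows$fragment_mz), , drop = FALSE]
    rownames(rows) <- NULL
    sl <- spectral_library(rows, matrix_id = m, provenance = "harmonized",
                           validate = FALSE)
    attr(sl, "template_source") <- stats::setNames(accepted$best_matrix,
                                                   accepted$peptide)
    out[[m]] <- sl
  }
  out
}

#' Harmonization summary report
#'
#' Per matrix: target peptides before and after harmonization, fraction of
#' imputed retention times, fraction of non-quantifiable peptides, and the
#' number of peptides whose fragmentation template came from this matrix.
#'
#' @param before Named list of input [spectral_library()].
#' @param after Named list of harmonized [spectral_library()].
#' @return Data frame with one row per matrix (zero rows when the
#'   harmonized libraries are empty).
#' @export
harmonization_report <- function(before, after) {
  rows <- lapply(names(after), function(m) {
    e_b <- before[[m]]$entries
    e_a <- after[[m]]$entries
    if (nrow(e_a) == 0L) return(NULL)
    pep_a <- unique(e_a$peptide)
    per_pep_quant <- tapply(e_a$quant_flag == "quant", e_a$peptide, any)
    per_pep_imputed <- tapply(e_a$rt_origin == "imputed", e_a$peptide, any)
    src <- attr(after[[m]], "template_source")
    data.frame(
      matrix_id = m,
      peptides_before = length(unique(e_b$peptide[!e_b$is_decoy])),
      peptides_after = length(pep_a),
      frac_imputed_rt = mean(per_pep_imputed),
      frac_nonquant = mean(!per_pep_quant),
      templates_from = if (is.null(src)) NA_integer_ else
        sum(unname(src) == m),
      stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(matrix_id = character(0),
                      peptides_before = integer(0),
                      peptides_after = integer(0),
                      frac_imputed_rt = numeric(0),
                      frac_nonquant = numeric(0),
                      templates_from = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
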