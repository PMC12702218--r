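# Global peptide-level false-discovery-rate control across matrices:
# best-evidence picking ("best-scoring biofluid"), conservative target-decoy
# q-value estimation, and the global acceptance filter.

# Precursor-level rows (one per peptide/charge) from a library or a list of
# libraries; also accepts a pre-built data frame with the needed columns.
as_precursor_table <- function(libraries) {
  if (is.data.frame(libraries)) {
    stopifnot(all(c("peptide", "matrix_id", "score", "is_decoy") %in%
                    names(libraries)))
    return(libraries)
  }
  if (inherits(libraries, "spectral_library")) libraries <- list(libraries)
  do.call(rbind, lapply(libraries, function(lib) {
    e <- lib$entries
    e[!duplicated(paste(e$peptide, e$precursor_charge, sep = "\r")),
      intersect(names(e), c("peptide", "precursor_charge", "precursor_mz",
                            "matrix_id", "score", "is_decoy",
                            "rt_seconds")),
      drop = FALSE]
  }))
}

#' Pick the best evidence per peptide across matrices
#'
#' Collapses per-matrix library entries to one record per unique peptide
#' string, keeping the maximal score over all matrices and charge states
#' ("best-scoring biofluid"). Exact score ties between matrices are broken
#' by ascending lexicographic matrix_id for determinism.
#'
#' @param libraries List of [spectral_library()] objects (or a precursor
#'   data frame with columns peptide, matrix_id, score, is_decoy).
#' @return Data frame with one row per peptide: peptide, best_matrix,
#'   best_score, is_decoy (and q_value once [compute_qvalues()] has run).
#' @export
pick_best_evidence <- function(libraries) {
  tab <- as_precursor_table(libraries)
  if (nrow(tab) == 0L) stop("no library entries", call. = FALSE)
  u <- unique(tab[, c("peptide", "is_decoy")])
  if (anyDuplicated(u$peptide) > 0L) {
    bad <- u$peptide[duplicated(u$peptide)][1L]
    stop("integrity error: peptide '", bad,
         "' is target in one library and decoy in another", call. = FALSE)
  }
  ord <- order(tab$peptide, -tab$score, tab$matrix_id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  best <- tab[!duplicated(tab$peptide), , drop = FALSE]
  out <- data.frame(peptide = best$peptide, best_matrix = best$matrix_id,
                    best_score = best$score, is_decoy = best$is_decoy,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$peptide, method = "radix"), , drop = FALSE]
}

#' Target-decoy q-values
#'
#' Conservative competition estimator: at score threshold t,
#' \eqn{\widehat{FDR}(t) = (1 + \#\{decoys \ge t\}) / \#\{targets \ge t\}},
#' and the q-value of score s is the minimum of \eqn{\widehat{FDR}(t)} over
#' all thresholds \eqn{t \le s}, capped at 1. q-values are therefore
#' non-increasing in score.
#'
#' @param peptides Data frame from [pick_best_evidence()] (columns
#'   best_score, is_decoy; any extra columns pass through).
#' @return The same data frame with a `q_value` column (decoys receive the
#'   q-value of their score threshold too).
#' @export
compute_qvalues <- function(peptides) {
  stopifnot(is.data.frame(peptides),
            all(c("best_score", "is_decoy") %in% names(peptides)))
  if (!any(!peptides$is_decoy)) {
    stop("q-value estimation needs at least one target", call. = FALSE)
  }
  if (!any(peptides$is_decoy)) {
    warning("no decoys present; q-values use the +1 numerator only")
  }
  s <- peptides$best_score
  d <- peptides$is_decoy
  ord <- order(s)  # ascending score
  s_sorted <- s[ord]
  # counts at threshold t = s_i (inclusive >=): suffix sums over sorted order
  n <- length(s)
  dec_suffix <- rev(cumsum(rev(d[ord])))
  tgt_suffix <- rev(cumsum(rev(!d[ord])))
  # tie handling: at equal scores the threshold counts everything >= score
  first_of_tie <- !duplicated(s_sorted)
  tie_group <- cumsum(first_of_tie)
  dec_ge <- dec_suffix[first_of_tie][tie_group]
  tgt_ge <- tgt_suffix[first_of_tie][tie_group]
  fdr <- ifelse(tgt_ge > 0, (1 + dec_ge) / tgt_ge, Inf)
  # q(s) = min over thresholds t <= s  => running min from the low end
  q_sorted <- pmin(cummin(fdr), 1)
  q <- numeric(n)
  q[ord] <- q_sorted
  peptides$q_value <- q
  peptides
}

#' Globally accepted peptide set
#'
#' Target peptides whose q-value is at most `alpha`; decoys are never
#' returned. Idempotent and order-independent.
#'
#' @param peptides Data frame with q_value from [compute_qvalues()].
#' @param alpha FDR threshold (default 0.01).
#' @return Subset of `peptides` (targets with q_value <= alpha).
#' @export
global_filter <- function(peptides, alpha = 0.01) {
  stopifnot("q_value" %in% names(peptides))
  out <- peptides[!peptides$is_decoy & peptides$q_value <= alpha, ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full global FDR stage
#'
#' Convenience wrapper: best evidence, q-values, filter.
#'
#' @param libraries List of [spectral_library()].
#' @param alpha FDR threshold.
#' @return List with `scored` (all peptides with q-values) and `accepted`
#'   (the filtered targets).
#' @export
detection_fdr <- function(libraries, alpha = 0.01) {
  scored <- compute_qvalues(pick_best_evidence(libraries))
  list(scored = scored, accepted = global_filter(scored, alpha))
}
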