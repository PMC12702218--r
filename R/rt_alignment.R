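# Retention-time calibration between matrices: kernel-density warp fitting
# (binned conditional modes + isotonic regression), warp evaluation, and
# match-between-runs RT imputation for peptides missing from a matrix.

#' Fit a kernel-density retention-time warp
#'
#' Robust monotone map from one matrix's RT space to another's, fitted on
#' anchor peptides identified in both. Procedure: (1) bin source RTs on a
#' uniform grid; (2) within each bin, estimate the Gaussian kernel density
#' of the target RTs (Silverman's rule bandwidth when `"auto"`) and take
#' its mode; (3) force monotonicity across bin modes by isotonic
#' regression; (4) evaluation is linear interpolation between the resulting
#' knots, with linear extrapolation beyond the end knots. The conditional
#' mode makes the fit resistant to outlying anchors. The residual scale is
#' the MAD (x 1.4826) of anchors about the fitted warp.
#'
#' @param rt_source,rt_target Anchor retention times in seconds (equal
#'   length, >= 20 pairs).
#' @param bandwidth Kernel bandwidth in seconds, or `"auto"` for
#'   Silverman's rule per bin.
#' @param n_bins Number of uniform source-RT bins (default 64).
#' @param source_matrix,target_matrix Optional matrix labels stored on the
#'   warp.
#' @return Object of class `rt_warp` with `knots` (data frame source,
#'   target) and `residual_sd` (seconds).
#' @export
fit_kde_warp <- function(rt_source, rt_target, bandwidth = "auto",
                         n_bins = 64L, source_matrix = NA_character_,
                         target_matrix = NA_character_) {
  stopifnot(length(rt_source) == length(rt_target))
  keep <- is.finite(rt_source) & is.finite(rt_target)
  rt_source <- rt_source[keep]; rt_target <- rt_target[keep]
  if (length(rt_source) < 20L) {
    stop("insufficient anchors: need >= 20 shared peptides, got ",
         length(rt_source), call. = FALSE)
  }
  rng <- range(rt_source)
  if (diff(rng) <= 0 || stats::sd(rt_target) == 0) {
    stop("degenerate anchors: zero retention-time variance", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(rt_source, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  modes <- rep(NA_real_, n_bins)
  for (b in unique(bin)) {
    y <- rt_target[bin == b]
    if (length(y) < 3L) {
      if (length(y) >= 1L) modes[b] <- stats::median(y)
      next
    }
    bw <- if (identical(bandwidth, "auto")) {
      bwv <- stats::bw.nrd0(y)
      if (!is.finite(bwv) || bwv <= 0) 1 else bwv
    } else as.numeric(bandwidth)
    dens <- stats::density(y, bw = bw, n = 256L)
    modes[b] <- dens$x[which.max(dens$y)]
  }
  ok <- which(!is.na(modes))
  if (length(ok) < 2L) stop("degenerate anchors: too few occupied bins",
                            call. = FALSE)
  iso <- stats::isoreg(centers[ok], modes[ok])
  knots <- data.frame(source = centers[ok], target = iso$yf)
  warp <- structure(list(source_matrix = source_matrix,
                         target_matrix = target_matrix,
                         knots = knots, residual_sd = NA_real_,
                         n_anchors = length(rt_source)),
                    class = "rt_warp")
  resid <- rt_target - predict_rt(warp, rt_source)
  warp$residual_sd <- stats::median(abs(resid - stats::median(resid))) *
    1.4826
  warp
}

#' @export
print.rt_warp <- function(x, ...) {
  cat(sprintf(
    "<rt_warp> %s -> %s: %d knots over [%.0f, %.0f] s, residual sd %.1f s (%d anchors)\n",
    x$source_matrix, x$target_matrix, nrow(x$knots), min(x$knots$source),
    max(x$knots$source), x$residual_sd, x$n_anchors))
  invisible(x)
}

#' Identity warp
#'
#' @param source_matrix,target_matrix Matrix labels.
#' @param span RT range covered by the two knots (seconds).
#' @return An `rt_warp` mapping every RT to itself.
#' @export
identity_warp <- function(source_matrix = NA_character_,
                          target_matrix = NA_character_, span = c(0, 6000)) {
  structure(list(source_matrix = source_matrix,
                 target_matrix = target_matrix,
                 knots = data.frame(source = span, target = span),
                 residual_sd = 0, n_anchors = 0L),
            class = "rt_warp")
}

#' Evaluate a retention-time warp
#'
#' Linear interpolation between knots; beyond the end knots the map
#' extrapolates linearly with the slope of the terminal segment. Monotone
#' and continuous by construction.
#'
#' @param warp An `rt_warp`.
#' @param rt_source Source retention times (seconds, >= 0).
#' @return Predicted target retention times (seconds).
#' @export
predict_rt <- function(warp, rt_source) {
  stopifnot(inherits(warp, "rt_warp"))
  if (any(rt_source < 0, na.rm = TRUE)) {
    stop("negative retention time", call. = FALSE)
  }
  kx <- warp$knots$source; ky <- warp$knots$target
  n <- length(kx)
  out <- stats::approx(kx, ky, xout = rt_source, rule = 2, ties = mean)$y
  lo <- rt_source < kx[1L]
  hi <- rt_source > kx[n]
  if (any(lo)) {
    slope <- (ky[2L] - ky[1L]) / (kx[2L] - kx[1L])
    out[lo] <- ky[1L] + slope * (rt_source[lo] - kx[1L])
  }
  if (any(hi)) {
    slope <- (ky[n] - ky[n - 1L]) / (kx[n] - kx[n - 1L])
    out[hi] <- ky[n] + slope * (rt_source[hi] - kx[n])
  }
  out
}

#' @export
predict.rt_warp <- function(object, newdata, ...) predict_rt(object, newdata)

#' Fit warps between all matrix pairs
#'
#' Anchors are peptides identified in both matrices (decoys excluded,
#' non-interference use of the precursor-level RTs). Pairs with fewer than
#' `min_anchors` shared peptides get no direct warp.
#'
#' @param libraries Named list of [spectral_library()].
#' @param min_anchors Minimum shared peptides (default 20).
#' @param bandwidth,n_bins Passed to [fit_kde_warp()].
#' @return Nested list `warps[[source]][[target]]` of `rt_warp` objects.
#' @export
fit_all_warps <- function(libraries, min_anchors = 20L, bandwidth = "auto",
                          n_bins = 64L) {
  prec <- lapply(libraries, function(lib) {
    e <- lib$entries
    e <- e[!e$is_decoy, , drop = FALSE]
    e <- e[!duplicated(e$peptide), c("peptide", "rt_seconds"), drop = FALSE]
    e
  })
  ids <- names(libraries)
  warps <- stats::setNames(lapply(ids, function(i)
    stats::setNames(vector("list", length(ids)), ids)), ids)
  for (src in ids) {
    for (dst in ids) {
      if (src == dst) {
        warps[[src]][[dst]] <- identity_warp(src, dst)
        next
      }
      shared <- merge(prec[[src]], prec[[dst]], by = "peptide")
      if (nrow(shared) < min_anchors) next
      warps[[src]][[dst]] <- fit_kde_warp(
        shared$rt_seconds.x, shared$rt_seconds.y, bandwidth = bandwidth,
        n_bins = n_bins, source_matrix = src, target_matrix = dst)
    }
  }
  warps
}

# Direct or composed warp prediction src -> dst. Composition routes
# through the intermediate matrix with the most anchors on both legs.
warp_route_predict <- function(warps, src, dst, rt) {
  direct <- warps[[src]][[dst]]
  if (!is.null(direct)) return(predict_rt(direct, rt))
  mids <- setdiff(names(warps), c(src, dst))
  best_mid <- NULL; best_n <- -1L
  for (mid in mids) {
    w1 <- warps[[src]][[mid]]; w2 <- warps[[mid]][[dst]]
    if (is.null(w1) || is.null(w2)) next
    n <- min(w1$n_anchors, w2$n_anchors)
    if (n > best_n) { best_n <- n; best_mid <- mid }
  }
  if (is.null(best_mid)) return(NULL)
  predict_rt(warps[[best_mid]][[dst]],
             pmax(0, predict_rt(warps[[src]][[best_mid]], rt)))
}

#' Match-between-runs retention-time imputation
#'
#' Gives every accepted peptide a retention time in every matrix: observed
#' RTs are kept untouched (`rt_origin = "observed"`); a peptide missing
#' from a matrix receives the prediction of the warp from its best-scoring
#' matrix (`rt_origin = "imputed"`), composing through a third matrix when
#' no direct warp exists.
#'
#' @param accepted Data frame from [global_filter()] (columns peptide,
#'   best_matrix).
#' @param libraries Named list of [spectral_library()].
#' @param warps Warp table from [fit_all_warps()].
#' @return Data frame: peptide, matrix_id, rt_seconds, rt_origin.
#' @export
impute_missing_rts <- function(accepted, libraries, warps) {
  ids <- names(libraries)
  obs <- lapply(libraries, function(lib) {
    e <- lib$entries[!duplicated(lib$entries$peptide), , drop = FALSE]
    stats::setNames(e$rt_seconds, e$peptide)
  })
  out <- vector("list", length(ids))
  names(out) <- ids
  for (m in ids) {
    rt_obs <- unname(obs[[m]][accepted$peptide])
    have <- !is.na(rt_obs)
    rt <- rt_obs
    origin <- ifelse(have, "observed", "imputed")
    miss <- which(!have)
    if (length(miss) > 0L) {
      for (src in unique(accepted$best_matrix[miss])) {
        rows <- miss[accepted$best_matrix[miss] == src]
        src_rt <- obs[[src]][accepted$peptide[rows]]
        pred <- warp_route_predict(warps, src, m, unname(src_rt))
        if (is.null(pred)) {
          stop("unimputable: no warp path from '", src, "' to '", m,
               "' for peptides ",
               paste(utils::head(accepted$peptide[rows], 5L),
                     collapse = ", "), call. = FALSE)
        }
        rt[rows] <- pmax(0, pred)
      }
    }
    out[[m]] <- data.frame(peptide = accepted$peptide, matrix_id = m,
                           rt_seconds = rt, rt_origin = origin,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize warps to JSON
#'
#' @param warps Nested warp list from [fit_all_warps()].
#' @param path Output JSON path.
#' @export
write_warps <- function(warps, path) {
  out <- lapply(warps, function(row) {
    lapply(Filter(Negate(is.null), row), function(w) {
      list(source_matrix = w$source_matrix, target_matrix = w$target_matrix,
           knots = w$knots, residual_sd = w$residual_sd,
           n_anchors = w$n_anchors)
    })
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
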