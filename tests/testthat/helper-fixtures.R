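# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulated experiment reused by several files (cached per session).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_true_peptides = 150L,
                               n_false_targets = 100L, n_decoys = 250L,
                               n_interference_pairs = 10L,
                               runs_per_matrix = 4L, seed = 11L)
      cache <<- simulate_experiment(cfg)
    }
    cache
  }
})

# Minimal hand-built library data frame: one row per fragment.
make_entries <- function(peptide, charge, mz, score, decoy, rt, frag_mz,
                         frag_int = rep(100, length(frag_mz)),
                         matrix_id = "urine",
                         ion_series = rep("y", length(frag_mz)),
                         ordinal = seq_along(frag_mz) + 1L,
                         frag_charge = rep(1L, length(frag_mz))) {
  data.frame(matrix_id = matrix_id, peptide = peptide,
             precursor_charge = charge, precursor_mz = mz, score = score,
             is_decoy = decoy, rt_seconds = rt, rt_origin = "observed",
             ion_series = ion_series, fragment_ordinal = ordinal,
             fragment_charge = frag_charge, fragment_mz = frag_mz,
             library_intensity = frag_int, quant_flag = "unset",
             stringsAsFactors = FALSE)
}

# Gaussian trace sampled on a regular grid.
gaussian_trace <- function(run_id, matrix_id, peptide, charge, series,
                           ordinal, fcharge, apex, sigma = 6,
                           amplitude = 100, step = 0.5, halfwidth = 4) {
  tt <- seq(apex - halfwidth * sigma, apex + halfwidth * sigma, by = step)
  data.frame(run_id = run_id, matrix_id = matrix_id, peptide = peptide,
             precursor_charge = charge, ion_series = series,
             fragment_ordinal = ordinal, fragment_charge = fcharge,
             time_sec = tt,
             intensity = amplitude * exp(-(tt - apex)^2 / (2 * sigma^2)),
             stringsAsFactors = FALSE)
}

# Random transition-list library with deliberate near-collisions in
# fragment m/z, for interference-oracle equivalence studies. Independent
# of the simulator's mass arithmetic.
random_library <- function(n_prec, matrix_id = "urine",
                           gradient = 5400, n_frag = 6L,
                           collision_fraction = 0.3) {
  pep <- sprintf("PEP%05d", seq_len(n_prec))
  mz <- stats::runif(n_prec, 401, 999)
  rt <- stats::runif(n_prec, 0, gradient)
  frag_mz <- matrix(stats::runif(n_prec * n_frag, 200, 1200), n_prec)
  # force some cross-precursor fragment collisions within ~5 ppm
  n_coll <- round(collision_fraction * n_prec)
  if (n_coll > 0) {
    src <- sample(n_prec, n_coll, replace = TRUE)
    dst <- sample(n_prec, n_coll, replace = TRUE)
    keep <- src != dst
    src <- src[keep]; dst <- dst[keep]
    jf <- sample(n_frag, length(src), replace = TRUE)
    kf <- sample(n_frag, length(src), replace = TRUE)
    frag_mz[cbind(dst, kf)] <- frag_mz[cbind(src, jf)] *
      (1 + stats::runif(length(src), -5e-6, 5e-6))
  }
  rows <- data.frame(
    matrix_id = matrix_id,
    peptide = rep(pep, each = n_frag),
    precursor_charge = 2L,
    precursor_mz = rep(mz, each = n_frag),
    score = 1,
    is_decoy = FALSE,
    rt_seconds = rep(rt, each = n_frag),
    rt_origin = "observed",
    ion_series = "y",
    fragment_ordinal = rep(seq_len(n_frag) + 1L, n_prec),
    fragment_charge = 1L,
    fragment_mz = as.vector(t(frag_mz)),
    library_intensity = 100,
    quant_flag = "unset", stringsAsFactors = FALSE)
  spectral_library(rows, matrix_id = matrix_id, validate = FALSE)
}

# Brute-force all-pairs interference oracle: enumerates every precursor
# pair through outer() matrices (window sharing, co-elution) and then
# checks every fragment pair of the surviving precursor pairs. Returns
# the set of flagged fragment identifiers "peptide charge key".
oracle_interference <- function(library, scheme, cfg) {
  e <- library$entries
  pk <- paste(e$peptide, e$precursor_charge, sep = "\r")
  prec <- e[!duplicated(pk), , drop = FALSE]
  n <- nrow(prec)
  win <- lapply(seq_len(n), function(i) {
    if (prec$precursor_mz[i] < scheme$start_mz ||
        prec$precursor_mz[i] >= scheme$end_mz) return(integer(0))
    windows_for_precursor(scheme, prec$precursor_mz[i])
  })
  if (cfg$cofragmentation_rule == "demultiplexed" && scheme$staggered) {
    hw <- floor((prec$precursor_mz - scheme$start_mz) /
                  (scheme$window_width / 2))
    share <- outer(hw, hw, "==") &
      outer(lengths(win) > 0, lengths(win) > 0, "&")
  } else {
    # precursor x window membership matrix; a pair shares a window iff the
    # product of memberships is positive (all pairs enumerated)
    n_win <- nrow(scheme_windows(scheme))
    memb <- matrix(0L, n, n_win)
    for (i in seq_len(n)) memb[i, win[[i]]] <- 1L
    share <- (memb %*% t(memb)) > 0
  }
  coel <- abs(outer(prec$rt_seconds, prec$rt_seconds, "-")) <=
    cfg$coelution_tolerance
  cand <- share & coel
  diag(cand) <- FALSE
  upk <- pk[!duplicated(pk)]
  frag_by_prec <- split(seq_len(nrow(e)), match(pk, upk))
  flagged <- character(0)
  for (i in seq_len(n)) {
    others <- which(cand[i, ])
    if (length(others) == 0L) next
    fi <- frag_by_prec[[i]]
    other_mz <- e$fragment_mz[unlist(frag_by_prec[others])]
    for (r in fi) {
      ppm <- abs(other_mz - e$fragment_mz[r]) / e$fragment_mz[r] * 1e6
      if (any(ppm <= cfg$ppm_tolerance)) {
        flagged <- c(flagged,
                     paste(e$peptide[r], e$precursor_charge[r],
                           fragment_key(e$ion_series[r],
                                        e$fragment_ordinal[r],
                                        e$fragment_charge[r])))
      }
    }
  }
  unique(flagged)
}

flagged_set <- function(flags) {
  f <- flags[flags$flagged, , drop = FALSE]
  unique(paste(f$peptide, f$precursor_charge,
               fragment_key(f$ion_series, f$fragment_ordinal,
                            f$fragment_charge)))
}
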