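# Synthetic multi-matrix DIA experiments with known ground truth: tryptic
# peptides with real monoisotopic fragment ladders, matrix-specific monotone
# RT warps, target/decoy score mixtures, Gaussian elution profiles with
# multiplicative noise, injected co-isolating interferers, and per-protein
# group fold-changes.

#' Simulation configuration
#'
#' Defines one synthetic multi-matrix experiment. Defaults emulate a
#' three-biofluid study: urine, plasma and serum pools measured over a
#' 90-minute gradient (5400 s), eight paired runs per matrix split into two
#' groups, urine detecting more of the proteome than the blood matrices.
#'
#' @param n_true_peptides Number of genuinely present target peptides.
#' @param n_false_targets Target peptides with null (noise) scores.
#' @param n_decoys Decoy entries; scores share the null component with
#'   false targets (the standard target-decoy assumption).
#' @param matrices Matrix labels.
#' @param detection_probability Named per-matrix probability that a true
#'   peptide is identified in that matrix's library.
#' @param score_true,score_null Mean/sd of the Gaussian score components
#'   for true targets and for false targets + decoys.
#' @param gradient_length Gradient length in seconds.
#' @param warp_params Per-matrix retention-time warp (affine plus
#'   low-amplitude sinusoid): `slope * t + intercept + amplitude *
#'   sin(t / period)`; must be strictly monotone
#'   (`slope > amplitude / period`).
#' @param rt_jitter_sd Gaussian RT jitter (seconds) added on top of the
#'   warp, both in libraries and per-run apexes.
#' @param peak_sigma Gaussian elution peak sigma in seconds.
#' @param noise_sd Multiplicative (log-normal) intensity noise, as sd of
#'   the log.
#' @param sample_step Chromatogram sampling step in seconds.
#' @param n_interference_pairs Injected co-isolating interferer pairs.
#' @param interference_on_spiked Force interfered analytes onto spiked
#'   (fold-changing) proteins and their interferers onto unspiked ones, so
#'   interference demonstrably distorts relative quantification.
#' @param runs_per_matrix Runs (subjects) per matrix; subject k is paired
#'   across matrices, first half group "A", second half group "B".
#' @param fraction_spiked Fraction of proteins carrying the group
#'   fold-change.
#' @param fold_change Linear fold change of spiked proteins in group "B".
#' @param peptides_per_protein True peptides mapped to each protein.
#' @param seed Integer RNG seed; everything is deterministic given it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_true_peptides = 200L, n_false_targets = 200L, n_decoys = 400L,
    matrices = c("urine", "plasma", "serum"),
    detection_probability = c(urine = 0.9, plasma = 0.75, serum = 0.75),
    score_true = c(mean = 3.5, sd = 1),
    score_null = c(mean = 0, sd = 1),
    gradient_length = 5400,
    warp_params = list(
      urine = list(slope = 1.00, intercept = 0, amplitude = 0, period = 1500),
      plasma = list(slope = 0.97, intercept = 60, amplitude = 20, period = 1500),
      serum = list(slope = 1.03, intercept = -40, amplitude = 25, period = 1200)),
    rt_jitter_sd = 3,
    peak_sigma = 6,
    noise_sd = 0.1,
    sample_step = 2,
    n_interference_pairs = 15L,
    interference_on_spiked = FALSE,
    runs_per_matrix = 8L,
    fraction_spiked = 0.1,
    fold_change = 2,
    peptides_per_protein = 3L,
    seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  cfg$n_true_peptides <- as.integer(n_true_peptides)
  cfg$n_false_targets <- as.integer(n_false_targets)
  cfg$n_decoys <- as.integer(n_decoys)
  cfg$n_interference_pairs <- as.integer(n_interference_pairs)
  cfg$runs_per_matrix <- as.integer(runs_per_matrix)
  cfg$seed <- as.integer(seed)
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (!all(cfg$matrices %in% names(cfg$detection_probability))) {
    config_stop("config error: detection_probability missing for some matrices")
  }
  p <- cfg$detection_probability[cfg$matrices]
  if (any(p <= 0 | p > 1)) {
    config_stop("config error: detection probabilities must lie in (0, 1]")
  }
  if (!all(cfg$matrices %in% names(cfg$warp_params))) {
    config_stop("config error: warp_params missing for some matrices")
  }
  for (m in cfg$matrices) {
    w <- cfg$warp_params[[m]]
    if (w$slope <= abs(w$amplitude) / w$period) {
      config_stop("config error: warp for '", m, "' is not strictly monotone")
    }
  }
  if (2L * cfg$n_interference_pairs > cfg$n_true_peptides) {
    config_stop("config error: n_interference_pairs exceeds available true peptides")
  }
  invisible(cfg)
}

# Evaluate one matrix warp (true simulated warp, not the fitted one).
warp_eval <- function(wp, t) {
  wp$slope * t + wp$intercept + wp$amplitude * sin(t / wp$period)
}

# Invert the true warp numerically (monotone, so uniroot is safe).
warp_invert <- function(wp, y) {
  vapply(y, function(yy) {
    stats::uniroot(function(t) warp_eval(wp, t) - yy,
                   interval = c(-1e4, 2e4), tol = 1e-6)$root
  }, numeric(1))
}

#' Generate one tryptic-like peptide and its fragment ladder
#'
#' Random residue string of length 7-25 ending in K or R, with no internal
#' K/R (fully tryptic) and cysteines written carbamidomethylated in
#' bracketed-mass notation. Uses the session RNG.
#'
#' @return List with `peptide` (sequence string) and `ladder` (data frame
#'   from [fragment_ladder()], singly charged).
#' @export
make_peptide <- function() {
  len <- sample(7:25, 1L)
  aas <- setdiff(names(residue_masses()), c("K", "R"))
  body <- sample(aas, len - 1L, replace = TRUE)
  seq_plain <- paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
  seq_mod <- gsub("C", "C[+57.021464]", seq_plain, fixed = TRUE)
  list(peptide = seq_mod, ladder = fragment_ladder(seq_mod))
}

# A precursor whose m/z (charge 2 or 3) lands inside the scheme range,
# with its library fragment subset and base intensities.
make_precursor <- function(scheme, n_frag_range = c(6L, 10L)) {
  repeat {
    mp <- make_peptide()
    for (z in sample(2:3)) {
      mz <- precursor_mz_of(mp$peptide, z)
      if (mz >= scheme$start_mz && mz < scheme$end_mz) {
        lad <- mp$ladder
        lad <- lad[lad$ordinal >= 2 & lad$mz >= 200 & lad$mz <= 1800, ,
                   drop = FALSE]
        if (nrow(lad) < n_frag_range[1L]) break
        n_frag <- sample(seq(n_frag_range[1L],
                             min(n_frag_range[2L], nrow(lad))), 1L)
        frag <- lad[sort(sample(nrow(lad), n_frag)), , drop = FALSE]
        frag$base_intensity <- stats::rlnorm(n_frag, meanlog = 0, sdlog = 0.7)
        frag$base_intensity <- frag$base_intensity /
          max(frag$base_intensity) * 1000
        return(list(peptide = mp$peptide, charge = z, mz = mz,
                    fragments = frag))
      }
    }
  }
}

#' Simulate a complete multi-matrix experiment
#'
#' Generates per-matrix spectral libraries (true targets detected with
#' matrix-specific probability and high-component scores; false targets and
#' decoys with null scores), per-run fragment chromatograms (Gaussian
#' elution, shared apex per precursor per run, multiplicative noise), and a
#' ground-truth record. Injected interferer pairs co-isolate with their
#' analyte under the wide-window scheme, co-elute within the configured
#' tolerance, and carry one fragment within the ppm tolerance of an analyte
#' fragment; the interferer's profile is added onto the analyte's matching
#' fragment trace.
#'
#' @param cfg A [simulation_config()].
#' @param pcfg A [pipeline_config()]; supplies the wide-window scheme and
#'   the tolerances the interference ground truth must satisfy.
#' @param with_chromatograms Generate per-run traces (skip for score-only
#'   studies).
#' @return Object of class `harmolib_simulation`: list with `libraries`
#'   (named list of [spectral_library()]), `chromatograms` (long data frame
#'   or NULL), `truth` (ground-truth list) and the two configs.
#' @export
simulate_experiment <- function(cfg, pcfg = pipeline_config(),
                                with_chromatograms = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(pcfg, "pipeline_config"))
  set.seed(cfg$seed)
  scheme <- pcfg$wide_scheme
  n_total <- cfg$n_true_peptides + cfg$n_false_targets + cfg$n_decoys

  # --- peptide pool -------------------------------------------------------
  precursors <- vector("list", n_total)
  seen <- new.env(parent = emptyenv())
  i <- 1L
  while (i <= n_total) {
    pc <- make_precursor(scheme)
    if (is.null(seen[[pc$peptide]])) {
      assign(pc$peptide, TRUE, envir = seen)
      precursors[[i]] <- pc
      i <- i + 1L
    }
  }
  peptides <- vapply(precursors, `[[`, character(1), "peptide")
  charges <- vapply(precursors, `[[`, integer(1), "charge")
  prec_mz <- vapply(precursors, `[[`, numeric(1), "mz")
  role <- rep(c("true", "false_target", "decoy"),
              c(cfg$n_true_peptides, cfg$n_false_targets, cfg$n_decoys))
  ref_rt <- stats::runif(n_total, 0.05, 0.95) * cfg$gradient_length

  # --- proteins, abundances, fold changes ---------------------------------
  idx_true <- which(role == "true")
  n_prot <- ceiling(cfg$n_true_peptides / cfg$peptides_per_protein)
  protein <- rep(NA_character_, n_total)
  protein[idx_true] <- sprintf("P%04d", rep(seq_len(n_prot),
                                            each = cfg$peptides_per_protein
                                            )[seq_along(idx_true)])
  prot_ids <- sprintf("P%04d", seq_len(n_prot))
  base_abund <- stats::setNames(
    stats::rlnorm(n_prot, meanlog = log(1e5), sdlog = 1), prot_ids)
  matrix_factor <- matrix(stats::rlnorm(n_prot * length(cfg$matrices),
                                        0, 0.5),
                          nrow = n_prot,
                          dimnames = list(prot_ids, cfg$matrices))
  abundance <- base_abund * matrix_factor
  spiked <- stats::setNames(
    stats::runif(n_prot) < cfg$fraction_spiked, prot_ids)
  pept_factor <- stats::setNames(stats::rlnorm(n_total, 0, 0.3), peptides)

  # --- interference pairs -------------------------------------------------
  pairs <- NULL
  if (cfg$n_interference_pairs > 0L) {
    an_idx <- sample(idx_true, cfg$n_interference_pairs)
    pool <- setdiff(idx_true, an_idx)
    if (cfg$interference_on_spiked) {
      # keep analyte and interferer protein sets disjoint so that the
      # forced spiking below cannot cancel itself
      pool <- pool[!(protein[pool] %in% protein[an_idx])]
      if (length(pool) < cfg$n_interference_pairs) {
        config_stop("config error: not enough interferer candidates on ",
                    "distinct proteins")
      }
    }
    in_idx <- sample(pool, cfg$n_interference_pairs)
    if (cfg$interference_on_spiked) {
      spiked[protein[an_idx]] <- TRUE
      spiked[protein[in_idx]] <- FALSE
    }
    pair_rows <- vector("list", cfg$n_interference_pairs)
    for (k in seq_len(cfg$n_interference_pairs)) {
      a <- an_idx[k]; b <- in_idx[k]
      new_mz <- prec_mz[a] + stats::runif(1, -scheme$window_width / 4,
                                          scheme$window_width / 4)
      if (new_mz < scheme$start_mz || new_mz >= scheme$end_mz ||
          !coisolated(scheme, prec_mz[a], new_mz, "union")) {
        new_mz <- prec_mz[a] + 0.01
      }
      prec_mz[b] <- new_mz
      ref_rt[b] <- ref_rt[a] + stats::runif(1, -pcfg$coelution_tolerance / 3,
                                            pcfg$coelution_tolerance / 3)
      fa <- precursors[[a]]$fragments
      top3 <- order(fa$base_intensity, decreasing = TRUE)[
        seq_len(min(3L, nrow(fa)))]
      ai <- sample(top3, 1L)
      fb <- precursors[[b]]$fragments
      bi <- which.max(fb$base_intensity)
      fb$mz[bi] <- fa$mz[ai] * (1 + stats::runif(1, -5e-6, 5e-6))
      precursors[[b]]$fragments <- fb
      pair_rows[[k]] <- data.frame(
        analyte_peptide = peptides[a], analyte_charge = charges[a],
        analyte_ion_series = fa$ion_series[ai],
        analyte_fragment_ordinal = fa$ordinal[ai],
        analyte_fragment_charge = fa$charge[ai],
        analyte_fragment_mz = fa$mz[ai],
        interferer_peptide = peptides[b], interferer_charge = charges[b],
        interferer_ion_series = fb$ion_series[bi],
        interferer_fragment_ordinal = fb$ordinal[bi],
        interferer_fragment_charge = fb$charge[bi],
        interferer_fragment_mz = fb$mz[bi],
        stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pair_rows)
  }

  # --- per-matrix detection, scores, library RTs --------------------------
  detected <- matrix(FALSE, n_total, length(cfg$matrices),
                     dimnames = list(peptides, cfg$matrices))
  score_mat <- rt_mat <- matrix(NA_real_, n_total, length(cfg$matrices),
                                dimnames = list(peptides, cfg$matrices))
  for (m in cfg$matrices) {
    p <- cfg$detection_probability[[m]]
    det <- ifelse(role == "true", stats::runif(n_total) < p, TRUE)
    mu <- ifelse(role == "true", cfg$score_true[["mean"]],
                 cfg$score_null[["mean"]])
    sdv <- ifelse(role == "true", cfg$score_true[["sd"]],
                  cfg$score_null[["sd"]])
    detected[, m] <- det
    score_mat[, m] <- stats::rnorm(n_total, mu, sdv)
    rt_mat[, m] <- pmax(0, warp_eval(cfg$warp_params[[m]], ref_rt) +
                          stats::rnorm(n_total, 0, cfg$rt_jitter_sd))
  }
  # co-elution guarantee: every pair must co-elute in at least one matrix
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$analyte_peptide[k]; b <- pairs$interferer_peptide[k]
      if (all(abs(rt_mat[a, ] - rt_mat[b, ]) > pcfg$coelution_tolerance)) {
        rt_mat[b, 1L] <- rt_mat[a, 1L] + pcfg$coelution_tolerance / 3
      }
    }
  }

  # --- libraries ----------------------------------------------------------
  libraries <- stats::setNames(vector("list", length(cfg$matrices)),
                               cfg$matrices)
  for (m in cfg$matrices) {
    idx <- which(detected[, m])
    rows <- lapply(idx, function(i) {
      fr <- precursors[[i]]$fragments
      data.frame(
        matrix_id = m, peptide = peptides[i], precursor_charge = charges[i],
        precursor_mz = prec_mz[i], score = score_mat[i, m],
        is_decoy = role[i] == "decoy", rt_seconds = rt_mat[i, m],
        rt_origin = "observed", ion_series = fr$ion_series,
        fragment_ordinal = fr$ordinal, fragment_charge = fr$charge,
        fragment_mz = fr$mz,
        library_intensity = fr$base_intensity *
          stats::rlnorm(nrow(fr), 0, 0.2),
        quant_flag = "unset", stringsAsFactors = FALSE)
    })
    libraries[[m]] <- spectral_library(do.call(rbind, rows), matrix_id = m,
                                       provenance = "synthetic",
                                       validate = FALSE)
  }

  truth <- list(
    true_peptides = peptides[idx_true],
    roles = data.frame(peptide = peptides, precursor_charge = charges,
                       precursor_mz = prec_mz, role = role,
                       protein = protein, ref_rt = ref_rt,
                       pept_factor = unname(pept_factor),
                       stringsAsFactors = FALSE),
    warp_params = cfg$warp_params,
    interference_pairs = pairs,
    protein_map = data.frame(peptide = peptides[idx_true],
                             protein = protein[idx_true],
                             stringsAsFactors = FALSE),
    abundance = abundance,
    spiked = spiked,
    fold_change = cfg$fold_change,
    detected = detected,
    rt_matrix = rt_mat)

  chrom <- NULL
  run_meta <- simulation_run_meta(cfg)
  if (with_chromatograms) {
    chrom <- simulate_chromatograms(cfg, precursors, truth, run_meta, pairs)
  }

  structure(list(libraries = libraries, chromatograms = chrom,
                 truth = truth, run_meta = run_meta,
                 config = cfg, pipeline_config = pcfg),
            class = "harmolib_simulation")
}

#' Run metadata of a simulated experiment
#'
#' @param cfg A [simulation_config()].
#' @return Data frame with run_id, matrix_id, subject, group.
#' @export
simulation_run_meta <- function(cfg) {
  out <- expand.grid(subject = seq_len(cfg$runs_per_matrix),
                     matrix_id = cfg$matrices, stringsAsFactors = FALSE)
  out$run_id <- sprintf("%s_r%02d", out$matrix_id, out$subject)
  out$group <- ifelse(out$subject <= cfg$runs_per_matrix / 2, "A", "B")
  out[, c("run_id", "matrix_id", "subject", "group")]
}

# Gaussian elution traces for every true peptide in every run, with the
# interferer fragment profiles added onto the analyte traces.
simulate_chromatograms <- function(cfg, precursors, truth, run_meta, pairs) {
  roles <- truth$roles
  idx_true <- which(roles$role == "true")
  sigma <- cfg$peak_sigma
  offsets <- seq(-4 * sigma, 4 * sigma, by = cfg$sample_step)
  L <- length(offsets)

  # fragment-level skeleton for true peptides
  frag_tab <- do.call(rbind, lapply(idx_true, function(i) {
    fr <- precursors[[i]]$fragments
    data.frame(pep_idx = i, peptide = roles$peptide[i],
               precursor_charge = roles$precursor_charge[i],
               ion_series = fr$ion_series, fragment_ordinal = fr$ordinal,
               fragment_charge = fr$charge,
               base_intensity = fr$base_intensity / 1000,
               stringsAsFactors = FALSE)
  }))

  # apex per (run, peptide): true matrix RT warped + per-run jitter
  n_runs <- nrow(run_meta)
  apex <- matrix(NA_real_, length(idx_true), n_runs,
                 dimnames = list(roles$peptide[idx_true], run_meta$run_id))
  amp_pep <- apex  # peptide-level linear quantity per run
  for (r in seq_len(n_runs)) {
    m <- run_meta$matrix_id[r]
    grp <- run_meta$group[r]
    apex[, r] <- warp_eval(cfg$warp_params[[m]], roles$ref_rt[idx_true]) +
      stats::rnorm(length(idx_true), 0, cfg$rt_jitter_sd)
    prot <- roles$protein[idx_true]
    fc <- ifelse(truth$spiked[prot] & grp == "B", cfg$fold_change, 1)
    amp_pep[, r] <- truth$abundance[cbind(prot, m)] * fc *
      roles$pept_factor[idx_true] *
      stats::rlnorm(length(idx_true), 0, cfg$noise_sd)
  }
  # expand to trace level: one block of L points per (run, fragment)
  blocks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    apx <- apex[match(frag_tab$peptide, rownames(apex)), r]
    amp <- amp_pep[match(frag_tab$peptide, rownames(amp_pep)), r] *
      frag_tab$base_intensity
    n_tr <- nrow(frag_tab)
    tt <- rep(apx, each = L) + offsets
    shape <- rep(amp, each = L) * exp(-(rep(offsets, n_tr))^2 /
                                        (2 * sigma^2))
    noise <- exp(stats::rnorm(n_tr * L, 0, cfg$noise_sd))
    blocks[[r]] <- data.frame(
      run_id = run_meta$run_id[r], matrix_id = run_meta$matrix_id[r],
      peptide = rep(frag_tab$peptide, each = L),
      precursor_charge = rep(frag_tab$precursor_charge, each = L),
      ion_series = rep(frag_tab$ion_series, each = L),
      fragment_ordinal = rep(frag_tab$fragment_ordinal, each = L),
      fragment_charge = rep(frag_tab$fragment_charge, each = L),
      time_sec = tt, intensity = shape * noise, stringsAsFactors = FALSE)
  }
  chrom <- do.call(rbind, blocks)

  # inject interferer signal onto the analyte's matching fragment trace
  if (!is.null(pairs)) {
    trace_key <- paste(chrom$peptide, chrom$ion_series,
                       chrom$fragment_ordinal, chrom$fragment_charge,
                       sep = "\r")
    run_of <- match(chrom$run_id, run_meta$run_id)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$analyte_peptide[k]
      b <- pairs$interferer_peptide[k]
      b_frag <- precursors[[match(b, roles$peptide)]]$fragments
      bi <- which(b_frag$ion_series == pairs$interferer_ion_series[k] &
                    b_frag$ordinal == pairs$interferer_fragment_ordinal[k] &
                    b_frag$charge == pairs$interferer_fragment_charge[k])[1L]
      rows <- which(trace_key == paste(a, pairs$analyte_ion_series[k],
                                       pairs$analyte_fragment_ordinal[k],
                                       pairs$analyte_fragment_charge[k],
                                       sep = "\r"))
      if (length(rows) == 0L) next
      r <- run_of[rows]
      tt <- chrom$time_sec[rows]
      i_amp <- amp_pep[b, r] * b_frag$base_intensity[bi] / 1000
      contrib <- i_amp * exp(-(tt - apex[b, r])^2 / (2 * sigma^2)) *
        exp(stats::rnorm(length(tt), 0, cfg$noise_sd))
      chrom$intensity[rows] <- chrom$intensity[rows] + contrib
    }
  }
  attr(chrom, "amp_pep") <- amp_pep
  chrom
}

#' Fast score-only simulation for FDR studies
#'
#' Generates per-matrix peptide-level score tables (no fragments, no
#' chromatograms) for large-scale target-decoy calibration studies: true
#' targets draw from the high score component and appear in a matrix with
#' its detection probability; false targets and decoys draw from the shared
#' null component and appear in every matrix.
#'
#' @param n_targets Targets per matrix (true + false).
#' @param true_fraction Fraction of targets that are genuinely present.
#' @param n_decoys Decoys per matrix.
#' @param matrices Matrix labels.
#' @param detection_probability Named per-matrix detection probability for
#'   true targets.
#' @param score_true,score_null Gaussian component means/sds.
#' @param seed RNG seed.
#' @return List with `scores` (data frame: peptide, matrix_id, score,
#'   is_decoy) and `truth` (data frame: peptide, is_true, is_decoy).
#' @export
simulate_scored_peptides <- function(
    n_targets = 20000L, true_fraction = 0.3, n_decoys = 20000L,
    matrices = c("urine", "plasma", "serum"),
    detection_probability = c(urine = 0.9, plasma = 0.75, serum = 0.75),
    score_true = c(mean = 3, sd = 1), score_null = c(mean = 0, sd = 1),
    seed = 1L) {
  set.seed(as.integer(seed))
  n_true <- round(n_targets * true_fraction)
  n_false <- n_targets - n_true
  pep <- c(sprintf("TRUE%06d", seq_len(n_true)),
           sprintf("FALS%06d", seq_len(n_false)),
           sprintf("DECY%06d", seq_len(n_decoys)))
  is_true <- rep(c(TRUE, FALSE, FALSE), c(n_true, n_false, n_decoys))
  is_decoy <- rep(c(FALSE, FALSE, TRUE), c(n_true, n_false, n_decoys))
  out <- lapply(matrices, function(m) {
    present <- !is_true | stats::runif(length(pep)) <
      detection_probability[[m]]
    mu <- ifelse(is_true, score_true[["mean"]], score_null[["mean"]])
    sdv <- ifelse(is_true, score_true[["sd"]], score_null[["sd"]])
    sc <- stats::rnorm(length(pep), mu, sdv)
    data.frame(peptide = pep[present], matrix_id = m, score = sc[present],
               is_decoy = is_decoy[present], stringsAsFactors = FALSE)
  })
  list(scores = do.call(rbind, out),
       truth = data.frame(peptide = pep, is_true = is_true,
                          is_decoy = is_decoy, stringsAsFactors = FALSE))
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of a [simulate_experiment()] result.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    true_peptides = truth$true_peptides,
    roles = truth$roles,
    warp_params = truth$warp_params,
    interference_pairs = truth$interference_pairs,
    protein_map = truth$protein_map,
    abundance = as.data.frame(truth$abundance),
    spiked = as.list(truth$spiked),
    fold_change = truth$fold_change)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
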