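# End-to-end pipeline driver: simulate (or load) -> global FDR -> RT
# alignment -> interference screening / ion selection -> harmonized
# libraries -> quantification -> biofluid summaries, with a reproducible
# run manifest.

#' Read a pipeline specification (JSON)
#'
#' Schema: an object with optional sections `pipeline` (fields of
#' [pipeline_config()], wide_scheme embedded), `simulation` (fields of
#' [simulation_config()]) and `inputs` (paths to libraries, chromatograms
#' and run metadata for non-simulated runs).
#'
#' @param path JSON config path.
#' @return List with `pipeline` ([pipeline_config()]), `simulation`
#'   ([simulation_config()]) and `inputs` (list or NULL).
#' @export
read_pipeline_spec <- function(path) {
  if (!file.exists(path)) config_stop("missing input: config file ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pj <- j$pipeline
  pcfg <- if (is.null(pj)) pipeline_config() else {
    ws <- if (!is.null(pj$wide_scheme)) {
      isolation_scheme(pj$wide_scheme$start_mz, pj$wide_scheme$end_mz,
                       pj$wide_scheme$window_width,
                       isTRUE(pj$wide_scheme$staggered))
    } else isolation_scheme(400, 1000, 16, TRUE)
    args <- pj[intersect(names(pj),
                         c("fdr_alpha", "ppm_tolerance", "max_quant_ions",
                           "min_quant_ions", "coelution_tolerance",
                           "cofragmentation_rule",
                           "correlation_aggregation", "rng_seed"))]
    do.call(pipeline_config, c(args, list(wide_scheme = ws)))
  }
  sj <- j$simulation
  scfg <- if (is.null(sj)) simulation_config() else {
    for (fld in c("detection_probability", "score_true", "score_null")) {
      if (!is.null(sj[[fld]])) sj[[fld]] <- unlist(sj[[fld]])
    }
    known <- intersect(names(sj), names(formals(simulation_config)))
    do.call(simulation_config, sj[known])
  }
  list(pipeline = pcfg, simulation = scfg, inputs = j$inputs)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

stage_output <- function(outdir, path, rows) {
  list(path = path,
       rows = as.integer(rows),
       md5 = unname(tools::md5sum(file.path(outdir, path))))
}

#' Run the full harmonization pipeline
#'
#' Executes every stage against a simulated (default) or file-based
#' experiment, writes all stage outputs under `outdir`, and finishes with
#' an atomically written `manifest.json` recording the configuration,
#' seed, package version and the path, row count and digest of every
#' output. Re-running with the same configuration and seed reproduces
#' byte-identical outputs.
#'
#' @param config Path to a JSON pipeline spec, or a list as returned by
#'   [read_pipeline_spec()]; NULL uses all defaults.
#' @param outdir Output directory (created if absent).
#' @param seed Overrides the simulation seed when non-NULL.
#' @param simulate Generate the inputs with [simulate_experiment()]; when
#'   FALSE, `config$inputs` must name library TSVs, a chromatogram CSV and
#'   a run-metadata CSV.
#' @param verbose Log per-stage progress and counts.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL,
                         simulate = TRUE, verbose = FALSE) {
  spec <- if (is.null(config)) {
    list(pipeline = pipeline_config(), simulation = simulation_config(),
         inputs = NULL)
  } else if (is.character(config)) {
    read_pipeline_spec(config)
  } else config
  pcfg <- spec$pipeline
  scfg <- spec$simulation
  if (!is.null(seed)) scfg$seed <- as.integer(seed)
  validate_config(pcfg)
  validate_simulation_config(scfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "harmonized"), showWarnings = FALSE)
  dir.create(file.path(outdir, "catalog"), showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stages <- list()
  input_digests <- list()

  # --- stage 1: simulate or load -----------------------------------------
  if (simulate) {
    say("stage simulate: seed %d, %d true peptides, %d matrices",
        scfg$seed, scfg$n_true_peptides, length(scfg$matrices))
    sim <- simulate_experiment(scfg, pcfg, with_chromatograms = TRUE)
    libraries <- sim$libraries
    chrom <- sim$chromatograms
    run_meta <- sim$run_meta
    outs <- list()
    for (m in names(libraries)) {
      f <- sprintf("library_%s.tsv", m)
      write_library(libraries[[m]], file.path(outdir, f))
      outs[[f]] <- stage_output(outdir, f, nrow(libraries[[m]]$entries))
    }
    write_chromatograms(chrom, file.path(outdir, "chromatograms.csv"))
    outs[["chromatograms.csv"]] <-
      stage_output(outdir, "chromatograms.csv", nrow(chrom))
    utils::write.csv(run_meta, file.path(outdir, "run_meta.csv"),
                     row.names = FALSE, quote = FALSE)
    outs[["run_meta.csv"]] <- stage_output(outdir, "run_meta.csv",
                                           nrow(run_meta))
    write_ground_truth(sim$truth, file.path(outdir, "ground_truth.json"))
    outs[["ground_truth.json"]] <-
      stage_output(outdir, "ground_truth.json", NA)
    stages$simulate <- outs
  } else {
    inp <- spec$inputs
    if (is.null(inp) || is.null(inp$libraries)) {
      config_stop("missing input: 'inputs.libraries' required when not simulating")
    }
    for (f in c(unlist(inp$libraries), inp$chromatograms, inp$run_meta)) {
      if (!is.null(f) && !file.exists(f)) {
        config_stop("missing input: ", f)
      }
    }
    libraries <- lapply(inp$libraries, read_library)
    names(libraries) <- vapply(libraries, `[[`, character(1), "matrix_id")
    chrom <- if (!is.null(inp$chromatograms))
      read_chromatograms(inp$chromatograms) else NULL
    run_meta <- if (!is.null(inp$run_meta))
      utils::read.csv(inp$run_meta, stringsAsFactors = FALSE) else NULL
    input_digests <- lapply(c(unlist(inp$libraries), inp$chromatograms,
                              inp$run_meta),
                            function(f) unname(tools::md5sum(f)))
    names(input_digests) <- c(unlist(inp$libraries), inp$chromatograms,
                              inp$run_meta)
    stages$load_inputs <- list()
    say("stage load: %d libraries", length(libraries))
  }

  # --- stage 2: global FDR ------------------------------------------------
  fdr <- detection_fdr(libraries, alpha = pcfg$fdr_alpha)
  qv <- fdr$scored
  qv$accepted <- !qv$is_decoy & qv$q_value <= pcfg$fdr_alpha
  write_tsv(qv, file.path(outdir, "qvalues.tsv"))
  say("stage fdr: %d peptides scored, %d accepted at alpha %.3g",
      nrow(qv), sum(qv$accepted), pcfg$fdr_alpha)
  stages$fdr <- list("qvalues.tsv" = stage_output(outdir, "qvalues.tsv",
                                                  nrow(qv)))

  # --- stage 3: RT alignment ---------------------------------------------
  warps <- fit_all_warps(libraries)
  write_warps(warps, file.path(outdir, "warps.json"))
  n_fitted <- sum(vapply(warps, function(row)
    sum(!vapply(row, is.null, logical(1))), integer(1)))
  say("stage align: %d warps fitted", n_fitted)
  stages$align <- list("warps.json" = stage_output(outdir, "warps.json",
                                                   n_fitted))

  # --- stages 4-5: ion selection + harmonized libraries -------------------
  h <- harmonize(libraries, chromatograms = chrom, cfg = pcfg,
                 warps = warps)
  ion <- h$ion_decisions
  if (!is.null(ion)) {
    flags <- data.frame(
      peptide = ion$peptide, precursor_charge = ion$precursor_charge,
      fragment = fragment_key(ion$ion_series, ion$fragment_ordinal,
                              ion$fragment_charge),
      fragment_mz = ion$fragment_mz,
      aggregate_correlation = ion$aggregate_correlation,
      flagged = ion$flagged, decision = ion$quant_flag,
      quantifiable = ion$quantifiable, stringsAsFactors = FALSE)
  } else {
    flags <- data.frame(peptide = character(0))
  }
  write_tsv(flags, file.path(outdir, "ionflags.tsv"))
  say("stage select-ions: %d fragments, %d flagged, %d quant",
      nrow(flags), sum(flags$flagged), sum(flags$decision == "quant"))
  stages$select_ions <- list(
    "ionflags.tsv" = stage_output(outdir, "ionflags.tsv", nrow(flags)))

  outs <- list()
  for (m in names(h$harmonized)) {
    f <- file.path("harmonized", sprintf("%s.tsv", m))
    write_library(h$harmonized[[m]], file.path(outdir, f))
    outs[[f]] <- stage_output(outdir, f, nrow(h$harmonized[[m]]$entries))
  }
  write_tsv(h$report, file.path(outdir, "harmonized", "report.tsv"))
  outs[["harmonized/report.tsv"]] <-
    stage_output(outdir, "harmonized/report.tsv", nrow(h$report))
  say("stage harmonize: %d peptides per matrix",
      if (nrow(h$accepted) > 0) nrow(h$accepted) else 0L)
  stages$harmonize <- outs

  # --- stage 6: quantification -------------------------------------------
  outs <- list()
  qt <- NULL
  if (!is.null(chrom) && !is.null(run_meta)) {
    bw <- 3 * scfg$peak_sigma
    qt <- quantify_experiment(chrom, h$harmonized, run_meta,
                              boundary_halfwidth = bw)
    write_quant_table(qt, file.path(outdir, "quant.tsv"))
    outs[["quant.tsv"]] <- stage_output(outdir, "quant.tsv",
                                        nrow(qt$values))
    qn <- tryCatch(normalize_log2(qt), error = function(e) NULL)
    if (!is.null(qn)) {
      write_quant_table(qn, file.path(outdir, "quant_log2.tsv"))
      outs[["quant_log2.tsv"]] <- stage_output(outdir, "quant_log2.tsv",
                                               nrow(qn$values))
    }
    pmap <- if (simulate) sim$truth$protein_map else NULL
    if (!is.null(spec$inputs$protein_map)) {
      pmap <- utils::read.delim(spec$inputs$protein_map)
    }
    if (!is.null(pmap)) {
      pt <- rollup_protein(qt, pmap)
      write_quant_table(pt, file.path(outdir, "protein.tsv"))
      outs[["protein.tsv"]] <- stage_output(outdir, "protein.tsv",
                                            nrow(pt$values))
      pn <- tryCatch(normalize_log2(pt), error = function(e) NULL)
      if (!is.null(pn)) {
        write_quant_table(pn, file.path(outdir, "protein_log2.tsv"))
        outs[["protein_log2.tsv"]] <-
          stage_output(outdir, "protein_log2.tsv", nrow(pn$values))
      }
    } else pt <- NULL
    say("stage quantify: %d peptides x %d runs", nrow(qt$values),
        ncol(qt$values))
  } else {
    pt <- NULL
    say("stage quantify: skipped (no chromatograms or run metadata)")
  }
  stages$quantify <- outs

  # --- stage 7: biofluid summaries ---------------------------------------
  outs <- list()
  if (!is.null(qt) && exists("pt") && !is.null(pt) && nrow(pt$values) > 0) {
    summ <- protein_summary(pt)
    write_tsv(summ, file.path(outdir, "catalog", "summary.tsv"))
    outs[["catalog/summary.tsv"]] <-
      stage_output(outdir, "catalog/summary.tsv", nrow(summ))
    fluids <- unique(pt$meta$matrix_id)
    det <- lapply(fluids, function(m) {
      v <- pt$values[, pt$meta$matrix_id == m, drop = FALSE]
      rownames(v)[rowSums(!is.na(v)) > 0]
    })
    if (length(fluids) >= 3L) {
      venn <- overlap_partition(det[[1]], det[[2]], det[[3]],
                                labels = fluids[1:3])
      venn_df <- data.frame(region = names(venn), count = as.integer(venn))
      write_tsv(venn_df, file.path(outdir, "catalog", "venn.tsv"))
      outs[["catalog/venn.tsv"]] <-
        stage_output(outdir, "catalog/venn.tsv", nrow(venn_df))
    }
    if (!is.null(pt$meta$subject)) {
      deltas <- compute_deltas(pt)
      utils::write.csv(deltas, file.path(outdir, "catalog", "deltas.csv"),
                       row.names = FALSE, quote = FALSE)
      outs[["catalog/deltas.csv"]] <-
        stage_output(outdir, "catalog/deltas.csv", nrow(deltas))
      pn2 <- tryCatch(normalize_log2(pt), error = function(e) NULL)
      if (!is.null(pn2) && length(fluids) >= 2L) {
        fc <- do.call(rbind, lapply(seq_len(length(fluids) - 1L),
                                    function(k) {
          x <- fold_change_table(pn2, fluids[1L], fluids[k + 1L])
          if (nrow(x) == 0L) return(NULL)
          x$pair <- paste(fluids[1L], fluids[k + 1L], sep = "_vs_")
          x
        }))
        if (!is.null(fc)) {
          write_tsv(fc, file.path(outdir, "catalog", "foldchange.tsv"))
          outs[["catalog/foldchange.tsv"]] <-
            stage_output(outdir, "catalog/foldchange.tsv", nrow(fc))
        }
      }
    }
    if (!is.null(pt$meta$group) && !all(is.na(pt$meta$group))) {
      pn3 <- tryCatch(normalize_log2(pt), error = function(e) NULL)
      if (!is.null(pn3)) {
        tt <- group_ttest_table(pn3)
        write_tsv(tt, file.path(outdir, "catalog", "ttest.tsv"))
        outs[["catalog/ttest.tsv"]] <-
          stage_output(outdir, "catalog/ttest.tsv", nrow(tt))
      }
    }
    say("stage summarize: %d proteins summarized", nrow(pt$values))
  } else {
    say("stage summarize: skipped")
  }
  stages$summarize <- outs

  # --- manifest (atomic write) -------------------------------------------
  cfg_snapshot <- unclass(pcfg)
  cfg_snapshot$wide_scheme <- unclass(cfg_snapshot$wide_scheme)
  sim_snapshot <- unclass(scfg)
  manifest <- list(
    tool = "harmolib",
    version = as.character(utils::packageVersion("harmolib")),
    seed = scfg$seed,
    simulate = simulate,
    config = list(pipeline = cfg_snapshot, simulation = sim_snapshot),
    input_digests = input_digests,
    stages = lapply(stages, function(s) unname(s)))
  tmp <- file.path(outdir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(outdir, "manifest.json"))
  say("pipeline complete: %d stages, manifest written", length(stages))
  invisible(manifest)
}
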