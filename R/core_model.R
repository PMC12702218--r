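# Core domain types: spectral libraries (flat transition lists), isolation
# schemes, chromatograms, quant tables, pipeline configuration, and the
# plain-text readers/writers that the pipeline stages exchange.

# Full-precision float serialization: 17 significant digits round-trip
# an IEEE double exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Classed error for invalid configuration, so callers (notably the CLI)
# can distinguish bad config (exit 2) from stage failure (exit 1).
config_stop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("harmolib_config_error", "error",
                                "condition")))
}

#' Library transition-list column names
#'
#' Mandatory columns of the tab-separated library exchange format, one row
#' per fragment ion. Precursor-level fields (score, retention time, decoy
#' flag) are repeated on every fragment row of the same precursor.
#'
#' @return Character vector of column names in canonical order.
#' @export
library_columns <- function() {
  c("matrix_id", "peptide", "precursor_charge", "precursor_mz", "score",
    "is_decoy", "rt_seconds", "rt_origin", "ion_series", "fragment_ordinal",
    "fragment_charge", "fragment_mz", "library_intensity", "quant_flag")
}

#' Construct a spectral library
#'
#' A spectral library holds every fragment row of one biofluid matrix as a
#' flat data frame in transition-list layout (see [library_columns()]).
#' One precursor is the set of rows sharing (peptide, precursor_charge).
#'
#' @param entries Data frame with the columns of [library_columns()].
#' @param matrix_id Matrix label (e.g. "urine"); defaults to the single
#'   matrix_id found in `entries`.
#' @param provenance Free-text metadata string.
#' @param validate Check invariants (unique precursor metadata, non-empty
#'   fragment lists, non-negative retention times).
#' @return Object of class `spectral_library`.
#' @export
spectral_library <- function(entries, matrix_id = NULL, provenance = "",
                             validate = TRUE) {
  stopifnot(is.data.frame(entries))
  missing_cols <- setdiff(library_columns(), names(entries))
  if (length(missing_cols) > 0L) {
    stop("library is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  entries <- entries[, library_columns(), drop = FALSE]
  rownames(entries) <- NULL
  entries$is_decoy <- as.logical(entries$is_decoy)
  if (is.null(matrix_id)) {
    ids <- unique(entries$matrix_id)
    if (length(ids) > 1L) {
      stop("library mixes matrix_ids: ", paste(ids, collapse = ", "),
           call. = FALSE)
    }
    matrix_id <- if (length(ids) == 1L) ids else NA_character_
  }
  lib <- structure(
    list(matrix_id = matrix_id, entries = entries, provenance = provenance),
    class = "spectral_library"
  )
  if (validate) validate_library(lib)
  lib
}

#' @export
print.spectral_library <- function(x, ...) {
  n_prec <- nrow(unique(x$entries[, c("peptide", "precursor_charge")]))
  cat(sprintf(
    "<spectral_library> matrix '%s': %d precursors, %d fragment rows (%d decoy rows)\n",
    x$matrix_id, n_prec, nrow(x$entries), sum(x$entries$is_decoy)))
  invisible(x)
}

validate_library <- function(lib) {
  e <- lib$entries
  if (nrow(e) == 0L) return(invisible(lib))
  if (any(e$matrix_id != lib$matrix_id)) {
    stop("entries with matrix_id differing from library matrix_id '",
         lib$matrix_id, "'", call. = FALSE)
  }
  if (any(!is.finite(e$fragment_mz)) || any(e$fragment_mz <= 0)) {
    stop("fragment_mz must be positive and finite", call. = FALSE)
  }
  if (any(e$library_intensity < 0)) {
    stop("library_intensity must be non-negative", call. = FALSE)
  }
  if (any(e$rt_seconds < 0)) {
    stop("rt_seconds must be non-negative", call. = FALSE)
  }
  if (!all(e$ion_series %in% c("y", "b"))) {
    stop("ion_series must be 'y' or 'b'", call. = FALSE)
  }
  if (!all(e$rt_origin %in% c("observed", "imputed"))) {
    stop("rt_origin must be 'observed' or 'imputed'", call. = FALSE)
  }
  if (!all(e$quant_flag %in% c("quant", "detection_only", "unset"))) {
    stop("quant_flag must be quant/detection_only/unset", call. = FALSE)
  }
  # precursor-level fields must be constant within a precursor
  key <- paste(e$peptide, e$precursor_charge, sep = "\r")
  for (col in c("score", "rt_seconds", "is_decoy", "precursor_mz")) {
    rng <- tapply(e[[col]], key, function(v) length(unique(v)))
    if (any(rng > 1L)) {
      bad <- names(rng)[which(rng > 1L)[1L]]
      stop("integrity error: precursor '", sub("\r", "/", bad),
           "' has conflicting values in column '", col, "'", call. = FALSE)
    }
  }
  invisible(lib)
}

#' Fragment-ion key strings
#'
#' Canonical identifier for a fragment ion, e.g. `"y7^1"` for a singly
#' charged y7 ion.
#'
#' @param ion_series "y" or "b" (vectorized).
#' @param ordinal Fragment ordinal (positive integer).
#' @param charge Fragment charge (positive integer).
#' @return Character vector of keys.
#' @export
fragment_key <- function(ion_series, ordinal, charge) {
  sprintf("%s%d^%d", ion_series, as.integer(ordinal), as.integer(charge))
}

precursor_key <- function(peptide, charge) {
  paste(peptide, as.integer(charge), sep = "/")
}

#' Read a spectral library from a transition-list TSV
#'
#' @param path Path to a tab-separated file with header and the columns of
#'   [library_columns()].
#' @return A [spectral_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(library_columns(), header)
  if (length(missing_cols) > 0L) {
    stop("format error in ", path, ": missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  e <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE)
  num_cols <- c("precursor_charge", "precursor_mz", "score", "rt_seconds",
                "fragment_ordinal", "fragment_charge", "fragment_mz",
                "library_intensity")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(e[[col]]))
    bad <- which(is.na(v) | e[[col]] == "")
    if (length(bad) > 0L) {
      stop(sprintf("format error in %s, line %d: column '%s' is missing or non-numeric",
                   path, bad[1L] + 1L, col), call. = FALSE)
    }
    e[[col]] <- v
  }
  e$is_decoy <- e$is_decoy == "1" | toupper(e$is_decoy) == "TRUE"
  e$precursor_charge <- as.integer(e$precursor_charge)
  e$fragment_ordinal <- as.integer(e$fragment_ordinal)
  e$fragment_charge <- as.integer(e$fragment_charge)
  spectral_library(e)
}

#' Write a spectral library to a transition-list TSV
#'
#' Floats are serialized with 17 significant digits so that a read/write
#' cycle reproduces every field exactly.
#'
#' @param lib A [spectral_library()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  e <- lib$entries
  out <- e
  out$is_decoy <- as.integer(e$is_decoy)
  for (col in c("precursor_mz", "score", "rt_seconds", "fragment_mz",
                "library_intensity")) {
    out[[col]] <- fmt_num(e[[col]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(err) err)
  if (!isTRUE(ok)) stop("cannot write library to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Construct an isolation scheme
#'
#' Precursor isolation windows of fixed width tiling `[start_mz, end_mz)`,
#' half-open `[start, start + width)`. A staggered scheme adds a second
#' window cycle offset by half a window width, so interior precursors fall
#' in exactly two windows.
#'
#' @param start_mz,end_mz m/z range covered (Daltons).
#' @param window_width Window width in Daltons (> 0).
#' @param staggered Add the half-width-offset second cycle.
#' @return Object of class `isolation_scheme`.
#' @export
isolation_scheme <- function(start_mz, end_mz, window_width,
                             staggered = FALSE) {
  stopifnot(is.numeric(start_mz), is.numeric(end_mz),
            is.numeric(window_width))
  if (window_width <= 0) stop("window_width must be > 0", call. = FALSE)
  if (end_mz <= start_mz) stop("end_mz must exceed start_mz", call. = FALSE)
  structure(
    list(start_mz = as.numeric(start_mz), end_mz = as.numeric(end_mz),
         window_width = as.numeric(window_width),
         staggered = isTRUE(staggered)),
    class = "isolation_scheme"
  )
}

#' @export
print.isolation_scheme <- function(x, ...) {
  cat(sprintf("<isolation_scheme> [%g, %g) m/z, %g m/z windows%s\n",
              x$start_mz, x$end_mz, x$window_width,
              if (x$staggered) ", staggered" else ""))
  invisible(x)
}

#' Enumerate the windows of an isolation scheme
#'
#' @param scheme An [isolation_scheme()].
#' @return Data frame with columns `window` (1-based index), `start`, `end`
#'   (Daltons, half-open) and `cycle` (0 = primary, 1 = offset cycle).
#' @export
scheme_windows <- function(scheme) {
  stopifnot(inherits(scheme, "isolation_scheme"))
  w <- scheme$window_width
  starts0 <- seq(scheme$start_mz, scheme$end_mz - 1e-9, by = w)
  starts <- starts0
  cycle <- rep(0L, length(starts0))
  if (scheme$staggered) {
    s1 <- seq(scheme$start_mz - w / 2, scheme$end_mz - 1e-9, by = w)
    starts <- c(starts0, s1)
    cycle <- c(cycle, rep(1L, length(s1)))
  }
  data.frame(window = seq_along(starts), start = starts, end = starts + w,
             cycle = cycle)
}

#' Isolation windows co-isolating a precursor
#'
#' Windows are half-open, so a precursor exactly on a shared boundary
#' belongs to the higher window only.
#'
#' @param scheme An [isolation_scheme()].
#' @param mz Precursor m/z (must lie in `[start_mz, end_mz)`).
#' @return Integer vector of window indices into [scheme_windows()];
#'   length 2 for interior precursors of a staggered scheme.
#' @export
windows_for_precursor <- function(scheme, mz) {
  stopifnot(inherits(scheme, "isolation_scheme"), length(mz) == 1L)
  if (!is.finite(mz) || mz < scheme$start_mz || mz >= scheme$end_mz) {
    stop(sprintf("precursor m/z %g outside scheme range [%g, %g)",
                 mz, scheme$start_mz, scheme$end_mz), call. = FALSE)
  }
  win <- scheme_windows(scheme)
  which(win$start <= mz & mz < win$end)
}

# Half-window ordinal used by the demultiplexed co-isolation rule: two
# precursors of a staggered scheme share their full window pair iff they
# fall in the same half-width bin.
half_window_index <- function(scheme, mz) {
  floor((mz - scheme$start_mz) / (scheme$window_width / 2))
}

#' Test whether two precursors are co-isolated
#'
#' Under rule `"union"` two precursors co-isolate when any isolation window
#' (either staggered cycle) contains both. Under `"demultiplexed"` they must
#' share the half-width intersection window that demultiplexing resolves,
#' i.e. both staggered windows; `"union"` flags a superset of
#' `"demultiplexed"`.
#'
#' @param scheme An [isolation_scheme()].
#' @param mz1,mz2 Precursor m/z values inside the scheme range.
#' @param rule `"union"` or `"demultiplexed"`.
#' @return Logical scalar.
#' @export
coisolated <- function(scheme, mz1, mz2, rule = c("union", "demultiplexed")) {
  rule <- match.arg(rule)
  if (rule == "demultiplexed" && scheme$staggered) {
    return(half_window_index(scheme, mz1) == half_window_index(scheme, mz2))
  }
  length(intersect(windows_for_precursor(scheme, mz1),
                   windows_for_precursor(scheme, mz2))) > 0L
}

#' Read / write an isolation scheme as JSON
#'
#' Schema: `{"start_mz": float, "end_mz": float, "window_width": float,
#' "staggered": bool}`.
#'
#' @param path JSON path.
#' @return `read_scheme` returns an [isolation_scheme()].
#' @export
read_scheme <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  isolation_scheme(j$start_mz, j$end_mz, j$window_width,
                   isTRUE(j$staggered))
}

#' @rdname read_scheme
#' @param scheme An [isolation_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "isolation_scheme"))
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

chromatogram_columns <- function() {
  c("run_id", "matrix_id", "peptide", "precursor_charge", "ion_series",
    "fragment_ordinal", "fragment_charge", "time_sec", "intensity")
}

#' Validate a long-format chromatogram table
#'
#' One row per sampled point of one fragment trace. A trace is identified
#' by (run_id, peptide, precursor_charge, ion_series, fragment_ordinal,
#' fragment_charge); its times must be strictly ascending with at least
#' three points and non-negative intensities.
#'
#' @param chrom Data frame in long chromatogram layout.
#' @return The validated data frame, invisibly.
#' @export
validate_chromatograms <- function(chrom) {
  missing_cols <- setdiff(chromatogram_columns(), names(chrom))
  if (length(missing_cols) > 0L) {
    stop("chromatogram table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(chrom$intensity < 0)) stop("negative intensities", call. = FALSE)
  key <- paste(chrom$run_id, chrom$peptide, chrom$precursor_charge,
               chrom$ion_series, chrom$fragment_ordinal,
               chrom$fragment_charge, sep = "\r")
  ord <- order(key, chrom$time_sec)
  k <- key[ord]; tt <- chrom$time_sec[ord]
  same <- k[-1L] == k[-length(k)]
  if (length(tt) > 1L && any(same & diff(tt) <= 0)) {
    stop("trace times must be strictly ascending", call. = FALSE)
  }
  if (any(tabulate(factor(key)) < 3L)) {
    stop("every trace needs >= 3 points", call. = FALSE)
  }
  invisible(chrom)
}

#' Read / write chromatograms (long-format CSV)
#'
#' @param path CSV path.
#' @return `read_chromatograms` returns a validated data frame.
#' @export
read_chromatograms <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  chrom <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_chromatograms(chrom)
  chrom
}

#' @rdname read_chromatograms
#' @param chrom Long-format chromatogram data frame.
#' @export
write_chromatograms <- function(chrom, path) {
  out <- chrom[, chromatogram_columns(), drop = FALSE]
  for (col in c("time_sec", "intensity")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Construct a quantitative report table
#'
#' Rows are peptides or proteins, columns are runs. Missing quantities are
#' `NA`, never zero-filled; linear-scale values must be non-negative.
#'
#' @param values Numeric matrix (rows x runs) with dimnames.
#' @param meta Data frame with columns run_id, matrix_id and optionally
#'   group; one row per column of `values`, in column order.
#' @param row_type "peptide" or "protein".
#' @param scale "linear" or "log2".
#' @return Object of class `quant_table`.
#' @export
quant_table <- function(values, meta, row_type = c("peptide", "protein"),
                        scale = c("linear", "log2")) {
  row_type <- match.arg(row_type)
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.data.frame(meta))
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values))) {
    stop("values must carry row and column names", call. = FALSE)
  }
  if (!all(c("run_id", "matrix_id") %in% names(meta))) {
    stop("meta needs run_id and matrix_id columns", call. = FALSE)
  }
  if (!identical(colnames(values), as.character(meta$run_id))) {
    stop("meta run_ids must match value columns in order", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("linear intensities must be non-negative", call. = FALSE)
  }
  if (is.null(meta$group)) meta$group <- NA_character_
  structure(list(values = values, meta = meta, row_type = row_type,
                 scale = scale),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d %ss x %d runs (%s scale), %.1f%% missing\n",
              nrow(x$values), x$row_type, ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read / write a quant report (TSV plus metadata sidecar CSV)
#'
#' The report TSV has columns `row_id`, `row_type`, then one column per
#' run; the sidecar CSV holds run_id, matrix_id, group.
#'
#' @param path Report TSV path; the sidecar lives at `meta_path`.
#' @param meta_path Metadata CSV path (default: `path` with suffix
#'   `.meta.csv`).
#' @param scale Scale tag of the stored values ("linear" or "log2"); the
#'   flat TSV does not encode it.
#' @return `read_quant_table` returns a [quant_table()].
#' @export
read_quant_table <- function(path, meta_path = paste0(path, ".meta.csv"),
                             scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  run_cols <- setdiff(names(tab), c("row_id", "row_type"))
  values <- as.matrix(tab[, run_cols, drop = FALSE])
  rownames(values) <- tab$row_id
  row_type <- unique(tab$row_type)
  if (length(row_type) != 1L) stop("mixed row_type in ", path, call. = FALSE)
  quant_table(values, meta[match(run_cols, meta$run_id), , drop = FALSE],
              row_type = row_type, scale = scale)
}

#' @rdname read_quant_table
#' @param qt A [quant_table()].
#' @export
write_quant_table <- function(qt, path,
                              meta_path = paste0(path, ".meta.csv")) {
  stopifnot(inherits(qt, "quant_table"))
  tab <- data.frame(row_id = rownames(qt$values), row_type = qt$row_type,
                    stringsAsFactors = FALSE, check.names = FALSE)
  vals <- qt$values
  for (j in seq_len(ncol(vals))) {
    tab[[colnames(vals)[j]]] <- fmt_num(vals[, j])
  }
  lines <- c(paste(names(tab), collapse = "\t"),
             do.call(paste, c(unname(tab), sep = "\t")))
  writeLines(lines, path)
  utils::write.csv(qt$meta[, c("run_id", "matrix_id", "group")], meta_path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tolerances and limits used across all stages. Defaults
#' follow standard wide-window DIA practice: 1% global FDR, 10 ppm mass
#' tolerance, five quantitative ions with a minimum of three, and a
#' 16 m/z staggered wide-window scheme over 400-1000 m/z.
#'
#' @param fdr_alpha Global peptide FDR threshold (fraction, default 0.01).
#' @param ppm_tolerance Fragment mass tolerance in parts per million.
#' @param max_quant_ions Quantitative ions selected per peptide (default 5).
#' @param min_quant_ions Minimum quantitative ions for a peptide to be
#'   quantifiable (default 3).
#' @param coelution_tolerance Maximum retention-time distance (seconds) for
#'   two precursors to count as co-eluting.
#' @param wide_scheme Wide-window acquisition [isolation_scheme()] used for
#'   the interference check.
#' @param cofragmentation_rule "union" (conservative, any shared staggered
#'   window) or "demultiplexed" (half-width intersection window).
#' @param correlation_aggregation How per-matrix peak-shape correlations are
#'   aggregated: "min" (strictest) or "mean".
#' @param rng_seed Integer seed recorded for provenance.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_alpha = 0.01,
                            ppm_tolerance = 10.0,
                            max_quant_ions = 5L,
                            min_quant_ions = 3L,
                            coelution_tolerance = 30,
                            wide_scheme = isolation_scheme(400, 1000, 16, TRUE),
                            cofragmentation_rule = c("union", "demultiplexed"),
                            correlation_aggregation = c("min", "mean"),
                            rng_seed = 1L) {
  cofragmentation_rule <- match.arg(cofragmentation_rule)
  correlation_aggregation <- match.arg(correlation_aggregation)
  cfg <- structure(
    list(fdr_alpha = fdr_alpha, ppm_tolerance = ppm_tolerance,
         max_quant_ions = as.integer(max_quant_ions),
         min_quant_ions = as.integer(min_quant_ions),
         coelution_tolerance = coelution_tolerance,
         wide_scheme = wide_scheme,
         cofragmentation_rule = cofragmentation_rule,
         correlation_aggregation = correlation_aggregation,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!(cfg$fdr_alpha > 0 && cfg$fdr_alpha < 1)) {
    config_stop("config error: fdr_alpha must lie in (0, 1)")
  }
  if (cfg$ppm_tolerance <= 0) {
    config_stop("config error: ppm_tolerance must be > 0")
  }
  if (cfg$min_quant_ions > cfg$max_quant_ions) {
    config_stop("config error: min_quant_ions exceeds max_quant_ions")
  }
  if (!inherits(cfg$wide_scheme, "isolation_scheme")) {
    config_stop("config error: wide_scheme must be an isolation_scheme")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path JSON path; the wide scheme is embedded under `wide_scheme`.
#' @return `read_config` returns a [pipeline_config()].
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ws <- if (!is.null(j$wide_scheme)) {
    isolation_scheme(j$wide_scheme$start_mz, j$wide_scheme$end_mz,
                     j$wide_scheme$window_width,
                     isTRUE(j$wide_scheme$staggered))
  } else isolation_scheme(400, 1000, 16, TRUE)
  args <- j[intersect(names(j),
                      c("fdr_alpha", "ppm_tolerance", "max_quant_ions",
                        "min_quant_ions", "coelution_tolerance",
                        "cofragmentation_rule", "correlation_aggregation",
                        "rng_seed"))]
  do.call(pipeline_config, c(args, list(wide_scheme = ws)))
}

#' @rdname read_config
#' @param cfg A [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$wide_scheme <- unclass(out$wide_scheme)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
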