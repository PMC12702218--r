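# Monoisotopic peptide mass arithmetic. Sequences use bracketed-mass
# notation for modifications (e.g. "C[+57.021464]"); cysteine is assumed
# carbamidomethylated, the only modification considered.

PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.0105646863
CARBAMIDOMETHYL_MASS <- 57.021464

#' Monoisotopic residue masses
#'
#' Masses of the 20 amino-acid residues (Daltons, monoisotopic, residue =
#' amino acid minus water).
#'
#' @return Named numeric vector keyed by one-letter code.
#' @export
residue_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
}

# Split a bracketed-mass sequence into residues and per-residue added mass.
parse_peptide <- function(peptide) {
  chars <- strsplit(peptide, "")[[1]]
  residues <- character(0)
  mods <- numeric(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- i
      while (chars[close] != "]") close <- close + 1L
      mass <- as.numeric(paste(chars[(i + 1L):(close - 1L)], collapse = ""))
      mods[length(mods)] <- mods[length(mods)] + mass
      i <- close + 1L
    } else {
      residues <- c(residues, ch)
      mods <- c(mods, 0)
      i <- i + 1L
    }
  }
  bad <- setdiff(residues, names(residue_masses()))
  if (length(bad) > 0L) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  list(residues = residues, mods = mods)
}

# Per-residue masses including modifications, N- to C-terminal order.
residue_mass_vector <- function(peptide) {
  p <- parse_peptide(peptide)
  unname(residue_masses()[p$residues]) + p$mods
}

#' Peptide neutral monoisotopic mass
#'
#' @param peptide Sequence string, optionally with bracketed modification
#'   masses (e.g. `"AC[+57.021464]K"`).
#' @return Neutral mass in Daltons.
#' @export
peptide_neutral_mass <- function(peptide) {
  sum(residue_mass_vector(peptide)) + WATER_MASS
}

#' Precursor m/z of a peptide
#'
#' @inheritParams peptide_neutral_mass
#' @param charge Precursor charge (positive integer).
#' @return m/z in Daltons.
#' @export
precursor_mz_of <- function(peptide, charge) {
  (peptide_neutral_mass(peptide) + charge * PROTON_MASS) / charge
}

#' y/b fragment-ion m/z ladder
#'
#' Singly and multiply charged y (C-terminal) and b (N-terminal) fragment
#' ions. y_n includes the C-terminal water; b_n does not.
#'
#' @inheritParams peptide_neutral_mass
#' @param charges Fragment charges to enumerate (default 1).
#' @return Data frame with columns ion_series, ordinal, charge, mz covering
#'   ordinals 1 to length-1 of both series.
#' @export
fragment_ladder <- function(peptide, charges = 1L) {
  rm <- residue_mass_vector(peptide)
  n <- length(rm)
  if (n < 2L) stop("peptide too short for fragments", call. = FALSE)
  ords <- seq_len(n - 1L)
  b_neutral <- cumsum(rm)[ords]                      # residues 1..k
  suffix <- rev(cumsum(rev(rm)))                     # suffix[i] = sum rm[i..n]
  y_neutral <- suffix[n - ords + 1L] + WATER_MASS    # last k residues + water
  out <- do.call(rbind, lapply(as.integer(charges), function(z) {
    data.frame(
      ion_series = rep(c("b", "y"), each = n - 1L),
      ordinal = c(ords, ords),
      charge = z,
      mz = c((b_neutral + z * PROTON_MASS) / z,
             (y_neutral + z * PROTON_MASS) / z)
    )
  }))
  rownames(out) <- NULL
  out
}
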