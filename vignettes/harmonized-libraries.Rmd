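---
title: "Harmonizing DIA chromatogram libraries across biofluid matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing DIA chromatogram libraries across biofluid matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmolib)
```

## The problem

Wide-window data-independent acquisition (DIA) quantifies peptides by
extracting fragment-ion chromatograms against a spectral library. When the
same subjects contribute several biofluids — urine, plasma, serum — each
matrix usually gets its own chromatogram library, built from
gas-phase-fractionated narrow-window runs of a matrix pool. Three separate
libraries mean three separately controlled error rates, three fragmentation
templates per peptide, and fragment ions whose interference status differs
between matrices. Any of these differences can masquerade as biology when
fluids are compared.

`harmolib` merges per-matrix libraries into *harmonized* libraries that
share one peptide set, one fragmentation template per peptide and one set of
quantitative fragment ions, while keeping retention times matrix-specific.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## Global peptide FDR

All library entries are pooled and reduced to one record per peptide string,
keeping the maximum score over matrices and charge states (the
"best-scoring biofluid"; exact ties are broken by ascending lexicographic
matrix label so results are deterministic). The q-value of a peptide with
score $s$ uses the conservative target-decoy competition estimator

$$\widehat{FDR}(t) = \frac{1 + \#\{\text{decoys} \ge t\}}
                          {\#\{\text{targets} \ge t\}},
\qquad q(s) = \min_{t \le s} \widehat{FDR}(t) \wedge 1 .$$

Decoys and false targets are assumed to draw their scores from the same
null distribution — the standard target-decoy premise. The `+1` numerator
makes the estimator conservative and implies a floor of $1/n$ on attainable
q-values: a library of fewer than ~100 true peptides cannot clear a 1%
threshold no matter how well separated the scores are. This matters only at
toy scales; the calibration study below runs at $3 \times 40{,}000$ entries
where the filter is comfortably calibrated (realized false-discovery
proportion about 0.7% at $q \le 0.01$, averaged over 20 replicates).

Filtering operates at the peptide level after best-evidence picking (a
"picked" strategy). Decoys are never emitted downstream.

## Retention-time calibration

Matrix effects shift and warp elution. For every ordered matrix pair with at
least 20 shared peptides (anchors) a monotone warp is fitted:

1. bin the source RTs on a uniform grid (64 bins over the observed range);
2. within each bin, estimate the Gaussian kernel density of the target RTs
   (Silverman's rule bandwidth by default) and take the density *mode*;
3. enforce monotonicity across bin modes by isotonic regression;
4. evaluate by linear interpolation between the resulting knots, with
   linear extrapolation beyond the end knots.

Using the conditional mode rather than the mean makes the fit robust: 10%
gross outliers among 2,000 anchors still leave a held-out median prediction
error under 15 s for a drifting sinusoidal warp with 10 s noise. The
residual scale stored with each warp is the MAD of the anchors about the
fit, scaled by 1.4826 to estimate a Gaussian sd.

Match-between-runs then assigns an RT in every matrix to every accepted
peptide: observed RTs are never overwritten, and a peptide missing from a
matrix receives the prediction of the warp from its *best-scoring* matrix
(mirroring the template choice), composing through the intermediate matrix
with the most anchors when no direct warp exists. Grid size, bandwidth and
the minimum anchor count are all arguments of `fit_kde_warp()` /
`fit_all_warps()`.

## Interference screening under wide windows

Chromatogram libraries are built from narrow windows, but quantification
happens in wide (16 m/z, staggered) windows where more precursors
co-fragment. A fragment $f$ of analyte $a$ is flagged when some other
precursor $e$ satisfies all of:

* **co-isolation** — $e$ shares an isolation window with $a$ under the
  wide scheme. Windows are half-open $[start, start + width)$, so a
  precursor sitting exactly on a shared boundary belongs to the higher
  window only. Two rules are available: `"union"` (any shared staggered
  window; the default, conservative) and `"demultiplexed"` (both staggered
  windows shared, i.e. the same half-width bin — the windows a
  demultiplexing step would resolve). The union rule flags a superset of
  the demultiplexed rule by construction.
* **co-elution** — $|rt_e - rt_a| \le$ 30 s (configurable).
* **mass interference** — some fragment of $e$ lies within 10 ppm of
  $f$'s m/z.

The screen is evaluated on the *harmonized candidate libraries*: every
accepted peptide, with its template fragments and its (possibly imputed)
matrix-specific RT, against every matrix. A fragment flagged in any matrix
is excluded everywhere — the strictest reading of "interference-free in
all matrices at once", and the reason the cross-matrix design catches
interferences that a single matrix would miss.

## Quantitative-ion selection

Candidates are the fragments flagged nowhere. When chromatograms are
available, each candidate is scored per matrix by its peak-shape
correlation: all fragment traces of the precursor are resampled onto a
uniform 0.5 s grid (linear interpolation, zero outside the observed range)
and the fragment is correlated against the pointwise sum of the *other*
fragments. This leave-one-out reference prevents a dominant interfered ion
from validating itself. Zero-variance traces score 0; per-run scores are
averaged within a matrix and aggregated across matrices by the minimum
(default) or mean.

Candidates are ranked by aggregated correlation, ties broken by library
intensity (descending) then fragment m/z (ascending) for determinism. The
top 5 become quantitative ions; a peptide with fewer than 3 candidates is
retained with *all* ions marked detection-only rather than dropped, so the
harmonized library still supports detection of such peptides. The 5/3
limits, tolerances and aggregation live in `pipeline_config()`.

## Quantification, normalization, roll-up

Peptide intensity in a run is the sum of trapezoidal areas of its
quant-flagged fragment traces inside a fixed boundary (expected RT
$\pm 3\sigma_{peak}$, 18 s by default). A quant ion without a trace
contributes zero (and only that); a peptide with no quant ions is missing,
never zero. Normalization maps each run's log2 intensities so that all runs
share the same mean log2 intensity over complete-case rows, preserving the
grand mean; missing values stay missing. Protein roll-up enforces peptide
uniqueness at the protein level — a peptide mapping to more than one
protein contributes to none — and sums unique-peptide linear intensities.

Biofluid summaries follow the database conventions of the companion
catalogue: a fluid is "top" for a protein when its mean signal is within
50% of the most intense fluid (inclusive, applied to linear means; the rule
is scale-invariant under uniform scaling). Deltas are per-subject,
per-fluid-pair absolute intensity differences. Two-group comparisons use
the pooled two-sided Student t test with $n_A + n_B - 2$ degrees of
freedom; zero pooled variance yields $p = 1$ for equal means and $p = 0$
(with a warning) otherwise.

## The synthetic experiment generator

`simulate_experiment()` emulates a three-biofluid study: urine, plasma and
serum pools over a 90-minute (5,400 s) gradient, eight paired runs per
matrix split into two groups. Defaults: 200 true peptides (drawn as random
fully tryptic sequences of length 7–25 with carbamidomethylated cysteine
and genuine monoisotopic y/b fragment ladders), 200 false targets, 400
decoys; detection probabilities 0.9 (urine) and 0.75 (plasma, serum),
reflecting urine's deeper accessible proteome; true scores
$\mathcal N(3.5, 1)$ against a $\mathcal N(0, 1)$ null shared by false
targets and decoys; affine-plus-sinusoid strictly monotone RT warps per
matrix with 3 s jitter; Gaussian elution peaks ($\sigma = 6$ s) sampled
every 2 s (a realistic staggered-DIA cycle time) with multiplicative
log-normal noise (sd 0.1); 15 injected interference pairs; 10% of proteins
spiked two-fold in group B. Desk-scale peptide counts were chosen so the
complete pipeline runs in well under a minute; they are two orders of
magnitude below a real deep library, which matters only for the q-value
floor discussed above.

Injected interferers are constructed to satisfy the screening conditions by
design: the interferer's precursor is placed inside the analyte's wide
window, its reference RT within a third of the co-elution tolerance, and
one of its fragments within 5 ppm of one of the analyte's three most
intense fragments; the interferer's elution profile is added onto that
analyte fragment's trace in every run.

For the ion-selection benchmark (`ion_selection_benchmark()`) the generator
is run with `interference_on_spiked = TRUE`: interfered analytes are forced
onto spiked (fold-changing) proteins and their interferers onto flat ones,
with the two protein sets disjoint. This is a designed experiment, not a
neutral draw: an interferer whose profile matches the analyte's fold change
does not distort relative quantification, so the configuration that
demonstrates the harm (and the benefit of excluding flagged ions) is the
contrasting one. Group fold changes in the benchmark are computed from raw
log2 quantities because the generator applies no run-level scale factors.
On ten replicate experiments the harmonized selection's median absolute
log2 fold-change error on interfered peptides is roughly a third of the
naive top-5-by-intensity baseline's.

### What the simulation does not capture

Real data differ in ways the generator deliberately omits: no MS1 signal,
isotope envelopes or charge-state envelopes; no chimeric spectra beyond the
injected pairwise interferers; no peak-shape asymmetry (tailing), no
saturation, and no missing-value mechanism other than library-level
detection probability; scores are Gaussian rather than the skewed mixtures
real search engines produce. Passing the included studies therefore shows
the *algorithms* behave as specified under their own assumptions — it is
not evidence about any particular instrument or cohort.

## Numerical and design choices

* **File formats.** Libraries travel as flat transition-list TSVs (one row
  per fragment) with floats serialized at 17 significant digits, so
  read/write round-trips are bit-exact and outputs diff cleanly. Schemes,
  warps, configs and manifests are JSON (chosen over TOML because the R
  stack needs no extra parser for it); chromatograms are long-format CSV.
* **Half-open windows** resolve boundary precursors deterministically.
* **Tie-breaks everywhere** (matrix label, library intensity, fragment
  m/z, fixed output ordering by peptide/charge/fragment m/z) make the whole
  pipeline a pure function of inputs, config and seed; the run manifest
  records a digest of every output to make that checkable.
* **Degenerate inputs**: zero-variance traces score 0 correlation; empty
  accepted sets produce empty libraries and a zero-row report rather than
  errors; a missing quant-ion trace logs as a zero contribution while a
  fully missing peptide stays `NA`.
* **Boundary integration** uses plain trapezoids on the native sampling
  grid: at 0.5–2 s sampling of a 6 s-sigma peak the error against the
  closed-form Gaussian area is far below the 1% documented tolerance, and
  no smoothing or re-detection is attempted (interfered ions are excluded,
  never "repaired").

## Known limitations

FDR control is peptide-level only (no PSM- or protein-level control, no
score recalibration). RT calibration is matrix-level; within-matrix,
run-to-run drift is not modelled. The interference screen is a library
screen — it flags risk from co-eluting *identified* peptides and cannot see
interference from species absent from every library. Quantification
integrates fixed boundaries and will underestimate peptides whose true
apex drifts outside the expected window by more than the boundary
half-width.
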