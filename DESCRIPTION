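Package: harmolib
Title: Harmonized DIA Chromatogram Libraries Across Biofluid Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds harmonized data-independent acquisition (DIA) spectral
    libraries across biofluid matrices (urine, plasma, serum). Merges
    per-matrix chromatogram libraries under a global target-decoy
    false-discovery-rate filter, selects one fragmentation template per
    peptide from its best-scoring matrix, calibrates matrix-specific
    retention times by kernel-density alignment with match-between-runs
    imputation, screens fragment ions for co-fragmentation interference
    under wide staggered isolation windows, selects interference-free
    quantitative transitions shared by all matrices, quantifies peptides
    and proteins from extracted fragment chromatograms, and summarizes
    per-protein biofluid distributions. Includes a synthetic multi-matrix
    experiment generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
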