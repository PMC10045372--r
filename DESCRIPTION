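Package: tecurate
Title: Transposon Family Curation from Seed Homology to Target Site Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds transposable-element family consensus sequences from seed
    homology hits in a genome assembly and resolves element boundaries from
    terminal signatures, terminal inverted repeats (TIRs) and target site
    duplications (TSDs). Implements a transparent seed-and-extend homology
    search (protein and nucleotide modes), single-linkage clustering at
    identity/coverage thresholds, 50%-majority consensus construction with
    iterative flank elongation, per-copy TSD calling with a length-dependent
    mismatch budget, classification of TSD lengths into discrete classes
    (~4, ~15, ~25 bp), and family-level reporting. A synthetic-genome module
    implants element copies with known termini, TSD regimes, degeneracy and
    truncation, providing ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
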