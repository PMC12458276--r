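Package: retrodiff
Title: Dimorphic Retrotransposon Discovery and Rate Estimation from Genome Assembly Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects dimorphic LINE-1 and SINE insertions from pairwise genome
    assembly comparisons and estimates per-birth retrotransposition rates
    calibrated by a single-nucleotide mutation rate. Provides structural-variant
    filtering against exclusion regions, repeat-content classification,
    split-alignment breakpoint refinement with target-site-duplication and
    target-site-deletion calling, detection of the hallmarks of target-primed
    reverse transcription (poly(A) tails, endonuclease cleavage sites,
    orientation, subfamily), cross-sample locus merging with presence/absence
    matrices, neighbor-joining phylogenetics with bootstrap support and
    locus-to-branch assignment, 3' transduction source tracing, and a forward
    cohort simulator with complete ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), vcfR, withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
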