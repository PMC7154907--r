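Package: chloroprobe
Title: DMS-MaPseq Secondary-Structure Analysis of Chloroplast Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dimethyl-sulfate mutational-profiling
    (DMS-MaPseq) probing of chloroplast transcripts: per-position mutation
    counts are filtered (coverage, primer regions, RNA editing sites,
    modified rRNA nucleotides), converted to raw mutation rates, normalized
    separately for the A/C and G/U channels by percentile-window scaling,
    and winsorized per transcript. Structure statistics include regional
    mean reactivity (start codon, Shine-Dalgarno window, translation
    initiation region, coding region), the Gini index of reactivities, and
    ROC validation of reactivity against a reference structure with a
    solvent-accessibility mask. Shine-Dalgarno strength is scored as the
    minimum nearest-neighbor hybridization free energy of the anti-SD
    against the 5' UTR. A structure-conditioned synthetic count generator,
    a reactivity-guided Nussinov-style folding stand-in, and constraint-file
    export for external folding engines make every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
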