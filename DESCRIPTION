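Package: methscreen
Title: Targeted Bisulfite Amplicon Panels for Methylation-Based Liquid Biopsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating targeted bisulfite amplicon
    assays that detect circulating tumour DNA through dense tumour-specific
    hypermethylation. Covers discovery of candidate hypermethylated regions
    from methylation-array beta matrices, in-silico bisulfite conversion and
    construction of per-probe converted reference sequences, demultiplexing
    and per-read CpG methylation calling of amplicon sequencing reads with
    identity-based filtering, per-sample scoring via the fully-methylated-read
    fraction and a Methylation Index, control-based probe quality control,
    ROC summaries, filtering of clonal-hematopoiesis variant calls, and a
    seeded simulator that generates synthetic panels, beta matrices and read
    cohorts with tunable tumour fraction and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
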