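Package: canidscan
Title: Windowed Fst Selection Scans with Functional Annotation and a
    Coalescent Null for Domestication Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A selection-scan pipeline for contrasting a domesticated
    population against its wild progenitor using whole-genome SNP data.
    Implements per-site Weir & Cockerham (1984) Fst with variance
    components, windowed means with Z-score outlier detection, a
    simplified variant-effect classifier (missense, stop gain/loss,
    UTR, splice region) against GFF3 gene models, fixed/high-Fst site
    selection, pathway over-representation with Bonferroni correction,
    Fst-bin functional-category spectra, flanking-Fst contrasts via
    one-way ANOVA and Tukey's range test, a block-wise structured
    coalescent simulator for neutral windowed-Fst null distributions,
    and a ground-truthed synthetic data generator (VCF, GFF3, FASTA,
    pathway table) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
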