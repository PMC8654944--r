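Package: sng4kit
Title: Downstream Analysis of Single-Nuclei G-Quadruplex CUT&Tag Fragment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of single-nuclei G-quadruplex
    (G4) CUT&Tag experiments starting from 10X-style barcoded fragment files.
    Provides readers and writers for fragment, BED, TSS and copy-number
    tables; per-cell and per-library signal matrices over G4 peak sets with
    FRiP and pseudobulk aggregation; an identity-imputation stack built on
    Spearman correlation, a z-score/upper-quartile-cap/unit-rescale signal
    transform, and k-medoids clustering (PAM and its subsampling extension
    CLARA, implemented here); per-locus supporting-cell quantification with
    common/specific peak partitioning; a Poisson sliding-window peak caller,
    promoter differential-enrichment testing and gene copy-number annotation;
    and a synthetic barcoded-fragment simulator with full ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
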