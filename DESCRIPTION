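Package: methexpress
Title: Integrated Analysis of WGBS Methylomes and Region-Specific
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for integrating whole-genome bisulfite
    sequencing (WGBS) methylomes with matched expression profiles across
    tissue regions. Provides per-cytosine methylation quantification with
    depth filtering, pairwise Fisher's-exact differential methylation with
    Benjamini-Hochberg correction, differentially methylated gene calling
    via first-exon/CpG-island overlap, TMM normalization and deterministic
    PAM (k-medoids) clustering of expression for region-specific gene sets,
    a promoter-CGI methylation vs. expression Pearson correlation screen,
    and repeat-element methylation metaprofiles with inner/outer flank
    statistics. Includes a seeded synthetic-data generator emulating the
    multi-region study design, with machine-readable truth tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    cluster,
    edgeR,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
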