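Package: ampliprof
Title: Species-Level 16S rRNA V1-V2 Amplicon Profiling and Case/Control
    Dysbiosis Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-mapped profiling pipeline for 16S rRNA gene V1-V2
    amplicon reads. Builds a non-redundant full-length 16S reference database
    (quality filtering and 99.8% identity dereplication), quality-filters,
    subsamples and primer-trims per-sample reads, maps reads to references by
    semi-global identity search (>=96% identity, >=90% coverage), forms
    species-level units from mapped references (97% clustering, "rclust") and
    from unmapped reads (96% de-novo OTUs), assigns taxonomy by best-hit
    identity thresholds, and compares case and control communities by alpha
    diversity (observed OTUs, Chao1, Shannon), UniFrac/PCoA/ANOSIM, Welch +
    Benjamini-Hochberg differential abundance with a not-detected read rule,
    longitudinal fold-change validation, and neighbor-joining phylogeny with
    bootstrap support. Ships a synthetic-community generator with planted
    group effects and a known generating phylogeny so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
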