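Package: eaclock
Title: Experiential-Age DNA Methylation Signatures for Proliferating Cell
    Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Derives and applies "experiential age" DNA methylation
    signatures: regions of the genome that gain (or lose) methylation with
    the cumulative replicative history of a cell lineage rather than with
    the chronological age of its host.  Provides a beta-binomial simulator
    of WGBS-style CpG count cohorts with planted age-drifting loci, per-CpG
    two-group differential methylation testing with area-statistic DMR
    segmentation, signature scoring, weighted and mean-of-sites epigenetic
    clock application with saturation (plateau) diagnostics, preranked GSEA
    and binomial region-set enrichment, and genomic/CpG-island annotation
    of differentially methylated regions.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
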