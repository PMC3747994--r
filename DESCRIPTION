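Package: syncomics
Title: Multi-Omic Analysis of Defined Gnotobiotic Gut Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing defined (gnotobiotic) gut microbial
    communities profiled by shotgun sequencing and multi-omics.  Implements
    community profiling by sequencing (COPRO-Seq) with genome-uniqueness
    normalization and percentage-of-maximum-achieved (PoMA) diet-response
    summaries, Hellinger-distance ordination, dual-level (community and
    species) normalization and EC-number functional binning of
    metatranscriptomes with detection of masked within-species responses,
    in-silico tryptic peptidome construction with peptide-uniqueness
    accounting, label-free spectral-count differential calling with Storey
    q-values, polysaccharide utilization locus (PUL) activation calling from
    susC/susD marker pairs, transposon-insertion (INSeq) fitness estimation,
    and OD600 growth-curve phenotyping.  A synthetic-community simulator
    generates genomes, reads, count matrices, insertion libraries and growth
    curves with the statistical structure these analyses assume, so the whole
    pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
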