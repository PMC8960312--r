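Package: cnvconcord
Title: Point-Based Scoring and Inter-Laboratory Concordance Analysis for
    Copy-Number Variant Classification
Version: 0.1.0
Authors@R:
    person("NCCL", "Concordance Tools", email = "cnvconcord@example.org",
           role = c("aut", "cre"))
Description: Implements the ACMG-ClinGen semiquantitative point-based
    scoring metric for clinical copy-number variant (CNV) classification as
    a configurable rubric engine: evidence categories for losses and gains
    carry signed points that are summed and mapped to the five-tier
    pathogenic / likely pathogenic / uncertain / likely benign / benign
    scale.  Deterministic annotation-driven evidence assignment (genomic
    content, dosage sensitivity, gene number) reproduces the decision
    points known to drive inter-laboratory discordance.  A concordance
    module classifies multi-laboratory label patterns into complete
    concordance, confidence differences, conflicts impacting medical
    management, and conflicts impacting return of results, with chi-square
    rate comparisons; an audit module tabulates re-evaluation rounds and
    discordance reasons.  A simulator generates annotation sets, CNV panels
    and multi-laboratory classification matrices with injectable error
    modes so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
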