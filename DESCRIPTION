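Package: crosscall
Title: Consensus Somatic Variant Filtering for Tumor-Normal Exome Pairs
Version: 0.1.0
Authors@R: person("crosscall", "developers", role = c("aut", "cre"),
    email = "crosscall@example.org")
Description: Implements a dual-workflow consensus approach to somatic
    single-nucleotide variant discovery in tumor-normal exome pairs. Somatic
    VCFs from two independent variant callers are normalized into a common
    representation, passed through a shared filter cascade (caller PASS
    status, quality score, alternate-read support, germline coverage,
    homopolymer and repeat sequence context, population allele frequency,
    germline subtraction), and intersected so that only variants reported by
    both workflows are retained. Cohort-level summaries (subclonality by
    allele fraction, transition/transversion ratio, functional-consequence
    tallies, CADD deleteriousness tiers, and cross-sample recurrence) are
    computed over the consensus sets. A self-contained synthetic cohort
    generator emulates both caller dialects with designed true variants and
    injected artifact classes so the whole pipeline can be exercised and
    evaluated against ground truth without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    VariantAnnotation,
    SummarizedExperiment,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
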