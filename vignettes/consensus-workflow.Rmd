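---
title: "Dual-caller consensus filtering of somatic exome variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-caller consensus filtering of somatic exome variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosscall)
```

## The problem

Somatic variant discovery in tumor-normal exome pairs is notoriously
caller-dependent: two reasonable pipelines run on the same alignments
disagree on a substantial fraction of their raw calls, and the disagreeing
calls are enriched for low allele fractions and context artifacts. One
pragmatic remedy, used in tumor cohort studies including pituitary
neuroendocrine tumor exome work, is to run two independent somatic callers,
push both call sets through an identical filter cascade, and report only
variants on which both workflows agree. crosscall implements that whole
procedure as a reusable, auditable pipeline, together with the cohort
summaries such studies report and a synthetic data generator that makes
every stage testable without access to raw (typically controlled-access)
sequencing data.

## The procedure

Each caller's somatic VCF is first normalized into a common representation:
multi-allelic records are split, shared allele bases trimmed, indels
left-aligned against the reference, and each dialect's quality and read
support mapped onto unified fields. Dialect A stands for an
allele-depth-reporting caller (record `QUAL`, per-sample `DP`/`AD`);
dialect B for a tiered-count caller (site-level somatic score in an INFO
key, per-base tier-1 counts `AU`/`CU`/`GU`/`TU`, `TAR`/`TIR` for indels).

Every normalized call is then evaluated against all filters:

| filter | pass condition | default |
|---|---|---|
| caller verdict | `FILTER == "PASS"` | required |
| quality score | unified score ≥ `min_qual` | 10 (inclusive) |
| read support | tumor alt reads ≥ `min_alt_reads` | 4 (inclusive) |
| normal coverage | normal depth at site ≥ `min_normal_depth` | 10X (inclusive) |
| homopolymer context | not within or within `homopolymer_distance` nt of a run of ≥ `homopolymer_min_run` identical bases | 1 nt, 4 bases |
| repeat context | position outside the repeat mask | — |
| population frequency | no matching population record with MAF strictly > `max_population_maf` | 0.1% |
| germline subtraction | exact variant key absent from the patient's germline call set | — |

All predicates are evaluated for every call — the verdict is a conjunction,
so it cannot depend on evaluation order, and the audit trail records every
reason a call failed rather than the first one. Survivors of both callers
are intersected on the exact variant key `(contig, pos, ref, alt)`; the
intersection is the consensus call set, with the allele fraction computed
from the designated caller's read counts (`af_source`, default A, with
fallback to B when A lacks depth).

Cohort summaries over the consensus sets: per-sample counts,
transition/transversion ratio (A↔G and C↔T are transitions; undefined —
reported as `NA`, not an error — when there are no transversions),
subclonality (AF strictly below 0.20), consequence tallies over a fixed
Sequence-Ontology-derived category table with an exonic roll-up, CADD Phred
tiers (> 30, and the exclusive 20–30 band plus its cumulative sum, so both
readings of "a further N variants" are available), and recurrence at two
levels: identical variants shared by ≥ 2 samples, and genes hit in ≥ 2
distinct samples. A gene whose recurrence is carried entirely by one
identical shared variant is flagged `position_level` and not presented as
independent gene-level evidence.

## Boundary and tie-break choices

* Thresholds are inclusive exactly as the workflow is conventionally
  worded: a quality score of exactly 10, exactly 4 supporting reads and
  exactly 10X normal coverage all pass; a population MAF of exactly 0.1%
  passes (only strictly greater is filtered); an allele fraction of exactly
  0.20 is *not* subclonal; a CADD score of exactly 20 (or 30) sits below
  its tier boundary.
* Population matching is allele-aware by default. "Colocated" SNP matching
  is ambiguous in the field's usage; allele-aware is strictly safer (it
  never removes a different somatic allele at a known SNP position) and a
  position-only mode exists (`population_match = "position"`) for
  comparison experiments.
* Variant identity everywhere (intersection, germline subtraction,
  recurrence) is the exact normalized key; position-only matching was
  rejected because it conflates distinct alleles.
* The normal depth track, when it covers a site, wins over the normal DP
  recorded in a somatic VCF: it is the dedicated evidence for the coverage
  check. Positions covered by neither answer 0 and fail the coverage
  filter.
* Homopolymer runs of N are never reported: N encodes uncertainty, not
  sequence. Other IUPAC ambiguity codes are normalized to N on FASTA
  ingestion. Soft-masked (lowercase) sequence is uppercased, not treated as
  a repeat mask — repeat status comes only from the explicit repeat BED, so
  evidence sources stay separable.
* Indels are ingested and flow through every filter even though an
  SNV-only outcome is common in exome consensus sets; `snv_only = TRUE` is
  a configuration switch, not a hard-coded assumption.
* The dialect-B quality key is `SomaticEVS` by default and redirectable
  (`qual_info_key`), since which score field a "quality ≥ 10" threshold
  should read is the least standardized part of tiered-count somatic VCFs.

## The synthetic cohort generator

`simulation_config()` describes a stated world: 15 tumor-normal pairs over
a 100 kb two-contig genome, mean depth 50X (Poisson), clonal somatic
variants at AF 0.3–0.6, subclonal at AF below 0.20, roughly 31 truth
records per sample, substitutions drawn with transition probability 0.565
(expected Ti/Tv ≈ 1.3, the value typical of tumor exome consensus sets),
plus two records per sample of each artifact class. Each artifact class is
tied to exactly one filter — low score, < 4 alt reads, < 10X normal depth,
homopolymer-adjacent placement, repeat placement, population-SNP leak,
germline sharing, or presence in only one caller — so the evaluator's
confusion table is diagnostic about *which* filter removed *what*. For the
same reason the default fraction of artifact records carrying a non-PASS
caller FILTER string is 0 (`nonpass_fraction` raises it).

The background sequence is generated free of homopolymer runs ≥ 4 and the
configured runs are planted with flanks forced to differ from the run base,
so the planted runs are provably the exact maximal-run set — the scanner
can be tested against construction, not just against a brute-force oracle.

Two design points deserve emphasis:

* **Noise switch.** With `noise = FALSE` depth and alt counts are
  deterministic (`round(depth × af)`), which makes the strongest oracle
  available: the pipeline's consensus output must equal the
  CONSENSUS-fate truth set *exactly*. With `noise = TRUE` (default),
  binomial sampling means a designed subclonal variant can legitimately
  drop below the read-support threshold; the guaranteed property is then
  recall ≥ 0.95 for clonal variants at 50X, which binomial tail bounds
  make comfortably true.
* **Subclonal design floor.** A subclonal AF range reaching down to 0.05
  would be self-contradictory at 50X: `round(50 × 0.05) = 2 < 4` supporting
  reads, so such a variant could never be recovered and its designed fate
  could not be a pure function of its class. The generator therefore floors
  the subclonal draw at `min_alt_reads / mean_depth` (0.08 at defaults),
  keeping the whole range below the 0.20 threshold while making every
  designed subclonal variant recoverable in the noiseless regime.

What a green synthetic test does *not* establish: the generator models no
GC or mapping bias, no caller-specific error model, no contamination of the
tumor sample with normal cells, and both dialects observe the same pileup.
The filters under test consume only depths, scores and flags, so
richer read-level simulation would add realism without adding testable
surface; conclusions about real-data sensitivity/specificity still require
real data.

## Configuration and reproducibility

All stages are driven by a single declarative JSON configuration. There are
no hidden defaults: every threshold actually used — defaulted or not — is
materialized into `run_manifest.json` in the output directory, and the
logged attrition reports per-filter counts per caller per sample. The
entire synthetic bundle is a pure function of its configuration (seed
included) and is written with deterministic headers, so reruns are
byte-identical; this is enforced by tests. JSON was chosen over YAML
because the target environment guarantees a JSON parser.

A standalone summary entry point (`cmd_summarize`) builds the cohort report
directly from a pre-annotated variant table (TSV/CSV, or XLSX when readxl
is installed), with tolerant column-name resolution and percent-formatted
allele fractions parsed, so published supplementary variant tables can be
re-summarized without re-running variant calling.

## Known limitations

* Consequence and CADD annotations are consumed from a table, never
  computed; the consequence vocabulary covers the common exome categories
  and everything else tallies as "other".
* Germline subtraction is applied uniformly whenever a germline VCF is
  supplied, including to a caller that already reports somatic-only
  variants; for such callers the subtraction is a no-op safety net rather
  than a distortion.
* Left-alignment assumes the reference allele matches the reference
  sequence and stops at contig start; breakend and symbolic alleles are
  skipped with a logged count rather than normalized.
* Recurrence statistics are descriptive; no significance testing or
  driver-gene inference is attempted.
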