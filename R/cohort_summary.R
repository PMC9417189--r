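#' Cohort summary configuration
#'
#' @param subclonal_af_threshold Allele fraction strictly below which a
#'   variant is called subclonal (default 0.20).
#' @param cadd_high_tier CADD Phred score strictly above which a variant
#'   falls in the top deleteriousness tier (default 30, ~top 0.1%).
#' @param cadd_mid_tier Lower tier boundary (default 20, ~top 1%).
#' @return A `SummaryConfig` list.
#' @export
summary_config <- function(subclonal_af_threshold = 0.20,
                           cadd_high_tier = 30, cadd_mid_tier = 20) {
  stopifnot(subclonal_af_threshold > 0, subclonal_af_threshold < 1,
            cadd_mid_tier < cadd_high_tier)
  structure(list(subclonal_af_threshold = subclonal_af_threshold,
                 cadd_high_tier = cadd_high_tier,
                 cadd_mid_tier = cadd_mid_tier),
            class = "SummaryConfig")
}

#' Subclonality by allele fraction
#'
#' Strictly below the threshold: an AF of exactly 0.20 is clonal under the
#' default configuration.
#'
#' @param af Numeric vector of allele fractions in `[0, 1]` (NA allowed).
#' @param cfg A `SummaryConfig`.
#' @return Logical vector (NA where AF is unknown).
#' @export
classify_subclonal <- function(af, cfg = summary_config()) {
  bad <- !is.na(af) & (af < 0 | af > 1)
  if (any(bad)) stop("allele fraction outside [0,1]")
  af < cfg$subclonal_af_threshold
}

transition_pairs <- c("A:G", "G:A", "C:T", "T:C")

#' Transition/transversion ratio
#'
#' Transitions are purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T)
#' SNVs; every other SNV substitution is a transversion. Non-SNV records are
#' excluded. With zero transversions the ratio is undefined and `NA` is
#' returned (a tagged "undefined", not an error and not `Inf`).
#'
#' @param variants data.frame with `ref` and `alt` columns.
#' @return A list with `titv` (numeric or NA), `n_ts`, `n_tv`.
#' @export
titv_ratio <- function(variants) {
  snv <- variants[nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, ,
                  drop = FALSE]
  ts <- paste(snv$ref, snv$alt, sep = ":") %in% transition_pairs
  n_ts <- sum(ts); n_tv <- nrow(snv) - n_ts
  list(titv = if (n_tv == 0L) NA_real_ else n_ts / n_tv,
       n_ts = n_ts, n_tv = n_tv)
}

# Fixed mapping from normalized Sequence-Ontology-style consequence strings
# to tally categories.
consequence_category_map <- c(
  missense_variant = "amino_acid_changing",
  stop_gained = "amino_acid_changing",
  stop_lost = "amino_acid_changing",
  start_lost = "amino_acid_changing",
  protein_altering_variant = "amino_acid_changing",
  synonymous_variant = "synonymous",
  stop_retained_variant = "synonymous",
  "3_prime_utr_variant" = "utr3",
  "5_prime_utr_variant" = "utr5",
  non_coding_transcript_exon_variant = "noncoding_exon",
  intron_variant = "intron",
  non_coding_transcript_variant = "intron",
  splice_region_variant = "splice_region",
  splice_donor_variant = "splice_region",
  splice_acceptor_variant = "splice_region",
  upstream_gene_variant = "upstream_downstream",
  downstream_gene_variant = "upstream_downstream",
  intergenic_variant = "intergenic"
)

tally_categories <- c("amino_acid_changing", "synonymous", "utr3", "utr5",
                      "noncoding_exon", "intron", "splice_region",
                      "upstream_downstream", "intergenic", "other")

#' Map consequence strings to tally categories
#' @param consequence Character vector (raw or normalized strings).
#' @return Character vector of categories; unknown strings map to "other".
#' @export
consequence_category <- function(consequence) {
  x <- normalize_consequence(consequence)
  out <- unname(consequence_category_map[x])
  out[is.na(out)] <- "other"
  out
}

#' Tally variants by primary consequence category
#'
#' Each variant contributes to exactly one category; the `exonic` roll-up
#' (amino-acid changing + synonymous + 3'/5' UTR + non-coding exon) is
#' returned alongside.
#'
#' @param variants data.frame with a `consequence` column.
#' @return A list with `tally` (named integer vector over all categories)
#'   and `exonic` (integer roll-up).
#' @export
tally_consequences <- function(variants) {
  cat <- consequence_category(variants$consequence)
  tally <- vapply(tally_categories, function(k) sum(cat == k, na.rm = TRUE),
                  integer(1))
  exonic <- sum(tally[c("amino_acid_changing", "synonymous", "utr3", "utr5",
                        "noncoding_exon")])
  list(tally = tally, exonic = unname(exonic))
}

#' CADD deleteriousness tiers
#'
#' Tier boundaries are strict: `> cadd_high_tier` for the top tier,
#' `cadd_mid_tier < score <= cadd_high_tier` for the exclusive middle band.
#' Both the exclusive middle count and the cumulative count above the lower
#' boundary are reported; variants without a CADD score are counted
#' separately.
#'
#' @param variants data.frame with a `cadd_phred` column.
#' @param cfg A `SummaryConfig`.
#' @return List with `n_above_high`, `n_mid_exclusive`,
#'   `n_above_mid_cumulative`, `n_unknown`.
#' @export
cadd_tiers <- function(variants, cfg = summary_config()) {
  x <- variants$cadd_phred
  known <- !is.na(x)
  n_high <- sum(known & x > cfg$cadd_high_tier)
  n_mid <- sum(known & x > cfg$cadd_mid_tier & x <= cfg$cadd_high_tier)
  list(n_above_high = n_high, n_mid_exclusive = n_mid,
       n_above_mid_cumulative = n_high + n_mid, n_unknown = sum(!known))
}

#' Variants recurring at the same position across samples
#'
#' @param cohort Named list: sample_id -> consensus variant data.frame.
#' @return data.frame with one row per variant key present in >= 2 samples:
#'   `contig`, `pos1`, `ref`, `alt`, `n_samples`, `samples` (comma-joined),
#'   `afs` (comma-joined per-sample allele fractions, same order), sorted by
#'   descending sample count then genomic position.
#' @export
recurrent_positions <- function(cohort) {
  empty <- data.frame(contig = character(), pos1 = integer(),
                      ref = character(), alt = character(),
                      n_samples = integer(), samples = character(),
                      afs = character(), stringsAsFactors = FALSE)
  rows <- lapply(names(cohort), function(s) {
    v <- cohort[[s]]
    if (is.null(v) || nrow(v) == 0L) return(NULL)
    data.frame(sample_id = s, contig = v$contig, pos1 = v$pos1, ref = v$ref,
               alt = v$alt,
               af = if ("af" %in% names(v)) v$af else NA_real_,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0L) return(empty)
  key <- variant_key(all)
  keep <- names(which(vapply(split(all$sample_id, key),
                             function(s) length(unique(s)), integer(1)) >= 2L))
  if (!length(keep)) return(empty)
  out <- do.call(rbind, lapply(keep, function(k) {
    d <- all[key == k, , drop = FALSE]
    d <- d[!duplicated(d$sample_id), , drop = FALSE]
    data.frame(contig = d$contig[1L], pos1 = d$pos1[1L], ref = d$ref[1L],
               alt = d$alt[1L], n_samples = nrow(d),
               samples = paste(d$sample_id, collapse = ","),
               afs = paste(ifelse(is.na(d$af), "NA", sprintf("%.4f", d$af)),
                           collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_samples, out$contig, out$pos1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes carrying consensus variants in multiple samples
#'
#' A gene is recurrent when >= 2 distinct samples carry any consensus
#' variant in it. Genes that qualify only because the identical variant is
#' shared across samples are flagged `position_level = TRUE` (they are
#' already reported by [recurrent_positions()] and are not gene-level
#' evidence of independent hits).
#'
#' @param cohort Named list: sample_id -> annotated consensus data.frame
#'   (needs `gene`; `consequence`/`cadd_phred` carried through if present).
#' @return data.frame with one row per (gene, sample, variant): `gene`,
#'   `sample_id`, `contig`, `pos1`, `ref`, `alt`, `consequence`,
#'   `cadd_phred`, `n_samples`, `position_level`.
#' @export
recurrent_genes <- function(cohort) {
  empty <- data.frame(gene = character(), sample_id = character(),
                      contig = character(), pos1 = integer(),
                      ref = character(), alt = character(),
                      consequence = character(), cadd_phred = numeric(),
                      n_samples = integer(), position_level = logical(),
                      stringsAsFactors = FALSE)
  rows <- lapply(names(cohort), function(s) {
    v <- cohort[[s]]
    if (is.null(v) || nrow(v) == 0L || !"gene" %in% names(v)) return(NULL)
    data.frame(gene = v$gene, sample_id = s, contig = v$contig,
               pos1 = v$pos1, ref = v$ref, alt = v$alt,
               consequence = if ("consequence" %in% names(v)) v$consequence
                             else NA_character_,
               cadd_phred = if ("cadd_phred" %in% names(v)) v$cadd_phred
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (is.null(all)) return(empty)
  all <- all[!is.na(all$gene) & nzchar(all$gene), , drop = FALSE]
  if (nrow(all) == 0L) return(empty)
  out <- do.call(rbind, lapply(split(all, all$gene), function(d) {
    if (length(unique(d$sample_id)) < 2L) return(NULL)
    keys <- variant_key(d)
    # position-level: every pair of samples shares the identical variant key
    d$n_samples <- length(unique(d$sample_id))
    d$position_level <- length(unique(keys)) == 1L
    d
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$gene, out$sample_id, out$contig, out$pos1), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the full cohort report
#'
#' @param cohort Named list: sample_id -> consensus variant data.frame
#'   (annotated with `gene`, `consequence`, `cadd_phred` where available).
#' @param cfg A `SummaryConfig`.
#' @return A `CohortReport` list: per-sample counts, mean/range,
#'   consequence tally with exonic roll-up, Ti/Tv, subclonal counts, CADD
#'   tiers, recurrent positions and genes.
#' @export
build_cohort_report <- function(cohort, cfg = summary_config()) {
  nz <- lapply(cohort, function(v) if (is.null(v)) somatic_calls()[0, ] else v)
  per_sample <- vapply(nz, nrow, integer(1))
  all <- do.call(rbind, lapply(names(nz), function(s) {
    v <- nz[[s]]
    if (nrow(v) == 0L) return(NULL)
    v$sample_id <- s
    v
  }))
  n_total <- sum(per_sample)
  if (is.null(all))
    all <- data.frame(sample_id = character(), contig = character(),
                      pos1 = integer(), ref = character(), alt = character(),
                      af = numeric(), consequence = character(),
                      cadd_phred = numeric(), stringsAsFactors = FALSE)
  if (!"af" %in% names(all)) all$af <- rep(NA_real_, nrow(all))
  if (!"consequence" %in% names(all))
    all$consequence <- rep(NA_character_, nrow(all))
  if (!"cadd_phred" %in% names(all)) all$cadd_phred <- rep(NA_real_, nrow(all))

  sub <- classify_subclonal(all$af, cfg)
  n_af_known <- sum(!is.na(sub))
  n_subclonal <- sum(sub, na.rm = TRUE)
  tv <- tally_consequences(all)
  report <- list(
    n_samples = length(nz),
    per_sample_counts = per_sample,
    n_total = n_total,
    mean_per_sample = if (length(per_sample)) mean(per_sample) else NA_real_,
    range_per_sample = if (length(per_sample)) range(per_sample)
                       else c(NA_integer_, NA_integer_),
    consequence_tally = tv$tally,
    n_exonic = tv$exonic,
    titv = titv_ratio(all),
    n_subclonal = n_subclonal,
    n_af_known = n_af_known,
    subclonal_fraction = if (n_af_known > 0L) n_subclonal / n_af_known
                         else NA_real_,
    cadd = cadd_tiers(all, cfg),
    recurrent_positions = recurrent_positions(nz),
    recurrent_genes = recurrent_genes(nz),
    config = cfg
  )
  structure(report, class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("Cohort consensus report\n")
  cat(sprintf("  samples: %d, consensus variants: %d (mean %.2f, range %s-%s)\n",
              x$n_samples, x$n_total, x$mean_per_sample,
              x$range_per_sample[1], x$range_per_sample[2]))
  cat("  consequence tally:\n")
  for (k in names(x$consequence_tally))
    if (x$consequence_tally[[k]] > 0L)
      cat(sprintf("    %-20s %d\n", k, x$consequence_tally[[k]]))
  cat(sprintf("  exonic (roll-up): %d\n", x$n_exonic))
  if (is.na(x$titv$titv)) {
    cat(sprintf("  Ti/Tv: undefined (%d transitions, 0 transversions)\n",
                x$titv$n_ts))
  } else {
    cat(sprintf("  Ti/Tv: %.2f (%d transitions / %d transversions)\n",
                x$titv$titv, x$titv$n_ts, x$titv$n_tv))
  }
  if (x$n_af_known > 0L)
    cat(sprintf("  subclonal (AF < %.2f): %d of %d with known AF (%.2f%%)\n",
                x$config$subclonal_af_threshold, x$n_subclonal, x$n_af_known,
                100 * x$subclonal_fraction))
  cat(sprintf("  CADD tiers: >%g: %d; %g-%g: %d (cumulative >%g: %d); unknown: %d\n",
              x$config$cadd_high_tier, x$cadd$n_above_high,
              x$config$cadd_mid_tier, x$config$cadd_high_tier,
              x$cadd$n_mid_exclusive, x$config$cadd_mid_tier,
              x$cadd$n_above_mid_cumulative, x$cadd$n_unknown))
  cat(sprintf("  recurrent positions (>=2 samples): %d\n",
              nrow(x$recurrent_positions)))
  rg <- x$recurrent_genes
  gene_level <- unique(rg$gene[!rg$position_level])
  pos_level <- unique(rg$gene[rg$position_level])
  cat(sprintf("  recurrent genes (distinct positions): %s\n",
              if (length(gene_level)) paste(gene_level, collapse = ", ")
              else "none"))
  if (length(pos_level))
    cat(sprintf("  genes recurrent via a shared identical variant: %s\n",
                paste(pos_level, collapse = ", ")))
  invisible(x)
}

#' Serialize a CohortReport to TSV files and a text summary
#'
#' @param report A `CohortReport`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    w(data.frame(sample_id = names(report$per_sample_counts),
                 n_consensus = unname(report$per_sample_counts)),
      "per_sample_counts.tsv"),
    w(data.frame(category = names(report$consequence_tally),
                 n = unname(report$consequence_tally)),
      "consequence_tally.tsv"),
    w(report$recurrent_positions, "recurrent_positions.tsv"),
    w(report$recurrent_genes, "recurrent_genes.tsv")
  )
  txt <- file.path(dir, "cohort_summary.txt")
  con <- file(txt, "w")
  sink(con); print(report); sink()
  close(con)
  invisible(c(paths, txt))
}
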