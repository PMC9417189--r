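#' Filter cascade configuration
#'
#' Thresholds are inclusive exactly as the workflow is worded: a quality
#' score of 10, four alternate reads and 10X normal coverage all pass; the
#' population filter removes only frequencies strictly above
#' `max_population_maf`.
#'
#' @param min_qual Minimum unified quality score (pass when `qual >=`).
#' @param min_alt_reads Minimum tumor alternate-read support (pass when `>=`).
#' @param min_normal_depth Minimum normal-sample depth at the site (`>=`).
#' @param homopolymer_min_run Minimum homopolymer run length considered a
#'   context hazard.
#' @param homopolymer_distance Adjacency distance in nucleotides.
#' @param max_population_maf Population MAF above which a known variant is
#'   removed (strict `>`).
#' @param require_pass Require the caller's own FILTER field to be "PASS".
#' @param snv_only Drop non-SNV records (off by default; indels flow through
#'   every filter unless switched on).
#' @param population_match `"allele"` (default, exact allele match) or
#'   `"position"` (any allele at the site).
#' @param af_source Which caller's read counts define the consensus allele
#'   fraction, `"A"` or `"B"`.
#' @param qual_info_key INFO key holding the dialect-B somatic score.
#' @return A `FilterConfig` list.
#' @export
filter_config <- function(min_qual = 10, min_alt_reads = 4L,
                          min_normal_depth = 10L, homopolymer_min_run = 4L,
                          homopolymer_distance = 1L,
                          max_population_maf = 0.001, require_pass = TRUE,
                          snv_only = FALSE,
                          population_match = c("allele", "position"),
                          af_source = c("A", "B"),
                          qual_info_key = "SomaticEVS") {
  population_match <- match.arg(population_match)
  af_source <- match.arg(af_source)
  stopifnot(min_qual >= 0, min_alt_reads >= 0, min_normal_depth >= 0,
            homopolymer_min_run >= 2, homopolymer_distance >= 0,
            max_population_maf >= 0, max_population_maf <= 1)
  structure(list(
    min_qual = min_qual, min_alt_reads = as.integer(min_alt_reads),
    min_normal_depth = as.integer(min_normal_depth),
    homopolymer_min_run = as.integer(homopolymer_min_run),
    homopolymer_distance = as.integer(homopolymer_distance),
    max_population_maf = max_population_maf, require_pass = require_pass,
    snv_only = snv_only, population_match = population_match,
    af_source = af_source, qual_info_key = qual_info_key
  ), class = "FilterConfig")
}

filter_reasons <- c("FAIL_FILTER_FIELD", "FAIL_QUAL", "FAIL_ALT_READS",
                    "FAIL_NORMAL_COVERAGE", "FAIL_HOMOPOLYMER", "FAIL_REPEAT",
                    "FAIL_POPULATION_MAF", "FAIL_GERMLINE_MATCH",
                    "FAIL_NON_SNV")

outcome_from_flags <- function(calls, flags) {
  # flags: named list of logical vectors, one per reason
  mat <- do.call(cbind, flags)
  reasons <- apply(mat, 1L, function(r) paste(names(flags)[r], collapse = ";"))
  calls$passed <- !apply(mat, 1L, any)
  calls$reasons <- reasons
  calls
}

is_snv <- function(calls) nchar(calls$ref) == 1L & nchar(calls$alt) == 1L

#' Record-level filters
#'
#' Caller FILTER field, unified quality score, alternate-read support and
#' (optionally) SNV-only status. Every failing predicate contributes its
#' reason; nothing short-circuits.
#'
#' @param calls Somatic call table.
#' @param cfg A `FilterConfig`.
#' @return The calls with `passed` and `reasons` columns (a `;`-joined
#'   subset of the reason vocabulary).
#' @export
apply_record_filters <- function(calls, cfg = filter_config()) {
  outcome_from_flags(calls, list(
    FAIL_FILTER_FIELD = if (cfg$require_pass) calls$filter != "PASS"
                        else rep(FALSE, nrow(calls)),
    FAIL_QUAL = calls$qual < cfg$min_qual,
    FAIL_ALT_READS = calls$alt_depth < cfg$min_alt_reads,
    FAIL_NON_SNV = if (cfg$snv_only) !is_snv(calls)
                   else rep(FALSE, nrow(calls))
  ))
}

# Resolve the normal-sample depth for each call: the dedicated depth track
# wins wherever it covers the position; otherwise the normal DP recorded in
# the somatic VCF; otherwise 0 (no evidence of coverage).
resolved_normal_depth <- function(calls, track) {
  n <- nrow(calls)
  if (n == 0L) return(integer())
  out <- ifelse(is.na(calls$normal_depth), 0L, calls$normal_depth)
  if (!is.null(track)) {
    for (ctg in unique(calls$contig)) {
      sel <- calls$contig == ctg
      d <- track[track$contig == ctg, , drop = FALSE]
      if (nrow(d) == 0L) next
      pos0 <- calls$pos1[sel] - 1L
      idx <- findInterval(pos0, d$start)
      covered <- idx > 0L & pos0 < d$end[pmax(idx, 1L)]
      v <- out[sel]
      v[covered] <- as.integer(d$depth[idx[covered]])
      out[sel] <- v
    }
  }
  as.integer(out)
}

#' Site-context filters
#'
#' Normal-sample coverage, homopolymer proximity and repeat-region
#' membership at the variant position.
#'
#' @param calls Somatic call table.
#' @param runs Homopolymer runs from [scan_homopolymers()] (scanned with
#'   `cfg$homopolymer_min_run`).
#' @param repeats Repeat-region `IntervalSet`.
#' @param depth_track Normal-sample `DepthTrack` (or NULL).
#' @param cfg A `FilterConfig`.
#' @return Calls with `passed`/`reasons`.
#' @export
apply_site_filters <- function(calls, runs, repeats, depth_track,
                               cfg = filter_config()) {
  n <- nrow(calls)
  homop <- logical(n); rep_hit <- logical(n)
  for (ctg in unique(calls$contig)) {
    sel <- calls$contig == ctg
    homop[sel] <- is_homopolymer_proximal(ctg, calls$pos1[sel], runs,
                                          cfg$homopolymer_distance)
    rep_hit[sel] <- in_interval_set(ctg, calls$pos1[sel], repeats)
  }
  nd <- resolved_normal_depth(calls, depth_track)
  outcome_from_flags(calls, list(
    FAIL_NORMAL_COVERAGE = nd < cfg$min_normal_depth,
    FAIL_HOMOPOLYMER = homop,
    FAIL_REPEAT = rep_hit
  ))
}

#' Population allele-frequency filter
#'
#' A call matching a population record with MAF strictly above
#' `cfg$max_population_maf` fails; matches at or below the threshold (and
#' absent variants) pass. Matched records are "registered": the MAF is
#' recorded on the outcome either way.
#'
#' @param calls Somatic call table.
#' @param freqs A `pop_freqs` lookup (or NULL).
#' @param cfg A `FilterConfig`.
#' @return Calls with `passed`/`reasons` and a `population_maf` column.
#' @export
apply_population_filter <- function(calls, freqs, cfg = filter_config()) {
  maf <- pop_maf(freqs, calls, by_position = cfg$population_match == "position")
  out <- outcome_from_flags(calls, list(
    FAIL_POPULATION_MAF = !is.na(maf) & maf > cfg$max_population_maf
  ))
  out$population_maf <- maf
  out
}

#' Germline subtraction
#'
#' Removes tumor calls whose exact variant key (contig, position, ref, alt)
#' also appears in the patient's germline call set. Matching is
#' allele-level: the same position with a different alternate allele does
#' not match.
#'
#' @param calls Somatic call table.
#' @param germline_keys Character vector of germline variant keys (from
#'   [read_germline_vcf()]), or NULL/empty for no subtraction.
#' @return Calls with `passed`/`reasons`.
#' @export
subtract_germline <- function(calls, germline_keys) {
  if (is.null(germline_keys)) germline_keys <- character()
  outcome_from_flags(calls, list(
    FAIL_GERMLINE_MATCH = variant_key(calls) %in% germline_keys
  ))
}

#' Run the full filter cascade over one caller's call set
#'
#' All predicates are evaluated for every call (the verdict is the
#' conjunction of independently applied predicates, so it cannot depend on
#' evaluation order), and every failing predicate contributes its reason to
#' the audit trail.
#'
#' @param calls Somatic call table (normalized).
#' @param runs Homopolymer runs.
#' @param repeats Repeat `IntervalSet`.
#' @param depth_track Normal `DepthTrack` (or NULL).
#' @param freqs `pop_freqs` lookup (or NULL).
#' @param germline_keys Germline variant keys (or NULL).
#' @param cfg A `FilterConfig`.
#' @return A list with `survivors` (calls passing everything), `audit`
#'   (every call with `passed`, `reasons`, `population_maf`) and
#'   `attrition` (data.frame of per-reason failure counts plus totals).
#' @export
run_cascade <- function(calls, runs, repeats, depth_track = NULL,
                        freqs = NULL, germline_keys = NULL,
                        cfg = filter_config()) {
  if (nrow(calls) == 0L) {
    audit <- calls; audit$passed <- logical(); audit$reasons <- character()
    audit$population_maf <- numeric()
    return(list(survivors = calls, audit = audit,
                attrition = data.frame(reason = filter_reasons, n = 0L)))
  }
  rec <- apply_record_filters(calls, cfg)
  germ <- subtract_germline(calls, germline_keys)
  site <- apply_site_filters(calls, runs, repeats, depth_track, cfg)
  pop <- apply_population_filter(calls, freqs, cfg)

  join <- function(...) {
    parts <- cbind(...)
    apply(parts, 1L, function(r) paste(r[nzchar(r)], collapse = ";"))
  }
  audit <- calls
  audit$reasons <- join(rec$reasons, germ$reasons, site$reasons, pop$reasons)
  audit$passed <- !nzchar(audit$reasons)
  audit$population_maf <- pop$population_maf

  counts <- vapply(filter_reasons, function(r)
    sum(grepl(r, audit$reasons, fixed = TRUE)), integer(1))
  attrition <- data.frame(reason = filter_reasons, n = unname(counts))
  list(survivors = somatic_calls(audit[audit$passed, call_columns]),
       audit = audit, attrition = attrition)
}

#' Intersect two callers' surviving call sets into consensus variants
#'
#' A variant is consensus when its exact key survives the cascade in both
#' callers for the same sample. The allele fraction is computed from the
#' designated caller's read counts (`af_source`), falling back to the other
#' caller when those counts are absent or zero-depth.
#'
#' @param survivors_A Dialect-A survivors (one sample).
#' @param survivors_B Dialect-B survivors (same sample).
#' @param af_source `"A"` (default) or `"B"`.
#' @return data.frame of consensus variants sorted by (contig, pos1):
#'   `sample_id`, `contig`, `pos1`, `ref`, `alt`, `af`, per-caller
#'   qual/depth evidence columns.
#' @export
intersect_callsets <- function(survivors_A, survivors_B,
                               af_source = c("A", "B")) {
  af_source <- match.arg(af_source)
  sids <- unique(c(survivors_A$sample_id, survivors_B$sample_id))
  if (length(sids) > 1L)
    stop("intersect_callsets expects call sets from a single sample, got: ",
         paste(sids, collapse = ", "))
  ka <- variant_key(survivors_A); kb <- variant_key(survivors_B)
  if (anyDuplicated(ka)) stop("duplicate variant key in caller A survivors")
  if (anyDuplicated(kb)) stop("duplicate variant key in caller B survivors")
  shared <- intersect(ka, kb)
  a <- survivors_A[match(shared, ka), , drop = FALSE]
  b <- survivors_B[match(shared, kb), , drop = FALSE]
  af_of <- function(x) ifelse(!is.na(x$total_depth) & x$total_depth > 0L,
                              x$alt_depth / x$total_depth, NA_real_)
  af_primary <- if (af_source == "A") af_of(a) else af_of(b)
  af_fallback <- if (af_source == "A") af_of(b) else af_of(a)
  out <- data.frame(
    sample_id = a$sample_id, contig = a$contig, pos1 = a$pos1,
    ref = a$ref, alt = a$alt,
    af = ifelse(is.na(af_primary), af_fallback, af_primary),
    qual_A = a$qual, qual_B = b$qual,
    alt_depth_A = a$alt_depth, total_depth_A = a$total_depth,
    alt_depth_B = b$alt_depth, total_depth_B = b$total_depth,
    dbsnp_id = ifelse(is.na(a$dbsnp_id), b$dbsnp_id, a$dbsnp_id),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$pos1, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write consensus variants as a flat TSV
#' @param consensus Annotated consensus table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(consensus, path) {
  cols <- intersect(c("sample_id", "contig", "pos1", "ref", "alt", "af",
                      "gene", "consequence", "cadd_phred", "pop_freq"),
                    names(consensus))
  utils::write.table(consensus[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write consensus variants as a minimal VCF
#'
#' One record per consensus variant with the allele fraction in INFO (`AF`).
#' Dropped calls are simply absent. Header is deterministic (no dates).
#'
#' @param consensus Consensus table for one sample.
#' @param path Output path.
#' @param contig_lengths Named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, path, contig_lengths = NULL) {
  hdr <- "##fileformat=VCFv4.2"
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr,
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Tumor allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  id <- if ("dbsnp_id" %in% names(consensus))
    ifelse(is.na(consensus$dbsnp_id), ".", consensus$dbsnp_id)
  else rep(".", nrow(consensus))
  af <- ifelse(is.na(consensus$af), ".", sprintf("%.6g", consensus$af))
  recs <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%s", consensus$contig,
                  consensus$pos1, id, consensus$ref, consensus$alt, af)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
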