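#' @importFrom SummarizedExperiment rowRanges
#' @importFrom data.table data.table as.data.table setkeyv
NULL

# Canonical column layout for a set of somatic calls. All functions in the
# package exchange calls as a data.frame with exactly these columns.
call_columns <- c("sample_id", "caller_id", "contig", "pos1", "ref", "alt",
                  "filter", "qual", "alt_depth", "total_depth",
                  "normal_depth", "dbsnp_id")

#' Construct an empty (or validated) somatic call table
#'
#' @param df Optional data.frame carrying the canonical call columns.
#' @return data.frame with columns `sample_id`, `caller_id`, `contig`,
#'   `pos1`, `ref`, `alt`, `filter`, `qual`, `alt_depth`, `total_depth`,
#'   `normal_depth`, `dbsnp_id`.
#' @export
somatic_calls <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      sample_id = character(), caller_id = character(), contig = character(),
      pos1 = integer(), ref = character(), alt = character(),
      filter = character(), qual = numeric(), alt_depth = integer(),
      total_depth = integer(), normal_depth = integer(),
      dbsnp_id = character(), stringsAsFactors = FALSE
    )
  }
  missing_cols <- setdiff(call_columns, names(df))
  if (length(missing_cols))
    stop("call table missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, call_columns, drop = FALSE]
  if (nrow(df)) {
    if (any(df$alt_depth > df$total_depth, na.rm = TRUE))
      stop("alt_depth exceeds total_depth")
    if (any(df$ref == df$alt))
      stop("ref allele equals alt allele")
  }
  rownames(df) <- NULL
  df
}

#' Variant key strings for call-like tables
#'
#' Exact-match identity used throughout: `contig:pos1:ref:alt`.
#'
#' @param df data.frame with `contig`, `pos1`, `ref`, `alt` columns.
#' @return Character vector of keys.
#' @export
variant_key <- function(df) {
  paste(df$contig, df$pos1, df$ref, df$alt, sep = ":")
}

is_simple_allele <- function(x) grepl("^[ACGT]+$", x)

#' Read a somatic VCF in one of the two supported caller dialects
#'
#' Dialect "A" is an allele-depth-reporting somatic VCF: record-level QUAL,
#' per-sample DP/AD, tumor identified by a sample column named `sample_id`
#' (any other sample column is treated as the matched normal and its DP is
#' recorded). Dialect "B" is a tiered-count somatic VCF: no genotype
#' likelihoods, site-level somatic quality in an INFO key (default
#' `SomaticEVS`), tumor in the column named `TUMOR`, SNV read support in the
#' tier-1 components of the AU/CU/GU/TU base counts and indel support in
#' TAR/TIR.
#'
#' Records with symbolic or breakend ALT alleles are skipped (a count is
#' reported via `message()`); multi-allelic records are split into one call
#' per ALT allele.
#'
#' @param path Path to a VCF 4.x file.
#' @param dialect `"A"` or `"B"`.
#' @param sample_id Sample identifier; for dialect A also the tumor column
#'   name.
#' @param qual_info_key INFO key holding the dialect-B somatic quality score.
#' @return A somatic call table (see [somatic_calls()]).
#' @export
read_somatic_vcf <- function(path, dialect = c("A", "B"), sample_id,
                             qual_info_key = "SomaticEVS") {
  dialect <- match.arg(dialect)
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0L) return(somatic_calls())

  rr <- rowRanges(vcf)
  contig <- as.character(GenomeInfoDb::seqnames(rr))
  pos1 <- BiocGenerics::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alts <- lapply(seq_len(n), function(i) as.character(alts[[i]]))
  filt <- VariantAnnotation::filt(vcf)
  quals <- VariantAnnotation::qual(vcf)
  geno <- VariantAnnotation::geno(vcf)
  smp <- colnames(vcf)

  # rowRanges names carry the ID column, except that "." is replaced by a
  # synthesized "contig:pos_ref/alt" label; undo that to recover dbSNP ids
  ids <- names(rr)
  synthesized <- paste0(contig, ":", pos1, "_", refs, "/",
                        vapply(alts, function(a) if (length(a)) a[1L] else "",
                               character(1)))
  ids[ids == synthesized | ids == "."] <- NA_character_

  if (dialect == "A") {
    if (!sample_id %in% smp)
      stop("tumor sample column '", sample_id, "' not found in ", path)
    tumor_col <- sample_id
    normal_col <- setdiff(smp, tumor_col)
    normal_col <- if (length(normal_col)) normal_col[1L] else NA_character_
  } else {
    if (!"TUMOR" %in% smp)
      stop("dialect B VCF must contain a TUMOR sample column: ", path)
    tumor_col <- "TUMOR"
    normal_col <- if ("NORMAL" %in% smp) "NORMAL" else NA_character_
    if (!qual_info_key %in% names(VariantAnnotation::info(vcf)))
      stop("dialect B VCF lacks INFO key '", qual_info_key, "': ", path)
    sevs <- VariantAnnotation::info(vcf)[[qual_info_key]]
  }

  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(n)) {
    for (k in seq_along(alts[[i]])) {
      a <- alts[[i]][k]
      if (!is_simple_allele(a) || !is_simple_allele(refs[i])) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (dialect == "A") {
        ad <- geno$AD[[i, tumor_col]]
        alt_dp <- as.integer(ad[k + 1L])
        tot_dp <- as.integer(sum(ad))
        q <- as.numeric(quals[i])
        nd <- if (!is.na(normal_col) && "DP" %in% names(geno))
          as.integer(geno$DP[i, normal_col]) else NA_integer_
      } else {
        q <- as.numeric(sevs[[i]])[1L]
        if (nchar(refs[i]) == 1L && nchar(a) == 1L) {
          counts <- c(
            A = geno$AU[i, tumor_col, 1L], C = geno$CU[i, tumor_col, 1L],
            G = geno$GU[i, tumor_col, 1L], T = geno$TU[i, tumor_col, 1L]
          )
          alt_dp <- as.integer(counts[[a]])
          tot_dp <- as.integer(sum(counts))
        } else {
          alt_dp <- as.integer(geno$TIR[i, tumor_col, 1L])
          tot_dp <- as.integer(geno$TAR[i, tumor_col, 1L]) + alt_dp
        }
        nd <- if (!is.na(normal_col) && "DP" %in% names(geno))
          as.integer(geno$DP[i, normal_col]) else NA_integer_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, caller_id = dialect, contig = contig[i],
        pos1 = pos1[i], ref = refs[i], alt = a, filter = filt[i],
        qual = q, alt_depth = alt_dp, total_depth = tot_dp,
        normal_depth = nd, dbsnp_id = ids[i], stringsAsFactors = FALSE
      )
    }
  }
  if (n_skipped > 0L)
    message("read_somatic_vcf: skipped ", n_skipped,
            " record(s) with symbolic/non-ACGT alleles in ", path)
  if (length(rows) == 0L) return(somatic_calls())
  somatic_calls(do.call(rbind, rows))
}

#' Write a somatic call table as a VCF in a caller dialect
#'
#' Inverse of [read_somatic_vcf()]; used by the synthetic cohort writer and
#' for round-trip testing. Output is plain text with a deterministic header
#' (no timestamps).
#'
#' @param calls Somatic call table.
#' @param path Output path.
#' @param dialect `"A"` or `"B"`.
#' @param contig_lengths Named integer vector for `##contig` header lines.
#' @param qual_info_key INFO key for the dialect-B somatic score.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(calls, path, dialect = c("A", "B"),
                              contig_lengths = NULL,
                              qual_info_key = "SomaticEVS") {
  dialect <- match.arg(dialect)
  sample_id <- if (nrow(calls)) calls$sample_id[1L] else "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  ord <- order(calls$contig, calls$pos1, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  id <- ifelse(is.na(calls$dbsnp_id), ".", calls$dbsnp_id)
  ref_dp <- calls$total_depth - calls$alt_depth
  nd <- ifelse(is.na(calls$normal_depth), ".",
               as.character(calls$normal_depth))
  if (dialect == "A") {
    hdr <- c(hdr,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
             sample_id, "\t", sample_id, "-N"))
    tumor <- sprintf("0/1:%d:%d,%d", calls$total_depth, ref_dp,
                     calls$alt_depth)
    normal <- sprintf("0/0:%s:%s,0", nd, nd)
    recs <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t.\tGT:DP:AD\t%s\t%s",
                    calls$contig, calls$pos1, id, calls$ref, calls$alt,
                    fmt_num(calls$qual), calls$filter, tumor, normal)
  } else {
    hdr <- c(hdr,
      sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Somatic quality score\">",
              qual_info_key),
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"A tier counts\">",
      "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"C tier counts\">",
      "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"G tier counts\">",
      "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"T tier counts\">",
      "##FORMAT=<ID=TAR,Number=2,Type=Integer,Description=\"Reference-supporting tier counts\">",
      "##FORMAT=<ID=TIR,Number=2,Type=Integer,Description=\"Indel-supporting tier counts\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
    recs <- character(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      is_snv <- nchar(calls$ref[i]) == 1L && nchar(calls$alt[i]) == 1L
      if (is_snv) {
        cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
        cnt[calls$ref[i]] <- ref_dp[i]
        cnt[calls$alt[i]] <- calls$alt_depth[i]
        t_fmt <- sprintf("%d:%d,0:%d,0:%d,0:%d,0", calls$total_depth[i],
                         cnt["A"], cnt["C"], cnt["G"], cnt["T"])
        n_cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
        nd_i <- if (is.na(calls$normal_depth[i])) 0L else calls$normal_depth[i]
        n_cnt[calls$ref[i]] <- nd_i
        n_fmt <- sprintf("%d:%d,0:%d,0:%d,0:%d,0", nd_i,
                         n_cnt["A"], n_cnt["C"], n_cnt["G"], n_cnt["T"])
        fmt <- "DP:AU:CU:GU:TU"
      } else {
        t_fmt <- sprintf("%d:%d,0:%d,0", calls$total_depth[i], ref_dp[i],
                         calls$alt_depth[i])
        nd_i <- if (is.na(calls$normal_depth[i])) 0L else calls$normal_depth[i]
        n_fmt <- sprintf("%d:%d,0:0,0", nd_i, nd_i)
        fmt <- "DP:TAR:TIR"
      }
      recs[i] <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s=%s\t%s\t%s\t%s",
                         calls$contig[i], calls$pos1[i], id[i], calls$ref[i],
                         calls$alt[i], calls$filter[i], qual_info_key,
                         fmt_num(calls$qual[i]), fmt, n_fmt, t_fmt)
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a germline VCF as a set of variant keys
#'
#' Only the variant identity matters for germline subtraction; multi-allelic
#' records contribute one key per ALT allele.
#'
#' @param path Path to a VCF file.
#' @return Character vector of `contig:pos1:ref:alt` keys.
#' @export
read_germline_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (length(vcf) == 0L) return(character())
  rr <- rowRanges(vcf)
  contig <- as.character(GenomeInfoDb::seqnames(rr))
  pos1 <- BiocGenerics::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  keys <- unlist(lapply(seq_along(vcf), function(i) {
    a <- as.character(alts[[i]])
    a <- a[grepl("^[ACGT]+$", a)]
    if (!length(a)) return(character())
    paste(contig[i], pos1[i], refs[i], a, sep = ":")
  }))
  unique(keys)
}

#' Write a minimal germline VCF from variant keys
#'
#' @param df data.frame with `contig`, `pos1`, `ref`, `alt`.
#' @param path Output path.
#' @param sample_id Sample column name.
#' @param contig_lengths Named integer vector for header lines.
#' @return `path`, invisibly.
#' @export
write_germline_vcf <- function(df, path, sample_id = "NORMAL",
                               contig_lengths = NULL) {
  hdr <- "##fileformat=VCFv4.2"
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
  df <- df[order(df$contig, df$pos1, df$ref, df$alt), , drop = FALSE]
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.\tGT\t0/1",
                  df$contig, df$pos1, df$ref, df$alt)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Normalize variant representation against the reference
#'
#' Shared leading/trailing bases are trimmed and indels are left-aligned
#' (the standard parsimony/left-alignment algorithm); SNVs pass through
#' unchanged apart from a reference consistency check. A REF allele that
#' does not match the reference sequence at its position is an error.
#'
#' @param calls Somatic call table.
#' @param ref A `ReferenceSet`.
#' @return The call table with normalized `pos1`, `ref`, `alt`.
#' @export
normalize_variants <- function(calls, ref) {
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    r <- calls$ref[i]; a <- calls$alt[i]; p <- calls$pos1[i]
    ctg <- calls$contig[i]
    if (ref_base(ref, ctg, p, nchar(r)) != r)
      stop("REF allele mismatch at ", ctg, ":", p, " (VCF says '", r,
           "', reference has '", ref_base(ref, ctg, p, nchar(r)), "')")
    repeat {
      nr <- nchar(r); na <- nchar(a)
      if (nr > 0L && na > 0L &&
          substring(r, nr, nr) == substring(a, na, na) &&
          (nr > 1L || na > 1L)) {
        r <- substring(r, 1L, nr - 1L)
        a <- substring(a, 1L, na - 1L)
        if (nchar(r) == 0L || nchar(a) == 0L) {
          if (p == 1L) stop("cannot left-align variant at contig start: ",
                            ctg, ":", calls$pos1[i])
          p <- p - 1L
          b <- ref_base(ref, ctg, p)
          r <- paste0(b, r); a <- paste0(b, a)
        }
      } else if (nchar(r) > 1L && nchar(a) > 1L &&
                 substring(r, 1L, 1L) == substring(a, 1L, 1L)) {
        r <- substring(r, 2L); a <- substring(a, 2L); p <- p + 1L
      } else break
    }
    calls$ref[i] <- r; calls$alt[i] <- a; calls$pos1[i] <- p
  }
  calls
}

#' Read a population allele-frequency resource
#'
#' Accepts either a VCF with an `AF` INFO field or a 5-column TSV
#' (`contig`, `pos1`, `ref`, `alt`, `maf`; header optional). Frequencies
#' outside `[0, 1]` are rejected.
#'
#' @param path Path to the resource.
#' @return A `pop_freqs` lookup (data.table keyed on the variant identity).
#' @export
read_population_frequencies <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.vcf(\\.gz)?$", path) || startsWith(first, "##fileformat=VCF")) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- rowRanges(vcf)
    contig <- as.character(GenomeInfoDb::seqnames(rr))
    pos1 <- BiocGenerics::start(rr)
    refs <- as.character(VariantAnnotation::ref(vcf))
    alts <- VariantAnnotation::alt(vcf)
    afs <- VariantAnnotation::info(vcf)$AF
    if (is.null(afs)) stop("population VCF lacks AF INFO field: ", path)
    rows <- lapply(seq_along(vcf), function(i) {
      a <- as.character(alts[[i]])
      data.frame(contig = contig[i], pos1 = pos1[i], ref = refs[i],
                 alt = a, maf = as.numeric(afs[[i]])[seq_along(a)],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    has_header <- is.na(suppressWarnings(
      as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][2])))
    # read everything as character: a ref/alt column of bare "T"s must not
    # be parsed as logical
    df <- utils::read.delim(path, header = has_header,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 5L) stop("population TSV needs 5 columns: ", path)
    df <- df[, 1:5]
    names(df) <- c("contig", "pos1", "ref", "alt", "maf")
    df$pos1 <- as.integer(df$pos1)
  }
  df$maf <- as.numeric(df$maf)
  if (anyNA(df$maf) || any(df$maf < 0 | df$maf > 1))
    stop("population MAF outside [0,1] in ", path)
  dt <- data.table::as.data.table(df)
  data.table::setkeyv(dt, c("contig", "pos1", "ref", "alt"))
  structure(dt, class = c("pop_freqs", class(dt)))
}

#' Look up population frequencies for calls
#'
#' @param freqs A `pop_freqs` lookup (or NULL for "no resource").
#' @param calls data.frame with `contig`, `pos1`, `ref`, `alt`.
#' @param by_position If TRUE, match on position only (any allele at the
#'   site); default FALSE (allele-aware).
#' @return Numeric vector of MAFs, `NA` where no record exists.
#' @export
pop_maf <- function(freqs, calls, by_position = FALSE) {
  if (is.null(freqs) || nrow(freqs) == 0L || nrow(calls) == 0L)
    return(rep(NA_real_, nrow(calls)))
  if (by_position) {
    vapply(seq_len(nrow(calls)), function(i) {
      hit <- freqs[list(calls$contig[i], calls$pos1[i]), on = c("contig", "pos1"),
                   nomatch = NULL]
      if (nrow(hit) == 0L) NA_real_ else max(hit$maf)
    }, numeric(1))
  } else {
    q <- data.table::data.table(contig = calls$contig, pos1 = calls$pos1,
                                ref = calls$ref, alt = calls$alt)
    freqs[q, on = c("contig", "pos1", "ref", "alt")]$maf
  }
}

# Consequence strings are normalized to Sequence-Ontology style:
# lowercase, spaces/hyphens to underscores ("Missense variant" ->
# "missense_variant", "3 prime UTR variant" -> "3_prime_utr_variant").
normalize_consequence <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ -]+", "_", x)
  x
}

# Fixed vocabulary recognized by the consequence tally; anything else is
# preserved verbatim but tallied under "other".
consequence_vocabulary <- c(
  "missense_variant", "stop_gained", "stop_lost", "start_lost",
  "protein_altering_variant", "synonymous_variant", "stop_retained_variant",
  "3_prime_utr_variant", "5_prime_utr_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "non_coding_transcript_variant", "splice_region_variant",
  "splice_donor_variant", "splice_acceptor_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant"
)

#' Read a variant annotation table
#'
#' TSV with a header naming at least contig, position, ref, alt, gene,
#' consequence, CADD Phred and population frequency columns (common synonyms
#' such as `chr`/`chrom`, `pos`, `cadd` are accepted). Consequence strings
#' are normalized to Sequence-Ontology style; strings outside the known
#' vocabulary are kept but flagged `"other"` in `consequence_class`.
#'
#' @param path Path to the TSV.
#' @return An `annotation_table` data.frame keyed by variant.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  resolve <- function(cands, required = TRUE) {
    hit <- which(tolower(names(df)) %in% cands)
    if (length(hit) == 0L) {
      if (required)
        stop("annotation table missing a column among {",
             paste(cands, collapse = ", "), "}: ", path)
      return(NA_integer_)
    }
    hit[1L]
  }
  ic <- resolve(c("contig", "chr", "chrom", "chromosome"))
  ip <- resolve(c("pos", "pos1", "position"))
  irf <- resolve(c("ref", "reference", "ref_allele"))
  ia <- resolve(c("alt", "alternative", "alt_allele"))
  ig <- resolve(c("gene", "gene_symbol"))
  icq <- resolve(c("consequence", "csq"))
  icd <- resolve(c("cadd_phred", "cadd", "cadd_score"))
  ifr <- resolve(c("pop_freq", "population_freq", "maf", "gnomad_freq"))
  out <- data.frame(
    contig = as.character(df[[ic]]), pos1 = as.integer(df[[ip]]),
    ref = as.character(df[[irf]]), alt = as.character(df[[ia]]),
    gene = as.character(df[[ig]]),
    consequence = normalize_consequence(as.character(df[[icq]])),
    cadd_phred = suppressWarnings(as.numeric(df[[icd]])),
    pop_freq = suppressWarnings(as.numeric(df[[ifr]])),
    stringsAsFactors = FALSE
  )
  out$consequence_class <- ifelse(out$consequence %in% consequence_vocabulary,
                                  out$consequence, "other")
  structure(out, class = c("annotation_table", "data.frame"))
}

#' Attach annotations to a variant table
#'
#' @param variants data.frame with `contig`, `pos1`, `ref`, `alt`.
#' @param annotations An `annotation_table` (or NULL).
#' @return `variants` with `gene`, `consequence`, `cadd_phred`, `pop_freq`
#'   columns appended (NA where no annotation exists).
#' @export
annotate_variants <- function(variants, annotations) {
  add <- c("gene", "consequence", "cadd_phred", "pop_freq")
  if (is.null(annotations) || nrow(variants) == 0L) {
    n <- nrow(variants)
    for (col in add)
      variants[[col]] <- if (col %in% c("cadd_phred", "pop_freq"))
        rep(NA_real_, n) else rep(NA_character_, n)
    return(variants)
  }
  idx <- match(variant_key(variants), variant_key(annotations))
  for (col in add) variants[[col]] <- annotations[[col]][idx]
  variants
}

#' Read a per-base depth track
#'
#' Bedgraph-style TSV with columns `contig`, `start` (0-based), `end`
#' (exclusive), `depth`; header optional.
#'
#' @param path Path to the TSV.
#' @return A `DepthTrack` data.frame sorted by contig and start.
#' @export
read_depth_track <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][2])))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("depth track needs 4 columns: ", path)
  df <- df[, 1:4]
  names(df) <- c("contig", "start", "end", "depth")
  if (any(df$depth < 0)) stop("negative depth in ", path)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("DepthTrack", "data.frame"))
}

#' Depth at 1-based positions
#'
#' @param track A `DepthTrack`.
#' @param contig Contig name (scalar).
#' @param pos1 Vector of 1-based positions.
#' @return Integer depths; positions not covered by any interval answer 0.
#' @export
depth_at <- function(track, contig, pos1) {
  d <- track[track$contig == contig, , drop = FALSE]
  if (nrow(d) == 0L) return(rep(0L, length(pos1)))
  pos0 <- pos1 - 1L
  idx <- findInterval(pos0, d$start)
  hit <- idx > 0L & pos0 < d$end[pmax(idx, 1L)]
  out <- rep(0L, length(pos1))
  out[hit] <- as.integer(d$depth[idx[hit]])
  out
}

#' Write a depth track TSV
#' @param track A `DepthTrack` (or plain data.frame with its columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("contig", "start", "end", "depth")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
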