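# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately avoid the code paths they check.

# quadratic homopolymer oracle: test every substring of length min_run for
# uniformity, extend maximally, deduplicate
brute_force_homopolymers <- function(seq, min_run) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  found <- list()
  for (s in seq_len(max(n - min_run + 1L, 0L))) {
    win <- chars[s:(s + min_run - 1L)]
    if (length(unique(win)) != 1L || win[1L] == "N") next
    b <- win[1L]
    lo <- s
    while (lo > 1L && chars[lo - 1L] == b) lo <- lo - 1L
    hi <- s + min_run - 1L
    while (hi < n && chars[hi + 1L] == b) hi <- hi + 1L
    found[[paste(lo, hi)]] <- c(lo, hi)
  }
  if (!length(found))
    return(data.frame(start1 = integer(), end1 = integer(),
                      base = character()))
  m <- do.call(rbind, found)
  out <- data.frame(start1 = m[, 1L], end1 = m[, 2L],
                    base = chars[m[, 1L]], stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$start1), , drop = FALSE]
}

# linear-scan membership over raw, un-merged intervals
linear_scan_member <- function(contig, pos1, raw) {
  pos0 <- pos1 - 1L
  any(raw$contig == contig & raw$start <= pos0 & pos0 < raw$end)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# minimal valid call table with overridable fields
make_calls <- function(n = 1L, ...) {
  base <- data.frame(
    sample_id = rep("S01", n), caller_id = rep("A", n),
    contig = rep("c1", n), pos1 = seq(100L, by = 10L, length.out = n),
    ref = rep("C", n), alt = rep("T", n), filter = rep("PASS", n),
    qual = rep(50, n), alt_depth = rep(20L, n), total_depth = rep(50L, n),
    normal_depth = rep(50L, n), dbsnp_id = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  somatic_calls(base)
}

# brute-force recurrence oracles over all sample pairs
brute_recurrent_positions <- function(cohort) {
  keys <- list()
  for (s in names(cohort)) {
    v <- cohort[[s]]
    if (is.null(v) || nrow(v) == 0L) next
    keys[[s]] <- unique(variant_key(v))
  }
  all_keys <- unique(unlist(keys))
  hits <- character()
  for (k in all_keys) {
    carriers <- names(keys)[vapply(keys, function(x) k %in% x, logical(1))]
    if (length(carriers) >= 2L) hits <- c(hits, k)
  }
  sort(hits)
}

brute_recurrent_genes <- function(cohort) {
  pairs <- list()
  for (s in names(cohort)) {
    v <- cohort[[s]]
    if (is.null(v) || nrow(v) == 0L) next
    g <- unique(v$gene[!is.na(v$gene) & nzchar(v$gene)])
    for (gene in g) pairs[[length(pairs) + 1L]] <- c(gene, s)
  }
  if (!length(pairs)) return(character())
  m <- do.call(rbind, pairs)
  tab <- tapply(m[, 2L], m[, 1L], function(x) length(unique(x)))
  sort(names(tab)[tab >= 2L])
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
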