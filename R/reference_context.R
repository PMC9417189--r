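#' Read a reference FASTA into a ReferenceSet
#'
#' Loads every record of a (possibly soft-masked) FASTA file and normalizes
#' the sequences to uppercase A/C/G/T/N. IUPAC ambiguity codes other than N
#' are normalized to N: downstream predicates only distinguish the four
#' unambiguous bases from "unknown".
#'
#' @param path Path to a FASTA file.
#' @return A `ReferenceSet`: a named character vector of uppercase sequences
#'   (one per contig, in file order) with class `"ReferenceSet"`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  # readDNAStringSet keeps the full header line; contig name is the first word
  nm <- sub("\\s.*$", "", names(seqs))
  if (any(nm == "")) stop("FASTA record with empty contig name in ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  s <- toupper(as.character(seqs))
  s <- gsub("[^ACGTN]", "N", s)
  reference_set(stats::setNames(s, nm))
}

#' Construct a ReferenceSet from named sequences
#'
#' @param contigs Named character vector of uppercase A/C/G/T/N sequences.
#' @return A `ReferenceSet`.
#' @export
reference_set <- function(contigs) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  if (any(names(contigs) == "") || anyDuplicated(names(contigs)))
    stop("contig names must be unique and non-empty")
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("sequence contains characters outside A/C/G/T/N in contig(s): ",
         paste(names(contigs)[bad], collapse = ", "))
  structure(contigs, class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet with", length(x), "contig(s):\n")
  for (nm in names(x)) cat(" ", nm, ":", nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Reference base(s) at 1-based positions
#'
#' @param ref A `ReferenceSet`.
#' @param contig Contig name.
#' @param pos1 Vector of 1-based positions.
#' @param width Number of bases to extract at each position (default 1).
#' @return Character vector of bases.
#' @export
ref_base <- function(ref, contig, pos1, width = 1L) {
  if (!contig %in% names(ref)) stop("unknown contig: ", contig)
  n <- nchar(ref[[contig]])
  if (any(pos1 < 1L | pos1 + width - 1L > n))
    stop("position out of bounds on contig ", contig)
  substring(ref[[contig]], pos1, pos1 + width - 1L)
}

#' Write a ReferenceSet to FASTA
#'
#' @param ref A `ReferenceSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Scan a reference for homopolymer runs
#'
#' Reports every maximal run of >= `min_run` identical A/C/G/T bases. Runs of
#' N are never reported: N encodes uncertainty, not sequence. Coordinates are
#' 1-based inclusive (VCF convention).
#'
#' @param ref A `ReferenceSet`.
#' @param min_run Minimum run length (default 4).
#' @return data.frame with columns `contig`, `start1`, `end1`, `base`,
#'   `length`, sorted by contig (reference order) then `start1`.
#' @export
scan_homopolymers <- function(ref, min_run = 4L) {
  stopifnot(min_run >= 2L)
  out <- lapply(names(ref), function(nm) {
    chars <- strsplit(ref[[nm]], "", fixed = TRUE)[[1]]
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_run & r$values != "N"
    data.frame(
      contig = rep(nm, sum(keep)),
      start1 = starts[keep], end1 = ends[keep],
      base = r$values[keep], length = r$lengths[keep],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Is a position within or adjacent to a homopolymer run?
#'
#' True when some run on `contig` satisfies
#' `start1 - distance <= pos1 <= end1 + distance`, i.e. the run interval
#' widened symmetrically by `distance` nucleotides.
#'
#' @param contig Contig name.
#' @param pos1 Vector of 1-based positions.
#' @param runs data.frame from [scan_homopolymers()].
#' @param distance Adjacency distance in nucleotides (default 1).
#' @return Logical vector, one element per position.
#' @export
is_homopolymer_proximal <- function(contig, pos1, runs, distance = 1L) {
  if (is.null(runs) || nrow(runs) == 0L) return(rep(FALSE, length(pos1)))
  r <- runs[runs$contig == contig, , drop = FALSE]
  if (nrow(r) == 0L) return(rep(FALSE, length(pos1)))
  lo <- r$start1 - distance
  hi <- r$end1 + distance
  vapply(pos1, function(p) any(lo <= p & p <= hi), logical(1))
}

#' Construct an IntervalSet
#'
#' Sorted, merged collection of 0-based half-open genomic intervals.
#' Overlapping or abutting intervals on the same contig are merged (via
#' `IRanges::reduce`), so membership queries are resolved with a single
#' binary search per contig.
#'
#' @param df data.frame with columns `contig`, `start` (0-based inclusive),
#'   `end` (0-based exclusive).
#' @return An `IntervalSet`.
#' @export
interval_set <- function(df = data.frame(contig = character(), start = integer(),
                                         end = integer())) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  if (nrow(df) > 0L && any(df$start >= df$end))
    stop("interval with start >= end")
  if (nrow(df) == 0L) {
    out <- data.frame(contig = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("IntervalSet", "data.frame")))
  }
  pieces <- lapply(split(df, df$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(contig = d$contig[1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("IntervalSet", "data.frame"))
}

#' Membership query against an IntervalSet
#'
#' @param contig Contig name (scalar).
#' @param pos1 Vector of 1-based positions.
#' @param set An `IntervalSet`.
#' @return Logical vector: does each position (as a 0-based offset) fall
#'   inside any interval?
#' @export
in_interval_set <- function(contig, pos1, set) {
  d <- set[set$contig == contig, , drop = FALSE]
  if (nrow(d) == 0L) return(rep(FALSE, length(pos1)))
  pos0 <- pos1 - 1L
  idx <- findInterval(pos0, d$start)
  idx > 0L & pos0 < d$end[pmax(idx, 1L)]
}

#' Read a BED file into an IntervalSet
#'
#' 3+ column BED, 0-based half-open; extra columns ignored; intervals merged.
#'
#' @param path Path to a BED file.
#' @return An `IntervalSet`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) return(interval_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", which(nf < 3L)[1L], " has fewer than 3 columns in ", path)
  df <- data.frame(
    contig = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-numeric BED coordinates at line ",
         which(is.na(df$start) | is.na(df$end))[1L], " in ", path)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("BED line ", bad[1L], " has start >= end in ", path)
  interval_set(df)
}

#' Write an IntervalSet as BED
#'
#' @param set An `IntervalSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(set, path) {
  df <- as.data.frame(set)
  lines <- sprintf("%s\t%d\t%d", df$contig, df$start, df$end)
  writeLines(lines, path)
  invisible(path)
}

#' Total number of bases covered by an IntervalSet
#' @param set An `IntervalSet`.
#' @return Integer base count.
#' @export
interval_set_width <- function(set) {
  if (nrow(set) == 0L) return(0L)
  sum(set$end - set$start)
}

#' Complement of an IntervalSet within contig bounds
#'
#' @param set An `IntervalSet`.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return An `IntervalSet` covering every base not in `set`.
#' @export
complement_interval_set <- function(set, contig_lengths) {
  pieces <- lapply(names(contig_lengths), function(nm) {
    len <- contig_lengths[[nm]]
    d <- set[set$contig == nm, , drop = FALSE]
    if (nrow(d) == 0L)
      return(data.frame(contig = nm, start = 0L, end = len))
    starts <- c(0L, d$end)
    ends <- c(d$start, len)
    keep <- starts < ends
    data.frame(contig = nm, start = starts[keep], end = ends[keep])
  })
  interval_set(do.call(rbind, pieces))
}
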