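#' Synthetic cohort simulation configuration
#'
#' The defaults describe a desk-scale stand-in for a 15-sample tumor-normal
#' exome cohort: two 50 kb contigs, mean sequencing depth 50X, clonal
#' somatic variants at allele fractions 0.3-0.6, subclonal ones below the
#' 0.20 subclonality threshold, and two injected artifact records per
#' artifact class per sample so each filter of the cascade is exercised.
#'
#' @param seed Integer seed; the whole bundle is a pure function of this
#'   configuration (seed included).
#' @param n_samples Number of tumor-normal pairs.
#' @param contig_lengths Named integer vector of synthetic contig lengths.
#' @param n_homopolymers Planted homopolymer runs (whole genome).
#' @param homopolymer_length_range Run length range (inclusive).
#' @param repeat_fraction Approximate fraction of the genome masked as
#'   repeat.
#' @param n_common_snps Population-table entries with MAF above the 0.1%
#'   filter threshold.
#' @param common_snp_maf_range MAF range for those entries.
#' @param n_clonal,n_subclonal,n_germline,n_snp_leak Per-sample counts of
#'   true clonal/subclonal somatic variants, germline variants (shared with
#'   the matched normal) and common-SNP leak-through calls.
#' @param n_artifact_homopolymer,n_artifact_repeat,n_artifact_low_qual,n_artifact_low_alt_reads,n_artifact_caller_unique_A,n_artifact_caller_unique_B,n_artifact_low_normal_depth
#'   Per-sample counts of each injected artifact class; each class is
#'   designed to trip exactly one filter (or the consensus intersection).
#' @param shared_variant_samples Plant one identical clonal somatic variant
#'   in this many samples (0 disables), to exercise recurrence detection.
#' @param mean_depth Mean tumor/normal sequencing depth (Poisson).
#' @param clonal_af_range,subclonal_af_range Designed allele-fraction ranges.
#' @param transition_prob Probability that a simulated substitution is a
#'   transition (default 0.565, i.e. an expected Ti/Tv near 1.3).
#' @param noise If TRUE, site depth is Poisson(`mean_depth`) and alt-read
#'   support Binomial(depth, af); if FALSE both are deterministic
#'   (`round()`), enabling exact truth-set oracles.
#' @param nonpass_fraction Fraction of artifact records written with a
#'   non-PASS FILTER string (default 0 so each artifact class keeps a single
#'   diagnostic filter reason).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L, n_samples = 15L,
                              contig_lengths = c(c1 = 50000L, c2 = 50000L),
                              n_homopolymers = 30L,
                              homopolymer_length_range = c(4L, 8L),
                              repeat_fraction = 0.10,
                              n_common_snps = 60L,
                              common_snp_maf_range = c(0.002, 0.05),
                              n_clonal = 6L, n_subclonal = 4L,
                              n_germline = 4L, n_snp_leak = 3L,
                              n_artifact_homopolymer = 2L,
                              n_artifact_repeat = 2L,
                              n_artifact_low_qual = 2L,
                              n_artifact_low_alt_reads = 2L,
                              n_artifact_caller_unique_A = 2L,
                              n_artifact_caller_unique_B = 2L,
                              n_artifact_low_normal_depth = 2L,
                              shared_variant_samples = 3L,
                              mean_depth = 50,
                              clonal_af_range = c(0.3, 0.6),
                              subclonal_af_range = c(0.05, 0.19),
                              transition_prob = 0.565,
                              noise = TRUE, nonpass_fraction = 0) {
  if (is.na(seed)) stop("simulation seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              contig_lengths = contig_lengths,
              n_homopolymers = n_homopolymers,
              homopolymer_length_range = homopolymer_length_range,
              repeat_fraction = repeat_fraction,
              n_common_snps = n_common_snps,
              common_snp_maf_range = common_snp_maf_range,
              n_clonal = n_clonal, n_subclonal = n_subclonal,
              n_germline = n_germline, n_snp_leak = n_snp_leak,
              n_artifact_homopolymer = n_artifact_homopolymer,
              n_artifact_repeat = n_artifact_repeat,
              n_artifact_low_qual = n_artifact_low_qual,
              n_artifact_low_alt_reads = n_artifact_low_alt_reads,
              n_artifact_caller_unique_A = n_artifact_caller_unique_A,
              n_artifact_caller_unique_B = n_artifact_caller_unique_B,
              n_artifact_low_normal_depth = n_artifact_low_normal_depth,
              shared_variant_samples = shared_variant_samples,
              mean_depth = mean_depth, clonal_af_range = clonal_af_range,
              subclonal_af_range = subclonal_af_range,
              transition_prob = transition_prob, noise = noise,
              nonpass_fraction = nonpass_fraction)
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  stopifnot(all(counts >= 0), repeat_fraction >= 0, repeat_fraction < 1,
            all(clonal_af_range > 0 & clonal_af_range < 1),
            all(subclonal_af_range > 0 & subclonal_af_range < 1),
            subclonal_af_range[2] < 0.20,
            all(common_snp_maf_range > 0.001 & common_snp_maf_range <= 1))
  structure(cfg, class = "SimulationConfig")
}

truth_classes <- c("SOMATIC_CLONAL", "SOMATIC_SUBCLONAL", "GERMLINE",
                   "COMMON_SNP_LEAK", "ARTIFACT_HOMOPOLYMER",
                   "ARTIFACT_REPEAT", "ARTIFACT_LOW_QUAL",
                   "ARTIFACT_LOW_ALT_READS", "ARTIFACT_CALLER_UNIQUE_A",
                   "ARTIFACT_CALLER_UNIQUE_B", "ARTIFACT_LOW_NORMAL_DEPTH")

# expected_fate is a pure function of the class, per the filter rules
class_fate <- c(
  SOMATIC_CLONAL = "CONSENSUS", SOMATIC_SUBCLONAL = "CONSENSUS",
  GERMLINE = "FILTERED", COMMON_SNP_LEAK = "FILTERED",
  ARTIFACT_HOMOPOLYMER = "FILTERED", ARTIFACT_REPEAT = "FILTERED",
  ARTIFACT_LOW_QUAL = "FILTERED", ARTIFACT_LOW_ALT_READS = "FILTERED",
  ARTIFACT_CALLER_UNIQUE_A = "CALLER_UNIQUE",
  ARTIFACT_CALLER_UNIQUE_B = "CALLER_UNIQUE",
  ARTIFACT_LOW_NORMAL_DEPTH = "FILTERED"
)

# which audit reason each filtered class must trigger
class_signature_reason <- c(
  GERMLINE = "FAIL_GERMLINE_MATCH", COMMON_SNP_LEAK = "FAIL_POPULATION_MAF",
  ARTIFACT_HOMOPOLYMER = "FAIL_HOMOPOLYMER", ARTIFACT_REPEAT = "FAIL_REPEAT",
  ARTIFACT_LOW_QUAL = "FAIL_QUAL",
  ARTIFACT_LOW_ALT_READS = "FAIL_ALT_READS",
  ARTIFACT_LOW_NORMAL_DEPTH = "FAIL_NORMAL_COVERAGE"
)

#' Signature audit reason for each filtered truth class
#' @return Named character vector: truth class -> expected filter reason.
#' @export
truth_class_reasons <- function() class_signature_reason

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)
transition_of <- c(A = "G", G = "A", C = "T", T = "C")

draw_alt <- function(ref_base, p_transition) {
  if (stats::runif(1) < p_transition) {
    transition_of[[ref_base]]
  } else {
    sample(setdiff(other_bases(ref_base), transition_of[[ref_base]]), 1L)
  }
}

#' Generate the synthetic reference, homopolymer runs, repeat and target masks
#'
#' The background sequence is generated free of homopolymer runs of length
#' >= 4, then the configured number of runs is planted at non-overlapping
#' positions with flanking bases forced to differ from the run base, so the
#' planted runs are exactly the maximal runs of the final sequence. Repeat
#' intervals cover about `repeat_fraction` of each contig; targets are the
#' complement. Deterministic given `cfg$seed`.
#'
#' @param cfg A `SimulationConfig`.
#' @return List with `ref` (ReferenceSet), `runs` (planted homopolymer
#'   runs, same layout as [scan_homopolymers()]), `repeats` and `targets`
#'   (IntervalSets).
#' @export
generate_reference <- function(cfg) {
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  lens <- cfg$contig_lengths
  seqs <- lapply(lens, function(len) {
    x <- character(len)
    x[1:3] <- sample(bases, 3L, replace = TRUE)
    for (i in 4:len) {
      if (x[i - 1L] == x[i - 2L] && x[i - 2L] == x[i - 3L]) {
        x[i] <- sample(setdiff(bases, x[i - 1L]), 1L)
      } else {
        x[i] <- sample(bases, 1L)
      }
    }
    x
  })
  # plant homopolymer runs, spread across contigs proportionally to length
  n_runs <- cfg$n_homopolymers
  run_rows <- NULL
  if (n_runs > 0L) {
    contig_of <- sample(names(lens), n_runs, replace = TRUE,
                        prob = lens / sum(lens))
    placed <- list()
    for (nm in names(lens)) {
      k <- sum(contig_of == nm)
      if (k == 0L) next
      len <- lens[[nm]]
      max_l <- cfg$homopolymer_length_range[2]
      taken <- integer(0)
      starts <- integer(k); lengths_k <- integer(k)
      for (j in seq_len(k)) {
        ok <- FALSE
        for (try in 1:200) {
          L <- sample(seq(cfg$homopolymer_length_range[1],
                          cfg$homopolymer_length_range[2]), 1L)
          s <- sample(seq(5L, len - max_l - 5L), 1L)
          if (!any(abs(s - taken) < (2L * max_l + 4L))) { ok <- TRUE; break }
        }
        if (!ok) stop("cannot place ", n_runs,
                      " homopolymer runs in a genome this small")
        taken <- c(taken, s)
        starts[j] <- s; lengths_k[j] <- L
        b <- sample(bases, 1L)
        seqs[[nm]][s:(s + L - 1L)] <- b
        # force flanks to differ from the run base and from their outer
        # neighbors so no run is extended or newly created
        for (fl in c(s - 1L, s + L)) {
          nb <- c(seqs[[nm]][max(fl - 1L, 1L)],
                  seqs[[nm]][min(fl + 1L, len)])
          choice <- setdiff(bases, c(b, nb))
          if (!length(choice)) choice <- setdiff(bases, b)
          seqs[[nm]][fl] <- choice[1L]
        }
      }
      placed[[nm]] <- data.frame(contig = nm, start1 = starts,
                                 end1 = starts + lengths_k - 1L,
                                 base = seqs[[nm]][starts],
                                 length = lengths_k, stringsAsFactors = FALSE)
    }
    run_rows <- do.call(rbind, placed)
    run_rows <- run_rows[order(match(run_rows$contig, names(lens)),
                               run_rows$start1), , drop = FALSE]
    rownames(run_rows) <- NULL
  }
  ref <- reference_set(vapply(seqs, paste, character(1), collapse = ""))
  scanned <- scan_homopolymers(ref, min_run = 4L)
  planted_keys <- if (is.null(run_rows)) character() else
    paste(run_rows$contig, run_rows$start1, run_rows$end1)
  scanned_keys <- if (is.null(scanned) || nrow(scanned) == 0L) character() else
    paste(scanned$contig, scanned$start1, scanned$end1)
  if (!setequal(planted_keys, scanned_keys))
    stop("homopolymer planting produced unexpected runs; ",
         "reduce n_homopolymers or enlarge the genome")
  if (is.null(run_rows))
    run_rows <- data.frame(contig = character(), start1 = integer(),
                           end1 = integer(), base = character(),
                           length = integer(), stringsAsFactors = FALSE)

  # repeat mask: fixed-width blocks on a deterministic grid per contig
  rep_rows <- do.call(rbind, lapply(names(lens), function(nm) {
    len <- lens[[nm]]
    width <- 500L
    k <- max(1L, round(cfg$repeat_fraction * len / width))
    anchors <- round(seq(0.05, 0.95, length.out = k) * (len - width))
    data.frame(contig = nm, start = as.integer(anchors),
               end = as.integer(anchors + width), stringsAsFactors = FALSE)
  }))
  repeats <- if (cfg$repeat_fraction > 0) interval_set(rep_rows)
             else interval_set()
  targets <- complement_interval_set(repeats, lens)
  list(ref = ref, runs = run_rows, repeats = repeats, targets = targets)
}

# candidate positions that pass every site-context predicate
clean_positions <- function(ref, runs, repeats, n_wanted) {
  pools <- lapply(names(ref), function(nm) {
    len <- nchar(ref[[nm]])
    pos <- seq(5L, len - 5L)
    pos <- pos[!in_interval_set(nm, pos, repeats)]
    pos <- pos[!is_homopolymer_proximal(nm, pos, runs, distance = 1L)]
    data.frame(contig = nm, pos1 = pos, stringsAsFactors = FALSE)
  })
  pool <- do.call(rbind, pools)
  if (nrow(pool) < n_wanted)
    stop("not enough clean positions for the requested variant counts")
  pool
}

#' Generate the cohort truth set and population-frequency table
#'
#' Places every truth class in its designed sequence context: clean somatic
#' variants outside repeat and homopolymer-adjacent zones, homopolymer
#' artifacts within one nucleotide of a planted run, repeat artifacts inside
#' the repeat mask, and common-SNP leaks at generated population-table sites
#' with MAF above the filter threshold. Subclonal allele fractions are drawn
#' from `subclonal_af_range` floored at `min_alt_reads / mean_depth` (0.08
#' at defaults) so that a designed subclonal variant always carries enough
#' read support to be recoverable, keeping `expected_fate` a pure function
#' of the class. Deterministic given `cfg$seed`.
#'
#' @param cfg A `SimulationConfig`.
#' @param ref,runs,repeats Output of [generate_reference()].
#' @param min_alt_reads The alt-read threshold the pipeline will apply
#'   (default 4); used only for the subclonal design floor.
#' @return List with `truth` (data.frame: `sample_id`, `contig`, `pos1`,
#'   `ref`, `alt`, `class`, `designed_af`, `expected_fate`, `shared`) and
#'   `population` (data.frame: `contig`, `pos1`, `ref`, `alt`, `maf`).
#' @export
generate_truth <- function(cfg, ref, runs, repeats, min_alt_reads = 4L) {
  set.seed(cfg$seed + 1L)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))

  n_clean_per_sample <- cfg$n_clonal + cfg$n_subclonal + cfg$n_germline +
    cfg$n_artifact_low_qual + cfg$n_artifact_low_alt_reads +
    cfg$n_artifact_caller_unique_A + cfg$n_artifact_caller_unique_B +
    cfg$n_artifact_low_normal_depth
  n_clean <- n_clean_per_sample * cfg$n_samples + cfg$n_common_snps + 1L
  pool <- clean_positions(ref, runs, repeats, n_clean)
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  take_clean <- local({
    i <- 0L
    function(k) {
      if (k == 0L) return(pool[0L, , drop = FALSE])
      out <- pool[(i + 1L):(i + k), , drop = FALSE]
      i <<- i + k
      out
    }
  })

  # population table (all entries above the 0.1% MAF filter threshold)
  pop_sites <- take_clean(cfg$n_common_snps)
  if (nrow(pop_sites)) {
    rb <- mapply(function(c, p) ref_base(ref, c, p), pop_sites$contig,
                 pop_sites$pos1, USE.NAMES = FALSE)
    population <- data.frame(
      contig = pop_sites$contig, pos1 = pop_sites$pos1, ref = rb,
      alt = vapply(rb, draw_alt, character(1),
                   p_transition = cfg$transition_prob),
      maf = round(stats::runif(nrow(pop_sites),
                               cfg$common_snp_maf_range[1],
                               cfg$common_snp_maf_range[2]), 5),
      stringsAsFactors = FALSE
    )
  } else {
    population <- data.frame(contig = character(), pos1 = integer(),
                             ref = character(), alt = character(),
                             maf = numeric(), stringsAsFactors = FALSE)
  }

  # context-specific position pools
  hp_pool <- if (nrow(runs)) do.call(rbind, lapply(seq_len(nrow(runs)),
    function(i) data.frame(contig = runs$contig[i],
                           pos1 = c(runs$start1[i] - 1L, runs$start1[i],
                                    runs$end1[i], runs$end1[i] + 1L),
                           stringsAsFactors = FALSE))) else NULL
  if (!is.null(hp_pool)) {
    keep <- !in_interval_set_multi(hp_pool$contig, hp_pool$pos1, repeats)
    hp_pool <- hp_pool[keep, , drop = FALSE]
    hp_pool <- hp_pool[sample.int(nrow(hp_pool)), , drop = FALSE]
  }
  rep_pool <- local({
    d <- as.data.frame(repeats)
    if (nrow(d) == 0L) return(NULL)
    rows <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
      data.frame(contig = d$contig[i],
                 pos1 = seq(d$start[i] + 1L, d$end[i]),
                 stringsAsFactors = FALSE)))
    keep <- !is_homopolymer_proximal_multi(rows$contig, rows$pos1, runs)
    rows <- rows[keep, , drop = FALSE]
    rows[sample.int(nrow(rows)), , drop = FALSE]
  })
  hp_i <- 0L; rep_i <- 0L
  take_ctx <- function(pool_name, k) {
    if (k == 0L) return(NULL)
    if (pool_name == "hp") {
      if (is.null(hp_pool) || hp_i + k > nrow(hp_pool))
        stop("not enough homopolymer-adjacent positions; plant more runs")
      out <- hp_pool[(hp_i + 1L):(hp_i + k), , drop = FALSE]
      hp_i <<- hp_i + k
    } else {
      if (is.null(rep_pool) || rep_i + k > nrow(rep_pool))
        stop("not enough repeat-region positions; raise repeat_fraction")
      out <- rep_pool[(rep_i + 1L):(rep_i + k), , drop = FALSE]
      rep_i <<- rep_i + k
    }
    out
  }

  af_floor <- min_alt_reads / cfg$mean_depth
  sub_lo <- max(cfg$subclonal_af_range[1], af_floor)
  if (sub_lo >= cfg$subclonal_af_range[2])
    stop("subclonal_af_range incompatible with mean_depth and min_alt_reads")

  draw_af <- function(class, n) {
    switch(class,
      SOMATIC_CLONAL = ,
      COMMON_SNP_LEAK = ,
      ARTIFACT_HOMOPOLYMER = , ARTIFACT_REPEAT = , ARTIFACT_LOW_QUAL = ,
      ARTIFACT_CALLER_UNIQUE_A = , ARTIFACT_CALLER_UNIQUE_B = ,
      ARTIFACT_LOW_NORMAL_DEPTH = , ARTIFACT_LOW_ALT_READS =
        stats::runif(n, cfg$clonal_af_range[1], cfg$clonal_af_range[2]),
      SOMATIC_SUBCLONAL = stats::runif(n, sub_lo, cfg$subclonal_af_range[2]),
      GERMLINE = rep(0.5, n)
    )
  }

  # one shared clonal variant planted across the first k samples
  shared_rec <- NULL
  if (cfg$shared_variant_samples >= 2L && cfg$n_samples >= 2L) {
    site <- take_clean(1L)
    rb <- ref_base(ref, site$contig, site$pos1)
    shared_rec <- data.frame(contig = site$contig, pos1 = site$pos1,
                             ref = rb,
                             alt = draw_alt(rb, cfg$transition_prob),
                             stringsAsFactors = FALSE)
  }

  rows <- list()
  for (s in samples) {
    mk <- function(sites, class) {
      if (is.null(sites) || nrow(sites) == 0L) return(NULL)
      rb <- mapply(function(c, p) ref_base(ref, c, p), sites$contig,
                   sites$pos1, USE.NAMES = FALSE)
      data.frame(
        sample_id = s, contig = sites$contig, pos1 = sites$pos1, ref = rb,
        alt = vapply(rb, draw_alt, character(1),
                     p_transition = cfg$transition_prob),
        class = class, designed_af = draw_af(class, nrow(sites)),
        expected_fate = class_fate[[class]], shared = FALSE,
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_clonal), "SOMATIC_CLONAL")
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_subclonal),
                                    "SOMATIC_SUBCLONAL")
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_germline), "GERMLINE")
    if (cfg$n_snp_leak > 0L) {
      if (nrow(population) < cfg$n_snp_leak)
        stop("n_snp_leak exceeds n_common_snps")
      pick <- population[sample.int(nrow(population), cfg$n_snp_leak), ,
                         drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, contig = pick$contig, pos1 = pick$pos1,
        ref = pick$ref, alt = pick$alt, class = "COMMON_SNP_LEAK",
        designed_af = draw_af("COMMON_SNP_LEAK", nrow(pick)),
        expected_fate = class_fate[["COMMON_SNP_LEAK"]], shared = FALSE,
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- mk(take_ctx("hp", cfg$n_artifact_homopolymer),
                                    "ARTIFACT_HOMOPOLYMER")
    rows[[length(rows) + 1L]] <- mk(take_ctx("rep", cfg$n_artifact_repeat),
                                    "ARTIFACT_REPEAT")
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_artifact_low_qual),
                                    "ARTIFACT_LOW_QUAL")
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_artifact_low_alt_reads),
                                    "ARTIFACT_LOW_ALT_READS")
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_artifact_caller_unique_A),
                                    "ARTIFACT_CALLER_UNIQUE_A")
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_artifact_caller_unique_B),
                                    "ARTIFACT_CALLER_UNIQUE_B")
    rows[[length(rows) + 1L]] <- mk(take_clean(cfg$n_artifact_low_normal_depth),
                                    "ARTIFACT_LOW_NORMAL_DEPTH")
    if (!is.null(shared_rec) &&
        match(s, samples) <= cfg$shared_variant_samples) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, contig = shared_rec$contig, pos1 = shared_rec$pos1,
        ref = shared_rec$ref, alt = shared_rec$alt,
        class = "SOMATIC_CLONAL",
        designed_af = draw_af("SOMATIC_CLONAL", 1L),
        expected_fate = "CONSENSUS", shared = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(truth = truth, population = population)
}

# vectorized helpers across mixed contigs
in_interval_set_multi <- function(contig, pos1, set) {
  out <- logical(length(pos1))
  for (nm in unique(contig)) {
    sel <- contig == nm
    out[sel] <- in_interval_set(nm, pos1[sel], set)
  }
  out
}
is_homopolymer_proximal_multi <- function(contig, pos1, runs, distance = 1L) {
  out <- logical(length(pos1))
  for (nm in unique(contig)) {
    sel <- contig == nm
    out[sel] <- is_homopolymer_proximal(nm, pos1[sel], runs, distance)
  }
  out
}

#' Simulate read evidence and write the per-sample file bundle
#'
#' Site depth is Poisson(`mean_depth`) and alternate-read support
#' Binomial(depth, designed AF) (both deterministic `round()`s when
#' `cfg$noise` is FALSE). Both caller dialects observe the same pileup;
#' quality scores are drawn independently per caller. Low-quality artifacts
#' receive scores below 10 in both callers, low-alt-read artifacts are
#' forced below 4 supporting reads, caller-unique artifacts are written to
#' exactly one dialect's VCF, and low-normal-depth artifact sites are
#' covered below 10X in the normal depth track. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A `SimulationConfig`.
#' @param truth Truth data.frame from [generate_truth()].
#' @param ref A `ReferenceSet`.
#' @param population Population table from [generate_truth()].
#' @param dir Output directory.
#' @return Named list of written paths: `reference`, `repeats_bed`,
#'   `targets_bed`, `population_tsv`, `annotation_tsv`, `truth_tsv`,
#'   `sample_sheet`, and per-sample `caller_A`, `caller_B`, `germline`,
#'   `depth_track` vectors.
#' @export
simulate_evidence_and_write <- function(cfg, truth, ref, population, dir) {
  set.seed(cfg$seed + 2L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lens <- vapply(names(ref), function(nm) nchar(ref[[nm]]), integer(1))
  samples <- unique(truth$sample_id)

  paths <- list(
    reference = file.path(dir, "reference.fa"),
    repeats_bed = file.path(dir, "repeats.bed"),
    targets_bed = file.path(dir, "targets.bed"),
    population_tsv = file.path(dir, "population.tsv"),
    annotation_tsv = file.path(dir, "annotation.tsv"),
    truth_tsv = file.path(dir, "truth.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.tsv")
  )
  write_fasta(ref, paths$reference)
  utils::write.table(population, paths$population_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # annotation over unique variant keys: tiling gene model, consequence
  # strings from the categories seen in real exome callsets, CADD spanning
  # the tier boundaries
  ann <- truth[!duplicated(variant_key(truth)), c("contig", "pos1", "ref",
                                                  "alt"), drop = FALSE]
  ann$gene <- sprintf("GENE_%s_%03d", ann$contig, ann$pos1 %/% 2000L)
  csq_pool <- c("missense_variant", "intron_variant", "synonymous_variant",
                "3_prime_UTR_variant", "5_prime_UTR_variant",
                "non_coding_transcript_exon_variant",
                "downstream_gene_variant", "splice_region_variant")
  csq_w <- c(0.40, 0.30, 0.15, 0.03, 0.02, 0.03, 0.04, 0.03)
  ann$consequence <- sample(csq_pool, nrow(ann), replace = TRUE, prob = csq_w)
  ann$cadd_phred <- round(stats::runif(nrow(ann), 0, 40), 2)
  pk <- variant_key(population)
  ann$pop_freq <- population$maf[match(variant_key(ann), pk)]
  ann$pop_freq[is.na(ann$pop_freq)] <- 0
  utils::write.table(ann, paths$annotation_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  draw_depth <- function(n) {
    if (cfg$noise) pmax(stats::rpois(n, cfg$mean_depth), 1L)
    else rep(as.integer(round(cfg$mean_depth)), n)
  }
  draw_alt_depth <- function(depth, af) {
    if (cfg$noise) stats::rbinom(length(depth), depth, af)
    else as.integer(round(depth * af))
  }

  sheet <- data.frame(sample_id = samples, caller_A = "", caller_B = "",
                      germline = "", depth_track = "",
                      stringsAsFactors = FALSE)
  for (s in samples) {
    tr <- truth[truth$sample_id == s, , drop = FALSE]
    n <- nrow(tr)
    depth <- draw_depth(n)
    alt_dp <- draw_alt_depth(depth, tr$designed_af)
    low_alt <- tr$class == "ARTIFACT_LOW_ALT_READS"
    if (any(low_alt))
      alt_dp[low_alt] <- pmin(alt_dp[low_alt],
                              sample(1:3, sum(low_alt), replace = TRUE))
    alt_dp <- pmin(alt_dp, depth)

    qual_A <- round(stats::runif(n, 15, 60), 1)
    qual_B <- round(stats::runif(n, 15, 60), 1)
    low_q <- tr$class == "ARTIFACT_LOW_QUAL"
    qual_A[low_q] <- round(stats::runif(sum(low_q), 0, 9.5), 1)
    qual_B[low_q] <- round(stats::runif(sum(low_q), 0, 9.5), 1)

    filter_A <- rep("PASS", n); filter_B <- rep("PASS", n)
    is_artifact <- startsWith(tr$class, "ARTIFACT_")
    if (cfg$nonpass_fraction > 0 && any(is_artifact)) {
      hit <- is_artifact & stats::runif(n) < cfg$nonpass_fraction
      filter_A[hit] <- "LowQual"; filter_B[hit] <- "LowEVS"
    }

    normal_dp <- draw_depth(n)
    low_nd <- tr$class == "ARTIFACT_LOW_NORMAL_DEPTH"
    normal_dp[low_nd] <- sample(0:9, sum(low_nd), replace = TRUE)

    base <- data.frame(
      sample_id = s, contig = tr$contig, pos1 = tr$pos1, ref = tr$ref,
      alt = tr$alt, alt_depth = alt_dp, total_depth = depth,
      normal_depth = normal_dp, dbsnp_id = NA_character_,
      stringsAsFactors = FALSE
    )
    in_A <- tr$class != "ARTIFACT_CALLER_UNIQUE_B"
    in_B <- tr$class != "ARTIFACT_CALLER_UNIQUE_A"
    calls_A <- base[in_A, , drop = FALSE]
    calls_A$caller_id <- "A"; calls_A$filter <- filter_A[in_A]
    calls_A$qual <- qual_A[in_A]
    calls_B <- base[in_B, , drop = FALSE]
    calls_B$caller_id <- "B"; calls_B$filter <- filter_B[in_B]
    calls_B$qual <- qual_B[in_B]

    pa <- file.path(dir, paste0(s, "_callerA.vcf"))
    pb <- file.path(dir, paste0(s, "_callerB.vcf"))
    pg <- file.path(dir, paste0(s, "_germline.vcf"))
    pd <- file.path(dir, paste0(s, "_normal_depth.tsv"))
    write_somatic_vcf(somatic_calls(calls_A), pa, "A", lens)
    write_somatic_vcf(somatic_calls(calls_B), pb, "B", lens)
    write_germline_vcf(tr[tr$class == "GERMLINE", , drop = FALSE], pg,
                       sample_id = paste0(s, "-N"), contig_lengths = lens)

    # normal depth track: constant design depth except at low-normal sites
    low_sites <- tr[low_nd, , drop = FALSE]
    low_df <- if (nrow(low_sites)) data.frame(
      contig = low_sites$contig, start = low_sites$pos1 - 1L,
      end = low_sites$pos1, depth = normal_dp[low_nd],
      stringsAsFactors = FALSE) else NULL
    default_depth <- as.integer(round(cfg$mean_depth))
    track_rows <- do.call(rbind, lapply(names(lens), function(nm) {
      len <- lens[[nm]]
      lows <- if (is.null(low_df)) NULL
              else low_df[low_df$contig == nm, , drop = FALSE]
      if (is.null(lows) || nrow(lows) == 0L)
        return(data.frame(contig = nm, start = 0L, end = len,
                          depth = default_depth))
      lows <- lows[order(lows$start), , drop = FALSE]
      starts <- c(0L, lows$end); ends <- c(lows$start, len)
      fill <- data.frame(contig = nm, start = starts, end = ends,
                         depth = default_depth)
      fill <- fill[fill$start < fill$end, , drop = FALSE]
      out <- rbind(fill, lows)
      out[order(out$start), , drop = FALSE]
    }))
    write_depth_track(track_rows, pd)

    i <- match(s, sheet$sample_id)
    sheet$caller_A[i] <- pa; sheet$caller_B[i] <- pb
    sheet$germline[i] <- pg; sheet$depth_track[i] <- pd
  }
  # the written sheet holds paths relative to the bundle directory so the
  # bundle is relocatable and byte-identical across output directories
  rel <- sheet
  for (col in c("caller_A", "caller_B", "germline", "depth_track"))
    rel[[col]] <- basename(rel[[col]])
  utils::write.table(rel, paths$sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$per_sample <- sheet
  paths
}

#' Generate and write a complete synthetic cohort bundle
#'
#' Convenience wrapper chaining [generate_reference()], [generate_truth()]
#' and [simulate_evidence_and_write()], and writing the repeat/target BEDs.
#'
#' @param cfg A `SimulationConfig`.
#' @param dir Output directory.
#' @param min_alt_reads Alt-read threshold used for the subclonal design
#'   floor (see [generate_truth()]).
#' @return List with `paths`, `truth`, `population`, `ref`, `runs`,
#'   `repeats`, `targets`.
#' @export
simulate_cohort <- function(cfg, dir, min_alt_reads = 4L) {
  geno <- generate_reference(cfg)
  tp <- generate_truth(cfg, geno$ref, geno$runs, geno$repeats, min_alt_reads)
  paths <- simulate_evidence_and_write(cfg, tp$truth, geno$ref,
                                       tp$population, dir)
  write_bed(geno$repeats, paths$repeats_bed)
  write_bed(geno$targets, paths$targets_bed)
  list(paths = paths, truth = tp$truth, population = tp$population,
       ref = geno$ref, runs = geno$runs, repeats = geno$repeats,
       targets = geno$targets)
}

#' Read a truth manifest TSV
#'
#' Reads `truth.tsv` as written by [simulate_evidence_and_write()], forcing
#' allele columns to character (a column of bare "T"s must not become
#' logical).
#'
#' @param path Path to the manifest.
#' @return Truth data.frame.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character",
                                         alt = "character"))
  df
}

#' Evaluate pipeline output against the simulation truth
#'
#' Recall is the fraction of CONSENSUS-fate truth records recovered in the
#' consensus output; precision the fraction of reported consensus variants
#' that are CONSENSUS-fate truths (undefined, `NA`, when nothing was
#' reported). The per-class confusion table shows, for every truth class,
#' how many records ended up in consensus, were removed by a filter (with
#' the audit reasons observed), or were absent from both callers'
#' audit trails.
#'
#' @param consensus_cohort Named list: sample_id -> consensus data.frame.
#' @param truth Truth data.frame (as from [generate_truth()] or read back
#'   from `truth.tsv`).
#' @param audit Optional combined audit data.frame (both callers, all
#'   samples; needs `sample_id`, `contig`, `pos1`, `ref`, `alt`, `reasons`).
#' @return List with `recall`, `precision`, `confusion` (data.frame per
#'   class) and `truth_key_fate` (per-record observed fate).
#' @export
evaluate_against_truth <- function(consensus_cohort, truth, audit = NULL) {
  cons_keys <- unlist(lapply(names(consensus_cohort), function(s) {
    v <- consensus_cohort[[s]]
    if (is.null(v) || nrow(v) == 0L) return(character())
    paste(s, variant_key(v))
  }))
  missing_samples <- setdiff(unique(truth$sample_id), names(consensus_cohort))
  if (length(missing_samples))
    stop("consensus results missing sample(s): ",
         paste(missing_samples, collapse = ", "))
  tkey <- paste(truth$sample_id, variant_key(truth))
  in_consensus <- tkey %in% cons_keys
  want <- truth$expected_fate == "CONSENSUS"
  recall <- if (any(want)) sum(in_consensus & want) / sum(want) else NA_real_
  n_reported <- length(cons_keys)
  precision <- if (n_reported > 0L)
    sum(cons_keys %in% tkey[want]) / n_reported else NA_real_

  reasons_of <- rep(NA_character_, nrow(truth))
  if (!is.null(audit) && nrow(audit) > 0L) {
    akey <- paste(audit$sample_id, variant_key(audit))
    reasons_of <- vapply(tkey, function(k) {
      r <- unique(audit$reasons[akey == k])
      r <- r[nzchar(r)]
      if (!length(r)) NA_character_ else paste(sort(unique(unlist(
        strsplit(r, ";", fixed = TRUE)))), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  observed_fate <- ifelse(in_consensus, "CONSENSUS",
                          ifelse(!is.na(reasons_of), "FILTERED", "DROPPED"))
  confusion <- do.call(rbind, lapply(sort(unique(truth$class)), function(cl) {
    sel <- truth$class == cl
    data.frame(class = cl, n = sum(sel),
               n_consensus = sum(sel & in_consensus),
               n_filtered = sum(sel & observed_fate == "FILTERED"),
               n_dropped = sum(sel & observed_fate == "DROPPED"),
               reasons = paste(sort(unique(stats::na.omit(
                 reasons_of[sel & !in_consensus]))), collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  rownames(confusion) <- NULL
  list(recall = recall, precision = precision, confusion = confusion,
       truth_key_fate = data.frame(key = tkey, class = truth$class,
                                   expected_fate = truth$expected_fate,
                                   observed_fate = observed_fate,
                                   reasons = reasons_of,
                                   stringsAsFactors = FALSE))
}
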