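empty_ctx <- function() {
  list(runs = data.frame(contig = character(), start1 = integer(),
                         end1 = integer(), base = character(),
                         length = integer()),
       repeats = interval_set())
}

test_that("record filters: inclusive thresholds, multi-reason reporting", {
  cfg <- filter_config()
  cases <- make_calls(4,
    filter = c("PASS", "PASS", "LowEVS", "PASS"),
    qual = c(10.0, 9.9, 50, 50),
    alt_depth = c(4L, 4L, 3L, 4L))
  out <- apply_record_filters(cases, cfg)
  expect_true(out$passed[1])            # qual 10.0 and 4 alt reads pass
  expect_equal(out$reasons[2], "FAIL_QUAL")
  expect_setequal(strsplit(out$reasons[3], ";")[[1]],
                  c("FAIL_FILTER_FIELD", "FAIL_ALT_READS"))
  expect_true(out$passed[4])
  # snv_only flags indels only when switched on
  indel <- make_calls(1, ref = "AT", alt = "A")
  expect_true(apply_record_filters(indel, cfg)$passed)
  expect_equal(apply_record_filters(indel,
               filter_config(snv_only = TRUE))$reasons, "FAIL_NON_SNV")
})

test_that("site filters: normal coverage boundary, homopolymer adjacency, repeats", {
  runs <- data.frame(contig = "c1", start1 = 101L, end1 = 104L, base = "A",
                     length = 4L, stringsAsFactors = FALSE)
  repeats <- interval_set(data.frame(contig = "c1", start = 500L, end = 600L))
  track <- structure(data.frame(contig = "c1", start = 0L, end = 1000L,
                                depth = 10L),
                     class = c("DepthTrack", "data.frame"))
  cfg <- filter_config()
  ok <- apply_site_filters(make_calls(1, pos1 = 300L), runs, repeats, track, cfg)
  expect_true(ok$passed)  # exactly 10X passes
  low <- structure(data.frame(contig = "c1", start = 0L, end = 1000L,
                              depth = 9L),
                   class = c("DepthTrack", "data.frame"))
  expect_equal(apply_site_filters(make_calls(1, pos1 = 300L), runs, repeats,
                                  low, cfg)$reasons, "FAIL_NORMAL_COVERAGE")
  # 1 nt left of the AAAA run
  expect_equal(apply_site_filters(make_calls(1, pos1 = 100L), runs, repeats,
                                  track, cfg)$reasons, "FAIL_HOMOPOLYMER")
  expect_true(apply_site_filters(make_calls(1, pos1 = 99L), runs, repeats,
                                 track, cfg)$passed)
  expect_equal(apply_site_filters(make_calls(1, pos1 = 550L), runs, repeats,
                                  track, cfg)$reasons, "FAIL_REPEAT")
  # depth track wins over the VCF normal DP where it covers the site
  conflicted <- make_calls(1, pos1 = 300L, normal_depth = 50L)
  expect_false(apply_site_filters(conflicted, runs, repeats, low,
                                  cfg)$passed)
  # without track coverage the VCF normal DP is the evidence
  no_track <- structure(data.frame(contig = character(), start = integer(),
                                   end = integer(), depth = integer()),
                        class = c("DepthTrack", "data.frame"))
  expect_true(apply_site_filters(conflicted, runs, repeats, no_track,
                                 cfg)$passed)
})

test_that("population filter boundary is strictly above 0.1%", {
  p <- write_lines_tmp(c("c1\t100\tC\tT\t0.002", "c1\t110\tC\tT\t0.001",
                         "c1\t120\tC\tT\t0.0011"), ".tsv")
  freqs <- read_population_frequencies(p)
  calls <- make_calls(4, pos1 = c(100L, 110L, 120L, 130L))
  out <- apply_population_filter(calls, freqs, filter_config())
  expect_equal(out$reasons, c("FAIL_POPULATION_MAF", "", "FAIL_POPULATION_MAF",
                              ""))
  # matched MAF is registered on the outcome either way
  expect_equal(out$population_maf, c(0.002, 0.001, 0.0011, NA))
})

test_that("germline subtraction is allele-level", {
  calls <- make_calls(3, pos1 = c(100L, 110L, 120L),
                      alt = c("T", "T", "T"))
  germ <- c("c1:100:C:T", "c1:110:C:G")  # second: same pos, different alt
  out <- subtract_germline(calls, germ)
  expect_equal(out$reasons, c("FAIL_GERMLINE_MATCH", "", ""))
  expect_true(all(subtract_germline(calls, character())$passed))
})

test_that("cascade verdict equals conjunction of independent predicates", {
  set.seed(11)
  n <- 20
  runs <- data.frame(contig = "c1", start1 = 101L, end1 = 104L, base = "A",
                     length = 4L, stringsAsFactors = FALSE)
  repeats <- interval_set(data.frame(contig = "c1", start = 500L, end = 600L))
  track <- structure(data.frame(contig = "c1", start = 0L, end = 1000L,
                                depth = 50L),
                     class = c("DepthTrack", "data.frame"))
  p <- write_lines_tmp("c1\t333\tC\tT\t0.05", ".tsv")
  freqs <- read_population_frequencies(p)
  germ <- "c1:444:C:T"
  calls <- make_calls(n,
    pos1 = sample(c(100L, 333L, 444L, 550L, sample(1:1000, 16)), n),
    qual = round(runif(n, 0, 30), 1),
    alt_depth = sample(0:10, n, replace = TRUE),
    filter = sample(c("PASS", "LowQual"), n, replace = TRUE,
                    prob = c(0.7, 0.3)))
  cfg <- filter_config()
  res <- run_cascade(calls, runs, repeats, track, freqs, germ, cfg)
  # oracle: each predicate independently, conjunction
  expected <- apply_record_filters(calls, cfg)$passed &
    apply_site_filters(calls, runs, repeats, track, cfg)$passed &
    apply_population_filter(calls, freqs, cfg)$passed &
    subtract_germline(calls, germ)$passed
  expect_identical(res$audit$passed, expected)
  expect_identical(variant_key(res$survivors), variant_key(calls[expected, ]))
  # attrition counts match reasons in the audit
  expect_equal(sum(res$attrition$n),
               sum(lengths(strsplit(res$audit$reasons[nzchar(res$audit$reasons)],
                                    ";"))))
})

test_that("raising thresholds never enlarges the survivor set (monotonicity)", {
  set.seed(23)
  ctx <- empty_ctx()
  track <- structure(data.frame(contig = "c1", start = 0L, end = 2000L,
                                depth = 50L),
                     class = c("DepthTrack", "data.frame"))
  p <- write_lines_tmp(paste0("c1\t", seq(5, 2000, 40), "\tC\tT\t",
                              runif(50, 0, 0.01), collapse = "\n"), ".tsv")
  freqs <- read_population_frequencies(p)
  for (rep in 1:5) {
    n <- 40
    calls <- make_calls(n, pos1 = sample(1:2000, n),
                        qual = round(runif(n, 0, 40), 1),
                        alt_depth = sample(0:20, n, replace = TRUE),
                        normal_depth = sample(0:30, n, replace = TRUE))
    base_cfg <- filter_config()
    base <- variant_key(run_cascade(calls, ctx$runs, ctx$repeats, NULL,
                                    freqs, NULL, base_cfg)$survivors)
    variants <- list(
      filter_config(min_qual = 20),
      filter_config(min_alt_reads = 8),
      filter_config(min_normal_depth = 20),
      filter_config(max_population_maf = 0.0001)
    )
    for (cfg in variants) {
      tightened <- variant_key(run_cascade(calls, ctx$runs, ctx$repeats,
                                           NULL, freqs, NULL, cfg)$survivors)
      expect_true(all(tightened %in% base))
    }
  }
})

test_that("intersection: identity, disjoint, partial overlap, symmetry", {
  a <- make_calls(2, pos1 = c(100L, 110L))
  b <- make_calls(2, pos1 = c(110L, 120L), caller_id = "B")
  cons <- intersect_callsets(a, b)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$pos1, 110L)
  # identical sets
  b2 <- a; b2$caller_id <- "B"
  expect_equal(nrow(intersect_callsets(a, b2)), 2L)
  # disjoint
  b3 <- make_calls(2, pos1 = c(900L, 910L), caller_id = "B")
  expect_equal(nrow(intersect_callsets(a, b3)), 0L)
  # symmetric in variant keys
  k1 <- paste(cons$contig, cons$pos1)
  sw <- intersect_callsets(b, a)
  expect_identical(k1, paste(sw$contig, sw$pos1))
  # consensus is a subset of both survivor sets, AF from designated source
  a2 <- make_calls(1, pos1 = 110L, alt_depth = 25L, total_depth = 50L)
  b4 <- make_calls(1, pos1 = 110L, alt_depth = 10L, total_depth = 40L,
                   caller_id = "B")
  expect_equal(intersect_callsets(a2, b4)$af, 0.5)
  expect_equal(intersect_callsets(a2, b4, af_source = "B")$af, 0.25)
  # duplicate keys are rejected
  dup <- rbind(a, a[1, ])
  expect_error(intersect_callsets(dup, b), "duplicate")
  # mixed samples are rejected
  other <- make_calls(1, sample_id = "S02", caller_id = "B")
  expect_error(intersect_callsets(a, other), "single sample")
})
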