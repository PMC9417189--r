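dialect_a_fixture <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPN01\tPN01-N",
    "c1\t100\t.\tA\tT,G\t30\tPASS\t.\tGT:DP:AD\t0/1:80:46,30,4\t0/0:60:60,0,0",
    "c1\t200\trs123\tC\tT\t12\tLowQual\t.\tGT:DP:AD\t0/1:50:40,10\t0/0:55:55,0",
    "c1\t300\t.\tG\t<DEL>\t40\tPASS\t.\tGT:DP:AD\t0/1:50:40,10\t0/0:55:55,0"
  ), ".vcf")
}

dialect_b_fixture <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "##INFO=<ID=SomaticEVS,Number=1,Type=Float,Description=\"score\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"A counts\">",
    "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"C counts\">",
    "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"G counts\">",
    "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"T counts\">",
    "##FORMAT=<ID=TAR,Number=2,Type=Integer,Description=\"ref tiers\">",
    "##FORMAT=<ID=TIR,Number=2,Type=Integer,Description=\"indel tiers\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR",
    paste0("c1\t100\t.\tC\tT\t.\tPASS\tSomaticEVS=25.1\tDP:AU:CU:GU:TU\t",
           "60:0,0:58,0:1,0:1,0\t40:0,0:36,0:0,0:4,0"),
    paste0("c1\t300\t.\tAT\tA\t.\tPASS\tSomaticEVS=18\tDP:TAR:TIR\t",
           "60:58,0:0,0\t50:40,0:9,0")
  ), ".vcf")
}

test_that("dialect A mapping: QUAL, AD, multi-allelic split, symbolic skip", {
  expect_message(calls <- read_somatic_vcf(dialect_a_fixture(), "A", "PN01"),
                 "skipped 1")
  expect_equal(nrow(calls), 3L)  # 2 alts at pos 100 + 1 at pos 200
  first <- calls[calls$pos1 == 100L & calls$alt == "T", ]
  expect_equal(first$qual, 30)
  expect_equal(first$alt_depth, 30L)
  expect_equal(first$total_depth, 80L)
  expect_equal(first$normal_depth, 60L)
  second <- calls[calls$pos1 == 100L & calls$alt == "G", ]
  expect_equal(second$alt_depth, 4L)
  low <- calls[calls$pos1 == 200L, ]
  expect_equal(low$filter, "LowQual")
  expect_equal(low$dbsnp_id, "rs123")
  expect_true(is.na(first$dbsnp_id))
  expect_error(read_somatic_vcf(dialect_a_fixture(), "A", "NOPE"),
               "tumor sample column")
})

test_that("dialect B mapping: somatic score key, tier-1 counts, indels", {
  calls <- read_somatic_vcf(dialect_b_fixture(), "B", "S1")
  snv <- calls[calls$pos1 == 100L, ]
  expect_equal(snv$qual, 25.1)
  expect_equal(snv$alt_depth, 4L)
  expect_equal(snv$total_depth, 40L)
  indel <- calls[calls$pos1 == 300L, ]
  expect_equal(indel$alt_depth, 9L)
  expect_equal(indel$total_depth, 49L)
  expect_equal(indel$qual, 18)
})

test_that("dialect A write/read round-trip preserves normalized records", {
  calls <- make_calls(4, pos1 = c(100L, 150L, 200L, 250L),
                      ref = c("C", "G", "A", "T"),
                      alt = c("T", "A", "G", "C"),
                      qual = c(30, 9.5, 50, 10),
                      filter = c("PASS", "LowQual", "PASS", "PASS"),
                      alt_depth = c(30L, 4L, 8L, 12L))
  p <- tempfile(fileext = ".vcf")
  write_somatic_vcf(calls, p, "A", c(c1 = 1000L))
  back <- read_somatic_vcf(p, "A", "S01")
  expect_equal(back, calls)
})

test_that("dialect B SNV write/read round-trip preserves evidence", {
  calls <- make_calls(3, pos1 = c(10L, 20L, 30L), ref = c("A", "C", "G"),
                      alt = c("G", "A", "T"), qual = c(11.5, 25, 8),
                      caller_id = "B", alt_depth = c(5L, 20L, 3L))
  p <- tempfile(fileext = ".vcf")
  write_somatic_vcf(calls, p, "B", c(c1 = 1000L))
  back <- read_somatic_vcf(p, "B", "S01")
  expect_equal(back$qual, calls$qual)
  expect_equal(back$alt_depth, calls$alt_depth)
  expect_equal(back$total_depth, calls$total_depth)
})

test_that("multi-allelic split conserves ALT-allele count", {
  expect_message(calls <- read_somatic_vcf(dialect_a_fixture(), "A", "PN01"),
                 "skipped")
  # 4 ALT alleles total in the file: 3 simple + 1 symbolic (skipped)
  expect_equal(nrow(calls) + 1L, 4L)
})

test_that("normalize_variants trims, left-aligns, validates REF", {
  ref <- reference_set(c(c1 = "GGGACACACTTTT"))
  # SNV untouched
  snv <- make_calls(1, pos1 = 4L, ref = "A", alt = "T")
  expect_equal(normalize_variants(snv, ref), snv)
  # shared-base trim: AC>AT at 4 is really C>T at 5
  mnp <- make_calls(1, pos1 = 4L, ref = "AC", alt = "AT")
  got <- normalize_variants(mnp, ref)
  expect_equal(got$pos1, 5L)
  expect_equal(got$ref, "C")
  expect_equal(got$alt, "T")
  # 2 bp deletion inside the CA repeat slides to the leftmost anchor:
  # GGGACACACTTTT minus any "CA"/"AC" of the repeat is GGGACACTTTT,
  # whose leftmost representation is GAC>G at position 3
  del <- make_calls(1, pos1 = 7L, ref = "CAC", alt = "C")
  got <- normalize_variants(del, ref)
  expect_equal(got$pos1, 3L)
  expect_equal(got$ref, "GAC")
  expect_equal(got$alt, "G")
  # REF mismatch is an error naming the site
  bad <- make_calls(1, pos1 = 4L, ref = "G", alt = "T")
  expect_error(normalize_variants(bad, ref), "c1:4")
})

test_that("population frequency table: lookup, absent keys, validation", {
  p <- write_lines_tmp(c("c1\t50\tC\tT\t0.002", "c1\t60\tG\tA\t0.0005"), ".tsv")
  freqs <- read_population_frequencies(p)
  q <- data.frame(contig = c("c1", "c1", "c2"), pos1 = c(50L, 60L, 50L),
                  ref = c("C", "G", "C"), alt = c("T", "A", "T"))
  expect_equal(pop_maf(freqs, q), c(0.002, 0.0005, NA))
  # allele-aware by default: same site, different alt -> no record
  q2 <- data.frame(contig = "c1", pos1 = 50L, ref = "C", alt = "G")
  expect_true(is.na(pop_maf(freqs, q2)))
  expect_equal(pop_maf(freqs, q2, by_position = TRUE), 0.002)

  bad <- write_lines_tmp("c1\t50\tC\tT\t1.5", ".tsv")
  expect_error(read_population_frequencies(bad), "\\[0,1\\]")
})

test_that("population frequencies load from a VCF with AF", {
  p <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t50\trs1\tC\tT\t.\tPASS\tAF=0.002"
  ), ".vcf")
  freqs <- read_population_frequencies(p)
  q <- data.frame(contig = "c1", pos1 = 50L, ref = "C", alt = "T")
  expect_equal(pop_maf(freqs, q), 0.002)
})

test_that("annotation table normalizes consequences and handles missing CADD", {
  p <- write_lines_tmp(c(
    "contig\tpos\tref\talt\tgene\tconsequence\tcadd_phred\tpop_freq",
    "c1\t100\tC\tT\tGNAS\tMissense variant\t34\t0",
    "c1\t200\tT\tA\tX1\tIntron variant\t\t0.003",
    "c1\t300\tG\tA\tX2\tweird_thing\t5\t0"
  ), ".tsv")
  ann <- read_annotation_table(p)
  expect_equal(ann$consequence[1], "missense_variant")
  expect_equal(ann$consequence[2], "intron_variant")
  expect_true(is.na(ann$cadd_phred[2]))
  expect_equal(ann$consequence_class[3], "other")
  bad <- write_lines_tmp(c("contig\tpos\tref\talt", "c1\t1\tA\tC"), ".tsv")
  expect_error(read_annotation_table(bad), "missing a column")
})

test_that("depth_at honors half-open intervals and uncovered positions", {
  p <- write_lines_tmp(c("c1\t0\t100\t15", "c1\t100\t200\t20"), ".tsv")
  track <- read_depth_track(p)
  expect_equal(depth_at(track, "c1", 50L), 15L)
  expect_equal(depth_at(track, "c1", 100L), 15L)  # offset 99, first interval
  expect_equal(depth_at(track, "c1", 101L), 20L)  # offset 100, second
  expect_equal(depth_at(track, "c1", 201L), 0L)
  expect_equal(depth_at(track, "c2", 50L), 0L)
})
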