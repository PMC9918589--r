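# Core model: interval arithmetic, CNV parsing/writing, merging.

test_that("reciprocal overlap and containment match hand-derived values", {
  expect_equal(reciprocal_overlap("1", 0, 100, "1", 0, 100), 1)
  expect_equal(reciprocal_overlap("1", 0, 100, "1", 200, 300), 0)
  expect_equal(reciprocal_overlap("1", 0, 100, "1", 50, 150), 0.5)
  expect_equal(reciprocal_overlap("chr1", 0, 100, "2", 0, 100), 0)
  expect_equal(containment_fraction("1", 10, 20, "1", 0, 100), 1)
  expect_equal(containment_fraction("1", 0, 100, "1", 50, 150), 0.5)
  expect_equal(containment_fraction("chr1", 0, 10, "chr2", 0, 10), 0)
  # chromosome-dialect normalization: "chr1" and "1" compare equal
  expect_equal(reciprocal_overlap("chr1", 0, 100, "1", 0, 100), 1)
})

test_that("interval arithmetic agrees with a per-base set-intersection oracle", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_interval_pair()
    sh <- oracle_shared_bases(p$c1, p$s1, p$e1, p$c2, p$s2, p$e2)
    expect_equal(
      reciprocal_overlap(p$c1, p$s1, p$e1, p$c2, p$s2, p$e2),
      min(sh / (p$e1 - p$s1), sh / (p$e2 - p$s2)))
    expect_equal(
      containment_fraction(p$c1, p$s1, p$e1, p$c2, p$s2, p$e2),
      sh / (p$e1 - p$s1))
  }
})

test_that("union coverage counts abutting records as one region", {
  regions <- data.frame(chrom = "chr1", start = c(0, 50), end = c(50, 100),
                        label = "repeat")
  expect_equal(union_cover_fraction("chr1", 10, 90, regions), 1)
  expect_equal(union_cover_fraction("chr1", 10, 200, regions), 90 / 190)
  expect_equal(union_cover_fraction("chr2", 10, 90, regions), 0)
})

test_that("bed_tsv parsing maps fields directly and collects record errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend\ttype",
               "chr1\t1000\t5000\tDEL",
               "chr1\t6000\t7000\tDUP\tcallerX",
               "chr1\toops\t9000\tDEL",
               "chr2\t100\t50\tDEL",
               "chr3\t1\t2\tWEIRD"), tf)
  calls <- parse_cnv_calls(tf, "bed_tsv", sample_id = "S1")
  expect_s3_class(calls, "cnv_calls")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$chrom[1], "chr1")
  expect_equal(calls$start[1], 1000)
  expect_equal(calls$end[1], 5000)
  expect_equal(calls$type, c("deletion", "duplication"))
  expect_equal(calls$caller[2], "callerX")
  errs <- attr(calls, "errors")
  expect_length(errs, 3)
  expect_match(errs[1], "line 4")
})

test_that("copy-neutral SV types are skipped with a warning, not an error", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000\t5000\tDEL", "chr1\t8000\t9000\tINV"), tf)
  expect_warning(calls <- parse_cnv_calls(tf), "copy-neutral")
  expect_equal(nrow(calls), 1)
})

test_that("a file with zero parseable records is fatal", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(character(0), tf)
  expect_error(parse_cnv_calls(tf), "no parseable")
  writeLines("chr1\tbad\tworse\tDEL", tf)
  expect_error(parse_cnv_calls(tf), "no parseable")
})

test_that("VCF records convert from 1-based inclusive to 0-based half-open", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##contig=<ID=chr1,length=100000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1001\tsv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5000",
    "chr1\t7001\tsv2\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=9000"), tf)
  calls <- parse_cnv_calls(tf, "vcf", sample_id = "S1")
  expect_equal(calls$start, c(1000, 7000))
  expect_equal(calls$end, c(5000, 9000))
  expect_equal(calls$type, c("deletion", "duplication"))
})

test_that("parse -> write -> parse round-trips a call table", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000\t5000\tDEL\terds",
               "chr2\t100\t90000\tDUP\tcnvnator"), tf)
  a <- parse_cnv_calls(tf, sample_id = "S1")
  tf2 <- tempfile(fileext = ".tsv")
  write_cnv_calls(a, tf2)
  b <- parse_cnv_calls(tf2, sample_id = "S1")
  expect_equal(a[c("chrom", "start", "end", "type", "caller")],
               b[c("chrom", "start", "end", "type", "caller")],
               ignore_attr = TRUE)
  # and the written file itself is stable under a second round trip
  tf3 <- tempfile(fileext = ".tsv")
  write_cnv_calls(b, tf3)
  expect_identical(readLines(tf2), readLines(tf3))
})

test_that("zero-length intervals are rejected at construction", {
  expect_error(cnv_calls("chr1", 100, 100, "deletion"), "end > start")
  expect_error(cnv_calls("chr1", -5, 100, "deletion"), ">= 0")
  expect_error(cnv_calls("chr1", 0, 100, "inversion"), "unknown CNV type")
})

test_that("merging bridges small gaps for same-sample same-type calls only", {
  calls <- cnv_calls(rep("chrT", 2), c(0, 12000), c(10000, 30000), "deletion")
  m <- merge_nearby_cnvs(calls, max_gap = 5000)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0)
  expect_equal(m$end, 30000)
  expect_equal(m$source_line, "1,2")
  # gap above threshold: not merged
  m2 <- merge_nearby_cnvs(calls, max_gap = 1000)
  expect_equal(nrow(m2), 2)
  # deletion + duplication adjacent: never merged
  mixed <- cnv_calls(rep("chrT", 2), c(0, 10000), c(10000, 20000),
                     c("deletion", "duplication"))
  expect_equal(nrow(merge_nearby_cnvs(mixed, 50000)), 2)
  # single call unchanged
  one <- cnv_calls("chrT", 5, 10, "deletion")
  expect_equal(merge_nearby_cnvs(one, 1000)$start, 5)
})

test_that("merging is idempotent", {
  set.seed(7)
  calls <- cnv_calls(sample(c("chr1", "chr2"), 40, TRUE),
                     s <- sample(0:100000, 40),
                     s + sample(1000:20000, 40),
                     sample(c("deletion", "duplication"), 40, TRUE))
  m1 <- merge_nearby_cnvs(calls, 5000)
  m2 <- merge_nearby_cnvs(m1, 5000)
  expect_equal(as.data.frame(m1)[c("chrom", "start", "end", "type")],
               as.data.frame(m2)[c("chrom", "start", "end", "type")])
})
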