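# Fixture generator: determinism, reference FASTA, engineered signal,
# annotation recipe consistency.

test_that("fixture specs validate their CNV recipes", {
  expect_error(fixture_spec(chrom_lengths = c(1e6)), "named")
  expect_error(fixture_spec(cnvs = data.frame(
    chrom = "chrT", start = 0, end = 2e6, type = "deletion"),
    chrom_lengths = c(chrT = 1e6)), "outside chromosome bounds")
  expect_error(fixture_spec(cnvs = data.frame(
    chrom = "chrT", start = 0, end = 100, type = "inversion"),
    chrom_lengths = c(chrT = 1e6)), "deletion/duplication")
})

test_that("reference FASTA generation is seed-deterministic", {
  spec <- fixture_spec(seed = 42, chrom_lengths = c(chrA = 5000, chrB = 3000))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  make_reference_fasta(spec, f1)
  make_reference_fasta(spec, f2)
  expect_identical(readLines(f1), readLines(f2))
  fa <- Rsamtools::FaFile(f1)
  idx <- Rsamtools::scanFaIndex(fa)
  expect_equal(as.character(GenomicRanges::seqnames(idx)), c("chrA", "chrB"))
  expect_equal(IRanges::width(idx), c(5000, 3000))
  # a different seed gives a different sequence
  make_reference_fasta(fixture_spec(seed = 43,
                                    chrom_lengths = c(chrA = 5000, chrB = 3000)), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
  expect_error(make_reference_fasta(
    fixture_spec(chrom_lengths = setNames(numeric(0), character(0))), f1), "named")
})

test_that("alignment simulation is byte-deterministic per seed", {
  spec <- fixture_spec(seed = 77, chrom_lengths = c(chrT = 2e5), mean_depth = 5,
                       read_length = 100,
                       cnvs = data.frame(chrom = "chrT", start = 8e4, end = 1.2e5,
                                         type = "deletion", zygosity = "het",
                                         n_discordant_pairs = 5L, n_split_reads = 2L))
  d1 <- tempfile(); d2 <- tempfile(); dir.create(d1); dir.create(d2)
  simulate_alignments_with_cnv(spec, file.path(d1, "s"), keep_sam = TRUE)
  simulate_alignments_with_cnv(spec, file.path(d2, "s"), keep_sam = TRUE)
  expect_identical(readLines(file.path(d1, "s.sam")),
                   readLines(file.path(d2, "s.sam")))
  expect_true(file.exists(file.path(d1, "s.bam")))
  expect_true(file.exists(file.path(d1, "s.bam.bai")))
})

test_that("seeded anomalous reads are present in exactly the seeded numbers", {
  fx <- shared_fixture()
  # direct scan, independent of the classifier: count by read-name prefix
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag"))
  res <- Rsamtools::scanBam(fx$bam, param = param)[[1]]
  primary <- bitwAnd(res$flag, bitwOr(0x100L, 0x800L)) == 0L
  qn <- unique(res$qname[primary])
  expect_equal(sum(grepl("^disc_c1_", qn)), 12)
  expect_equal(sum(grepl("^split_c1_", qn)), 4)
  expect_equal(sum(grepl("^outw_c3_", qn)), 8)
})

test_that("simulated depth honours zygosity", {
  td <- tempfile(); dir.create(td)
  spec <- fixture_spec(seed = 21, chrom_lengths = c(chrT = 4e5), mean_depth = 12,
                       read_length = 100,
                       cnvs = data.frame(chrom = "chrT",
                                         start = c(1e5, 2.5e5), end = c(1.5e5, 3e5),
                                         type = "deletion",
                                         zygosity = c("hom", "het")))
  bam <- simulate_alignments_with_cnv(spec, file.path(td, "zyg"))
  hom <- depth_metrics(bam, cnv_calls("chrT", 1e5, 1.5e5, "deletion"),
                       flank_bp = 5e4)
  expect_lt(hom$depth_ratio, 0.1)
  het <- depth_metrics(bam, cnv_calls("chrT", 2.5e5, 3e5, "deletion"),
                       flank_bp = 5e4)
  expect_lt(abs(het$depth_ratio - 0.5), 0.12)
})

test_that("a no-CNV fixture is flat with zero type-consistent support", {
  td <- tempfile(); dir.create(td)
  spec <- fixture_spec(seed = 31, chrom_lengths = c(chrT = 4e5), mean_depth = 10,
                       read_length = 100)
  bam <- simulate_alignments_with_cnv(spec, file.path(td, "flat"))
  fake <- cnv_calls("chrT", 1.5e5, 2.5e5, "deletion")
  m <- depth_metrics(bam, fake, flank_bp = 5e4)
  expect_lt(abs(m$depth_ratio - 1), 0.1)
  an <- classify_anomalous_reads(bam, "chrT", 1e5, 3e5,
                                 list(lower = 100, upper = 700))
  expect_equal(count_supporting_reads(an, fake, 1000,
                                      list(upper = 700))$count, 0)
})

test_that("toy annotations parse back losslessly and satisfy the recipe floor", {
  spec <- default_fixture_spec()
  dir <- tempfile()
  annot <- make_toy_annotations(spec, dir)
  back <- load_annotations(dir)
  expect_equal(nrow(back$dosage), nrow(annot$dosage))
  # at least one HI region, one TS region, one constrained gene with pext,
  # one common population SV per type, one problem region
  expect_true(any(back$dosage$kind == "region" & !is.na(back$dosage$hi_score)))
  expect_true(any(back$dosage$kind == "region" & !is.na(back$dosage$ts_score)))
  con <- back$constraint$symbol[back$constraint$pli >= 0.9]
  expect_true(length(con) >= 1)
  expect_true(any(back$pext$symbol %in% con))
  expect_true(any(back$population_svs$sv_type == "deletion" &
                    back$population_svs$popmax_af > 0.01))
  expect_true(any(back$population_svs$sv_type == "duplication" &
                    back$population_svs$popmax_af > 0.01))
  expect_gte(nrow(back$problem_regions), 1)
})

test_that("family recipe feeds the inheritance fixture end to end", {
  spec <- default_fixture_spec()
  spec$family <- data.frame(
    sample_id = c("SIM01", "SIM_M", "SIM_F"), family_id = "FAM1",
    relation = c("proband", "mother", "father"),
    chrom = "chrT", start = c(1, 282000, 1),
    end = c(2, 381000, 2), type = "deletion", stringsAsFactors = FALSE)
  annot <- make_toy_annotations(spec)
  fm <- match_family_cnvs(cnv_calls("chrT", 280000, 380000, "deletion"),
                          annot$internal_cohort, "FAM1")
  inh <- infer_inheritance(fm, trio_is_complete(annot$internal_cohort, "FAM1"))
  expect_equal(inh$label, "maternal")
})
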