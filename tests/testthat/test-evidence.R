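# Alignment evidence: flanks, bins, depth metrics, insert bounds,
# anomalous-read classification, support counting, quality score.

test_that("flank rule: half the variant size with a 100-kb minimum", {
  expect_equal(compute_flanks(40e3), 100e3)
  expect_equal(compute_flanks(1e6), 500e3)
  expect_equal(compute_flanks(200e3), 100e3)   # boundary: both rules agree
  expect_equal(compute_flanks(cnv_calls("chr1", 0, 40000, "deletion")), 100e3)
})

test_that("insert-size bounds are empirical percentiles", {
  expect_equal(insert_size_bounds(rep(400, 50))$lower, 400)
  expect_equal(insert_size_bounds(rep(400, 50))$upper, 400)
  x <- seq(1, 1000)
  b <- insert_size_bounds(x, 0, 100)
  expect_equal(b$lower, 1); expect_equal(b$upper, 1000)
  set.seed(3)
  z <- rnorm(1e5, 400, 50)
  up <- insert_size_bounds(z)$upper
  expect_lt(abs(up - quantile(z, 0.995, names = FALSE)), 1e-9)
  expect_error(insert_size_bounds(numeric(0)), "no insert sizes")
})

test_that("binned depth/MQ recovers uniform coverage and tiles the window", {
  fx <- shared_fixture()
  # a CNV-free region of the fixture: expect flat ~depth coverage
  bins <- binned_depth_mq(fx$bam, "chrT", 400000, 500000, n_bins = 20)
  expect_equal(nrow(bins), 20)
  expect_equal(bins$start[1], 400000)
  expect_equal(bins$end[20], 500000)
  expect_true(all(bins$start[-1] == bins$end[-20]))   # no gaps, no overlap
  expect_lt(abs(mean(bins$depth) - fx$spec$mean_depth), 2)
  expect_true(all(abs(bins$mq - 60) < 1e-9))
  # single-bin degenerate case equals whole-window means
  one <- binned_depth_mq(fx$bam, "chrT", 400000, 500000, n_bins = 1)
  expect_equal(one$depth, mean(bins$depth), tolerance = 1e-6)
  # a region without reads: zero depth, absent MQ
  empty <- binned_depth_mq(fx$bam, "chrT", 400000, 500000, n_bins = 4)
  expect_true(all(empty$depth >= 0))
})

test_that("missing BAM index is fatal with a remediation hint", {
  fx <- shared_fixture()
  naked <- file.path(tempdir(), "noindex.bam")
  file.copy(fx$bam, naked, overwrite = TRUE)
  expect_error(binned_depth_mq(naked, "chrT", 0, 1000, 2), "index")
})

test_that("depth metrics recover the engineered het deletion and duplication", {
  fx <- shared_fixture()
  del <- cnv_calls("chrT", 280000, 380000, "deletion")
  m <- depth_metrics(fx$bam, del)
  expect_lt(abs(m$depth_ratio - 0.5), 0.1)
  expect_equal(m$median_mq_inside, 60)
  dup <- cnv_calls("chrT", 1040000, 1052000, "duplication")
  md <- depth_metrics(fx$bam, dup)
  expect_lt(abs(md$depth_ratio - 1.5), 0.1)
  # no-CNV region: ratio ~ 1
  flat <- cnv_calls("chrT", 450000, 470000, "deletion")
  expect_lt(abs(depth_metrics(fx$bam, flat)$depth_ratio - 1), 0.1)
})

test_that("anomalous classification is exhaustive, exclusive and leak-free", {
  fx <- shared_fixture()
  # generous fixed bounds: the background Normal(400, 50) never escapes them
  bounds <- list(lower = 100, upper = 700)
  an <- classify_anomalous_reads(fx$bam, "chrT", 180000, 480000, bounds)
  expect_true(all(an$category %in% c("inward_insert_outlier", "outward",
                                     "same_direction", "split")))
  expect_equal(anyDuplicated(paste(an$read_name, an$start)), 0)
  kind <- sub("_c.*", "", an$read_name)
  # every seeded discordant pair and split read is recovered...
  expect_equal(sum(kind == "disc" & an$category == "inward_insert_outlier"), 24)
  expect_equal(sum(kind == "split" & an$category == "split"), 4)
  # ...with zero category leakage and no background reads misclassified
  expect_equal(sum(kind == "disc" & an$category != "inward_insert_outlier"), 0)
  expect_equal(sum(kind == "split" & an$category != "split"), 0)
  expect_equal(sum(kind == "bg"), 0)
  # duplication window: outward pairs recovered
  an2 <- classify_anomalous_reads(fx$bam, "chrT", 1000000, 1100000, bounds)
  kind2 <- sub("_c.*", "", an2$read_name)
  expect_equal(sum(kind2 == "outw" & an2$category == "outward"), 16)
  expect_equal(sum(kind2 == "bg"), 0)
})

test_that("supporting reads are counted by type-consistent geometry", {
  fx <- shared_fixture()
  bounds <- list(lower = 100, upper = 700)
  del <- cnv_calls("chrT", 280000, 380000, "deletion")
  an <- classify_anomalous_reads(fx$bam, "chrT", 180000, 480000, bounds)
  sup <- count_supporting_reads(an, del, tolerance_bp = 1000, bounds = bounds)
  expect_equal(sup$count, 12 + 4)   # seeded discordant pairs + split reads
  expect_true(all(sup$anomalous$supports_cnv %in% c(TRUE, FALSE)))
  # outward pairs never support a deletion
  dup_an <- classify_anomalous_reads(fx$bam, "chrT", 1000000, 1100000, bounds)
  del_like <- cnv_calls("chrT", 1040000, 1052000, "deletion")
  expect_equal(count_supporting_reads(dup_an, del_like, 1000, bounds)$count, 0)
  # but do support the duplication
  dup <- cnv_calls("chrT", 1040000, 1052000, "duplication")
  expect_equal(count_supporting_reads(dup_an, dup, 1000, bounds)$count, 8)
  # count is non-increasing as tolerance shrinks
  cnts <- vapply(c(2000, 1000, 500, 100, 0), function(tol)
    count_supporting_reads(an, del, tol, bounds)$count, numeric(1))
  expect_true(all(diff(cnts) <= 0))
})

test_that("exact-breakpoint fixtures are recovered at zero tolerance", {
  td <- tempfile(); dir.create(td)
  spec <- fixture_spec(seed = 5, chrom_lengths = c(chrT = 6e5),
                       mean_depth = 8, read_length = 100,
                       breakpoint_jitter = 0,
                       cnvs = data.frame(chrom = "chrT", start = 2e5, end = 3e5,
                                         type = "deletion", zygosity = "het",
                                         n_discordant_pairs = 9L,
                                         n_split_reads = 3L))
  bam <- simulate_alignments_with_cnv(spec, file.path(td, "exact"))
  bounds <- list(lower = 100, upper = 700)
  an <- classify_anomalous_reads(bam, "chrT", 1e5, 4e5, bounds)
  del <- cnv_calls("chrT", 2e5, 3e5, "deletion")
  expect_equal(count_supporting_reads(an, del, tolerance_bp = 0,
                                      bounds = bounds)$count, 12)
})

test_that("quality score is bounded, monotone in support, and zero-floored", {
  expect_equal(quality_score(0.5, 60, 10, "deletion"), 1)
  expect_equal(quality_score(1.0, 60, 10, "deletion"), 0)
  expect_equal(quality_score(1.5, 60, 10, "duplication"), 1)
  expect_equal(quality_score(1.0, 60, 10, "duplication"), 0)
  # hand-computed mid-grade value: depth (1-0.8)/0.4 = 0.5; MQ 20/40 = 0.5;
  # support 2/5 = 0.4 -> 0.1
  expect_equal(quality_score(0.8, 20, 2, "deletion"), 0.5 * 0.5 * 0.4)
  expect_true(is.na(quality_score(NA, 60, 5, "deletion")))
  set.seed(9)
  for (i in 1:50) {
    q <- quality_score(runif(1, 0, 2), runif(1, 0, 60),
                       sample(0:20, 1), sample(c("deletion", "duplication"), 1))
    expect_true(q >= 0 && q <= 1)
  }
  qs <- vapply(0:8, function(n) quality_score(0.7, 30, n, "deletion"), numeric(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("reference comparison flags reference-driven artifact bins only", {
  grid <- data.frame(bin = 1:10, start = seq(0, 900, 100),
                     end = seq(100, 1000, 100))
  sample_bins <- transform(grid, depth = 30, mq = 60)
  ref_flat <- transform(grid, depth = 30, mq = 60)
  expect_equal(compare_reference_sample(sample_bins, ref_flat), integer(0))
  ref_dip <- ref_flat; ref_dip$depth[4] <- 10
  expect_equal(compare_reference_sample(sample_bins, ref_dip), 4L)
  # the flag describes the reference: a flat reference never flags,
  # even if the sample dips
  sample_dip <- sample_bins; sample_dip$depth[4] <- 10
  expect_equal(compare_reference_sample(sample_dip, ref_flat), integer(0))
  # mismatched grids are fatal
  bad <- ref_flat; bad$start <- bad$start + 1
  expect_error(compare_reference_sample(sample_bins, bad), "grids")
})

test_that("the full evidence profile ties the pieces together", {
  fx <- shared_fixture()
  del <- cnv_calls("chrT", 280000, 380000, "deletion")
  ev <- extract_evidence(fx$bam, del, ref_bam = fx$bam)
  expect_s3_class(ev, "evidence_profile")
  expect_equal(ev$flank_bp, 100e3)
  expect_equal(nrow(ev$bins), default_config()$n_bins)
  expect_lt(abs(ev$depth_ratio - 0.5), 0.1)
  expect_gte(ev$supporting_read_count, 12)
  expect_true(ev$quality_score > 0.9)
  expect_true(all(ev$reference_flagged_bins %in% seq_len(nrow(ev$bins))))
  # a plot file can be written
  png <- file.path(tempdir(), "evidence.png")
  plot_evidence(ev, png)
  expect_true(file.size(png) > 0)
})
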