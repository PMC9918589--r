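# Annotation bundles, score ladders, adverse criteria, ranking, summaries.

test_that("annotating a CNV with no overlaps yields an empty bundle", {
  annot <- make_toy_annotations(default_fixture_spec())
  b <- annotate_cnv(cnv_calls("chrT", 10000, 11000, "deletion"), annot)
  expect_equal(nrow(b$population_hits), 0)
  expect_equal(nrow(b$known_sv_hits), 0)
  expect_equal(nrow(b$dosage_hits), 0)
  expect_equal(nrow(b$gene_impacts), 0)
  expect_equal(b$problem_cover, 0)
})

test_that("gene impacts distinguish full from partial overlap and count exons", {
  annot <- make_toy_annotations(default_fixture_spec())
  # whole-gene deletion
  b <- annotate_cnv(cnv_calls("chrT", 280000, 380000, "deletion"), annot)
  gi <- b$gene_impacts
  expect_equal(gi$symbol, "GENE_HI")
  expect_equal(gi$overlap_kind, "full")
  expect_equal(gi$pli, 0.98)
  expect_match(gi$disease, "OMIM")
  # deletion covering exons 1-7 of the 10-exon canonical transcript
  # (exons every 1000 bp from 310000; exon 7 ends at 316150)
  b2 <- annotate_cnv(cnv_calls("chrT", 309000, 316500, "deletion"), annot)
  tx <- b2$affected_transcripts
  expect_equal(nrow(tx), 1)
  expect_equal(tx$exons_affected, "1-7")
  expect_equal(tx$n_exons_affected, 7L)
  expect_true(tx$is_canonical)
  expect_equal(tx$cds_bp, 7 * 150)
  expect_true(tx$pext_max <= 1 && tx$pext_min >= 0)
  expect_equal(b2$gene_impacts$overlap_kind, "partial")
})

test_that("exon numbering follows transcription order on the minus strand", {
  genes <- toy_gene_rows("GM", "chrT", 100000, n_exons = 4, strand = "-")
  annot <- annotation_set(genes = genes)
  # hit the left-most genomic exon, which is exon 4 in transcription order
  b <- annotate_cnv(cnv_calls("chrT", 100000, 100100, "deletion"), annot)
  expect_equal(b$affected_transcripts$exons_affected, "4")
})

test_that("the deletion ladder scores every rung as designed", {
  for (nm in names(sc <- deletion_ladder_scenarios())) {
    s <- sc[[nm]]
    got <- clinical_relevance_score(annotate_cnv(s$cnv, s$annot))
    expect_equal(got$score, s$expected, label = nm)
  }
})

test_that("the duplication ladder scores every rung as designed", {
  for (nm in names(sc <- duplication_ladder_scenarios())) {
    s <- sc[[nm]]
    got <- clinical_relevance_score(annotate_cnv(s$cnv, s$annot))
    expect_equal(got$score, s$expected, label = nm)
  }
})

test_that("clinical relevance stays in the documented ranges", {
  for (s in deletion_ladder_scenarios()) {
    sc <- clinical_relevance_score(annotate_cnv(s$cnv, s$annot))$score
    expect_true(sc %in% c(1:5, 99))
  }
  for (s in duplication_ladder_scenarios()) {
    sc <- clinical_relevance_score(annotate_cnv(s$cnv, s$annot))$score
    expect_true(sc %in% c(1:7, 99))
  }
})

test_that("the rule ladder is configurable as data", {
  s <- deletion_ladder_scenarios()$pli_gene_cds
  cfg <- default_config()
  cfg$rules <- transform(default_clinical_rules(),
                         score = ifelse(rule == "DEL_PLI_CDS", 2, score))
  got <- clinical_relevance_score(annotate_cnv(s$cnv, s$annot), cfg)
  expect_equal(got$score, 2L)
})

test_that("adverse criterion (a): common same-type population overlap", {
  annot <- annotation_set(population_svs = data.frame(
    chrom = "chr1", start = 0, end = 80000, sv_type = "deletion",
    id = "P1", af_all = 0.05))
  # 80% reciprocal overlap with the AF-5% SV
  b <- annotate_cnv(cnv_calls("chr1", 0, 100000, "deletion"), annot)
  ad <- adverse_information_score(b)
  expect_equal(ad$score, 100L)
  expect_equal(ad$adverse_reasons, "SUBSTANTIAL_POPULATION_OVERLAP")
  # same overlap but opposite type: clean
  b2 <- annotate_cnv(cnv_calls("chr1", 0, 100000, "duplication"), annot)
  expect_equal(adverse_information_score(b2)$score, 0L)
})

test_that("evidence-based adverse criteria fire only when evidence exists", {
  annot <- annotation_set()
  b <- annotate_cnv(cnv_calls("chr1", 0, 100000, "deletion"), annot)
  expect_equal(adverse_information_score(b, NULL)$score, 0L)
  flat <- list(depth_ratio = 1.0, median_mq_inside = 60)
  ad <- adverse_information_score(b, flat)
  expect_equal(ad$score, 100L)
  expect_equal(ad$adverse_reasons, "DEPTH_INCONSISTENT")
  lowmq <- list(depth_ratio = 0.5, median_mq_inside = 10)
  expect_equal(adverse_information_score(b, lowmq)$adverse_reasons,
               "LOW_MAPPING_QUALITY")
  ok <- list(depth_ratio = 0.5, median_mq_inside = 60)
  expect_equal(adverse_information_score(b, ok)$score, 0L)
  # duplications are judged against the opposite depth direction
  bd <- annotate_cnv(cnv_calls("chr1", 0, 100000, "duplication"), annot)
  expect_equal(adverse_information_score(bd, list(depth_ratio = 1.0,
                                                  median_mq_inside = 60))$score, 100L)
  expect_equal(adverse_information_score(bd, list(depth_ratio = 1.5,
                                                  median_mq_inside = 60))$score, 0L)
})

test_that("problem-region cover above 70% is adverse on its own", {
  annot <- annotation_set(problem_regions = data.frame(
    chrom = "chr1", start = 0, end = 8000, label = "gap"))
  b <- annotate_cnv(cnv_calls("chr1", 0, 10000, "deletion"), annot)
  expect_equal(adverse_information_score(b)$adverse_reasons,
               "PROBLEM_REGION_OVERLAP")
  b2 <- annotate_cnv(cnv_calls("chr1", 0, 20000, "deletion"), annot)
  expect_equal(adverse_information_score(b2)$score, 0L)
})

test_that("priority combines components with the documented tiers", {
  expect_equal(priority_score(1, 0, "deletion")$priority, 1L)
  expect_equal(priority_score(1, 0, "deletion")$tier, "high")
  expect_equal(priority_score(99, 0, "deletion")$tier, "moderate")
  expect_equal(priority_score(1, 100, "deletion")$priority, 101L)
  expect_equal(priority_score(1, 100, "deletion")$tier, "low")
  expect_equal(priority_score(7, 0, "duplication")$tier, "high")
  expect_error(priority_score(6, 0, "deletion"), "illegal")
  expect_error(priority_score(1, 50, "deletion"), "0 or 100")
})

test_that("tier is high iff clinical < 99 and adverse == 0", {
  for (cl in c(1:5, 99)) for (ad in c(0L, 100L)) {
    p <- priority_score(cl, ad, "deletion")
    expect_equal(p$tier == "high", cl < 99 && ad == 0)
    expect_equal(p$priority, cl + ad)
  }
})

test_that("scoring is a pure function of its inputs", {
  s <- deletion_ladder_scenarios()$contains_hi_region
  b <- annotate_cnv(s$cnv, s$annot)
  r1 <- clinical_relevance_score(b)
  r2 <- clinical_relevance_score(b)
  expect_identical(r1, r2)
})

test_that("ranking is by ascending priority then descending size, stable", {
  calls <- cnv_calls(rep("chr1", 4), c(0, 100, 200, 300),
                     c(1e6, 10100, 200300, 1e6 + 300),
                     "deletion")
  # priorities 99, 1, 101, 1: ties on 1 broken by size (1 Mb first)
  o <- rank_cnvs(calls, c(99L, 1L, 101L, 1L))
  expect_equal(o, c(4, 2, 1, 3))
  expect_equal(rank_cnvs(calls[0, ], integer(0)), integer(0))
})

test_that("summaries carry finding codes for rules and adverse reasons", {
  s <- deletion_ladder_scenarios()$contains_hi_region
  res <- score_cnv(s$cnv, s$annot)
  fnd <- summarize_findings(res$bundle, res$priority)
  expect_true("FULLY_CONTAINS_HI" %in% fnd$positive$code)
  expect_true(all(nzchar(fnd$positive$sentence)))
  annot <- annotation_set(population_svs = data.frame(
    chrom = "chr1", start = 0, end = 80000, sv_type = "deletion",
    id = "P1", af_all = 0.05))
  res2 <- score_cnv(cnv_calls("chr1", 0, 100000, "deletion"), annot)
  fnd2 <- summarize_findings(res2$bundle, res2$priority)
  expect_true("SUBSTANTIAL_POPULATION_OVERLAP" %in% fnd2$negative$code)
  expect_match(fnd2$links[["gnomad"]], "^https://gnomad")
  # no findings at all
  res3 <- score_cnv(cnv_calls("chr1", 500000, 501000, "deletion"), annotation_set())
  fnd3 <- summarize_findings(res3$bundle, res3$priority)
  expect_equal(nrow(fnd3$positive), 0)
  expect_equal(nrow(fnd3$negative), 0)
})
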