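# Shared fixtures, built once per test run and cached in the session.

.fixture_cache <- new.env(parent = emptyenv())

# The standard demonstration fixture: 2-Mb toy chromosome, six engineered
# CNVs, simulated BAM and toy annotation database.
shared_fixture <- function(depth = 20) {
  key <- sprintf("sim_%g", depth)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  td <- file.path(tempdir(), sprintf("cnvtriage_fix_%g", depth))
  dir.create(td, showWarnings = FALSE, recursive = TRUE)
  spec <- default_fixture_spec(seed = 104729, mean_depth = depth)
  bam <- simulate_alignments_with_cnv(spec, file.path(td, "sample"))
  annot <- make_toy_annotations(spec)
  res <- list(spec = spec, bam = bam, annot = annot, dir = td)
  .fixture_cache[[key]] <- res
  res
}

# Small single-gene annotation set for scoring scenarios. The gene G1 spans
# chrT:100000-104150 (5 exons of 150 bp every 1000 bp), optionally curated.
scenario_annotation <- function(pli = 0.01, disease = FALSE, hi_gene = FALSE,
                                ts_gene = FALSE, dosage_regions = NULL,
                                coding = TRUE, chrom = "chrT") {
  genes <- toy_gene_rows("G1", chrom, 100000, n_exons = 5, coding = coding)
  span <- c(100000, max(genes$end[genes$feature == "gene"]))
  dosage <- dosage_regions
  if (hi_gene || ts_gene) {
    dosage <- rbind(dosage, data.frame(
      chrom = chrom, start = span[1], end = span[2], kind = "gene",
      symbol = "G1", hi_score = if (hi_gene) "3" else NA,
      ts_score = if (ts_gene) "3" else NA, stringsAsFactors = FALSE))
  }
  annotation_set(
    genes = genes,
    constraint = data.frame(symbol = "G1", pli = pli),
    disease = if (disease)
      data.frame(symbol = "G1", source = "OMIM", condition = "toy condition")
    else NULL,
    dosage = dosage)
}

dosage_region_df <- function(start, end, hi = TRUE, chrom = "chrT",
                             symbol = "REGION_1") {
  data.frame(chrom = chrom, start = start, end = end, kind = "region",
             symbol = symbol, hi_score = if (hi) "3" else NA,
             ts_score = if (hi) NA else "3", stringsAsFactors = FALSE)
}

# Scenario builders covering every rung of the two clinical-relevance
# ladders. Each returns list(cnv, annot, expected).
deletion_ladder_scenarios <- function() {
  reg <- function(hi) dosage_region_df(100000, 200000, hi = hi)
  list(
    contains_hi_region = list(
      cnv = cnv_calls("chrT", 90000, 210000, "deletion"),
      annot = annotation_set(dosage = reg(TRUE)), expected = 1L),
    partial_hi_region = list(
      cnv = cnv_calls("chrT", 150000, 250000, "deletion"),
      annot = annotation_set(dosage = reg(TRUE)), expected = 2L),
    hi_gene_cds = list(
      cnv = cnv_calls("chrT", 99000, 100200, "deletion"),
      annot = scenario_annotation(pli = 0.98, hi_gene = TRUE), expected = 2L),
    pli_gene_cds = list(
      cnv = cnv_calls("chrT", 99000, 100200, "deletion"),
      annot = scenario_annotation(pli = 0.95), expected = 3L),
    disease_gene_cds = list(
      cnv = cnv_calls("chrT", 99000, 100200, "deletion"),
      annot = scenario_annotation(pli = 0.1, disease = TRUE), expected = 4L),
    disease_gene_intronic = list(
      cnv = cnv_calls("chrT", 100300, 100800, "deletion"),
      annot = scenario_annotation(pli = 0.1, disease = TRUE), expected = 5L),
    benign_gene = list(
      cnv = cnv_calls("chrT", 99000, 100200, "deletion"),
      annot = scenario_annotation(pli = 0.01), expected = 99L))
}

duplication_ladder_scenarios <- function() {
  ts_reg <- dosage_region_df(100000, 200000, hi = FALSE)
  list(
    contains_ts_region = list(
      cnv = cnv_calls("chrT", 90000, 210000, "duplication"),
      annot = annotation_set(dosage = ts_reg), expected = 1L),
    partial_ts_region = list(
      cnv = cnv_calls("chrT", 150000, 250000, "duplication"),
      annot = annotation_set(dosage = ts_reg), expected = 2L),
    contains_hi_gene = list(
      cnv = cnv_calls("chrT", 90000, 150000, "duplication"),
      annot = scenario_annotation(pli = 0.98, hi_gene = TRUE), expected = 3L),
    breaks_hi_gene = list(
      cnv = cnv_calls("chrT", 99000, 100200, "duplication"),
      annot = scenario_annotation(pli = 0.98, hi_gene = TRUE), expected = 4L),
    breaks_pli_gene = list(
      cnv = cnv_calls("chrT", 99000, 100200, "duplication"),
      annot = scenario_annotation(pli = 0.95), expected = 4L),
    contains_pli_gene = list(
      cnv = cnv_calls("chrT", 90000, 150000, "duplication"),
      annot = scenario_annotation(pli = 0.95), expected = 5L),
    contains_disease_gene = list(
      cnv = cnv_calls("chrT", 90000, 150000, "duplication"),
      annot = scenario_annotation(pli = 0.1, disease = TRUE), expected = 6L),
    partial_disease_gene_intron = list(
      cnv = cnv_calls("chrT", 100300, 100800, "duplication"),
      annot = scenario_annotation(pli = 0.1, disease = TRUE), expected = 7L),
    benign_gene = list(
      cnv = cnv_calls("chrT", 99000, 100200, "duplication"),
      annot = scenario_annotation(pli = 0.01), expected = 99L))
}

# Brute-force per-base set-intersection oracle for interval arithmetic.
oracle_shared_bases <- function(c1, s1, e1, c2, s2, e2) {
  if (norm_chrom(c1) != norm_chrom(c2)) return(0)
  length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1)))
}

random_interval_pair <- function(max_pos = 500) {
  s1 <- sample(0:max_pos, 1); e1 <- s1 + sample(1:100, 1)
  s2 <- sample(0:max_pos, 1); e2 <- s2 + sample(1:100, 1)
  ch <- sample(c("chr1", "1", "chr2"), 2, replace = TRUE)
  list(c1 = ch[1], s1 = s1, e1 = e1, c2 = ch[2], s2 = s2, e2 = e2)
}
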