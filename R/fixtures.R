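#' Declarative specification of a synthetic test fixture
#'
#' Describes a toy genome, a sequencing library, engineered CNVs and an
#' annotation recipe; the seed fully determines every generated byte, so two
#' runs are diff-clean. Stands in for controlled-access clinical data.
#'
#' @param seed integer RNG seed
#' @param chrom_lengths named numeric vector of chromosome lengths (keep the
#'   total at a few Mb for tests)
#' @param mean_depth haploid-pair mean coverage of the background library
#' @param read_length read length in bp
#' @param insert_mean,insert_sd insert-size (template-length) distribution
#' @param cnvs data.frame of engineered CNVs: chrom, start, end, type,
#'   zygosity (het/hom), n_discordant_pairs, n_split_reads. Deletions halve
#'   (het) or zero (hom) depth inside and add large-insert inward pairs plus
#'   split reads at the breakpoints; duplications raise depth 1.5x (het) /
#'   2x (hom) and add outward pairs.
#' @param breakpoint_jitter maximum bp offset of engineered anomalous reads
#'   from the exact breakpoints (0 = exact)
#' @param family optional data.frame of family CNV calls (sample_id,
#'   family_id, relation, chrom, start, end, type) injected into the toy
#'   internal cohort
#' @return list with class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1,
                         chrom_lengths = c(chrT = 1e6),
                         mean_depth = 30,
                         read_length = 150,
                         insert_mean = 400,
                         insert_sd = 50,
                         cnvs = NULL,
                         breakpoint_jitter = 150,
                         family = NULL) {
  if (!length(chrom_lengths) || is.null(names(chrom_lengths)))
    abort_input("chrom_lengths must be a named vector with >= 1 chromosome")
  if (is.null(cnvs)) {
    cnvs <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), type = character(0),
                       zygosity = character(0), n_discordant_pairs = integer(0),
                       n_split_reads = integer(0))
  }
  cnvs <- as.data.frame(cnvs)
  if (nrow(cnvs)) {
    if (is.null(cnvs$zygosity)) cnvs$zygosity <- "het"
    if (is.null(cnvs$n_discordant_pairs)) cnvs$n_discordant_pairs <- 0L
    if (is.null(cnvs$n_split_reads)) cnvs$n_split_reads <- 0L
    bad <- !cnvs$chrom %in% names(chrom_lengths) |
      cnvs$start < 0 | cnvs$end > chrom_lengths[cnvs$chrom]
    if (any(bad)) abort_input("engineered CNV(s) outside chromosome bounds")
    if (!all(cnvs$type %in% c("deletion", "duplication")))
      abort_input("fixture CNV types must be deletion/duplication")
    if (!all(cnvs$zygosity %in% c("het", "hom")))
      abort_input("fixture zygosity must be het/hom")
  }
  structure(list(seed = seed, chrom_lengths = chrom_lengths,
                 mean_depth = mean_depth, read_length = read_length,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 cnvs = cnvs, breakpoint_jitter = breakpoint_jitter,
                 family = family),
            class = "fixture_spec")
}

#' CNV call table corresponding to a fixture's engineered CNVs
#'
#' @param spec [fixture_spec()]
#' @param sample_id sample identifier for the calls
#' @return [cnv_calls()]
#' @export
fixture_calls <- function(spec, sample_id = "SIM01") {
  if (!nrow(spec$cnvs)) return(cnv_calls(character(0), numeric(0), numeric(0),
                                         character(0), sample_id))
  cnv_calls(spec$cnvs$chrom, spec$cnvs$start, spec$cnvs$end, spec$cnvs$type,
            sample_id = sample_id, caller = "simulated")
}

#' Write a seeded random reference FASTA
#'
#' @param spec [fixture_spec()]
#' @param path output FASTA path (a .fai index is created alongside)
#' @return `path`, invisibly
#' @export
make_reference_fasta <- function(spec, path) {
  seqs <- with_seed(spec$seed, {
    lapply(spec$chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(spec$chrom_lengths)
  Biostrings::writeXStringSet(dna, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

## -- read simulation ---------------------------------------------------------

sam_record <- function(qname, flag, rname, pos0, mapq, cigar, rnext, pnext0,
                       tlen, tags = "") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*%s",
          qname, flag, rname, pos0 + 1, mapq, cigar, rnext, pnext0 + 1, tlen,
          ifelse(nzchar(tags), paste0("\t", tags), ""))
}

#' Simulate a sorted, indexed BAM with engineered CNV signal
#'
#' Background proper pairs are laid down at `mean_depth` with
#' Normal(insert_mean, insert_sd) template lengths. For each engineered CNV:
#' a heterozygous deletion drops half of the overlapping fragments
#' (homozygous: all) and adds `n_discordant_pairs` inward pairs whose insert
#' is inflated by the deletion length, straddling the breakpoints, plus
#' `n_split_reads` reads split across the junction with
#' supplementary-alignment records (SA tags); a duplication duplicates half
#' (het) or all (hom) of the overlapping fragments and adds outward-facing
#' pairs at the breakpoints. Reads are written directly as aligned records
#' (no read-mapper round trip) with constant base quality; output is
#' coordinate-sorted and indexed.
#'
#' @param spec [fixture_spec()]
#' @param out_prefix output path prefix; creates `<out_prefix>.bam` and its
#'   index
#' @param keep_sam keep the intermediate SAM text next to the BAM (for
#'   byte-level determinism checks)
#' @return path to the BAM, invisibly
#' @export
simulate_alignments_with_cnv <- function(spec, out_prefix, keep_sam = FALSE) {
  recs <- with_seed(spec$seed + 1, simulate_sam_records(spec))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(spec$chrom_lengths),
                      as.integer(spec$chrom_lengths)))
  sam <- paste0(out_prefix, ".sam")
  writeLines(c(header, recs), sam)
  bam <- Rsamtools::asBam(sam, destination = out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  if (!keep_sam) unlink(sam)
  invisible(bam)
}

simulate_sam_records <- function(spec) {
  rl <- spec$read_length
  all_lines <- list()
  for (chrom in names(spec$chrom_lengths)) {
    L <- spec$chrom_lengths[[chrom]]
    n_pairs <- round(L * spec$mean_depth / (2 * rl))
    frag <- pmax(rl + 10, round(rnorm(n_pairs, spec$insert_mean, spec$insert_sd)))
    frag <- pmin(frag, L)
    left <- floor(runif(n_pairs, 0, L - frag))
    keep_mult <- rep(1L, n_pairs)   # 0 = dropped, 2 = duplicated
    cnvs <- spec$cnvs[spec$cnvs$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(cnvs))) {
      ov <- pmax(0, pmin(left + frag, cnvs$end[i]) - pmax(left, cnvs$start[i])) > 0
      hap <- runif(n_pairs) < 0.5    # which haplotype the fragment came from
      if (cnvs$type[i] == "deletion") {
        drop <- ov & (if (cnvs$zygosity[i] == "hom") TRUE else hap)
        keep_mult[drop] <- 0L
      } else {
        dup <- ov & (if (cnvs$zygosity[i] == "hom") TRUE else hap)
        keep_mult[dup & keep_mult > 0L] <- 2L
      }
    }
    idx <- rep(seq_len(n_pairs), keep_mult)
    copy <- sequence(keep_mult)
    qn <- sprintf("bg_%s_%07d%s", chrom, idx, ifelse(copy > 1, "_d", ""))
    p1 <- left[idx]; fr <- frag[idx]
    p2 <- p1 + fr - rl
    cig <- sprintf("%dM", rl)
    lines <- c(
      sam_record(qn, 99L, chrom, p1, 60L, cig, "=", p2, fr),
      sam_record(qn, 147L, chrom, p2, 60L, cig, "=", p1, -fr))
    pos_key <- c(p1, p2)
    # engineered anomalous reads
    for (i in seq_len(nrow(cnvs))) {
      eng <- engineered_reads(cnvs[i, ], chrom, rl, spec$insert_mean,
                              spec$breakpoint_jitter, i)
      lines <- c(lines, eng$lines)
      pos_key <- c(pos_key, eng$pos)
    }
    o <- order(pos_key)
    all_lines[[chrom]] <- lines[o]
  }
  unlist(all_lines, use.names = FALSE)
}

engineered_reads <- function(cnv, chrom, rl, insert_mean, jitter, cnv_idx) {
  lines <- character(0); pos <- numeric(0)
  s <- cnv$start; e <- cnv$end
  jit <- function(n) if (jitter > 0) floor(runif(n, 0, jitter + 1)) else rep(0, n)
  nd <- cnv$n_discordant_pairs
  if (nd > 0) {
    if (cnv$type == "deletion") {
      g1 <- jit(nd); g2 <- jit(nd)
      p1 <- s - g1 - rl          # left read ends at s - g1
      p2 <- e + g2               # right read starts at e + g2
      tl <- (p2 + rl) - p1
      qn <- sprintf("disc_c%d_%04d", cnv_idx, seq_len(nd))
      lines <- c(lines,
                 sam_record(qn, 99L, chrom, p1, 60L, sprintf("%dM", rl), "=", p2, tl),
                 sam_record(qn, 147L, chrom, p2, 60L, sprintf("%dM", rl), "=", p1, -tl))
      pos <- c(pos, p1, p2)
    } else {
      gA <- jit(nd); gB <- jit(nd)
      pA <- s + gA               # reverse read just inside the left breakpoint
      pB <- e - gB - rl          # forward read ending just inside the right one
      tl <- (pB + rl) - pA
      qn <- sprintf("outw_c%d_%04d", cnv_idx, seq_len(nd))
      # leftmost read reverse, rightmost forward: outward-facing pair
      lines <- c(lines,
                 sam_record(qn, 81L, chrom, pA, 60L, sprintf("%dM", rl), "=", pB, tl),
                 sam_record(qn, 161L, chrom, pB, 60L, sprintf("%dM", rl), "=", pA, -tl))
      pos <- c(pos, pA, pB)
    }
  }
  ns <- cnv$n_split_reads
  if (ns > 0) {
    k <- floor(rl / 2)
    qn <- sprintf("split_c%d_%04d", cnv_idx, seq_len(ns))
    # primary: first k bases match up to the left breakpoint, rest soft-clipped;
    # supplementary carries the other half at the right breakpoint
    p_primary <- rep(s - k, ns)
    p_suppl <- rep(e, ns)
    p_mate <- rep(max(0, s - insert_mean), ns)
    sa_fwd <- sprintf("SA:Z:%s,%d,+,%dS%dM,60,0;", chrom, e + 1, k, rl - k)
    sa_back <- sprintf("SA:Z:%s,%d,+,%dM%dS,60,0;", chrom, s - k + 1, k, rl - k)
    tlen <- p_primary + k - p_mate
    # inward pair: forward mate on the left, reverse split primary on the right
    lines <- c(lines,
               sam_record(qn, 81L, chrom, p_primary, 60L,
                          sprintf("%dM%dS", k, rl - k), "=", p_mate,
                          -tlen, sa_fwd),
               sam_record(qn, 2129L, chrom, p_suppl, 60L,
                          sprintf("%dS%dM", k, rl - k), "=", p_mate,
                          0L, sa_back),
               sam_record(qn, 161L, chrom, p_mate, 60L, sprintf("%dM", rl), "=",
                          p_primary, tlen))
    pos <- c(pos, p_primary, p_suppl, p_mate)
  }
  list(lines = lines, pos = pos)
}

## -- toy annotations ---------------------------------------------------------

#' Build the gene-model rows of one toy gene
#'
#' @param symbol gene symbol
#' @param chrom,start chromosome and 0-based start of exon 1's span side
#' @param n_exons number of exons
#' @param exon_len,intron_len exon/intron sizes in bp
#' @param strand "+" or "-" (exon numbering reversed on "-")
#' @param coding emit CDS rows (all exons coding)?
#' @param transcript_id canonical transcript identifier
#' @return data.frame of gene/transcript/exon/CDS rows
#' @export
toy_gene_rows <- function(symbol, chrom, start, n_exons = 10, exon_len = 150,
                          intron_len = 850, strand = "+", coding = TRUE,
                          transcript_id = paste0(symbol, "-201")) {
  ex_start <- start + (seq_len(n_exons) - 1) * (exon_len + intron_len)
  ex_end <- ex_start + exon_len
  span_end <- max(ex_end)
  exon_number <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
  base <- function(feature, s, e, en = NA) {
    data.frame(chrom = chrom, start = s, end = e, feature = feature,
               symbol = symbol, transcript_id = transcript_id,
               exon_number = en, strand = strand, is_canonical = TRUE,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    base("gene", start, span_end)[, ],
    base("transcript", start, span_end),
    base("exon", ex_start, ex_end, exon_number))
  rows$transcript_id[rows$feature == "gene"] <- "."
  if (coding) rows <- rbind(rows, base("CDS", ex_start, ex_end, exon_number))
  rows
}

#' Generate the toy annotation database of a fixture
#'
#' Emulates the external annotation inputs of a triage run on a toy genome:
#' a curated HI region and HI gene, a TS region and TS gene, a constrained
#' (pLI 0.95) gene, a disease-associated gene, a benign gene, a non-coding
#' gene on the exception list (all with multi-exon canonical transcripts and
#' pext scores), common (>1% AF) deletion- and duplication-type population
#' SVs plus a rare one, a known pathogenic SV, a problem region, and the
#' internal cohort rows from `spec$family`. Contradictory recipes (features
#' outside chromosome bounds) are fatal.
#'
#' @param spec [fixture_spec()]
#' @param dir optional directory; when given, tables are also written in the
#'   on-disk dialects via [write_annotations()]
#' @return [annotation_set()]
#' @export
make_toy_annotations <- function(spec, dir = NULL) {
  chrom <- names(spec$chrom_lengths)[1]
  L <- spec$chrom_lengths[[1]]
  if (L < 2e6) abort_input("toy annotation recipe needs a first chromosome >= 2 Mb")
  genes <- rbind(
    toy_gene_rows("GENE_HI", chrom, 310000, n_exons = 10),
    toy_gene_rows("GENE_PLI", chrom, 550000, n_exons = 8),
    toy_gene_rows("GENE_DIS", chrom, 700000, n_exons = 6),
    toy_gene_rows("GENE_BENIGN", chrom, 850000, n_exons = 6),
    toy_gene_rows("GENE_TS", chrom, 1050000, n_exons = 6),
    toy_gene_rows("GENE_POP", chrom, 1200000, n_exons = 6),
    toy_gene_rows("GENE_NC", chrom, 1400000, n_exons = 4, coding = FALSE))
  hi_span <- range_of(genes, "GENE_HI"); ts_span <- range_of(genes, "GENE_TS")
  if (max(genes$end) > L) abort_input("toy gene recipe exceeds chromosome length")
  dosage <- data.frame(
    chrom = chrom,
    start = c(300000, hi_span[1], 1000000, ts_span[1]),
    end = c(360000, hi_span[2], 1060000, ts_span[2]),
    kind = c("region", "gene", "region", "gene"),
    symbol = c("REGION_HI_1", "GENE_HI", "REGION_TS_1", "GENE_TS"),
    hi_score = c("3", "3", NA, NA),
    ts_score = c(NA, NA, "3", "3"),
    stringsAsFactors = FALSE)
  population <- data.frame(
    chrom = chrom,
    start = c(1500000, 1500000, 1195000, 1560000),
    end = c(1540000, 1540000, 1260000, 1570000),
    sv_type = c("deletion", "duplication", "deletion", "deletion"),
    id = c("POPDEL1", "POPDUP1", "POPDEL_CDS", "POPDEL_RARE"),
    af_afr = c(0.05, 0.04, 0.05, 0.001),
    af_eur = c(0.02, 0.03, 0.02, 0.0005),
    stringsAsFactors = FALSE)
  known <- data.frame(
    chrom = chrom, start = 305000, end = 355000, sv_type = "deletion",
    id = "KNOWN_PATH_1", interpretation = "pathogenic",
    condition = "toy contiguous gene syndrome", allele_origin = "de novo",
    genes = "GENE_HI", stringsAsFactors = FALSE)
  problem <- data.frame(chrom = chrom, start = 1690000, end = 1740000,
                        label = "centromere", stringsAsFactors = FALSE)
  exons <- genes[genes$feature == "exon", , drop = FALSE]
  pext <- data.frame(
    symbol = exons$symbol, transcript_id = exons$transcript_id,
    exon_number = exons$exon_number,
    # first exons highly expressed, trailing exons less so
    pext = round(pmax(0.1, 1 - 0.05 * (exons$exon_number - 1)), 2),
    stringsAsFactors = FALSE)
  annot <- annotation_set(
    population_svs = population,
    known_svs = known,
    dosage = dosage,
    genes = genes,
    constraint = data.frame(symbol = c("GENE_HI", "GENE_TS", "GENE_PLI",
                                       "GENE_DIS", "GENE_BENIGN", "GENE_POP",
                                       "GENE_NC"),
                            pli = c(0.98, 0.2, 0.95, 0.1, 0.01, 0.3, 0.5)),
    disease = data.frame(symbol = c("GENE_HI", "GENE_DIS", "GENE_NC"),
                         source = c("OMIM", "OMIM", "GenCC"),
                         condition = c("toy syndrome A", "toy syndrome B",
                                       "toy non-coding disorder")),
    pext = pext,
    internal_cohort = spec$family,
    problem_regions = problem,
    noncoding_exception_genes = "GENE_NC")
  if (!is.null(dir)) write_annotations(annot, dir)
  annot
}

range_of <- function(genes, symbol) {
  g <- genes[genes$symbol == symbol & genes$feature == "gene", ]
  c(g$start[1], g$end[1])
}

#' The standard end-to-end demonstration fixture
#'
#' One sample with six engineered CNVs on a 1-Mb toy chromosome, arranged so
#' filtration removes exactly one call per step: a heterozygous deletion
#' fully containing the curated HI region (the pathogenic-like finding, with
#' discordant-pair and split-read support), a benign-gene deletion, a
#' duplication partially overlapping the TS region, a deletion fully
#' contained in a common population variant (filtration step 3), a fully
#' intronic deletion (step 2), and a deletion inside the problem region
#' (step 1).
#'
#' @param seed RNG seed
#' @param mean_depth background coverage
#' @return [fixture_spec()]
#' @export
default_fixture_spec <- function(seed = 1, mean_depth = 30) {
  fixture_spec(
    seed = seed,
    chrom_lengths = c(chrT = 2e6),
    mean_depth = mean_depth,
    read_length = 150,
    insert_mean = 400,
    insert_sd = 50,
    cnvs = data.frame(
      chrom = "chrT",
      start = c(280000, 850000, 1040000, 1200000, 700300, 1700000),
      end = c(380000, 852000, 1052000, 1202000, 700800, 1710000),
      type = c("deletion", "deletion", "duplication", "deletion",
               "deletion", "deletion"),
      zygosity = "het",
      n_discordant_pairs = c(12L, 4L, 8L, 0L, 0L, 0L),
      n_split_reads = c(4L, 2L, 0L, 0L, 0L, 0L),
      stringsAsFactors = FALSE)
  )
}
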