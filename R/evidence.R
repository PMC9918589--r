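#' Per-side flanking window width for evidence extraction
#'
#' Half the variant size, with a 100-kb minimum, on each side (the window
#' itself is clamped to chromosome bounds when alignments are fetched).
#'
#' @param cnv_length CNV length in bp (or a one-row [cnv_calls()])
#' @param config [default_config()] (keys flank_fraction, flank_min_bp)
#' @return flank width in bp (per side)
#' @export
#' @examples
#' compute_flanks(40e3)   # 100000
#' compute_flanks(1e6)    # 500000
compute_flanks <- function(cnv_length, config = default_config()) {
  if (is.data.frame(cnv_length) || is.list(cnv_length))
    cnv_length <- cnv_length$end - cnv_length$start
  max(config$flank_fraction * cnv_length, config$flank_min_bp)
}

## -- BAM access helpers ------------------------------------------------------

depth_flags <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                         isDuplicate = FALSE, isNotPassingQualityControls = FALSE,
                         isSupplementaryAlignment = FALSE)
}

bam_chrom_length <- function(bam, chrom) {
  tg <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  len <- tg[match(chrom, names(tg))]
  if (is.na(len)) len <- tg[match(norm_chrom(chrom), norm_chrom(names(tg)))]
  if (is.na(len)) abort_input("chromosome ", chrom, " not in BAM header")
  unname(len)
}

check_bam_index <- function(bam) {
  if (!file.exists(bam)) abort_input("alignment file not found: ", bam)
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam),
           paste0(bam, ".csi"))
  if (!any(file.exists(idx)))
    abort_input("no index found for ", bam,
                "; create one with Rsamtools::indexBam() or `samtools index`")
  invisible(bam)
}

# window: 0-based half-open; returns GAlignments of depth-policy reads
read_window_alignments <- function(bam, chrom, start, end) {
  check_bam_index(bam)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  param <- Rsamtools::ScanBamParam(flag = depth_flags(), which = which,
                                   what = "mapq")
  GenomicAlignments::readGAlignments(bam, param = param)
}

# per-base depth over [start, end) as an integer vector
window_depth_vector <- function(gal, chrom, start, end) {
  if (!length(gal)) return(integer(end - start))
  cov <- GenomicAlignments::coverage(gal)[[as.character(chrom)]]
  n <- end - start
  out <- integer(n)
  lo <- start + 1; hi <- min(end, length(cov))
  if (hi >= lo) out[seq_len(hi - lo + 1)] <- as.integer(cov[lo:hi])
  out
}

#' Binned read depth and mapping quality across a window
#'
#' Splits `[start, end)` into `n_bins` near-equal bins and reports per-bin
#' mean depth (per-base coverage of reads passing the depth policy: mapped,
#' primary, non-duplicate, QC-pass) and mean mapping quality of overlapping
#' reads. Bins without reads report depth 0 and MQ `NA`.
#'
#' @param bam indexed BAM path
#' @param chrom,start,end window, 0-based half-open
#' @param n_bins number of bins (>= 1)
#' @return data.frame: bin, start, end, depth, mq
#' @export
binned_depth_mq <- function(bam, chrom, start, end,
                            n_bins = default_config()$n_bins) {
  if (n_bins < 1) abort_input("n_bins must be >= 1")
  gal <- read_window_alignments(bam, chrom, start, end)
  edges <- round(seq(start, end, length.out = n_bins + 1))
  bins <- data.frame(bin = seq_len(n_bins),
                     start = edges[-length(edges)], end = edges[-1])
  depth <- window_depth_vector(gal, chrom, start, end)
  bins$depth <- vapply(seq_len(n_bins), function(i) {
    if (bins$end[i] <= bins$start[i]) return(0)
    mean(depth[(bins$start[i] - start + 1):(bins$end[i] - start)])
  }, numeric(1))
  bins$mq <- NA_real_
  if (length(gal)) {
    r <- IRanges::IRanges(GenomicAlignments::start(gal), GenomicAlignments::end(gal))
    b <- IRanges::IRanges(bins$start + 1, bins$end)
    ov <- IRanges::findOverlaps(b, r)
    if (length(ov)) {
      mq <- S4Vectors::mcols(gal)$mapq[S4Vectors::subjectHits(ov)]
      agg <- tapply(mq, S4Vectors::queryHits(ov), mean, na.rm = TRUE)
      bins$mq[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  bins
}

#' Depth ratio and median mapping quality for a CNV
#'
#' Median per-base read depth inside the CNV divided by the median over the
#' two flanks pooled; plus the median mapping quality of reads overlapping
#' the CNV. A flank median of zero yields `depth_ratio = NA` (reported
#' absent).
#'
#' @param bam indexed BAM path
#' @param cnv one-row [cnv_calls()]
#' @param flank_bp per-side flank width ([compute_flanks()])
#' @return list(depth_ratio, median_mq_inside, median_depth_inside,
#'   median_depth_flank)
#' @export
depth_metrics <- function(bam, cnv, flank_bp = compute_flanks(cnv)) {
  cnv <- as.data.frame(cnv)[1, , drop = FALSE]
  clen <- bam_chrom_length(bam, cnv$chrom)
  w_start <- max(0, cnv$start - flank_bp)
  w_end <- min(clen, cnv$end + flank_bp)
  gal <- read_window_alignments(bam, cnv$chrom, w_start, w_end)
  depth <- window_depth_vector(gal, cnv$chrom, w_start, w_end)
  idx_in <- (cnv$start - w_start + 1):(cnv$end - w_start)
  inside <- depth[idx_in]
  flank <- depth[-idx_in]
  med_in <- median(inside)
  med_fl <- median(flank)
  mq_in <- {
    r <- IRanges::IRanges(GenomicAlignments::start(gal), GenomicAlignments::end(gal))
    hit <- IRanges::overlapsAny(r, IRanges::IRanges(cnv$start + 1, cnv$end))
    v <- S4Vectors::mcols(gal)$mapq[hit]
    if (length(v)) median(v, na.rm = TRUE) else NA_real_
  }
  list(depth_ratio = if (med_fl > 0) med_in / med_fl else NA_real_,
       median_mq_inside = mq_in,
       median_depth_inside = med_in,
       median_depth_flank = med_fl)
}

#' Insert-size outlier bounds from a vector of insert sizes
#'
#' Empirical percentiles (default 0.5 and 99.5) of absolute template
#' lengths; read pairs outside these bounds are insert-size outliers.
#'
#' @param isizes numeric vector of (absolute) insert sizes
#' @param lower_pct,upper_pct percentiles in \[0, 100\]
#' @return list(lower, upper, lower_pct, upper_pct, n)
#' @export
#' @examples
#' insert_size_bounds(rep(400, 10))$upper  # 400
insert_size_bounds <- function(isizes,
                               lower_pct = default_config()$insert_lower_pct,
                               upper_pct = default_config()$insert_upper_pct) {
  isizes <- abs(isizes[!is.na(isizes) & isizes != 0])
  if (!length(isizes)) abort_input("no insert sizes supplied")
  q <- quantile(isizes, probs = c(lower_pct, upper_pct) / 100, names = FALSE)
  list(lower = q[1], upper = q[2], lower_pct = lower_pct,
       upper_pct = upper_pct, n = length(isizes))
}

#' Estimate insert-size outlier bounds from a BAM window
#'
#' Uses absolute template lengths of inward-oriented (proper-orientation)
#' pairs in the window. If fewer than `min_pairs` are found, falls back to a
#' genome-wide sample of up to `fallback_sample` pairs; still too few is a
#' fatal error (the library's insert distribution cannot be estimated).
#'
#' @param bam indexed BAM path
#' @param chrom,start,end window, 0-based half-open
#' @param lower_pct,upper_pct percentiles (defaults 0.5 / 99.5)
#' @param min_pairs minimum window pairs before falling back
#' @param fallback_sample genome-wide cap
#' @return [insert_size_bounds()] result
#' @export
estimate_insert_bounds <- function(bam, chrom, start, end,
                                   lower_pct = default_config()$insert_lower_pct,
                                   upper_pct = default_config()$insert_upper_pct,
                                   min_pairs = default_config()$min_insert_pairs,
                                   fallback_sample = default_config()$insert_fallback_sample) {
  iz <- window_inward_isizes(bam, chrom, start, end)
  if (length(iz) < min_pairs) {
    clen <- bam_chrom_length(bam, chrom)
    iz <- window_inward_isizes(bam, chrom, 0, clen)
    if (length(iz) > fallback_sample) iz <- iz[seq_len(fallback_sample)]
  }
  if (length(iz) < 2)
    abort_input("too few read pairs to estimate insert-size bounds; ",
                "supply a larger window or a deeper alignment file")
  insert_size_bounds(iz, lower_pct, upper_pct)
}

window_inward_isizes <- function(bam, chrom, start, end) {
  check_bam_index(bam)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
                                  isSecondaryAlignment = FALSE, isDuplicate = FALSE,
                                  isNotPassingQualityControls = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isMinusStrand = FALSE, isMateMinusStrand = TRUE),
    which = which, what = c("pos", "mpos", "isize"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$isize) & res$isize > 0 & res$pos <= res$mpos
  abs(res$isize[keep])
}

#' Classify anomalous reads in a window
#'
#' Every primary alignment with a mapped mate on the same chromosome is
#' assigned at most one category, with precedence: `split` if the read
#' carries supplementary-alignment evidence (SA tag); else `same_direction`
#' if both mates map to the same strand; else `outward` if the pair faces
#' away from each other; else `inward_insert_outlier` if the inward pair's
#' absolute insert size falls outside the bounds. Properly sized inward
#' pairs are excluded (not anomalous).
#'
#' @param bam indexed BAM path
#' @param chrom,start,end window, 0-based half-open
#' @param bounds [insert_size_bounds()] result (or list with lower/upper)
#' @return data.frame: read_name, category, start, end (0-based half-open
#'   alignment span), mate_pos, insert, strand, supports_cnv (NA until
#'   [count_supporting_reads()])
#' @export
classify_anomalous_reads <- function(bam, chrom, start, end, bounds) {
  check_bam_index(bam)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
                                  isSecondaryAlignment = FALSE, isDuplicate = FALSE,
                                  isNotPassingQualityControls = FALSE,
                                  isSupplementaryAlignment = FALSE),
    which = which,
    what = c("qname", "flag", "pos", "cigar", "mrnm", "mpos", "isize", "strand", "rname"),
    tag = "SA")
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (!n) return(empty_anomalous())
  same_chrom <- !is.na(res$mrnm) & as.character(res$mrnm) == as.character(res$rname)
  sa <- res$tag$SA
  has_sa <- if (is.null(sa)) rep(FALSE, n) else !is.na(sa) & nzchar(sa)
  strand <- as.character(res$strand)
  mate_rev <- bitwAnd(res$flag, 0x20L) != 0L
  mate_strand <- ifelse(mate_rev, "-", "+")
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  leftmost <- res$pos <= res$mpos
  inward <- ifelse(leftmost, strand == "+" & mate_strand == "-",
                   strand == "-" & mate_strand == "+")
  outlier <- !is.na(res$isize) &
    (abs(res$isize) > bounds$upper | abs(res$isize) < bounds$lower)
  category <- rep(NA_character_, n)
  category[has_sa] <- "split"
  pick <- is.na(category) & same_chrom & strand == mate_strand
  category[pick] <- "same_direction"
  pick <- is.na(category) & same_chrom & !inward & strand != mate_strand
  category[pick] <- "outward"
  pick <- is.na(category) & same_chrom & inward & outlier
  category[pick] <- "inward_insert_outlier"
  keep <- !is.na(category)
  if (!any(keep)) return(empty_anomalous())
  data.frame(read_name = res$qname[keep],
             category = category[keep],
             start = res$pos[keep] - 1,
             end = res$pos[keep] - 1 + width[keep],
             mate_pos = res$mpos[keep] - 1,
             insert = res$isize[keep],
             strand = strand[keep],
             supports_cnv = rep(NA, sum(keep)),
             stringsAsFactors = FALSE)
}

empty_anomalous <- function() {
  data.frame(read_name = character(0), category = character(0),
              start = numeric(0), end = numeric(0), mate_pos = numeric(0),
              insert = numeric(0), strand = character(0), supports_cnv = logical(0))
}

#' Count anomalous reads whose geometry supports the CNV
#'
#' Type-consistent support: for a deletion, inward pairs with insert size
#' above the upper bound whose left-read end and right-read start lie within
#' `tolerance_bp` of the two breakpoints, plus split reads aligned within
#' `tolerance_bp` of either breakpoint; for a duplication, outward pairs
#' whose reads lie within `tolerance_bp` of the breakpoints, plus split
#' reads. Pairs are counted once (by read name). Sets the `supports_cnv`
#' flag on the returned classification table.
#'
#' @param anomalous [classify_anomalous_reads()] result
#' @param cnv one-row [cnv_calls()]
#' @param tolerance_bp breakpoint tolerance in bp (default 1000; read-depth
#'   callers have imprecise edges)
#' @param bounds insert-size bounds used for the large-insert test
#' @return list(count = integer, anomalous = flagged data.frame)
#' @export
count_supporting_reads <- function(anomalous, cnv,
                                   tolerance_bp = default_config()$support_tolerance_bp,
                                   bounds = list(upper = Inf)) {
  cnv <- as.data.frame(cnv)[1, , drop = FALSE]
  a <- anomalous
  if (!nrow(a)) return(list(count = 0L, anomalous = a))
  bk1 <- cnv$start; bk2 <- cnv$end
  pair_left <- pmin(a$start, a$mate_pos)
  is_left <- a$start <= a$mate_pos
  supports <- rep(FALSE, nrow(a))
  near <- function(x, bk) abs(x - bk) <= tolerance_bp
  split_near <- a$category == "split" &
    (pmin(abs(a$start - bk1), abs(a$end - bk1),
          abs(a$start - bk2), abs(a$end - bk2)) <= tolerance_bp)
  if (cnv$type == "deletion") {
    big <- a$category == "inward_insert_outlier" & abs(a$insert) > bounds$upper
    # left read's end near the left breakpoint, mate start near the right one
    str_left <- big & is_left & near(a$end, bk1) & near(a$mate_pos, bk2)
    str_right <- big & !is_left & near(a$start, bk2) & near(a$mate_pos + (a$end - a$start), bk1)
    supports <- str_left | str_right | split_near
  } else {
    outw <- a$category == "outward"
    str_left <- outw & is_left & near(a$start, bk1) & near(a$mate_pos, bk2)
    str_right <- outw & !is_left & near(a$end, bk2) & near(pair_left, bk1)
    supports <- str_left | str_right | split_near
  }
  a$supports_cnv <- supports
  list(count = length(unique(a$read_name[supports])), anomalous = a)
}

#' Composite quality score (guidance only)
#'
#' Product of three terms, each in \[0, 1\]: a depth-consistency term that
#' peaks at the expected heterozygous ratio (0.5 for deletions, 1.5 for
#' duplications) and falls to 0 at ratio 1 (no depth change); a mapping
#' quality term saturating at `mq_saturation` (default 40); and a
#' read-support term saturating at `support_saturation` supporting reads
#' (default 5). Monotone non-decreasing in MQ and support count; `NA` when
#' the depth ratio is unavailable.
#'
#' @param depth_ratio inside/flank median depth ratio
#' @param median_mq_inside median mapping quality inside the CNV
#' @param supporting_read_count [count_supporting_reads()] count
#' @param cnv_type "deletion" or "duplication"
#' @param config [default_config()]
#' @return numeric in \[0, 1\] (or NA)
#' @export
#' @examples
#' quality_score(0.5, 60, 10, "deletion")  # 1
#' quality_score(1.0, 60, 10, "deletion")  # 0
quality_score <- function(depth_ratio, median_mq_inside, supporting_read_count,
                          cnv_type, config = default_config()) {
  if (is.na(depth_ratio)) return(NA_real_)
  depth_term <- if (cnv_type == "deletion") {
    min(1, max(0, (1 - depth_ratio) / 0.4))   # 1 at ratio <= 0.6, 0 at ratio >= 1
  } else {
    min(1, max(0, (depth_ratio - 1) / 0.4))   # 1 at ratio >= 1.4, 0 at ratio <= 1
  }
  mq_term <- if (is.na(median_mq_inside)) 0 else
    min(1, median_mq_inside / config$mq_saturation)
  support_term <- min(1, supporting_read_count / config$support_saturation)
  depth_term * mq_term * support_term
}

#' Flag bins where the reference sample shows spurious depth changes
#'
#' Regions with systematic mapping artifacts show depth deviations in any
#' sample, including a reference control. Bins where the *reference*
#' deviates from its own flank baseline by more than `deviation_threshold`
#' (fractionally) are flagged so matching dips/rises in the clinical sample
#' can be discounted. Both samples must be binned on the identical grid.
#'
#' @param sample_bins,reference_bins [binned_depth_mq()] tables on the same
#'   grid
#' @param deviation_threshold fractional deviation from baseline (default
#'   0.25)
#' @param cnv optional one-row [cnv_calls()]; when given, the baseline is the
#'   median reference depth over bins outside the CNV
#' @return integer vector of flagged bin indices
#' @export
compare_reference_sample <- function(sample_bins, reference_bins,
                                     deviation_threshold = default_config()$reference_deviation,
                                     cnv = NULL) {
  if (nrow(sample_bins) != nrow(reference_bins) ||
      any(sample_bins$start != reference_bins$start) ||
      any(sample_bins$end != reference_bins$end))
    abort_input("sample and reference bins are on different grids")
  ref <- reference_bins$depth
  outside <- rep(TRUE, nrow(reference_bins))
  if (!is.null(cnv)) {
    cnv <- as.data.frame(cnv)[1, , drop = FALSE]
    outside <- reference_bins$end <= cnv$start | reference_bins$start >= cnv$end
  }
  base <- median(ref[outside])
  if (base <= 0) return(integer(0))
  which(abs(ref - base) / base > deviation_threshold)
}

#' Extract the full alignment-evidence profile for one CNV
#'
#' Orchestrates the evidence computations: flank sizing, binned depth/MQ
#' across the CNV-plus-flanks window, depth ratio and median MQ, insert-size
#' outlier bounds, anomalous-read classification, type-consistent
#' supporting-read count, the composite quality score, and (when a reference
#' control BAM is given) reference-flagged bins.
#'
#' @param bam indexed BAM for the proband
#' @param cnv one-row [cnv_calls()]
#' @param config [default_config()]
#' @param ref_bam optional indexed BAM of a reference control sample
#' @return list with class `evidence_profile`: cnv, flank_bp, window
#'   (chrom/start/end), bins, depth_ratio, median_mq_inside, insert_bounds,
#'   anomalous_reads, supporting_read_count, quality_score,
#'   reference_flagged_bins
#' @export
extract_evidence <- function(bam, cnv, config = default_config(),
                             ref_bam = NULL) {
  cnv <- as.data.frame(cnv)[1, , drop = FALSE]
  flank <- compute_flanks(cnv, config)
  clen <- bam_chrom_length(bam, cnv$chrom)
  w_start <- max(0, cnv$start - flank)
  w_end <- min(clen, cnv$end + flank)
  bins <- binned_depth_mq(bam, cnv$chrom, w_start, w_end, config$n_bins)
  dm <- depth_metrics(bam, cnv, flank)
  bounds <- estimate_insert_bounds(bam, cnv$chrom, w_start, w_end,
                                   config$insert_lower_pct,
                                   config$insert_upper_pct,
                                   config$min_insert_pairs,
                                   config$insert_fallback_sample)
  anom <- classify_anomalous_reads(bam, cnv$chrom, w_start, w_end, bounds)
  sup <- count_supporting_reads(anom, cnv, config$support_tolerance_bp, bounds)
  ref_flagged <- integer(0)
  if (!is.null(ref_bam)) {
    ref_bins <- binned_depth_mq(ref_bam, cnv$chrom, w_start, w_end, config$n_bins)
    ref_flagged <- compare_reference_sample(bins, ref_bins,
                                            config$reference_deviation, cnv)
  }
  res <- list(
    cnv = cnv,
    flank_bp = flank,
    window = list(chrom = cnv$chrom, start = w_start, end = w_end),
    bins = bins,
    depth_ratio = dm$depth_ratio,
    median_mq_inside = dm$median_mq_inside,
    insert_bounds = bounds,
    anomalous_reads = sup$anomalous,
    supporting_read_count = sup$count,
    quality_score = quality_score(dm$depth_ratio, dm$median_mq_inside,
                                  sup$count, cnv$type, config),
    reference_flagged_bins = ref_flagged
  )
  class(res) <- "evidence_profile"
  res
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat(sprintf("evidence_profile: %s %s:%s-%s\n", x$cnv$type, x$cnv$chrom,
              format(x$cnv$start, scientific = FALSE),
              format(x$cnv$end, scientific = FALSE)))
  cat(sprintf("  flank %s bp | depth ratio %.3f | median MQ %.1f | supports %d | quality %.2f\n",
              format(x$flank_bp, scientific = FALSE),
              x$depth_ratio, x$median_mq_inside, x$supporting_read_count,
              x$quality_score))
  invisible(x)
}

#' Static depth/MQ and anomalous-read panel for one CNV
#'
#' Writes a two-panel PNG: binned depth (with CNV breakpoints and reference
#' flags) over mapping quality, and anomalous reads coloured by category
#' (inward insert outlier red, outward blue, same direction cyan, split
#' purple).
#'
#' @param evidence [extract_evidence()] result
#' @param file output PNG path
#' @return `file`, invisibly
#' @export
plot_evidence <- function(evidence, file) {
  grDevices::png(file, width = 1200, height = 800, res = 120)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  b <- evidence$bins
  mid <- (b$start + b$end) / 2
  graphics::plot(mid, b$depth, type = "h", col = "grey40",
                 xlab = evidence$window$chrom, ylab = "mean depth",
                 main = sprintf("%s %s:%d-%d", evidence$cnv$type,
                                evidence$cnv$chrom, evidence$cnv$start,
                                evidence$cnv$end))
  graphics::abline(v = c(evidence$cnv$start, evidence$cnv$end), col = "red", lty = 2)
  if (length(evidence$reference_flagged_bins))
    graphics::points(mid[evidence$reference_flagged_bins],
                     b$depth[evidence$reference_flagged_bins],
                     col = "orange", pch = 4)
  a <- evidence$anomalous_reads
  cols <- c(inward_insert_outlier = "red", outward = "blue",
            same_direction = "cyan3", split = "purple")
  graphics::plot(NA, xlim = c(evidence$window$start, evidence$window$end),
                 ylim = c(0, max(4, nrow(a))), xlab = evidence$window$chrom,
                 ylab = "anomalous reads", main = "anomalous reads")
  if (nrow(a)) {
    graphics::segments(a$start, seq_len(nrow(a)), pmax(a$end, a$mate_pos),
                       seq_len(nrow(a)), col = cols[a$category])
  }
  graphics::abline(v = c(evidence$cnv$start, evidence$cnv$end), col = "red", lty = 2)
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2, cex = 0.7)
  invisible(file)
}
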