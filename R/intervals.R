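#' Interval arithmetic on 0-based half-open genomic intervals
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' an interval covers bases `start .. end-1` and has length `end - start`.
#' VCF input is converted on ingest. These primitives are vectorized and
#' recycle their arguments.
#'
#' @name interval-arithmetic
NULL

#' Shared bases between two intervals
#'
#' @param chrom1,start1,end1 first interval(s)
#' @param chrom2,start2,end2 second interval(s)
#' @return integer-valued numeric vector of overlapping base counts (0 when
#'   the chromosomes differ after [norm_chrom()] normalization)
#' @export
#' @examples
#' overlap_bp("chr1", 0, 100, "1", 50, 150)  # 50
overlap_bp <- function(chrom1, start1, end1, chrom2, start2, end2) {
  same <- norm_chrom(chrom1) == norm_chrom(chrom2)
  sh <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  ifelse(same, sh, 0)
}

#' Reciprocal overlap of two intervals
#'
#' `min(shared/length(a), shared/length(b))` — the symmetric similarity used
#' throughout structural-variant comparison (e.g. the conventional "50%
#' reciprocal overlap" caller-concordance rule).
#'
#' @param chrom1,start1,end1 interval(s) a
#' @param chrom2,start2,end2 interval(s) b
#' @return numeric in \[0, 1\]
#' @export
#' @examples
#' reciprocal_overlap("1", 0, 100, "1", 50, 150)  # 0.5
reciprocal_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  sh <- overlap_bp(chrom1, start1, end1, chrom2, start2, end2)
  pmin(sh / (end1 - start1), sh / (end2 - start2))
}

#' Fraction of an inner interval contained in an outer interval
#'
#' `shared bases / length(inner)`; equals 1 iff `inner` is a subset of
#' `outer`.
#'
#' @param chrom_in,start_in,end_in inner interval(s)
#' @param chrom_out,start_out,end_out outer interval(s)
#' @return numeric in \[0, 1\]
#' @export
#' @examples
#' containment_fraction("1", 10, 20, "1", 0, 100)  # 1
containment_fraction <- function(chrom_in, start_in, end_in,
                                 chrom_out, start_out, end_out) {
  sh <- overlap_bp(chrom_in, start_in, end_in, chrom_out, start_out, end_out)
  sh / (end_in - start_in)
}

#' Fraction of an interval covered by the union of a set of intervals
#'
#' Computed against the merged union (via [IRanges::reduce()]), so an
#' interval straddling two abutting records still counts as fully covered.
#'
#' @param chrom,start,end query interval (scalar)
#' @param regions data.frame with columns chrom, start, end
#' @return scalar numeric in \[0, 1\]
#' @export
union_cover_fraction <- function(chrom, start, end, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(0)
  keep <- norm_chrom(regions$chrom) == norm_chrom(chrom)
  if (!any(keep)) return(0)
  # shift to 1-based closed for IRanges; widths are preserved
  red <- IRanges::reduce(IRanges::IRanges(regions$start[keep] + 1, regions$end[keep]))
  hit <- IRanges::restrict(red, start = start + 1, end = end)
  sum(IRanges::width(hit)) / (end - start)
}
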