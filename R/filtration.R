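#' Three-step variant filtration
#'
#' Reduces a raw CNV call list to review candidates:
#' step 1 removes calls fully contained in problem regions (assembly gaps,
#' centromeres, repeats, recurrence regions); step 2 retains calls that
#' overlap at least 1 bp of coding sequence (any transcript) or overlap a
#' gene on the non-coding exception list, removing the rest; step 3 removes
#' calls fully contained in a same-type population SV carrying any
#' per-population allele frequency strictly above the threshold (default 1%).
#'
#' @name filtration
NULL

#' Step 1: problem-region containment
#'
#' A call is removed iff it is fully contained in problem regions. By
#' default containment is tested against the merged union of all records, so
#' a call straddling two abutting repeats still counts as contained; set
#' `mode = "per_record"` to require containment within a single record.
#'
#' @param calls [cnv_calls()]
#' @param annotation [annotation_set()]
#' @param mode "union" or "per_record"
#' @return list(retained = cnv_calls, removed = cnv_calls, reason = character)
#' @export
filter_problem_regions <- function(calls, annotation,
                                   mode = default_config()$problem_region_mode) {
  pr <- annotation$problem_regions
  n <- nrow(calls)
  if (!n || is.null(pr) || !nrow(pr)) {
    return(list(retained = calls, removed = calls[integer(0), ],
                reason = character(0)))
  }
  contained <- vapply(seq_len(n), function(i) {
    if (mode == "union") {
      union_cover_fraction(calls$chrom[i], calls$start[i], calls$end[i], pr) >= 1
    } else {
      any(containment_fraction(calls$chrom[i], calls$start[i], calls$end[i],
                               pr$chrom, pr$start, pr$end) >= 1)
    }
  }, logical(1))
  split_partition(calls, contained, "problem-region containment")
}

#' Step 2: coding overlap retention
#'
#' Retained iff the call overlaps >= 1 bp of any CDS interval of any
#' transcript, or overlaps the gene span (exons and introns) of a gene on the
#' non-coding exception list. Everything else is removed with reason
#' "non-coding".
#'
#' @inheritParams filter_problem_regions
#' @return list(retained, removed, reason)
#' @export
filter_coding_overlap <- function(calls, annotation) {
  gm <- annotation$genes
  n <- nrow(calls)
  if (!n) return(list(retained = calls, removed = calls[integer(0), ],
                      reason = character(0)))
  cds <- gm[gm$feature == "CDS", , drop = FALSE]
  exc <- gm[gm$feature == "gene" &
              gm$symbol %in% annotation$noncoding_exception_genes, , drop = FALSE]
  keep <- vapply(seq_len(n), function(i) {
    hits_cds <- nrow(cds) > 0 &&
      any(overlap_bp(calls$chrom[i], calls$start[i], calls$end[i],
                     cds$chrom, cds$start, cds$end) > 0)
    hits_exc <- nrow(exc) > 0 &&
      any(overlap_bp(calls$chrom[i], calls$start[i], calls$end[i],
                     exc$chrom, exc$start, exc$end) > 0)
    hits_cds || hits_exc
  }, logical(1))
  split_partition(calls, !keep, "non-coding")
}

#' Step 3: population-variant containment
#'
#' Removed iff there exists a population SV of the same type, with any
#' per-population frequency strictly greater than `af_threshold`, that fully
#' contains the call.
#'
#' @inheritParams filter_problem_regions
#' @param af_threshold allele-frequency cutoff (strict inequality; default 0.01)
#' @return list(retained, removed, reason)
#' @export
filter_population_contained <- function(calls, annotation,
                                        af_threshold = default_config()$af_threshold) {
  pop <- annotation$population_svs
  n <- nrow(calls)
  if (!n || is.null(pop) || !nrow(pop)) {
    return(list(retained = calls, removed = calls[integer(0), ],
                reason = character(0)))
  }
  common <- pop[!is.na(pop$popmax_af) & pop$popmax_af > af_threshold, , drop = FALSE]
  removed <- vapply(seq_len(n), function(i) {
    same <- common[common$sv_type == calls$type[i], , drop = FALSE]
    nrow(same) > 0 &&
      any(containment_fraction(calls$chrom[i], calls$start[i], calls$end[i],
                               same$chrom, same$start, same$end) >= 1)
  }, logical(1))
  split_partition(calls, removed, "population-variant containment")
}

split_partition <- function(calls, removed_mask, reason) {
  list(retained = calls[!removed_mask, , drop = FALSE],
       removed = calls[removed_mask, , drop = FALSE],
       reason = rep(reason, sum(removed_mask)))
}

#' Run the full three-step filtration
#'
#' Steps are applied in order 1 -> 2 -> 3. The result records the survivors
#' (input order preserved), every removed call with its step and reason, and
#' the per-step remaining counts. With `config$skip_filtration = TRUE` all
#' calls survive (for users who perform their own filtering and start at
#' prioritization).
#'
#' @param calls [cnv_calls()]
#' @param annotation [annotation_set()]
#' @param config [default_config()]
#' @return list with class `filtration_result`: `survivors` (cnv_calls),
#'   `removed` (data.frame of calls plus step/reason columns),
#'   `per_step_counts` (named vector: input, after_step1..3)
#' @export
run_filtration <- function(calls, annotation, config = default_config()) {
  n0 <- nrow(calls)
  if (isTRUE(config$skip_filtration)) {
    res <- list(survivors = calls,
                removed = cbind(calls[integer(0), ],
                                step = integer(0), reason = character(0)),
                per_step_counts = c(input = n0, after_step1 = n0,
                                    after_step2 = n0, after_step3 = n0))
    class(res) <- "filtration_result"
    return(res)
  }
  removed <- list()
  s1 <- filter_problem_regions(calls, annotation, config$problem_region_mode)
  if (nrow(s1$removed)) removed$s1 <- cbind(as.data.frame(s1$removed),
                                            step = 1L, reason = s1$reason)
  s2 <- filter_coding_overlap(s1$retained, annotation)
  if (nrow(s2$removed)) removed$s2 <- cbind(as.data.frame(s2$removed),
                                            step = 2L, reason = s2$reason)
  s3 <- filter_population_contained(s2$retained, annotation, config$af_threshold)
  if (nrow(s3$removed)) removed$s3 <- cbind(as.data.frame(s3$removed),
                                            step = 3L, reason = s3$reason)
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    cbind(as.data.frame(calls[integer(0), ]), step = integer(0), reason = character(0))
  rownames(removed_df) <- NULL
  res <- list(
    survivors = s3$retained,
    removed = removed_df,
    per_step_counts = c(input = n0,
                        after_step1 = nrow(s1$retained),
                        after_step2 = nrow(s2$retained),
                        after_step3 = nrow(s3$retained))
  )
  class(res) <- "filtration_result"
  res
}

#' @export
print.filtration_result <- function(x, ...) {
  cat("filtration_result:\n")
  cat("  ", paste(sprintf("%s=%d", names(x$per_step_counts), x$per_step_counts),
                  collapse = " -> "), "\n")
  invisible(x)
}
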