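#' Match a proband CNV against family members' CNV lists
#'
#' Same-type calls from family members (relations mother/father/sibling in
#' the internal-cohort table) whose reciprocal overlap with the proband CNV
#' is at least `min_reciprocal`, sorted by overlap descending. Overlapping
#' parental calls that miss the reciprocal threshold but are highly
#' contained (either direction) are returned separately as size-discordant
#' candidates — under-called parental variants should not silently produce a
#' de novo label.
#'
#' @param cnv one-row [cnv_calls()] for the proband
#' @param internal_cohort cohort table (see [annotation_set()])
#' @param family_id family to match within
#' @param min_reciprocal reciprocal-overlap threshold (default 0.5)
#' @param containment_flag containment above which a sub-threshold parental
#'   overlap is flagged size-discordant (default 0.9)
#' @return list(matches = data.frame(relation, sample_id, chrom, start, end,
#'   type, reciprocal), size_discordant = data.frame like matches plus
#'   containment)
#' @export
match_family_cnvs <- function(cnv, internal_cohort, family_id,
                              min_reciprocal = default_config()$family_min_reciprocal,
                              containment_flag = default_config()$family_containment_flag) {
  cnv <- as.data.frame(cnv)[1, , drop = FALSE]
  empty <- data.frame(relation = character(0), sample_id = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0),
                      type = character(0), reciprocal = numeric(0))
  emptyd <- cbind(empty, containment = numeric(0))
  if (is.null(internal_cohort) || !nrow(internal_cohort))
    return(list(matches = empty, size_discordant = emptyd))
  fam <- internal_cohort[internal_cohort$family_id == family_id &
                           internal_cohort$relation %in% c("mother", "father", "sibling"), ,
                         drop = FALSE]
  if (!nrow(fam)) {
    if (!family_id %in% internal_cohort$family_id)
      warning("family_id '", family_id, "' not present in the internal cohort",
              call. = FALSE)
    return(list(matches = empty, size_discordant = emptyd))
  }
  fam <- fam[fam$type == cnv$type, , drop = FALSE]
  if (!nrow(fam)) return(list(matches = empty, size_discordant = emptyd))
  ro <- reciprocal_overlap(cnv$chrom, cnv$start, cnv$end,
                           fam$chrom, fam$start, fam$end)
  cont <- pmax(
    containment_fraction(cnv$chrom, cnv$start, cnv$end,
                         fam$chrom, fam$start, fam$end),
    containment_fraction(fam$chrom, fam$start, fam$end,
                         cnv$chrom, cnv$start, cnv$end))
  mk <- function(idx, extra = NULL) {
    out <- data.frame(relation = fam$relation[idx], sample_id = fam$sample_id[idx],
                      chrom = fam$chrom[idx], start = fam$start[idx],
                      end = fam$end[idx], type = fam$type[idx],
                      reciprocal = ro[idx], stringsAsFactors = FALSE)
    if (!is.null(extra)) out$containment <- extra[idx]
    out[order(-out$reciprocal), , drop = FALSE]
  }
  matches <- mk(which(ro >= min_reciprocal))
  disc <- mk(which(ro < min_reciprocal & cont >= containment_flag), cont)
  rownames(matches) <- NULL; rownames(disc) <- NULL
  list(matches = matches, size_discordant = disc)
}

#' Infer the inheritance label of a proband CNV
#'
#' With a complete trio and no parental match the variant is de novo;
#' mother-only matches are maternal, father-only paternal, both
#' inherited_unspecified. Without a complete trio and no match the label is
#' unknown (de novo is only assertable when both parents were assessed).
#' Sibling matches are informational and never affect the parental label.
#' Size-discordant parental overlaps block a de novo label (the variant may
#' be an under-called inherited one): the label falls back to unknown with
#' the `possible_inherited_size_discordant` flag set.
#'
#' @param family_matches [match_family_cnvs()] result
#' @param trio_complete were both parents' CNV lists available?
#' @return list with class `inheritance_call`: label (de_novo, maternal,
#'   paternal, inherited_unspecified, unknown), matching_calls,
#'   sibling_matches, trio_complete, possible_inherited_size_discordant
#' @export
infer_inheritance <- function(family_matches, trio_complete) {
  m <- family_matches$matches
  disc <- family_matches$size_discordant
  mom <- any(m$relation == "mother")
  dad <- any(m$relation == "father")
  parental_disc <- any(disc$relation %in% c("mother", "father"))
  label <- if (mom && dad) "inherited_unspecified"
  else if (mom) "maternal"
  else if (dad) "paternal"
  else if (isTRUE(trio_complete) && !parental_disc) "de_novo"
  else "unknown"
  res <- list(label = label,
              matching_calls = m[m$relation != "sibling", , drop = FALSE],
              sibling_matches = m[m$relation == "sibling", , drop = FALSE],
              trio_complete = isTRUE(trio_complete),
              possible_inherited_size_discordant = parental_disc)
  class(res) <- "inheritance_call"
  res
}

#' @export
print.inheritance_call <- function(x, ...) {
  cat("inheritance:", x$label,
      if (x$possible_inherited_size_discordant) "(possible inherited, size-discordant)" else "",
      "\n")
  invisible(x)
}

#' Is the trio complete for a family in a cohort table?
#'
#' Inferred from the relations present among the family's rows: both a
#' mother and a father entry must exist. A parent who was sequenced but had
#' zero CNV calls is indistinguishable from an unsequenced parent in a
#' calls-only table; pass `relations_present` explicitly when pedigree
#' information is available.
#'
#' @param internal_cohort cohort table
#' @param family_id family identifier
#' @param relations_present optional explicit character vector of relations
#'   assessed for this family
#' @return logical
#' @export
trio_is_complete <- function(internal_cohort, family_id,
                             relations_present = NULL) {
  if (!is.null(relations_present))
    return(all(c("mother", "father") %in% relations_present))
  fam <- internal_cohort[internal_cohort$family_id == family_id, , drop = FALSE]
  all(c("mother", "father") %in% fam$relation)
}
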