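#' Annotate one CNV against all five annotation categories
#'
#' Produces the evidence bundle consumed by the scoring functions and the
#' report writers: (1) overlapping population SVs with reciprocal overlap,
#' containment and allele frequencies; (2) overlapping known pathogenic SVs;
#' (3) overlapping internal-cohort calls; (4) overlapping dosage-sensitivity
#' regions/genes with the containment of each region within the CNV; (5)
#' overlapping genes with full/partial overlap kind, strand, pLI, disease
#' associations, and per-transcript affected exons, CDS base counts and pext
#' ranges. Hits are ordered deterministically by position then id.
#'
#' @param cnv one-row [cnv_calls()] (or a list/row with chrom, start, end,
#'   type)
#' @param annotation [annotation_set()]
#' @param config [default_config()]
#' @return list with class `annotation_bundle`; elements `cnv`,
#'   `population_hits`, `known_sv_hits`, `internal_hits`, `dosage_hits`,
#'   `gene_impacts`, `affected_transcripts`, `problem_cover`
#' @export
annotate_cnv <- function(cnv, annotation, config = default_config()) {
  cnv <- as.data.frame(cnv)[1, , drop = FALSE]
  ch <- cnv$chrom; s <- cnv$start; e <- cnv$end
  ord <- function(df) {
    if (!nrow(df)) return(df)
    o <- order(df$start, df$end, df$id %||% seq_len(nrow(df)))
    df2 <- df[o, , drop = FALSE]; rownames(df2) <- NULL; df2
  }

  pop <- annotation$population_svs
  pop_hits <- pop[overlap_bp(ch, s, e, pop$chrom, pop$start, pop$end) > 0, , drop = FALSE]
  if (nrow(pop_hits)) {
    pop_hits$reciprocal <- reciprocal_overlap(ch, s, e, pop_hits$chrom,
                                              pop_hits$start, pop_hits$end)
    pop_hits$containment <- containment_fraction(ch, s, e, pop_hits$chrom,
                                                 pop_hits$start, pop_hits$end)
  } else { pop_hits$reciprocal <- numeric(0); pop_hits$containment <- numeric(0) }

  ks <- annotation$known_svs
  ks_hits <- ks[overlap_bp(ch, s, e, ks$chrom, ks$start, ks$end) > 0, , drop = FALSE]
  if (nrow(ks_hits)) {
    ks_hits$reciprocal <- reciprocal_overlap(ch, s, e, ks_hits$chrom,
                                             ks_hits$start, ks_hits$end)
  } else ks_hits$reciprocal <- numeric(0)

  ic <- annotation$internal_cohort
  ic_hits <- ic[overlap_bp(ch, s, e, ic$chrom, ic$start, ic$end) > 0, , drop = FALSE]
  if (nrow(ic_hits)) {
    ic_hits$reciprocal <- reciprocal_overlap(ch, s, e, ic_hits$chrom,
                                             ic_hits$start, ic_hits$end)
    o <- order(ic_hits$start, ic_hits$end, ic_hits$sample_id)
    ic_hits <- ic_hits[o, , drop = FALSE]; rownames(ic_hits) <- NULL
  } else ic_hits$reciprocal <- numeric(0)

  dos <- annotation$dosage
  dos_hits <- dos[overlap_bp(ch, s, e, dos$chrom, dos$start, dos$end) > 0, , drop = FALSE]
  if (nrow(dos_hits)) {
    # containment of the curated region/gene within the CNV
    dos_hits$containment_in_cnv <- containment_fraction(
      dos_hits$chrom, dos_hits$start, dos_hits$end, ch, s, e)
    dos_hits$overlap_bp <- overlap_bp(ch, s, e, dos_hits$chrom,
                                      dos_hits$start, dos_hits$end)
    o <- order(dos_hits$start, dos_hits$end, dos_hits$symbol)
    dos_hits <- dos_hits[o, , drop = FALSE]; rownames(dos_hits) <- NULL
  } else { dos_hits$containment_in_cnv <- numeric(0); dos_hits$overlap_bp <- numeric(0) }

  gi <- gene_impacts(cnv, annotation)

  bundle <- structure(list(
    cnv = cnv,
    population_hits = ord(pop_hits),
    known_sv_hits = ord(ks_hits),
    internal_hits = ic_hits,
    dosage_hits = dos_hits,
    gene_impacts = gi$impacts,
    affected_transcripts = gi$transcripts,
    problem_cover = union_cover_fraction(ch, s, e, annotation$problem_regions)
  ), class = "annotation_bundle")
  bundle
}

#' Gene-level and transcript-level impact of a CNV
#' @noRd
gene_impacts <- function(cnv, annotation) {
  gm <- annotation$genes
  ch <- cnv$chrom; s <- cnv$start; e <- cnv$end
  empty_imp <- data.frame(symbol = character(0), overlap_kind = character(0),
                          strand = character(0), pli = numeric(0),
                          disease = character(0), cds_bp = numeric(0))
  empty_tx <- data.frame(symbol = character(0), transcript_id = character(0),
                         is_canonical = logical(0), exons_affected = character(0),
                         n_exons_affected = integer(0), cds_bp = numeric(0),
                         pext_min = numeric(0), pext_max = numeric(0))
  if (!nrow(gm)) return(list(impacts = empty_imp, transcripts = empty_tx))
  gene_rows <- gm[gm$feature == "gene", , drop = FALSE]
  hit <- gene_rows[overlap_bp(ch, s, e, gene_rows$chrom, gene_rows$start,
                              gene_rows$end) > 0, , drop = FALSE]
  if (!nrow(hit)) return(list(impacts = empty_imp, transcripts = empty_tx))
  hit <- hit[order(hit$start, hit$end, hit$symbol), , drop = FALSE]
  imp <- list(); txs <- list()
  for (i in seq_len(nrow(hit))) {
    sym <- hit$symbol[i]
    full <- containment_fraction(hit$chrom[i], hit$start[i], hit$end[i],
                                 ch, s, e) >= 1
    pli <- annotation$constraint$pli[match(sym, annotation$constraint$symbol)]
    dis <- annotation$disease[annotation$disease$symbol == sym, , drop = FALSE]
    g <- gm[gm$symbol == sym, , drop = FALSE]
    cds_total <- 0
    for (tx in unique(g$transcript_id[g$feature == "transcript"])) {
      ex <- g[g$feature == "exon" & g$transcript_id == tx, , drop = FALSE]
      cds <- g[g$feature == "CDS" & g$transcript_id == tx, , drop = FALSE]
      ex_ov <- if (nrow(ex)) overlap_bp(ch, s, e, ex$chrom, ex$start, ex$end) else numeric(0)
      cds_ov <- if (nrow(cds)) sum(overlap_bp(ch, s, e, cds$chrom, cds$start, cds$end)) else 0
      cds_total <- max(cds_total, cds_ov)
      aff <- ex$exon_number[ex_ov > 0]
      if (length(aff) || cds_ov > 0) {
        px <- annotation$pext
        pxv <- px$pext[px$symbol == sym & px$transcript_id == tx &
                         px$exon_number %in% aff]
        txs[[length(txs) + 1]] <- data.frame(
          symbol = sym, transcript_id = tx,
          is_canonical = isTRUE(g$is_canonical[g$feature == "transcript" &
                                                 g$transcript_id == tx][1]),
          exons_affected = collapse_exon_numbers(sort(aff)),
          n_exons_affected = length(aff),
          cds_bp = cds_ov,
          pext_min = if (length(pxv)) min(pxv) else NA_real_,
          pext_max = if (length(pxv)) max(pxv) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    imp[[i]] <- data.frame(
      symbol = sym,
      overlap_kind = if (full) "full" else "partial",
      strand = hit$strand[i],
      pli = if (length(pli)) pli else NA_real_,
      disease = if (nrow(dis)) paste(paste0(dis$source, ":", dis$condition),
                                     collapse = ";") else "",
      cds_bp = cds_total, stringsAsFactors = FALSE)
  }
  list(impacts = do.call(rbind, imp),
       transcripts = if (length(txs)) do.call(rbind, txs) else empty_tx)
}

#' Collapse sorted exon numbers to a compact range string ("1-7,9")
#' @noRd
collapse_exon_numbers <- function(x) {
  if (!length(x)) return("")
  x <- sort(unique(x))
  grp <- cumsum(c(1, diff(x) != 1))
  paste(vapply(split(x, grp), function(r) {
    if (length(r) == 1) as.character(r) else paste0(min(r), "-", max(r))
  }, character(1)), collapse = ",")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cnv <- x$cnv
  cat(sprintf("annotation_bundle: %s %s:%s-%s (%s bp)\n", cnv$type, cnv$chrom,
              format(cnv$start, scientific = FALSE),
              format(cnv$end, scientific = FALSE),
              format(cnv$end - cnv$start, scientific = FALSE)))
  cat(sprintf("  population SV hits: %d | known SVs: %d | cohort: %d | dosage: %d | genes: %d\n",
              nrow(x$population_hits), nrow(x$known_sv_hits),
              nrow(x$internal_hits), nrow(x$dosage_hits), nrow(x$gene_impacts)))
  invisible(x)
}

#' Default clinical-relevance rule ladders
#'
#' A rules table mapping rule identifiers to scores, per CNV type. Lower
#' scores denote stronger clinical relevance; the score of a CNV is the
#' minimum over fired rules, or 99 (no known clinical relevance) when none
#' fires. Deletions use 1-5, duplications 1-7. The ladder is data, not code:
#' pass a modified table as `config rules` to [clinical_relevance_score()].
#'
#' @return data.frame with columns cnv_type, rule, score
#' @export
default_clinical_rules <- function() {
  rbind(
    data.frame(cnv_type = "deletion",
               rule = c("DEL_CONTAINS_HI", "DEL_PARTIAL_HI_REGION",
                        "DEL_HI_GENE_CDS", "DEL_PLI_CDS",
                        "DEL_DISEASE_CDS", "DEL_DISEASE_OTHER"),
               score = c(1, 2, 2, 3, 4, 5)),
    data.frame(cnv_type = "duplication",
               rule = c("DUP_CONTAINS_TS", "DUP_PARTIAL_TS_REGION",
                        "DUP_CONTAINS_HI_GENE", "DUP_BREAKS_CONSTRAINED",
                        "DUP_CONTAINS_PLI", "DUP_CONTAINS_DISEASE",
                        "DUP_DISEASE_OTHER"),
               score = c(1, 2, 3, 4, 5, 6, 7))
  )
}

#' Clinical-relevance score of an annotated CNV
#'
#' Evaluates the rule ladder ([default_clinical_rules()]) against the bundle
#' and returns the lowest (best) score among fired rules, or 99 when no rule
#' fires. Deletion rules: 1 = fully contains a curated HI region/gene; 2 =
#' partially overlaps a curated HI region or deletes >= 1 CDS bp of a curated
#' HI gene; 3 = deletes CDS of a pLI-constrained gene; 4 = deletes CDS of an
#' OMIM/GenCC disease gene; 5 = any other overlap of a disease gene.
#' Duplication rules: 1 = fully contains a curated TS region/gene; 2 =
#' partially overlaps a TS region; 3 = fully contains an HI-curated gene
#' (whole-gene duplication); 4 = breaks an HI or pLI-constrained gene; 5 =
#' fully contains a pLI-constrained gene; 6 = fully contains a disease gene;
#' 7 = any other overlap of a disease gene.
#'
#' Known-pathogenic-SV and internal-cohort hits are reported as annotations
#' only and do not move the score.
#'
#' @param bundle [annotate_cnv()] result
#' @param config [default_config()]; `config$rules` may carry a modified
#'   rules table
#' @return list(score = integer, triggered_rules = character)
#' @export
clinical_relevance_score <- function(bundle, config = default_config()) {
  type <- bundle$cnv$type
  if (!type %in% c("deletion", "duplication"))
    abort_input("unknown CNV type: ", type)
  fired <- clinical_predicates(bundle, config)
  rules <- config$rules %||% default_clinical_rules()
  rules <- rules[rules$cnv_type == type & rules$rule %in% fired, , drop = FALSE]
  if (!nrow(rules)) return(list(score = 99L, triggered_rules = character(0)))
  list(score = as.integer(min(rules$score)),
       triggered_rules = rules$rule[order(rules$score)])
}

clinical_predicates <- function(bundle, config) {
  type <- bundle$cnv$type
  dos <- bundle$dosage_hits
  gi <- bundle$gene_impacts
  pli_cut <- config$pli_cutoff
  hi <- dos[!is.na(dos$hi_score), , drop = FALSE]
  ts <- dos[!is.na(dos$ts_score), , drop = FALSE]
  has_dis <- nrow(gi) > 0 & nzchar(gi$disease %||% character(0))
  constrained <- nrow(gi) > 0 & !is.na(gi$pli) & gi$pli >= pli_cut
  # HI-curated gene symbols among gene impacts (via dosage gene entries)
  hi_gene_syms <- hi$symbol[hi$kind == "gene"]
  fired <- character(0)
  hit <- function(x) isTRUE(any(x))
  if (type == "deletion") {
    if (hit(hi$containment_in_cnv >= 1)) fired <- c(fired, "DEL_CONTAINS_HI")
    if (hit(hi$kind == "region" & hi$overlap_bp > 0)) fired <- c(fired, "DEL_PARTIAL_HI_REGION")
    # deletes >= 1 CDS bp of a curated HI gene; falls back to interval overlap
    # when no gene model exists for that symbol
    hi_genes <- hi[hi$kind == "gene", , drop = FALSE]
    if (nrow(hi_genes)) {
      cds_hit <- vapply(hi_genes$symbol, function(sym) {
        j <- match(sym, gi$symbol)
        if (!is.na(j)) gi$cds_bp[j] > 0 else TRUE  # no model: overlap suffices
      }, logical(1))
      if (any(cds_hit)) fired <- c(fired, "DEL_HI_GENE_CDS")
    }
    if (hit(constrained & gi$cds_bp > 0)) fired <- c(fired, "DEL_PLI_CDS")
    if (hit(has_dis & gi$cds_bp > 0)) fired <- c(fired, "DEL_DISEASE_CDS")
    if (hit(has_dis)) fired <- c(fired, "DEL_DISEASE_OTHER")
  } else {
    if (hit(ts$containment_in_cnv >= 1)) fired <- c(fired, "DUP_CONTAINS_TS")
    if (hit(ts$kind == "region" & ts$overlap_bp > 0)) fired <- c(fired, "DUP_PARTIAL_TS_REGION")
    full_gene <- nrow(gi) > 0 & gi$overlap_kind == "full"
    partial_gene <- nrow(gi) > 0 & gi$overlap_kind == "partial"
    hi_curated <- nrow(gi) > 0 & gi$symbol %in% hi_gene_syms
    if (hit(hi_curated & full_gene)) fired <- c(fired, "DUP_CONTAINS_HI_GENE")
    if (hit((hi_curated | constrained) & partial_gene))
      fired <- c(fired, "DUP_BREAKS_CONSTRAINED")
    if (hit(constrained & full_gene)) fired <- c(fired, "DUP_CONTAINS_PLI")
    if (hit(has_dis & full_gene)) fired <- c(fired, "DUP_CONTAINS_DISEASE")
    if (hit(has_dis)) fired <- c(fired, "DUP_DISEASE_OTHER")
  }
  fired
}

#' Adverse-information score of an annotated CNV
#'
#' Binary: 100 when any evidence against the CNV being real and/or
#' pathogenic exists, else 0. Default criteria: (a) reciprocal overlap >=
#' `adverse_reciprocal` with a same-type population SV whose popmax frequency
#' exceeds `adverse_af`; (b) read-depth ratio inconsistent with the CNV type
#' (deletion ratio > `adverse_del_ratio`, duplication ratio <
#' `adverse_dup_ratio`); (c) median mapping quality inside the CNV below
#' `adverse_min_mq`; (d) more than `adverse_problem_cover` of the CNV covered
#' by problem regions. Criteria (b) and (c) require alignment evidence and
#' never fire when `evidence` is absent, so annotation-only runs still work.
#'
#' @param bundle [annotate_cnv()] result
#' @param evidence [extract_evidence()] result, or NULL
#' @param config [default_config()]
#' @return list(score = 0L or 100L, adverse_reasons = character)
#' @export
adverse_information_score <- function(bundle, evidence = NULL,
                                      config = default_config()) {
  reasons <- character(0)
  pop <- bundle$population_hits
  type <- bundle$cnv$type
  if (nrow(pop)) {
    same <- pop$sv_type == type & pop$reciprocal >= config$adverse_reciprocal &
      !is.na(pop$popmax_af) & pop$popmax_af > config$adverse_af
    if (any(same)) reasons <- c(reasons, "SUBSTANTIAL_POPULATION_OVERLAP")
  }
  if (!is.null(evidence)) {
    dr <- evidence$depth_ratio
    if (!is.null(dr) && !is.na(dr)) {
      if (type == "deletion" && dr > config$adverse_del_ratio)
        reasons <- c(reasons, "DEPTH_INCONSISTENT")
      if (type == "duplication" && dr < config$adverse_dup_ratio)
        reasons <- c(reasons, "DEPTH_INCONSISTENT")
    }
    mq <- evidence$median_mq_inside
    if (!is.null(mq) && !is.na(mq) && mq < config$adverse_min_mq)
      reasons <- c(reasons, "LOW_MAPPING_QUALITY")
  }
  if (isTRUE(bundle$problem_cover > config$adverse_problem_cover))
    reasons <- c(reasons, "PROBLEM_REGION_OVERLAP")
  list(score = if (length(reasons)) 100L else 0L, adverse_reasons = reasons)
}

#' Combine score components into a priority result
#'
#' priority = clinical relevance + adverse information; lower is more
#' urgent. Tier: high when priority < 99 (clinical relevance without adverse
#' information), moderate at exactly 99, low above 99.
#'
#' @param clinical clinical-relevance component (deletions: 1-5 or 99;
#'   duplications: 1-7 or 99)
#' @param adverse adverse-information component (0 or 100)
#' @param cnv_type "deletion" or "duplication" (validates the legal clinical
#'   range)
#' @param triggered_rules,adverse_reasons carried through into the result
#' @return list with class `priority_result`: clinical_relevance, adverse,
#'   priority, tier, triggered_rules, adverse_reasons
#' @export
#' @examples
#' priority_score(1, 0, "deletion")$tier    # "high"
#' priority_score(99, 0, "deletion")$tier   # "moderate"
#' priority_score(1, 100, "deletion")$tier  # "low"
priority_score <- function(clinical, adverse, cnv_type = "deletion",
                           triggered_rules = character(0),
                           adverse_reasons = character(0)) {
  legal <- if (cnv_type == "deletion") c(1:5, 99) else if
    (cnv_type == "duplication") c(1:7, 99) else
      abort_input("unknown CNV type: ", cnv_type)
  if (!clinical %in% legal)
    abort_input("illegal clinical relevance ", clinical, " for ", cnv_type)
  if (!adverse %in% c(0, 100))
    abort_input("adverse score must be 0 or 100, got ", adverse)
  priority <- clinical + adverse
  res <- list(
    clinical_relevance = as.integer(clinical),
    adverse = as.integer(adverse),
    priority = as.integer(priority),
    tier = if (priority < 99) "high" else if (priority == 99) "moderate" else "low",
    triggered_rules = triggered_rules,
    adverse_reasons = adverse_reasons
  )
  class(res) <- "priority_result"
  res
}

#' @export
print.priority_result <- function(x, ...) {
  cat(sprintf("priority %d (clinical %d + adverse %d) -> %s priority\n",
              x$priority, x$clinical_relevance, x$adverse, x$tier))
  if (length(x$triggered_rules))
    cat("  rules:", paste(x$triggered_rules, collapse = ", "), "\n")
  if (length(x$adverse_reasons))
    cat("  adverse:", paste(x$adverse_reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Score one CNV end to end (annotate + both components)
#'
#' @inheritParams annotate_cnv
#' @param evidence optional [extract_evidence()] result
#' @return list(bundle, priority) where priority is a [priority_score()]
#' @export
score_cnv <- function(cnv, annotation, evidence = NULL,
                      config = default_config()) {
  bundle <- annotate_cnv(cnv, annotation, config)
  cl <- clinical_relevance_score(bundle, config)
  ad <- adverse_information_score(bundle, evidence, config)
  list(bundle = bundle,
       priority = priority_score(cl$score, ad$score, bundle$cnv$type,
                                 cl$triggered_rules, ad$adverse_reasons))
}

#' Rank CNVs by priority score and size
#'
#' Ascending priority; within equal priority, descending size; stable for
#' full ties.
#'
#' @param calls [cnv_calls()]
#' @param priorities integer vector of priority scores aligned to `calls`
#' @return integer permutation such that `calls[rank_cnvs(...), ]` is ranked
#' @export
rank_cnvs <- function(calls, priorities) {
  if (nrow(calls) != length(priorities))
    abort_input("calls and priorities differ in length")
  order(priorities, -(calls$end - calls$start))
}

FINDING_SENTENCES <- c(
  FULLY_CONTAINS_HI = "Fully contains a curated haploinsufficient region or gene.",
  PARTIAL_HI = "Partially overlaps a curated haploinsufficient region, or removes coding sequence of a curated haploinsufficient gene.",
  FULLY_CONTAINS_TS = "Fully contains a curated triplosensitive region or gene.",
  PARTIAL_TS = "Partially overlaps a curated triplosensitive region.",
  WHOLE_GENE_DUP_HI = "Duplicates an entire curated haploinsufficient gene.",
  BREAKS_CONSTRAINED_GENE = "Disrupts a loss-of-function constrained gene.",
  CONSTRAINED_GENE_CDS = "Removes coding sequence of a loss-of-function constrained gene.",
  CONTAINS_CONSTRAINED_GENE = "Fully contains a loss-of-function constrained gene.",
  DISEASE_GENE_CDS = "Removes coding sequence of a disease-associated gene.",
  CONTAINS_DISEASE_GENE = "Fully contains a disease-associated gene.",
  DISEASE_GENE_OVERLAP = "Overlaps a disease-associated gene.",
  SUBSTANTIAL_POPULATION_OVERLAP = "Substantial overlap with common population variants of the same type.",
  DEPTH_INCONSISTENT = "Read-depth ratio is inconsistent with the called CNV type.",
  LOW_MAPPING_QUALITY = "Low median mapping quality inside the variant.",
  PROBLEM_REGION_OVERLAP = "Mostly covered by known problem regions."
)

RULE_TO_FINDING <- c(
  DEL_CONTAINS_HI = "FULLY_CONTAINS_HI",
  DEL_PARTIAL_HI_REGION = "PARTIAL_HI",
  DEL_HI_GENE_CDS = "PARTIAL_HI",
  DEL_PLI_CDS = "CONSTRAINED_GENE_CDS",
  DEL_DISEASE_CDS = "DISEASE_GENE_CDS",
  DEL_DISEASE_OTHER = "DISEASE_GENE_OVERLAP",
  DUP_CONTAINS_TS = "FULLY_CONTAINS_TS",
  DUP_PARTIAL_TS_REGION = "PARTIAL_TS",
  DUP_CONTAINS_HI_GENE = "WHOLE_GENE_DUP_HI",
  DUP_BREAKS_CONSTRAINED = "BREAKS_CONSTRAINED_GENE",
  DUP_CONTAINS_PLI = "CONTAINS_CONSTRAINED_GENE",
  DUP_CONTAINS_DISEASE = "CONTAINS_DISEASE_GENE",
  DUP_DISEASE_OTHER = "DISEASE_GENE_OVERLAP"
)

#' Structured summary of positive and negative findings
#'
#' Machine-readable finding codes plus human-readable sentences covering
#' every triggered clinical-relevance rule (positive findings) and adverse
#' reason (negative findings); evidence metrics (depth ratio, median MQ,
#' quality score, supporting reads) are included when available.
#'
#' @param bundle [annotate_cnv()] result
#' @param priority [priority_score()] result
#' @param evidence optional [extract_evidence()] result
#' @return list(positive = data.frame(code, sentence),
#'   negative = data.frame(code, sentence), metrics = named list,
#'   links = named character of external-resource URL strings)
#' @export
summarize_findings <- function(bundle, priority, evidence = NULL) {
  pos_codes <- unique(unname(RULE_TO_FINDING[priority$triggered_rules]))
  neg_codes <- unique(priority$adverse_reasons)
  as_tab <- function(codes) data.frame(
    code = codes, sentence = unname(FINDING_SENTENCES[codes]),
    stringsAsFactors = FALSE)
  metrics <- list()
  if (!is.null(evidence)) {
    metrics <- list(depth_ratio = evidence$depth_ratio,
                    median_mq_inside = evidence$median_mq_inside,
                    supporting_read_count = evidence$supporting_read_count,
                    quality_score = evidence$quality_score)
  }
  cnv <- bundle$cnv
  region <- sprintf("%s:%s-%s", cnv$chrom,
                    format(cnv$start + 1, scientific = FALSE, trim = TRUE),
                    format(cnv$end, scientific = FALSE, trim = TRUE))
  genes <- bundle$gene_impacts$symbol
  links <- c(
    gnomad = sprintf("https://gnomad.broadinstitute.org/region/%s", region),
    ucsc = sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?position=%s", region),
    omim_search = if (length(genes))
      sprintf("https://omim.org/search?search=%s", paste(genes, collapse = "+"))
    else "",
    genecards = if (length(genes))
      sprintf("https://www.genecards.org/cgi-bin/carddisp.pl?gene=%s", genes[1])
    else "",
    google = if (length(genes))
      sprintf("https://www.google.com/search?q=%s+%s", genes[1], cnv$type)
    else ""
  )
  list(positive = as_tab(pos_codes), negative = as_tab(neg_codes),
       metrics = metrics, links = links)
}
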