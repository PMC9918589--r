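#' Run the full triage pipeline for one sample
#'
#' Orchestrates parse -> merge -> three-step filtration -> annotation and
#' priority scoring -> (optional) alignment evidence -> (optional)
#' inheritance -> ranking, and assembles a per-sample report. Evidence and
#' inheritance stages are skipped gracefully when their inputs (`bam`,
#' `family`/internal cohort) are absent. The result is deterministic:
#' identical config and inputs give identical reports.
#'
#' @param config [default_config()] (or [load_config()]) carrying input
#'   paths: `cnv` (call list), `dialect`, `sample_id`, `annodir` (or pass
#'   `annotation`), optional `bam`, `ref_bam`, `family` (TSV appended to the
#'   internal cohort), plus all thresholds
#' @param calls optional pre-parsed [cnv_calls()] (overrides `config$cnv`)
#' @param annotation optional pre-built [annotation_set()] (overrides
#'   `config$annodir`)
#' @return list with class `sample_report`: `rows` (ranked data.frame, one
#'   CNV per row), `bundles`, `evidence`, `inheritance`, `filtration`
#'   ([run_filtration()] result), `meta` (versions, config hash, per-step
#'   counts)
#' @export
run_pipeline <- function(config = default_config(), calls = NULL,
                         annotation = NULL) {
  if (is.null(calls)) {
    if (is.null(config$cnv)) abort_input("no CNV input: set config$cnv or pass calls")
    calls <- parse_cnv_calls(config$cnv, config$dialect %||% "bed_tsv",
                             sample_id = config$sample_id %||% "sample")
  }
  if (is.null(annotation)) {
    if (is.null(config$annodir))
      abort_input("no annotations: set config$annodir or pass annotation")
    annotation <- load_annotations(config$annodir)
  }
  if (!is.null(config$family) && file.exists(config$family %||% "")) {
    fam <- read.delim(config$family, stringsAsFactors = FALSE)
    annotation$internal_cohort <- rbind(annotation$internal_cohort, fam)
  }
  calls <- merge_nearby_cnvs(calls, config$merge_max_gap)
  filt <- run_filtration(calls, annotation, config)
  surv <- filt$survivors
  sample_id <- if (nrow(calls)) calls$sample_id[1] else config$sample_id %||% "sample"
  family_id <- annotation$internal_cohort$family_id[
    match(sample_id, annotation$internal_cohort$sample_id)]
  has_bam <- !is.null(config$bam) && file.exists(config$bam %||% "")
  has_family <- !is.na(family_id %||% NA) && nrow(annotation$internal_cohort) > 0

  bundles <- list(); evidence <- list(); inheritance <- list()
  rows <- list()
  for (i in seq_len(nrow(surv))) {
    cnv <- surv[i, , drop = FALSE]
    ev <- if (has_bam) extract_evidence(config$bam, cnv, config,
                                        ref_bam = config$ref_bam) else NULL
    sc <- score_cnv(cnv, annotation, ev, config)
    inh <- if (has_family) {
      fm <- match_family_cnvs(cnv, annotation$internal_cohort, family_id,
                              config$family_min_reciprocal,
                              config$family_containment_flag)
      infer_inheritance(fm, trio_is_complete(annotation$internal_cohort, family_id))
    } else NULL
    fnd <- summarize_findings(sc$bundle, sc$priority, ev)
    bundles[[i]] <- sc$bundle; evidence[[i]] <- ev; inheritance[[i]] <- inh
    gi <- sc$bundle$gene_impacts
    rows[[i]] <- data.frame(
      sample_id = cnv$sample_id, chrom = cnv$chrom, start = cnv$start,
      end = cnv$end, type = cnv$type, length = cnv$end - cnv$start,
      clinical_relevance = sc$priority$clinical_relevance,
      adverse = sc$priority$adverse, priority = sc$priority$priority,
      tier = sc$priority$tier,
      triggered_rules = paste(sc$priority$triggered_rules, collapse = ","),
      adverse_reasons = paste(sc$priority$adverse_reasons, collapse = ","),
      n_genes = nrow(gi),
      genes = paste(gi$symbol, collapse = ","),
      full_overlap_genes = paste(gi$symbol[gi$overlap_kind == "full"], collapse = ","),
      n_population_hits = nrow(sc$bundle$population_hits),
      max_popmax_af = if (nrow(sc$bundle$population_hits))
        max(sc$bundle$population_hits$popmax_af) else NA_real_,
      n_known_pathogenic = sum(sc$bundle$known_sv_hits$interpretation %in%
                                 c("pathogenic", "likely_pathogenic")),
      dosage_hits = paste(sc$bundle$dosage_hits$symbol, collapse = ","),
      depth_ratio = if (!is.null(ev)) round(ev$depth_ratio, 4) else NA_real_,
      median_mq = if (!is.null(ev)) ev$median_mq_inside else NA_real_,
      supporting_reads = if (!is.null(ev)) ev$supporting_read_count else NA_integer_,
      quality_score = if (!is.null(ev)) round(ev$quality_score, 4) else NA_real_,
      inheritance = if (!is.null(inh)) inh$label else "unknown",
      findings_positive = paste(fnd$positive$code, collapse = ","),
      findings_negative = paste(fnd$negative$code, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    o <- rank_cnvs(surv, tab$priority)
    tab <- tab[o, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    bundles <- bundles[o]; evidence <- evidence[o]; inheritance <- inheritance[o]
  } else {
    tab <- data.frame()
  }
  rownames(tab) <- NULL
  res <- list(
    rows = tab, bundles = bundles, evidence = evidence,
    inheritance = inheritance, filtration = filt,
    meta = list(package_version = as.character(packageVersion("cnvtriage")),
                config_hash = config_hash(config),
                genome_build = config$genome_build,
                per_step_counts = as.list(filt$per_step_counts))
  )
  class(res) <- "sample_report"
  res
}

#' @export
print.sample_report <- function(x, ...) {
  cat("sample_report:", nrow(x$rows), "ranked CNV(s)\n")
  cat("  filtration:", paste(sprintf("%s=%d", names(x$filtration$per_step_counts),
                                     x$filtration$per_step_counts),
                             collapse = " -> "), "\n")
  if (nrow(x$rows))
    print.data.frame(x$rows[c("rank", "chrom", "start", "end", "type",
                              "priority", "tier", "genes")])
  invisible(x)
}

REPORT_TSV_COLUMNS <- c(
  "rank", "sample_id", "chrom", "start", "end", "type", "length",
  "clinical_relevance", "adverse", "priority", "tier", "triggered_rules",
  "adverse_reasons", "n_genes", "genes", "full_overlap_genes",
  "n_population_hits", "max_popmax_af", "n_known_pathogenic", "dosage_hits",
  "depth_ratio", "median_mq", "supporting_reads", "quality_score",
  "inheritance", "findings_positive", "findings_negative", "interpretation")

#' Write a sample report as TSV, JSON and text summary
#'
#' The TSV has one row per CNV in rank order with the documented column
#' schema ([report_tsv_columns()]); the JSON carries the full nested bundles
#' for downstream rendering; the text summary is human-readable. Previously
#' entered interpretations (see [read_interpretations()]) are merged into
#' the `interpretation` column and preserved across reruns.
#'
#' @param report [run_pipeline()] result
#' @param out_prefix path prefix for `<prefix>.tsv` / `.json` / `.txt`
#' @param formats subset of c("tsv", "json", "txt")
#' @param interpretations_file optional central interpretations store
#' @return named character of written paths, invisibly
#' @export
write_report <- function(report, out_prefix,
                         formats = c("tsv", "json", "txt"),
                         interpretations_file = NULL) {
  tab <- report$rows
  interp <- if (!is.null(interpretations_file))
    read_interpretations(interpretations_file) else
      data.frame(cnv_id = character(0), interpretation = character(0))
  if (nrow(tab)) {
    ids <- cnv_id(tab)
    tab$interpretation <- interp$interpretation[match(ids, interp$cnv_id)]
    tab$interpretation[is.na(tab$interpretation)] <- ""
    tab <- tab[REPORT_TSV_COLUMNS]
  }
  written <- character(0)
  if ("tsv" %in% formats) {
    p <- paste0(out_prefix, ".tsv")
    if (nrow(tab)) write.table(tab, p, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ".")
    else writeLines(paste(REPORT_TSV_COLUMNS, collapse = "\t"), p)
    written["tsv"] <- p
  }
  if ("json" %in% formats) {
    p <- paste0(out_prefix, ".json")
    payload <- list(
      meta = report$meta,
      filtration = list(per_step_counts = as.list(report$filtration$per_step_counts),
                        removed = report$filtration$removed),
      cnvs = lapply(seq_len(nrow(report$rows)), function(i) {
        list(row = as.list(report$rows[i, ]),
             bundle = bundle_to_list(report$bundles[[i]]),
             evidence = evidence_to_list(report$evidence[[i]]),
             inheritance = inheritance_to_list(report$inheritance[[i]]))
      }))
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    written["json"] <- p
  }
  if ("txt" %in% formats) {
    p <- paste0(out_prefix, ".txt")
    lines <- c(sprintf("cnvtriage report (package %s, config %s)",
                       report$meta$package_version, report$meta$config_hash),
               sprintf("filtration: %s",
                       paste(sprintf("%s=%d", names(report$filtration$per_step_counts),
                                     report$filtration$per_step_counts),
                             collapse = " -> ")),
               "")
    for (i in seq_len(nrow(report$rows))) {
      r <- report$rows[i, ]
      lines <- c(lines, sprintf(
        "#%d %s %s:%s-%s priority %d (%s)%s%s", r$rank, r$type, r$chrom,
        format(r$start, scientific = FALSE), format(r$end, scientific = FALSE),
        r$priority, r$tier,
        if (nzchar(r$genes)) paste0(" genes: ", r$genes) else "",
        if (nzchar(r$findings_positive)) paste0(" findings: ", r$findings_positive) else ""))
    }
    writeLines(lines, p)
    written["txt"] <- p
  }
  invisible(written)
}

cnv_id <- function(tab) {
  sprintf("%s_%s_%s_%s_%s", tab$sample_id, tab$chrom,
          format(tab$start, scientific = FALSE, trim = TRUE),
          format(tab$end, scientific = FALSE, trim = TRUE),
          tab$type)
}

#' The documented report TSV column schema
#' @return character vector of column names in order
#' @export
report_tsv_columns <- function() REPORT_TSV_COLUMNS

#' Read / update the central interpretations store
#'
#' Interpretations entered during review are kept in one tab-separated text
#' file (`cnv_id`, `interpretation`); updating one CNV's entry preserves all
#' prior entries, so interpretations survive pipeline reruns.
#'
#' @param path interpretations file (need not exist yet)
#' @return data.frame(cnv_id, interpretation)
#' @export
read_interpretations <- function(path) {
  if (!file.exists(path))
    return(data.frame(cnv_id = character(0), interpretation = character(0),
                      stringsAsFactors = FALSE))
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname read_interpretations
#' @param cnv_id identifier as in the report (`sample_chrom_start_end_type`)
#' @param text interpretation text (overwrites this CNV's prior entry)
#' @export
write_interpretation <- function(path, cnv_id, text) {
  store <- read_interpretations(path)
  store <- store[store$cnv_id != cnv_id, , drop = FALSE]
  store <- rbind(store, data.frame(cnv_id = cnv_id, interpretation = text,
                                   stringsAsFactors = FALSE))
  store <- store[order(store$cnv_id), , drop = FALSE]
  write.table(store, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bundle_to_list <- function(b) {
  if (is.null(b)) return(NULL)
  list(cnv = as.list(b$cnv), population_hits = b$population_hits,
       known_sv_hits = b$known_sv_hits, internal_hits = b$internal_hits,
       dosage_hits = b$dosage_hits, gene_impacts = b$gene_impacts,
       affected_transcripts = b$affected_transcripts,
       problem_cover = b$problem_cover)
}

evidence_to_list <- function(e) {
  if (is.null(e)) return(NULL)
  list(flank_bp = e$flank_bp, window = e$window,
       depth_ratio = e$depth_ratio, median_mq_inside = e$median_mq_inside,
       insert_bounds = e$insert_bounds,
       supporting_read_count = e$supporting_read_count,
       quality_score = e$quality_score,
       n_anomalous = nrow(e$anomalous_reads),
       reference_flagged_bins = e$reference_flagged_bins,
       bins = e$bins)
}

inheritance_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(label = x$label, trio_complete = x$trio_complete,
       possible_inherited_size_discordant = x$possible_inherited_size_discordant,
       matching_calls = x$matching_calls, sibling_matches = x$sibling_matches)
}

#' Check a report JSON against the shipped required-fields schema
#'
#' A light structural conformance check: every field listed in
#' `inst/extdata/report_schema.json` must be present (recursively for the
#' per-CNV objects).
#'
#' @param json_path report JSON written by [write_report()]
#' @param schema_path schema file (defaults to the shipped one)
#' @return TRUE invisibly, or an error describing the missing field
#' @export
validate_report_json <- function(json_path,
                                 schema_path = system.file("extdata", "report_schema.json",
                                                           package = "cnvtriage")) {
  doc <- jsonlite::read_json(json_path)
  schema <- jsonlite::read_json(schema_path)
  for (k in unlist(schema$required_top))
    if (is.null(doc[[k]])) abort_input("report JSON missing field: ", k)
  for (k in unlist(schema$required_meta))
    if (is.null(doc$meta[[k]])) abort_input("report JSON meta missing field: ", k)
  for (cnv in doc$cnvs)
    for (k in unlist(schema$required_cnv))
      if (!k %in% names(cnv)) abort_input("report JSON cnv entry missing field: ", k)
  invisible(TRUE)
}
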