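#' Assemble an annotation set from in-memory tables
#'
#' Container for the five annotation categories consulted during triage plus
#' the auxiliary tables used by filtration. All tables are plain data.frames
#' in 0-based half-open coordinates; any may be empty. Use
#' [load_annotations()] to read the on-disk dialects and
#' [write_annotations()] / [make_toy_annotations()] to produce them.
#'
#' @param population_svs data.frame: chrom, start, end, sv_type
#'   (deletion/duplication), id, one or more `af_<POPULATION>` columns.
#'   A `popmax_af` column is (re)computed as the row-wise max.
#' @param known_svs data.frame: chrom, start, end, sv_type, id,
#'   interpretation (pathogenic, likely_pathogenic, vus, likely_benign,
#'   benign), condition, allele_origin, genes (comma-separated symbols)
#' @param dosage data.frame: chrom, start, end, kind (region/gene), symbol,
#'   hi_score, ts_score (NA when uncurated; at least one present per row)
#' @param genes data.frame of gene-model rows: chrom, start, end, feature
#'   (gene/transcript/exon/CDS), symbol, transcript_id, exon_number, strand,
#'   is_canonical. Exon numbering is 1-based in transcription order.
#' @param constraint data.frame: symbol, pli
#' @param disease data.frame: symbol, source (OMIM/GenCC), condition
#' @param pext data.frame: symbol, transcript_id, exon_number, pext in \[0,1\]
#' @param internal_cohort data.frame: sample_id, family_id, relation
#'   (proband/mother/father/sibling/other), chrom, start, end, type
#' @param problem_regions data.frame: chrom, start, end, label (gaps,
#'   centromeres, repeats, recurrence regions)
#' @param noncoding_exception_genes character vector of gene symbols with
#'   clinically relevant non-coding variation (kept through filtration step 2
#'   even without CDS overlap)
#' @return list with class `annotation_set`
#' @export
annotation_set <- function(population_svs = NULL, known_svs = NULL,
                           dosage = NULL, genes = NULL, constraint = NULL,
                           disease = NULL, pext = NULL,
                           internal_cohort = NULL, problem_regions = NULL,
                           noncoding_exception_genes = character(0)) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    num <- intersect(c("start", "end", "pli", "pext", "exon_number"), cols)
    for (k in num) df[[k]] <- numeric(0)
    df
  }
  as_df <- function(x, cols) {
    if (is.null(x) || !nrow(as.data.frame(x))) return(empty(cols))
    x <- as.data.frame(x)
    miss <- setdiff(cols, names(x))
    if (length(miss))
      abort_input("annotation table missing column(s): ", paste(miss, collapse = ", "))
    x
  }
  pop <- as_df(population_svs, c("chrom", "start", "end", "sv_type", "id"))
  afc <- grep("^af_", names(pop), value = TRUE)
  pop$popmax_af <- if (nrow(pop) && length(afc))
    do.call(pmax, c(pop[afc], na.rm = TRUE)) else numeric(nrow(pop))
  if (nrow(pop) && length(afc)) {
    vals <- unlist(pop[afc])
    if (any(vals < 0 | vals > 1, na.rm = TRUE))
      abort_input("population allele frequencies must lie in [0, 1]")
  }
  ks <- as_df(known_svs, c("chrom", "start", "end", "sv_type", "id",
                           "interpretation", "condition", "allele_origin", "genes"))
  if (nrow(ks)) {
    legal <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign")
    if (!all(ks$interpretation %in% legal))
      abort_input("known SV interpretation must be one of: ", paste(legal, collapse = ", "))
  }
  dos <- as_df(dosage, c("chrom", "start", "end", "kind", "symbol",
                         "hi_score", "ts_score"))
  if (nrow(dos)) {
    dos$hi_score[dos$hi_score %in% c(".", "")] <- NA
    dos$ts_score[dos$ts_score %in% c(".", "")] <- NA
    if (any(is.na(dos$hi_score) & is.na(dos$ts_score)))
      abort_input("each dosage row needs at least one of hi_score/ts_score")
  }
  gm <- as_df(genes, c("chrom", "start", "end", "feature", "symbol",
                       "transcript_id", "exon_number", "strand", "is_canonical"))
  if (nrow(gm)) {
    gm$is_canonical <- as.logical(gm$is_canonical)
    gm$exon_number <- suppressWarnings(as.numeric(gm$exon_number))
    validate_gene_models(gm)
  }
  obj <- structure(list(
    population_svs = pop,
    known_svs = ks,
    dosage = dos,
    genes = gm,
    constraint = as_df(constraint, c("symbol", "pli")),
    disease = as_df(disease, c("symbol", "source", "condition")),
    pext = as_df(pext, c("symbol", "transcript_id", "exon_number", "pext")),
    internal_cohort = as_df(internal_cohort,
                            c("sample_id", "family_id", "relation",
                              "chrom", "start", "end", "type")),
    problem_regions = as_df(problem_regions, c("chrom", "start", "end", "label")),
    noncoding_exception_genes = as.character(noncoding_exception_genes)
  ), class = "annotation_set")
  obj
}

validate_gene_models <- function(gm) {
  for (sym in unique(gm$symbol)) {
    g <- gm[gm$symbol == sym, , drop = FALSE]
    if (!any(g$feature == "transcript"))
      abort_input("gene ", sym, " has no transcript rows")
    for (tx in unique(g$transcript_id[g$feature == "transcript"])) {
      ex <- g[g$feature == "exon" & g$transcript_id == tx, , drop = FALSE]
      if (!nrow(ex)) next
      ex <- ex[order(ex$start), , drop = FALSE]
      if (any(ex$start[-1] < ex$end[-nrow(ex)]))
        abort_input("overlapping exons in transcript ", tx)
      cds <- g[g$feature == "CDS" & g$transcript_id == tx, , drop = FALSE]
      if (nrow(cds)) {
        cov <- vapply(seq_len(nrow(cds)), function(i)
          union_cover_fraction(cds$chrom[i], cds$start[i], cds$end[i], ex),
          numeric(1))
        if (any(cov < 1))
          abort_input("CDS outside exons in transcript ", tx)
      }
    }
  }
  invisible(gm)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:\n")
  for (k in names(x)) {
    n <- if (is.data.frame(x[[k]])) nrow(x[[k]]) else length(x[[k]])
    cat(sprintf("  %-26s %d\n", k, n))
  }
  invisible(x)
}

ANNOTATION_FILES <- c(
  population_svs = "population_svs.tsv",
  known_svs = "known_svs.tsv",
  dosage = "dosage.tsv",
  genes = "gene_models.tsv",
  constraint = "gene_constraint.tsv",
  disease = "gene_disease.tsv",
  pext = "exon_pext.tsv",
  internal_cohort = "internal_cohort.tsv",
  problem_regions = "problem_regions.bed"
)

#' Load an annotation directory
#'
#' Reads the documented tab-separated dialects (one file per category; see
#' [annotation_set()] for columns). Missing files yield empty tables, so an
#' annotation directory may carry only the categories a site maintains.
#' File names: population_svs.tsv, known_svs.tsv, dosage.tsv,
#' gene_models.tsv, gene_constraint.tsv, gene_disease.tsv, exon_pext.tsv,
#' internal_cohort.tsv, problem_regions.bed (chrom/start/end/label, no
#' header), noncoding_exceptions.txt (one symbol per line).
#'
#' @param dir directory of annotation tables
#' @return [annotation_set()]
#' @export
load_annotations <- function(dir) {
  if (!dir.exists(dir)) abort_input("annotation directory not found: ", dir)
  rd <- function(file, header = TRUE, cols = NULL) {
    p <- file.path(dir, file)
    if (!file.exists(p)) return(NULL)
    df <- read.delim(p, header = header, sep = "\t", quote = "",
                     comment.char = "", stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (!header && !is.null(cols)) names(df) <- cols[seq_len(ncol(df))]
    df
  }
  exc <- file.path(dir, "noncoding_exceptions.txt")
  annotation_set(
    population_svs = rd(ANNOTATION_FILES["population_svs"]),
    known_svs = rd(ANNOTATION_FILES["known_svs"]),
    dosage = rd(ANNOTATION_FILES["dosage"]),
    genes = rd(ANNOTATION_FILES["genes"]),
    constraint = rd(ANNOTATION_FILES["constraint"]),
    disease = rd(ANNOTATION_FILES["disease"]),
    pext = rd(ANNOTATION_FILES["pext"]),
    internal_cohort = rd(ANNOTATION_FILES["internal_cohort"]),
    problem_regions = rd(ANNOTATION_FILES["problem_regions"], header = FALSE,
                         cols = c("chrom", "start", "end", "label")),
    noncoding_exception_genes =
      if (file.exists(exc)) readLines(exc, warn = FALSE) else character(0)
  )
}

#' Write an annotation set to a directory in the documented dialects
#'
#' Inverse of [load_annotations()]; `load_annotations(write_annotations(x, d))`
#' reproduces `x`.
#'
#' @param annot [annotation_set()]
#' @param dir destination directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_annotations <- function(annot, dir) {
  stopifnot(inherits(annot, "annotation_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file, header = TRUE) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = header, na = ".")
  }
  pop <- annot$population_svs
  wr(pop[setdiff(names(pop), "popmax_af")], ANNOTATION_FILES["population_svs"])
  wr(annot$known_svs, ANNOTATION_FILES["known_svs"])
  wr(annot$dosage, ANNOTATION_FILES["dosage"])
  wr(annot$genes, ANNOTATION_FILES["genes"])
  wr(annot$constraint, ANNOTATION_FILES["constraint"])
  wr(annot$disease, ANNOTATION_FILES["disease"])
  wr(annot$pext, ANNOTATION_FILES["pext"])
  wr(annot$internal_cohort, ANNOTATION_FILES["internal_cohort"])
  wr(annot$problem_regions, ANNOTATION_FILES["problem_regions"], header = FALSE)
  writeLines(annot$noncoding_exception_genes,
             file.path(dir, "noncoding_exceptions.txt"))
  invisible(dir)
}

#' Pre-compute recurrence regions from an internal cohort
#'
#' Intervals where the same-type CNV carrier fraction across cohort samples
#' exceeds `carrier_fraction` are emitted as problem-region rows (label
#' "recurrence"), to be appended to the problem-region table consumed by
#' filtration step 1.
#'
#' @param internal_cohort cohort call table (see [annotation_set()])
#' @param n_samples total number of cohort samples (defaults to the number of
#'   distinct sample_ids in the table)
#' @param carrier_fraction threshold carrier fraction (default 0.03)
#' @return data.frame chrom, start, end, label
#' @export
recurrence_regions <- function(internal_cohort,
                               n_samples = length(unique(internal_cohort$sample_id)),
                               carrier_fraction = default_config()$recurrence_carrier_fraction) {
  out <- list()
  if (is.null(internal_cohort) || !nrow(internal_cohort)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0)))
  }
  for (ty in unique(internal_cohort$type)) {
    sub <- internal_cohort[internal_cohort$type == ty, , drop = FALSE]
    for (ch in unique(norm_chrom(sub$chrom))) {
      s <- sub[norm_chrom(sub$chrom) == ch, , drop = FALSE]
      # carrier depth per base: coverage counting each sample once
      s <- s[!duplicated(s[c("sample_id", "start", "end")]), , drop = FALSE]
      cov <- IRanges::coverage(IRanges::IRanges(s$start + 1, s$end))
      thr <- carrier_fraction * n_samples
      hot <- IRanges::slice(cov, lower = thr + 1e-9, rangesOnly = TRUE)
      if (length(hot)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = s$chrom[1],
          start = IRanges::start(hot) - 1,
          end = IRanges::end(hot),
          label = "recurrence", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), label = character(0)))
  do.call(rbind, out)
}
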