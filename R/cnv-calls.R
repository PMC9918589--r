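#' Construct a CNV call table
#'
#' The central container: a data.frame (class `cnv_calls`) with one row per
#' deletion or duplication call. Coordinates are 0-based half-open; every
#' interval must have positive extent (CNVs have positive length by
#' definition; zero-length records are rejected).
#'
#' @param chrom character chromosome names (input dialect preserved)
#' @param start,end numeric 0-based half-open coordinates, `end > start >= 0`
#' @param type "deletion" or "duplication" (recycled)
#' @param sample_id sample identifier (recycled)
#' @param caller caller provenance, may be "" (recycled)
#' @param source_line integer provenance (input line numbers); defaults to
#'   sequence along the calls
#' @return `cnv_calls` data.frame with columns chrom, start, end, type,
#'   sample_id, caller, source_line
#' @export
#' @examples
#' cnv_calls("chr1", 1000, 5000, "deletion", sample_id = "S1")
cnv_calls <- function(chrom, start, end, type,
                      sample_id = "sample", caller = "",
                      source_line = seq_along(chrom)) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    type = as.character(type),
    sample_id = rep_len(as.character(sample_id), length(chrom)),
    caller = rep_len(as.character(caller), length(chrom)),
    source_line = as.character(rep_len(source_line, length(chrom))),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(df)
}

validate_cnv_calls <- function(df) {
  if (nrow(df)) {
    if (any(is.na(df$start) | is.na(df$end)))
      abort_input("CNV calls contain missing coordinates")
    if (any(df$start < 0)) abort_input("CNV start coordinates must be >= 0")
    if (any(df$end <= df$start))
      abort_input("CNV intervals must satisfy end > start (zero-length calls rejected)")
    bad <- !df$type %in% c("deletion", "duplication")
    if (any(bad))
      abort_input("unknown CNV type(s): ", paste(unique(df$type[bad]), collapse = ", "))
  }
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("cnv_calls: %d call(s), %d sample(s)\n",
              nrow(x), length(unique(x$sample_id))))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

cnv_length <- function(calls) calls$end - calls$start

#' Parse a CNV call list from a BED-like TSV or a VCF
#'
#' The `bed_tsv` dialect expects at least four tab-separated columns —
#' chrom, start (0-based), end, type — plus an optional fifth caller column;
#' a header line starting with `#` or `chrom` is skipped. Type tokens
#' DEL/DUP/deletion/duplication (case-insensitive) are accepted. Copy-neutral
#' SV types (e.g. INV, BND) are skipped with a warning. Other malformed lines
#' are collected as record-level errors (attribute `"errors"`, with line
#' numbers) and parsing continues; a file with zero parseable records is a
#' fatal error.
#'
#' The `vcf` dialect uses `SVTYPE` (DEL/DUP) and `END` INFO fields and
#' converts 1-based inclusive `[POS, END]` to internal 0-based half-open
#' coordinates.
#'
#' @param path input file
#' @param dialect "bed_tsv" or "vcf"
#' @param sample_id sample the calls belong to
#' @param caller default caller label when the file carries none
#' @return [cnv_calls()] in input order, with attribute `"errors"` (character
#'   vector, possibly empty)
#' @export
parse_cnv_calls <- function(path, dialect = c("bed_tsv", "vcf"),
                            sample_id = "sample", caller = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_input("CNV file not found: ", path)
  if (dialect == "bed_tsv") parse_cnv_bed(path, sample_id, caller)
  else parse_cnv_vcf(path, sample_id, caller)
}

normalize_type_token <- function(x) {
  x <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("del", "deletion")] <- "deletion"
  out[x %in% c("dup", "duplication")] <- "duplication"
  out
}

COPY_NEUTRAL_TOKENS <- c("inv", "bnd", "tra", "ins", "ctx", "inversion",
                         "translocation", "insertion")

parse_cnv_bed <- function(path, sample_id, caller) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !grepl("^#", lines) & !grepl("^chrom\\b", lines, ignore.case = TRUE) &
    nzchar(trimws(lines))
  lines <- lines[keep]; ln <- ln[keep]
  errors <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) {
      errors <- c(errors, sprintf("line %d: fewer than 4 columns", ln[i]))
      next
    }
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      errors <- c(errors, sprintf("line %d: non-numeric coordinates", ln[i]))
      next
    }
    ty <- normalize_type_token(f[4])
    if (is.na(ty)) {
      if (tolower(f[4]) %in% COPY_NEUTRAL_TOKENS) {
        warning(sprintf("line %d: copy-neutral SV type '%s' skipped", ln[i], f[4]),
                call. = FALSE)
      } else {
        errors <- c(errors, sprintf("line %d: unknown type token '%s'", ln[i], f[4]))
      }
      next
    }
    if (s < 0 || e <= s) {
      errors <- c(errors, sprintf("line %d: invalid interval [%s, %s)", ln[i], f[2], f[3]))
      next
    }
    rows[[i]] <- data.frame(chrom = f[1], start = s, end = e, type = ty,
                            caller = if (length(f) >= 5) f[5] else caller,
                            source_line = as.character(ln[i]),
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    abort_input("no parseable CNV records in ", path,
                if (length(errors)) paste0(" (", length(errors), " malformed line(s))") else "")
  df <- do.call(rbind, rows)
  df$sample_id <- sample_id
  out <- validate_cnv_calls(df[c("chrom", "start", "end", "type",
                                 "sample_id", "caller", "source_line")])
  attr(out, "errors") <- errors
  out
}

parse_cnv_vcf <- function(path, sample_id, caller) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  svtype <- as.character(inf$SVTYPE)
  endpos <- as.numeric(unlist(lapply(inf$END, function(x) if (length(x)) x[1] else NA)))
  pos <- GenomicRanges::start(rr)
  errors <- character(0)
  ty <- normalize_type_token(svtype)
  keep <- rep(TRUE, length(ty))
  for (i in seq_along(ty)) {
    if (is.na(ty[i])) {
      if (tolower(svtype[i]) %in% COPY_NEUTRAL_TOKENS) {
        warning(sprintf("record %d: copy-neutral SVTYPE '%s' skipped", i, svtype[i]),
                call. = FALSE)
      } else {
        errors <- c(errors, sprintf("record %d: unknown SVTYPE '%s'", i, svtype[i]))
      }
      keep[i] <- FALSE
    } else if (is.na(endpos[i]) || endpos[i] < pos[i]) {
      errors <- c(errors, sprintf("record %d: missing or invalid END", i))
      keep[i] <- FALSE
    }
  }
  if (!any(keep)) abort_input("no parseable CNV records in ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    start = pos[keep] - 1,      # 1-based inclusive -> 0-based half-open
    end = endpos[keep],
    type = ty[keep],
    sample_id = sample_id,
    caller = caller,
    source_line = as.character(which(keep)),
    stringsAsFactors = FALSE
  )
  out <- validate_cnv_calls(df)
  attr(out, "errors") <- errors
  out
}

#' Write a CNV call table in the bed_tsv dialect
#'
#' Emits chrom, start, end, type (DEL/DUP), caller. `parse -> write -> parse`
#' round-trips a call table losslessly.
#'
#' @param calls [cnv_calls()]
#' @param path destination
#' @return `path`, invisibly
#' @export
write_cnv_calls <- function(calls, path) {
  df <- as.data.frame(calls)
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    type = ifelse(df$type == "deletion", "DEL", "DUP"),
    caller = df$caller
  )
  writeLines(c("#chrom\tstart\tend\ttype\tcaller",
               do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

#' Merge fragmented nearby CNV calls
#'
#' Read-depth callers can report one large CNV as several nearby fragments
#' (under-calling); downstream containment tests then misbehave, so merging
#' before triage is recommended. Calls from the same sample, of the same
#' type, on the same chromosome, whose gap is at most `max_gap` are merged
#' into one spanning call. The merged call concatenates the constituent
#' `source_line`s and callers. Idempotent.
#'
#' @param calls [cnv_calls()]
#' @param max_gap maximum bridged gap in bp (default from
#'   [default_config()]`$merge_max_gap`)
#' @return merged [cnv_calls()], sorted by (chrom, start)
#' @export
merge_nearby_cnvs <- function(calls, max_gap = default_config()$merge_max_gap) {
  if (max_gap < 0) abort_input("max_gap must be >= 0")
  df <- as.data.frame(calls)
  if (nrow(df) <= 1) return(sort_calls(validate_cnv_calls(df)))
  key <- paste(df$sample_id, df$type, norm_chrom(df$chrom), sep = "\r")
  pieces <- lapply(split(df, key), function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(g$start[-1] - cummax(g$end)[-nrow(g)] > max_gap)))
    do.call(rbind, lapply(split(g, grp), function(m) {
      data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
                 type = m$type[1], sample_id = m$sample_id[1],
                 caller = paste(unique(m$caller[nzchar(m$caller)]), collapse = ","),
                 source_line = paste(m$source_line, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  sort_calls(validate_cnv_calls(out))
}

sort_calls <- function(calls) {
  o <- order(norm_chrom(calls$chrom), calls$start, calls$end)
  out <- calls[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
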