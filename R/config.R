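#' Default run configuration
#'
#' Every threshold used anywhere in the package lives here, so that a single
#' text configuration file controls a run. Values not stated by upstream
#' conventions are this package's own documented defaults (see the methods
#' vignette for rationale).
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{af_threshold (0.01)}{Population allele-frequency cutoff; filtration
#'     step 3 removes a call fully contained in a same-type population SV with
#'     any per-population frequency strictly greater than this.}
#'   \item{merge_max_gap (50000)}{Maximum gap (bp) bridged when merging
#'     fragmented same-type calls in pre-processing.}
#'   \item{problem_region_mode ("union")}{Containment for filtration step 1 is
#'     tested against the merged union of problem regions ("union") or each
#'     record separately ("per_record").}
#'   \item{recurrence_carrier_fraction (0.03)}{Internal-cohort same-type
#'     carrier fraction above which a region is treated as recurrent (for
#'     [recurrence_regions()]).}
#'   \item{pli_cutoff (0.9)}{pLI at or above which a gene counts as
#'     loss-of-function constrained.}
#'   \item{adverse_reciprocal (0.7)}{Reciprocal overlap with a common
#'     same-type population SV at or above which adverse criterion (a) fires.}
#'   \item{adverse_af (0.01)}{popmax frequency that makes a population SV
#'     "common" for adverse criterion (a).}
#'   \item{adverse_del_ratio (0.85)}{A deletion with depth ratio above this is
#'     depth-inconsistent (adverse criterion b).}
#'   \item{adverse_dup_ratio (1.15)}{A duplication with depth ratio below this
#'     is depth-inconsistent (adverse criterion b).}
#'   \item{adverse_min_mq (20)}{Median mapping quality inside the CNV below
#'     this fires adverse criterion (c).}
#'   \item{adverse_problem_cover (0.7)}{Fraction of the CNV covered by problem
#'     regions above which adverse criterion (d) fires.}
#'   \item{flank_fraction (0.5), flank_min_bp (1e5)}{Per-side evidence flank =
#'     max(flank_fraction x CNV length, flank_min_bp), clamped to chromosome
#'     bounds.}
#'   \item{n_bins (200)}{Bins tiling the CNV-plus-flanks window.}
#'   \item{insert_lower_pct (0.5), insert_upper_pct (99.5)}{Percentiles of the
#'     inward-pair insert-size distribution used as outlier bounds.}
#'   \item{min_insert_pairs (1000), insert_fallback_sample (1e5)}{Minimum
#'     window pairs before falling back to a genome-wide sample of at most
#'     insert_fallback_sample pairs.}
#'   \item{support_tolerance_bp (1000)}{Breakpoint tolerance when counting
#'     type-consistent supporting reads.}
#'   \item{support_saturation (5), mq_saturation (40)}{Counts/MQ at which the
#'     corresponding quality-score terms saturate at 1.}
#'   \item{reference_deviation (0.25)}{Fractional deviation of the reference
#'     sample from its own flank baseline above which a bin is flagged
#'     spurious.}
#'   \item{family_min_reciprocal (0.5)}{Reciprocal overlap required for a
#'     family-member call to match the proband's CNV.}
#'   \item{family_containment_flag (0.9)}{Containment above which a
#'     sub-threshold family overlap is flagged "possible inherited,
#'     size-discordant".}
#'   \item{skip_filtration (FALSE)}{Pass all calls straight to
#'     prioritization.}
#'   \item{genome_build ("hg38")}{Metadata only; no liftover is performed.}
#' }
#'
#' @param ... named overrides of the defaults; unknown keys are an error.
#' @return a named list with class `cnvtriage_config`
#' @export
#' @examples
#' cfg <- default_config(af_threshold = 0.05)
#' cfg$af_threshold
default_config <- function(...) {
  cfg <- list(
    af_threshold = 0.01,
    merge_max_gap = 50000,
    problem_region_mode = "union",
    recurrence_carrier_fraction = 0.03,
    pli_cutoff = 0.9,
    adverse_reciprocal = 0.7,
    adverse_af = 0.01,
    adverse_del_ratio = 0.85,
    adverse_dup_ratio = 1.15,
    adverse_min_mq = 20,
    adverse_problem_cover = 0.7,
    flank_fraction = 0.5,
    flank_min_bp = 1e5,
    n_bins = 200,
    insert_lower_pct = 0.5,
    insert_upper_pct = 99.5,
    min_insert_pairs = 1000,
    insert_fallback_sample = 1e5,
    support_tolerance_bp = 1000,
    support_saturation = 5,
    mq_saturation = 40,
    reference_deviation = 0.25,
    family_min_reciprocal = 0.5,
    family_containment_flag = 0.9,
    skip_filtration = FALSE,
    genome_build = "hg38"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      abort_input("unknown configuration key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "cnvtriage_config")
}

#' Read a run configuration from a YAML/flat key-value file
#'
#' Unknown keys are rejected; keys not present keep their documented defaults.
#' Path-valued keys (`cnv`, `annodir`, `bam`, `ref_bam`, `reference`,
#' `family`, `sample_id`, `outdir`, `dialect`) are carried alongside the
#' thresholds.
#'
#' @param path YAML file
#' @return `cnvtriage_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_input("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  path_keys <- c("cnv", "annodir", "bam", "ref_bam", "reference", "family",
                 "sample_id", "outdir", "dialect")
  thresholds <- vals[setdiff(names(vals), path_keys)]
  cfg <- do.call(default_config, thresholds)
  for (k in intersect(path_keys, names(vals))) cfg[[k]] <- vals[[k]]
  cfg
}

#' Write a commented template configuration file
#'
#' @param path destination; will not overwrite unless `overwrite = TRUE`
#' @param overwrite logical
#' @return `path`, invisibly
#' @export
write_config_template <- function(path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    abort_input("refusing to overwrite ", path)
  cfg <- default_config()
  lines <- c(
    "# cnvtriage run configuration (YAML).",
    "# Input paths (uncomment and fill in):",
    "# cnv: calls.tsv        # CNV list, BED-coordinate TSV or VCF",
    "# dialect: bed_tsv      # or vcf",
    "# sample_id: SAMPLE01",
    "# annodir: annotations/ # directory of annotation tables",
    "# bam: sample.bam       # indexed alignments (optional)",
    "# ref_bam: reference.bam# reference control sample (optional)",
    "# family: cohort.tsv    # internal cohort incl. family members (optional)",
    "# outdir: out/",
    "# Thresholds (documented defaults shown):",
    vapply(names(unclass(cfg)), function(k) {
      v <- cfg[[k]]
      sprintf("%s: %s", k, if (is.logical(v)) tolower(as.character(v)) else as.character(v))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Hash of a configuration (run-metadata stamp)
#' @noRd
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg)[order(names(unclass(cfg)))], tf)
  unname(tools::md5sum(tf))
}
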