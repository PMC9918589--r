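---
title: "Methods: filtration, prioritization and read evidence for germline CNVs"
author: "cnvtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtration, prioritization and read evidence for germline CNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvtriage)
```

# The problem

A genome-sequenced patient typically yields a few thousand copy number
variant (CNV) calls, of which at most a handful are clinically meaningful.
Two things make manual triage slow: most calls are either artifacts or
common benign variation, and judging the remainder requires cross-referencing
several databases (population structural variants, dosage-sensitivity
curations, gene models and constraint scores, known pathogenic variants)
plus the raw read alignments. `cnvtriage` implements the backend of that
workflow as composable, deterministic functions: filter, annotate and score,
extract alignment evidence, label inheritance, and emit a ranked report.

All internal coordinates are 0-based half-open (BED convention); VCF input
is converted on ingest. Chromosome-name dialects ("chr1" vs "1") are
normalized for comparison only; input dialects are preserved in output.
Genome build (hg19/hg38) is carried as metadata — no liftover is attempted.

# Pre-processing: merging under-called CNVs

Read-depth callers sometimes fragment one large variant into several nearby
calls, which then defeats any containment-based test (each fragment may fit
inside a benign variant even though the true spanning variant does not).
`merge_nearby_cnvs()` therefore merges same-sample, same-type, same-chromosome
calls whose gap is at most `merge_max_gap` before filtration. The default of
50 kb is this package's own choice: it is a tenth of the recurrent-syndrome
scale (0.5–1+ Mb) at which fragmentation is actually hazardous, and far
larger than the bin size of common read-depth callers (~500 bp), so genuinely
distinct small variants are not fused. The operation is idempotent and the
merged call records its constituent input lines.

# Variant filtration

Filtration runs three ordered steps; each removed call is recorded with its
step and reason so the funnel is auditable.

1. **Problem regions.** A call is removed iff it is *fully contained* in
   known problem regions (assembly gaps, centromeres, repeats) or recurrence
   regions. Containment is computed against the merged union of records by
   default: a call straddling two abutting repeat records is still entirely
   repeat and should not escape on a record boundary (`per_record` mode is
   available for the stricter reading). Recurrence regions — loci where an
   internal cohort carries the same CNV type at high frequency — can be
   supplied directly as problem-region rows or pre-computed with
   `recurrence_regions()`, which flags bases where the same-type carrier
   fraction exceeds 3% of cohort samples (configurable).
2. **Coding overlap.** A call is retained iff it overlaps at least 1 bp of
   coding sequence of *any* transcript, or overlaps a gene on the non-coding
   exception list (genes with established clinically relevant non-coding
   variation, treated as coding). Using any transcript rather than only the
   canonical one keeps this step maximally sensitive; prioritization narrows
   the field later.
3. **Population containment.** A call is removed iff it is fully contained
   in a population SV of the *same type* with any per-population allele
   frequency *strictly greater* than 1% (configurable). Type matching
   matters: a deletion inside a common duplication is not explained by it.

Skipping filtration entirely (`skip_filtration`) is supported for users who
filter with their own pipeline and want prioritization only.

# Prioritization

Each surviving CNV is annotated against five categories: population SVs
(with reciprocal overlap, containment and allele frequencies), known
pathogenic/benign SVs, the internal cohort, dosage-sensitivity curations,
and gene models (full/partial overlap, strand, pLI, disease associations,
affected exons and transcripts, per-exon pext ranges). The priority score is
the sum of two components; lower is more urgent.

**Clinical relevance** is an integer ladder — 1–5 for deletions, 1–7 for
duplications, 99 when nothing fires — evaluated as the minimum over fired
rules:

| Deletions | Duplications |
|---|---|
| 1 fully contains a curated HI region/gene | 1 fully contains a curated TS region/gene |
| 2 partially overlaps an HI region, or removes CDS of an HI gene | 2 partially overlaps a TS region |
| 3 removes CDS of a pLI ≥ 0.9 gene | 3 fully contains an HI gene (whole-gene duplication) |
| 4 removes CDS of an OMIM/GenCC disease gene | 4 breaks an HI or pLI ≥ 0.9 gene |
| 5 any other overlap of a disease gene | 5 fully contains a pLI ≥ 0.9 gene |
| | 6 fully contains a disease gene |
| | 7 any other overlap of a disease gene |

The ladder encodes standard dosage reasoning: losing a haploinsufficient
region outranks everything; for duplications, whole-gene duplication of an
HI gene (local triploidy) and gene breakage are distinct mechanisms and are
ranked separately. The ladder is *data*, not code — `default_clinical_rules()`
returns the table and a modified copy can be supplied via the configuration —
because the exact rung ordering is a policy choice a laboratory may
reasonably tune. Known-pathogenic-SV and internal-cohort overlaps are
reported as annotations but do not move the score: a ClinVar overlap needs
human judgment about interpretation quality, and cohort overlaps serve
inheritance analysis. Where a curated HI *gene* has no gene model in the
annotation set, the CDS-overlap test for rung 2 falls back to plain interval
overlap with the curation entry.

**Adverse information** is binary: 100 if any evidence against the call
being real or pathogenic exists, else 0. Default criteria: (a) reciprocal
overlap ≥ 0.7 with a common (popmax > 1%) same-type population SV; (b) depth
ratio inconsistent with type (deletion > 0.85, duplication < 1.15); (c)
median mapping quality inside the CNV < 20; (d) problem regions covering
> 70% of the call. Criteria (b) and (c) require alignment evidence and never
fire in annotation-only runs. The numeric thresholds are this package's
documented defaults, all configurable: 0.85/1.15 sit halfway between the
heterozygous expectation (0.5/1.5) and no signal (1.0), MQ 20 is the usual
"unreliable placement" cutoff, and 0.7 mirrors common spreadsheet practice
for "substantially overlapping" calls.

Priority = clinical relevance + adverse information; tiers are high (< 99:
clinical relevance without adverse information), moderate (= 99), low
(> 99). Ranking is by ascending priority, then descending size (a larger
variant at equal priority deserves earlier attention), stable for full ties.

# Alignment evidence

Evidence is extracted from an indexed BAM over the CNV plus flanks of
`max(0.5 × length, 100 kb)` per side, clamped to chromosome ends. Reads used
for depth are mapped, primary, non-duplicate and QC-pass; supplementary
alignments are used only for split-read detection. The window is tiled into
200 bins (visual-resolution choice; configurable) carrying mean per-base
depth and mean mapping quality. The depth ratio is the median per-base depth
inside the CNV over the pooled flank median; a zero flank median reports the
ratio as absent rather than infinite.

Insert-size outlier bounds are the empirical 0.5/99.5 percentiles of the
absolute template lengths of inward-oriented pairs in the window; if fewer
than 1,000 pairs are available the estimate falls back to a genome-wide
sample of up to 100,000 pairs. Every primary alignment with a mapped mate is
then assigned at most one anomaly category with fixed precedence: **split**
(carries supplementary-alignment evidence, SA tag) beats **same-direction**
(both mates on one strand) beats **outward** (pair faces apart) beats
**inward insert-size outlier**; properly sized inward pairs are not
anomalous. Precedence makes the classification exhaustive and mutually
exclusive, which the tests verify property-style.

Supporting reads are the anomalous reads whose geometry matches the called
type: for deletions, large-insert inward pairs whose reads flank both
breakpoints within a tolerance (default 1,000 bp — read-depth callers with
~500-bp windows give imprecise edges) plus split reads at either breakpoint;
for duplications, outward pairs at the breakpoints plus split reads. Split
detection uses recorded supplementary alignments only — no re-alignment of
soft-clipped bases — which is also why a support count can sit slightly
below the number of visually apparent anomalous reads.

The composite quality score (guidance only, never part of the priority
score) is the product of three terms in [0, 1]: depth consistency (1 at the
heterozygous expectation, falling linearly to 0 at ratio 1.0), mapping
quality (saturating at MQ 40), and read support (saturating at 5 supporting
reads). The formula is this package's own, chosen to be monotone in each
component, zero when depth contradicts the call, and saturated for a clean
heterozygous event. The deletion depth term deliberately stays at 1 for
ratios below 0.6 so homozygous deletions are not penalized.

A reference control sample (e.g. a widely used benchmark genome) binned on
the identical grid lets systematic artifacts be discounted:
`compare_reference_sample()` flags bins where the *reference* deviates from
its own flank baseline by more than 25%, because a dip that the control
shows too is a mapping artifact, not patient signal.

# Inheritance

Family members' calls (relations mother/father/sibling in the internal
cohort table) match the proband CNV when same-typed with reciprocal overlap
≥ 0.5 — the same threshold conventionally used for caller concordance.
Labels: no parental match with a complete trio is de novo; mother-only /
father-only / both map to maternal / paternal / inherited-unspecified;
without a complete trio the label is unknown (de novo is never asserted from
absence of data). Two guards reflect known hazards: sibling matches never
affect the parental label, and an overlapping parental call that fails the
reciprocal threshold but is highly contained (≥ 0.9) blocks the de novo
label and raises a "possible inherited, size-discordant" flag — an
under-called parental variant must not masquerade as de novo. Trio
completeness is inferred from the relations present in the calls table
unless stated explicitly; a sequenced parent with zero calls is
indistinguishable from an unsequenced one in a calls-only table, which is a
documented limitation.

# Synthetic fixtures

Everything above is testable offline through a deterministic generator.
`fixture_spec()` declares a toy genome, library parameters and engineered
CNVs; `make_reference_fasta()`, `simulate_alignments_with_cnv()` and
`make_toy_annotations()` realize it. Reads are written directly as aligned
records — no read mapper in the loop — so the engineered signal is exact:
background proper pairs at the requested mean depth with Normal(400, 50) bp
templates and 150-bp reads (typical short-read WGS values), heterozygous
deletions dropping half of the overlapping fragments (homozygous: all),
duplications duplicating them, plus exact numbers of large-insert pairs,
outward pairs and SA-tagged split reads at the breakpoints. Base qualities
are constant and there is no sequencing-error or GC-bias model; those
features do not influence depth- and pair-geometry evidence, which is what
the fixtures exercise. Consequently, passing tests demonstrate correctness
of the *computations* on clean signal, not robustness to mapping ambiguity
in segmental duplications or noisy real-world libraries.

The standard demonstration fixture is a 2-Mb chromosome at 30× with six
engineered CNVs arranged so filtration removes exactly one call per step and
the surviving HI-region deletion ranks first. Test simulations use 0.4–2 Mb
chromosomes at 8–20× — sizes chosen so the whole suite exercises every code
path at desk scale; depth-recovery checks average 20 seeded simulations per
CNV type and require the mean ratio within ±0.1 of 0.5 (het deletion) and
1.5 (het duplication).

# Numerical and degenerate-input choices

* Zero-length intervals are rejected at parse (`end > start`); CNVs have
  positive extent by definition.
* The population-frequency cutoff is a strict inequality (removal requires
  AF > 1%, so exactly 1% is retained), matching the ">" phrasing of the
  rule it implements.
* Insert-size percentiles use R's default empirical quantile (type 7); a
  degenerate constant-insert library yields equal lower and upper bounds.
* Bins tile the window with `round`-spaced edges, so bin widths differ by at
  most 1 bp and no base is counted twice.
* Empty inputs are legal everywhere: an empty annotation table means "no
  hits", an all-filtered sample produces a valid empty report.
* Malformed call-list lines are collected as record-level errors with line
  numbers; only a file with zero parseable records is fatal. Copy-neutral SV
  types (INV, BND, INS) are skipped with a warning, not an error.

# Known limitations

* The score ladder defaults encode one laboratory policy; sites should
  review `default_clinical_rules()` against their own validation set.
* No phenotype-driven prioritization: ranking uses no patient HPO terms.
* No ACMG/ClinGen point-based classification; the tool prioritizes,
  classification remains human.
* Non-coding CNVs are handled only via the exception gene list.
* Full-chromosome aneuploidies and somatic/mosaic events are out of scope.
* CRAM support follows what `Rsamtools` provides; a reference FASTA must be
  resolvable for CRAM inputs.
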