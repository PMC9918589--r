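# cnvtriage

Backend toolkit for clinical triage of germline copy number variants (CNVs —
deletions and duplications) called from whole-genome sequencing. A sequenced
patient yields thousands of CNV calls; almost all are artifacts or benign
population variation. `cnvtriage` reduces that list to the handful worth an
analyst's time and attaches, for each survivor, everything the review needs:
database annotations, a priority score, raw-alignment evidence, and
inheritance status. It is written for clinical-genomics bioinformaticians
who want the triage logic as a scriptable, deterministic R library rather
than a spreadsheet pipeline.

## What it computes

**Filtration** (three ordered steps): remove calls fully contained in
problem regions (gaps, centromeres, repeats, recurrence regions); keep only
calls overlapping ≥ 1 bp of coding sequence or a gene with known clinically
relevant non-coding variation; remove calls fully contained in a same-type
population SV with allele frequency > 1% in any population.

**Prioritization**: each CNV is annotated against population SVs, known
pathogenic SVs, the internal cohort, ClinGen-style dosage curations and gene
models, then scored

    priority = clinical relevance + adverse information

Clinical relevance is a rule ladder — 1–5 for deletions, 1–7 for
duplications, 99 when the CNV has no known clinical relevance. Rung 1 is a
deletion fully containing a curated haploinsufficient (HI) region, or a
duplication fully containing a triplosensitive (TS) region; lower rungs
cover constrained genes (pLI ≥ 0.9) and disease-associated genes. Adverse
information is binary: 100 when evidence against the call exists
(substantial overlap with common population variants, depth ratio
inconsistent with the type, low mapping quality, mostly problem region),
else 0. Priority < 99 is high (review), = 99 moderate, > 99 low.

**Evidence**: from an indexed BAM, per-CNV binned read depth and mapping
quality across the variant ± flanks (max(50% of size, 100 kb) per side),
the inside/flank median depth ratio, insert-size outlier bounds
(0.5/99.5 percentiles of inward pairs), a four-way anomalous-read
classification (inward insert outlier / outward / same direction / split),
a type-consistent supporting-read count, and a composite [0, 1] quality
score.

**Inheritance**: reciprocal-overlap matching (≥ 0.5) of the proband CNV
against family members' calls — de novo / maternal / paternal /
inherited-unspecified / unknown, with a guard against under-called parental
variants masquerading as de novo.

Everything is testable offline: the fixtures module simulates a reference
FASTA, a sorted indexed BAM with engineered CNV signal (depth shifts,
discordant pairs, split reads) and a toy annotation database,
deterministically per seed.

## Worked example

Simulate the demonstration fixture (2-Mb toy chromosome, six engineered
CNVs), then run the full pipeline:

```r
library(cnvtriage)

td   <- tempfile(); dir.create(td)
spec <- default_fixture_spec(seed = 1)
bam  <- simulate_alignments_with_cnv(spec, file.path(td, "sample"))
annot <- make_toy_annotations(spec)

cfg <- default_config()
cfg$bam <- bam
report <- run_pipeline(cfg, calls = fixture_calls(spec), annotation = annot)
print(report)
```

```
sample_report: 3 ranked CNV(s)
  filtration: input=6 -> after_step1=5 -> after_step2=4 -> after_step3=3
  rank chrom   start     end        type priority     tier       genes
1    1  chrT  280000  380000    deletion        1     high     GENE_HI
2    2  chrT 1040000 1052000 duplication        2     high     GENE_TS
3    3  chrT  850000  852000    deletion       99 moderate GENE_BENIGN
```

Six calls went in; one was removed per filtration step (problem-region
containment, no coding overlap, population containment). The heterozygous
deletion containing the curated HI region ranks first with clinical
relevance 1 and no adverse information (priority 1, high tier); the
duplication partially overlapping the TS region scores 2; the benign-gene
deletion has no known clinical relevance (99, moderate). The top call's
alignment evidence:

```r
print(report$evidence[[1]])
```

```
evidence_profile: deletion chrT:280000-380000
  flank 100000 bp | depth ratio 0.500 | median MQ 60.0 | supports 16 | quality 1.00
```

A depth ratio of 0.50 is exactly the heterozygous-deletion expectation, and
the 16 supporting reads are the 12 engineered large-insert pairs plus 4
split reads — the variant is real, well supported, and the quality score
saturates at 1. `write_report(report, "out/sample")` emits the ranked TSV,
a nested JSON and a text summary.

A thin CLI wraps the same functions (`inst/cli/cnvtriage`), with
subcommands `filter`, `prioritize`, `evidence`, `simulate`, `run` and
`config`.

## Scope

No CNV calling, no liftover, no phenotype-driven ranking, no ACMG/ClinGen
point classification, no interactive GUI (plots are emitted as static
files). See the methods vignette (`vignettes/cnv-triage-methods.Rmd`) for
the model, parameter defaults and their rationale, and known limitations.
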