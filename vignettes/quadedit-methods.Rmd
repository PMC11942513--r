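---
title: "Methods: flipon-aware annotation of A-to-I editing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flipon-aware annotation of A-to-I editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadedit)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA; since
inosine is read as guanosine, exonic A-to-I edits can recode proteins
(nonsynonymous editing). A mechanistic picture in which ADAR1 is localized
to nascent transcripts by G-quadruplex (GQ) flipons predicts several
sequence-level signatures around nonsynonymous editing sites:

* a GQ motif on the same strand as the edited adenosine, within a short
  window around the edit;
* edited exons concentrated at transcript ends (recently exonized
  sequence), quantified by a positional classification of each edit within
  its transcript isoforms;
* partial overlap of edited exons with Alu-family repeats (the main source
  of exonized sequence in primates);
* association of edited exons with alternative splicing, operationalized as
  the edited exon of one isoform falling inside an intron of another
  isoform of the same gene;
* editing that *completes* a GQ: an adenosine whose substitution by
  guanosine (inosine) finishes an otherwise defective tetrad run.

`quadedit` implements each of these measurements as a reusable, tested
pipeline over standard formats (FASTA, GTF, BED, RepeatMasker `.out`,
tab-separated edit tables), together with a synthetic-data generator that
plants every signature with recorded truth, so the entire pipeline can be
validated without any external genome resource.

## The quadruplex grammar

The motif model is a grammar rather than a thermodynamic score: `n_runs`
runs of at least `min_run_length` consecutive guanosines separated by loops
of `loop_min`–`loop_max` arbitrary nucleotides. The default
(`gq_pattern()`) is four runs of two or more G with loops of 1–10 nt — the
two-tetrad minimum that suffices for an RNA quadruplex, which is more
permissive than the three tetrads a DNA quadruplex typically needs
(`gq_preset("dgq_strict")` raises the run minimum to 3). Loop bases are
unrestricted: a loop may contain G or N, but N never extends a run.

Because "two or more" is greedy, runs are taken *maximal within a match*:
no loop character adjacent to a run is a G. One hit is reported per
distinct match start, using the shortest-loop, earliest-run decomposition
with the final run taken to its full extent; overlapping matches with
distinct starts are all reported. This canonical policy is what downstream
window queries consume (they only need presence and position), while
`policy = "exhaustive"` enumerates every decomposable substring without the
maximality requirement — the superset a brute-force oracle enumerates — and
exists so that the scanner can be tested against an independent
re-implementation of the grammar.

Two properties of the policy matter downstream:

* a run longer than the minimum admits additional "suffix" match starts
  (the G preceding a match start lies outside the match and so does not
  violate maximality); the planted-truth generator therefore plants runs of
  exactly two G, making each planted motif exactly one hit;
* truncating a sequence at a window edge can cut a run, but the suffix-run
  policy makes window scanning equivalent to genome scanning followed by a
  containment filter — the fast path the permutation test uses.

Minus-strand scanning reverse-complements the contig, scans the literal
string, and maps hits back to plus-strand half-open intervals.

The Z-tract scanner (`scan_z_tract()`) reports maximal tracts of strictly
alternating purines and pyrimidines (the Z-DNA/Z-RNA-forming repeat class),
with a minimum length in dinucleotide units; `N` breaks a tract.

## Window association, classification, overlap, splicing

All in-memory coordinates are 0-based half-open on the plus strand; GTF and
RepeatMasker `.out` (1-based inclusive) are converted at the read/write
boundary only. A single internal convention removes the usual off-by-one
hazards when mixing resources.

**GQ association** (`gq_near_edit()`) extracts the window
`[position − flank, position + flank + 1)` (default `flank_bp = 200`),
clamped to contig bounds, and scans only the edit's strand by default. The
reported distance is `hit start − edit position`, signed in plus-strand
coordinates and minimized by absolute value (ties resolve to the more
negative value). Note that this convention is tied to interval *starts*:
under reverse-complementing the whole genome the distance maps to
`−(d + len − 1)` where `len` is the hit length, while every other
annotation field (classes, flags, overlap lengths) is exactly invariant —
the mirror tests assert precisely this.

**Positional classification** (`classify_edit()`) is exon-membership in
transcript orientation: `first_exon` if the edit lies in the 5′-most exon
(the genomically last exon of a minus-strand transcript), `last_exon` for
the 3′-most, `internal_exon` otherwise, `non_exonic` if in no exon.
Membership is parameter-free and strand-correct, which is why it was chosen
over a percentile-of-transcript-length rule; single-exon transcripts
classify as `last_exon` to avoid a fifth class. Isoforms are aggregated by
the precedence `last_exon > first_exon > internal_exon > non_exonic`; the
per-transcript detail is retained in the output so any other aggregation
can be recomputed.

**Repeat overlap** (`exon_repeat_overlaps()`) intersects edited exons with
repeat intervals (filtered to families whose name begins with `"Alu"` by
default; the prefix is configurable because repeat libraries name
subfamilies like `AluSx`, `AluY`). The summary is over the per-exon
*maximal* overlap. For an even number of exons the median is the lower of
the two central order statistics — overlaps are integer base counts and
this keeps the summary an observed value; `overlap_median()` also offers
the midpoint-mean convention.

**Splice association** (`splice_association()`) is true when another
isoform of the same gene has an intron overlapping the edited exon by at
least 1 bp. In `annotate_all()` it is evaluated only for exonic edits whose
window contains a GQ motif, mirroring the conditioning of the analysis the
pipeline packages (edited exons *associated with GQ motifs* are the ones
intersected with other isoforms' introns); edits that fail the condition
report `FALSE`.

**Edit-enabled GQ** (`edit_enabled_gq()`) substitutes each candidate
adenosine by guanosine, rescans, and reports hits that cover the offset and
are absent from the unedited scan; reverting the substitution removes every
reported hit by construction, and the tests assert this on hundreds of
constructed cases.

Reference-base checking is advisory: an edit whose genome base is not A on
its strand is flagged and excluded from annotation with a warning (a user's
edit list and genome build may legitimately disagree); `strict = TRUE`
escalates to an error.

## The synthetic-data generator

`simulate_dataset()` emulates multi-isoform genes with shared and
isoform-specific exons, planted motifs at controlled distances and strands,
Alu-like repeat intervals partially overlapping exons, a configurable
mixture over positional classes, and tetrad-completing edits. Its defaults
are the study conditions the pipeline targets: class mixture
0.17/0.59/0.19/0.05 (first/last/internal/non-exonic) and planted repeat
overlaps of 5–322 bp. Remaining defaults are ordinary gene geometry for a
compact simulation: 3–6 exons of 120–400 bp, introns of 200–600 bp, 1–3
isoforms, background GC 0.45, one gene per contig and one edit per gene.

The design goal is *exact* truth recovery, not mere statistical agreement:

* the background draw contains no `GG` and no `CC` dinucleotide, and motif
  loops are drawn from `{A, T}` — so on either strand the only G-runs of
  length ≥ 2 anywhere are planted runs on their intended strand, and the
  background provably cannot match the grammar (the negative control is
  analytic, not empirical);
* planted runs are exactly two G long, so each planted motif is exactly one
  canonical hit at its recorded start;
* planted elements keep ≥ 12 bp of background between them (more than the
  maximal loop), so runs of different elements cannot chain;
* bases flanking every element and every edit are forced to A/T, so an
  A→G substitution at a non-planted position can neither seed nor extend a
  run (a G would extend a plus-strand run, a C a minus-strand run);
* splice association is planted by emitting a skip isoform whose intron
  spans the edited exon (with an auxiliary terminal exon when the edited
  exon is itself terminal), and additional random isoforms only ever skip
  non-edited internal exons, so neither the aggregate class nor the splice
  flag can drift from the plant.

What the generator deliberately does *not* emulate: real Alu sequence
content (planted repeats are coordinate intervals labeled `AluSyn`),
editing levels, dsRNA secondary structure, base-composition heterogeneity,
overlapping genes, or chained/overlapping motifs. Passing the
planted-truth tests therefore demonstrates correctness of the measurement
machinery under controlled conditions — it does not validate the biological
model on real genomes, where motif density, repeat structure and isoform
complexity are far richer. With `background_gq_per_gene > 0` motifs are
planted independently of edits for permutation-null calibration; in that
mode the per-edit GQ truth columns no longer predict scan results, which is
why the mode is off by default.

## The permutation test

The descriptive outputs report association counts without a significance
statement. As an extension (flagged as such in its output),
`gq_enrichment()` tests GQ–edit association by repositioning each edit
uniformly within its host transcript's exonic space, preserving strand and
host transcript — this controls for transcript length and (coarsely)
composition without modeling base content. The p-value uses the add-one
convention `p = (1 + #{null ≥ observed}) / (1 + N)` with `N = 999` by
default and a required seed, so `1/(N+1) ≤ p ≤ 1` and results are exactly
reproducible. Calibration is checked empirically: over 200 replicate null
datasets (motifs independent of edits) the rejection rate at α = 0.05 stays
at or below nominal — the null is, if anything, slightly conservative
because observed edits weight terminal exons, where windows are more often
clipped by the gene boundary.

## Numerical and interface choices

* Ranges: half-open integer intervals throughout; interval intersection via
  `IRanges::findOverlaps()`, with the all-pairs comparator reserved for
  tests.
* Ties in the minimum-distance hit resolve to the more negative signed
  distance; documented rather than silent.
* Degenerate inputs: empty edit tables, windows clamped at contig ends,
  genes with a single isoform, and summary over zero overlaps (reported as
  `NA` with `n = 0`) are all defined, tested paths.
* Problem sizes in the shipped tests: the scanner–oracle comparison uses
  1,000 random sequences of 200–1,000 nt; truth recovery uses the default
  2,000-gene dataset; calibration uses 200 replicates of a 25-gene null
  with 199 permutations each. These sizes give stable checks while keeping
  the default test run light.
* The command-line layer (`run_cli()`, `inst/cli/quadedit.R`) is a thin
  wrapper over the exported functions with `simulate`, `scan`, `annotate`
  and `report` subcommands; every run writes a JSON manifest (inputs,
  parameters, seed, package version) sufficient to re-run it.

## Known limitations

* The scanner is a motif grammar; it does not score quadruplex stability
  (no G4Hunter-style scoring) and will report motifs that may not fold.
* Positional classification is exon-membership; an edit 1 bp inside a long
  terminal exon counts the same as one at its tip. The percentile
  alternative was considered and rejected as parameter-laden; per-transcript
  classes are retained so users can post-process.
* The splice-association criterion is purely structural (isoform-intron
  overlap); it does not use expression or splice-junction evidence.
* Genome-scale counts obtained on real annotations depend strongly on the
  annotation release and edit list used; the package reports the summary
  fields for such runs but makes no claim that specific published counts
  are reproduced across resource versions.
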