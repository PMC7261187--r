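---
title: "Processing single-cell DNA repair activity data with haircutr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing single-cell DNA repair activity data with haircutr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haircutr)
```

## The assay and its readout

Single-cell "Haircut" experiments add polyadenylated DNA hairpin substrates,
each carrying a defined lesion at a known position, to a droplet-based
single-cell sequencing run. When a droplet lyses its cell, repair enzymes in
the extract act on the substrates: a glycosylase/AP-endonuclease pair incises
one base downstream of a uracil, RNASEH2 incises 5′ of an embedded
ribonucleotide, and gap-filling polymerases leave products further
downstream. Every incision creates a new 5′ end. Reverse transcription
primed from the polyA tail copies the substrate up to that 5′ end, so after
sequencing, the 1-based position at which read 2 starts on the hairpin
reference *is* the measurement: position 1 means an intact substrate,
positions at or past the lesion record incision and processing.

The package converts paired FASTQ files into a sparse cells ×
(substrate:position) molecule count matrix and provides the downstream
scoring, classification and evaluation used with such matrices. A seeded
simulator generates complete experiments with ground truth, so the whole
chain is testable without sequencing data.

## Coordinates and substrates

All hairpin coordinates are 1-based and inclusive everywhere in the
package; conversion to 0-based offsets happens only inside the alignment
internals. The shipped example substrates place the lesion at position 44;
uracil substrates are scored at position 45 (lesion + 1), the ribonucleotide
substrate at 44, and the abasic substrate at 45 (short-patch) and 46
(long-patch), matching the conventional coordinates for these activities.

The example substrates are 80-mers rather than minimal 50-mers. This is a
deliberate design choice: a read produced by an incision at position 44 only
covers the reference from there to its 3′ end, and with a 50-mer that
fragment would be 7 nt — far below the 20 nt minimum the pipeline requires
for a trustworthy unique placement. With 80-mers every scored fragment
retains at least 31 alignable bases while the printed lesion coordinate is
preserved. Reference sequences exclude the polyA tail and the terminal
spacers, because read 2 is polyA-trimmed before alignment and spacers are
never sequenced.

## Read processing

Read 1 is `16 nt cell barcode + 10 nt UMI` (10x 3′ v2 layout); trailing
bases are ignored and shorter reads are tallied and excluded. Barcodes are
corrected against a whitelist by the unique Hamming-distance-1 rule: an
exact hit stands, a single-neighbor hit is corrected, anything else
(including two-neighbor ties) is dropped and tallied. No quality-weighted
posterior is used; with a known whitelist the unique-neighbor rule is the
established convention and keeps corrections unambiguous. UMIs containing N
are dropped and tallied; UMIs are otherwise not quality-filtered.

Read 2 trimming removes a template-switch prefix (the 13-mer
`AAGCAGTGGTATC` by default, overridable) when it matches the read start with
at most one mismatch, then removes the maximal 3′ suffix that begins with an
A, is at least 6 nt long and is at least 90% A. The start-with-A constraint
stops the suffix from swallowing a non-A body base that the percentage rule
alone would tolerate; the 90% tolerance lets a sequencing error inside a
long tail not block trimming. Reads shorter than `min_len = 20` nt after
trimming are tallied and discarded — below that, unique placement on ~80 nt
references is unreliable.

## Alignment

References are tens of bases long, so the package uses an exhaustive,
deterministic placement instead of a seeded aligner: every read is laid at
every offset of every reference, forward orientation only, ungapped, and
must fit inside the reference (a 3′ overhang would mean untrimmed polyA).
The unique placement with the fewest mismatches wins under a cap of
`max_mismatches = 2`; ties are reported ambiguous and excluded rather than
guessed, because a wrong placement would fabricate an incision position.
Indels are not modeled: on synthetic oligos the 5′ start is the signal and a
gapped alignment could only blur it. The test suite proves the
implementation equivalent to a brute-force all-offsets Hamming oracle on
randomized instances and verifies that reverse-complement reads are never
placed.

## UMI deduplication

Molecules are counted per (cell barcode, substrate, position) stratum —
never pooled across positions, since adjacent positions are distinct
biochemical outcomes. Within a stratum the default grouping is the
directional adjacency criterion: a directed edge runs from UMI *a* to UMI
*b* when they differ at exactly one base and `count(a) ≥ 2·count(b) − 1`;
clusters grow from unvisited highest-count roots, with ties broken
lexicographically so the result is independent of input order. The
molecule count is the number of clusters. A `unique` method (no merging) is
available for comparison and always gives counts at least as large.

## Matrix assembly and empty drops

The count matrix keeps rows only for cell-associated barcodes, which are an
*input* (in a real experiment they come from the mRNA pipeline's filtered
matrix); listed cells without signal keep explicit zero rows. A
`top_n_by_umi` fallback caller exists for purely synthetic runs and is
plumbing, not a statistical cell caller. Matrices serialize as MatrixMarket
triplets with `barcodes.tsv`/`features.tsv` in the familiar 10x layout and
round-trip exactly.

Ambient background is profiled from empty droplets: barcodes not in the
cell list are ranked by total UMI count (descending, ties lexicographic) and
the top *n* — by default as many as there are cells — are retained; the mean
count per hairpin position across those drops, counting absences as zero, is
the background profile. The ranking alone implements the filter; no extra
single-UMI cutoff is applied.

## Scoring, testing and classification

Counts are normalized per cell as `ln(1 + count / total × 10⁴)`, where the
total is the cell's sum over all repair features. The pseudocount is
required for zeros and matches the behavior of the method this mirrors; the
denominator is the repair fraction alone (not mRNA + repair), a choice that
keeps the matrix self-contained but means absolute score scales need not
match plots derived from combined totals. Activity scores read the
normalized value at each substrate's scored site(s); each scored site is an
independent activity (e.g. short-patch at 45 and long-patch at 46 on the
abasic substrate).

Group comparisons use the two-sided Wilcoxon rank-sum test per activity and
group pair — exact when samples are small and untied, otherwise the normal
approximation with tie correction, without continuity correction — with
Bonferroni correction across all reported tests by default (BH optional).
The reported `log_fold_change` is the difference of mean scores, which are
already on the natural-log scale.

Genotype calling for knockout-mixing experiments uses raw counts at the two
scored sites (uracil at 45, ribonucleotide at 44). An activity is "high"
when its count strictly exceeds 5% of that activity's maximum over all
cells. One high and one low assigns the corresponding knockout; both high
is a doublet; both low is unclassified. Equality with the 5% boundary falls
to "low": the published rule uses two strict inequalities and leaves
equality unassigned, and assigning it low keeps the unclassified category
conservative. Because the threshold is relative to the maximum, calls are
invariant to rescaling both count vectors.

Evaluation utilities compute one-vs-rest confusion tables (doublet and
unclassified predictions count as negatives for every true class), TPR/FPR,
a seeded label-permutation baseline whose expected TPR equals each class
frequency, a nearest-centroid classifier (Euclidean distance on normalized
profiles, lexicographic tie-break) standing in for reference-based label
transfer, and read-level downsampling: reads are subsampled per cell
*before* UMI deduplication — mirroring BAM-level downsampling — and the
pipeline is rerun to measure classification sensitivity versus depth.

## Droplet chemistry

Molecules per droplet are estimated as
`conc(M) / 2 × 270 pl × 6.02×10²³`: emulsion formation doubles the master
mix volume, halving the concentration. The stated ~270 pl droplet volume is
used directly rather than recomputed from the ~80 μm diameter (a sphere of
that diameter is ~268 pl; the stated value wins and the diameter is kept as
metadata). Reported per-drop counts are rounded to one significant figure,
the precision at which such loading tables are quoted; at 0.5–25 nM this
gives 40 000 to 2 000 000 molecules per drop. Recovery fractions divide
aligned reads per drop by this estimate.

## The simulator and what it does (not) show

`simulate_experiment()` draws, in a fixed documented order from one seeded
RNG stream: a barcode whitelist; droplet barcodes; doublet compositions;
per-cell molecule counts (Poisson per substrate) with positions from each
genotype's incision distribution; uniform random UMIs; geometric read
multiplicities (mean `reads_per_umi`); and per-base substitution errors on
both reads. R2 is `TSO + reference[position..end] + polyA`, R1 is
`barcode + UMI`. Outputs are byte-identical across reruns with the same
config.

The mixing configuration emulates a two-genotype knockout experiment:
500 + 500 cells by default, 100 molecules per cell per substrate, incision
mass 0.6 at the scored site with 0.25 intact and a small downstream
processing tail, 5% additional cross-genotype doublets (same-genotype
doublets are invisible to this assay and are not simulated), 500 empty
droplets with two intact-only ambient molecules per substrate, read
multiplicity 2 and error rate 0.001. These values were chosen once as a
realistic desk-scale rendering of such an experiment; incision
efficiencies per real cell type are not tabulated anywhere usable, so the
simulator's distributions are declared parameters, not estimates.

What passing end-to-end tests shows: the pipeline recovers the truth its
generative model encodes — barcode/UMI errors at the stated rates, UMI
duplication, ambient background, doublets. What it cannot show: robustness
to real-world artifacts the model omits (PCR chimeras, barcode swapping,
droplet size variation, position-dependent error profiles, RT stops inside
undamaged sequence), nor anything about real cell-type biology. The
per-activity recovery criteria (≥99% of singlets, ≥90% of doublets) are
properties of the stated conditions, not of arbitrary data.

## Numerical and degenerate-input choices

Positions are integer; no floating-point coordinates exist. The polyA
scanner uses an epsilon (1e-9) when comparing the non-A fraction so that
exact 10% boundaries qualify. Genotype calling errors out when either
activity's maximum is zero (a degenerate experiment in which the relative
threshold is meaningless). `log_normalize` leaves all-zero cells at zero
rather than dividing by zero. Ambiguous alignments and unmatched barcodes
are always excluded and tallied, never guessed; every pipeline run asserts
that its QC tallies partition the input reads.

## Problem sizes

The shipped validation suites run the full mixing condition (1050 cell
droplets plus 500 empty drops, ~440k read pairs) once and reuse it across
end-to-end checks; oracle-equivalence suites use 1000 randomized instances
for the aligner and 1000 random strata (≤50 UMIs) for UMI grouping; the
downsampling sensitivity analysis runs targets of 100, 500, 1500 and 5000
reads per cell. These sizes exercise every code path at full fidelity while
keeping a complete run to a couple of minutes on a laptop.
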