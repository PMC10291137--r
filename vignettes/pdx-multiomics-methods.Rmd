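---
title: "Methods: cross-species multi-omics comparison of tumors and PDX models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species multi-omics comparison of tumors and PDX models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxplore)
```

`pdxplore` compares patient tumor samples across disease timepoints
(diagnosis, relapse) with matched patient-derived xenografts (PDX). This
vignette is the package's account of the underlying methods: the models and
rules each stage implements, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one reasonable option existed.

## Xenograft read partitioning

A PDX sequencing library mixes human (graft) and mouse (host) reads. The
package builds a *chimeric k-mer index*: all canonical k-mers (the
lexicographically smaller of a k-mer and its reverse complement; `k = 21` by
default, odd so a k-mer is never its own reverse complement) of both
reference sequences, split into three disjoint sets — graft-only, host-only,
shared. K-mers containing N are skipped.

Classification is a deliberate, auditable evidence rule rather than a
probabilistic model: per read, count matches in each set; *graft* iff
graft-only matches exist and host-only matches do not, *host* symmetrically,
*ambiguous* iff both species-specific sets match, *both* iff only shared
k-mers match, *neither* otherwise. Mates are never split: pair classes come
from a fixed 5×5 table (any graft/host conflict or an ambiguous mate →
ambiguous; a species class dominates both/neither; both dominates neither).
The five classes partition the input exactly. Downstream stages consume only
the graft (human) and host (mouse) fractions.

The index is an in-memory character set, sized for the package's synthetic
genomes (≤ 100 kb per species). Whole-genome indexing, disk-backed k-mer
structures and quality-aware classification are out of scope.

## Somatic variant filtering and longitudinal comparison

Variant calls arrive as per-sample tables with evidence fields. The filter
keeps a call iff

* alt-supporting reads ≥ `min_alt_reads` (default 5),
* variant allele fraction ≥ `min_vaf` (default 0.05),
* population allele frequency ≤ `max_popaf` (default 0.01) in **both** of
  two population databases.

Boundary semantics follow the rule statements literally: strictly *fewer
than five* reads, and strictly *more than 1%* population frequency, are
removed, so a call with exactly 5 reads or exactly 1% frequency is kept. The
VAF clause is grammatically ambiguous in the usual phrasing; we keep
`vaf >= 0.05` to parallel the read-support rule. All three thresholds are
arguments. Missing evidence is never silently kept: calls lacking read
support or VAF are rejected with reason `incomplete`; a missing population
frequency defaults to 0 (not in the database ≈ rare), with a
`strict_missing` mode that rejects instead.

Sample similarity uses the Jaccard distance d(A,B) = 1 − |A∩B| / |A∪B|,
with d(∅,∅) ≡ 0. Set elements are variant keys `(chrom, pos, ref, alt)` by
default; whether gene-level sets would be preferable is not decidable from
the rule statements alone, so both resolutions exist and variant keys are
the default (gene-level collapsing loses allelic distinctions).
Conservation classes are a deterministic function of the timepoints a
variant appears in: *diagnosis-conserved* (at diagnosis and in ≥ 1 PDX),
*relapse-emergent* (absent at diagnosis, at relapse and in ≥ 1 PDX),
*pdx-private* (only in PDX), *other* (e.g. patient-only). The mutation gain
ratio is the later/earlier variant-count ratio per patient, with a cohort
mean ± sd.

## Copy-number categories

Segments (1-based, half-open) with integer total copy number are labeled:
deletion (CN = 0), loss (CN = 1), focal amplification (CN ≥ 7 on < 5 Mb,
strict at exactly 5 Mb), amplification (CN ≥ 7 otherwise), gain (remaining
2 ≤ CN < 7). Read literally, the gain band includes the diploid state and
would label every normal segment a gain; by default CN equal to
`neutral_cn` (2) is *neutral* and excluded from alteration sets, and
`as_printed = TRUE` restores the literal rule for comparison. Gene
annotation assigns a gene the category of any overlapping non-neutral
segment (≥ 1 shared base, half-open); with several overlaps the most extreme
category per direction wins (focal amplification > amplification > gain;
deletion > loss), and a gene spanning both directions yields one call per
direction. CNA Jaccard distances use `(gene, category)` pairs by default,
with a fixed-width (1 Mb) bin alternative.

## Fusion consensus and validation

Five callers are emulated as input tables. A fusion key is the **ordered**
gene pair (gene5, gene3) — A::B ≠ B::A, because the 5'/3' roles matter —
and keys match on the gene pair only, since per-tool breakpoints disagree by
a few bases; the reported breakpoint is the per-side median. A key is a
consensus candidate iff called by ≥ 3 distinct tools in a sample (a tool
repeating itself counts once). Candidates are validated by an evidence table
(junction reads per key and sample): ≥ 1 read validates; a validated key is
then looked up in *every* sample's evidence, and samples with ≥ 1 read are
marked present even where no tool called the fusion ("rescue" — presence may
grow, the cohort key set never does).

The three fusion categories are labels without published definitions, so the
rule here is a declared interpretation: *truncated* if the 3' breakpoint
falls in the 3' partner's last exon (the remaining span has no downstream
coding continuation); otherwise *5'-altered* vs *3'-altered* by which
partner loses the larger fraction of its coding span, with a configurable
50% loss threshold deciding directly and ties resolved to 3'-altered.

## Expression deconvolution

In a PDX, the human read fraction is the tumor-cell program and the mouse
fraction is the TME program. Genes expressed in patient tumors but absent
from the PDX human fraction are therefore microenvironment-derived in the
patient. The ME-gene test is implemented as an explicit, self-contained
negative-binomial rate comparison rather than a call into a DE framework, so
the decision rule is fully auditable: counts are library-size normalized
(per-sample size factor = library size / mean library size, keeping the
count scale); a gene is ME iff

1. its normalized mean in the PDX human fraction ≤ `absent_max_mean`
   (default 3 counts), and
2. a Wald test on the log-rate difference (method-of-moments NB dispersion,
   pooled as the per-group maximum; a half-count floor 0.5/n stabilizes
   zero-mean groups) rejects at BH-adjusted `alpha` (default 0.05) with a
   patient/PDX fold ≥ `min_fold` (default 4) in the patient direction.

All-zero genes are excluded and reported; the per-gene decision trace
(means, dispersion, fold, p, adjusted p) is returned. The thresholds are
declared defaults, not published values — the published analysis named only
the DE package it used — and the count of genes removed on the real cohort
(a cohort property) is deliberately not a test target; the synthetic
recall/precision contract replaces it.

The cross-species ME matrix maps ME genes to mouse orthologs (1:1 pairs
only; many-to-many pairs are dropped and reported, as are genes missing from
the mouse matrix), then merges patient columns with PDX mouse-fraction
columns. "Scaled by the nature of the samples" is implemented as: each
sample group is CPM-normalized, log1p-transformed, and per-gene standardized
*within its group* before merging, so neither platform/species dominates the
joint geometry. Zero-variance rows standardize to 0.

## Component analysis

PCA (`stats::prcomp` on gene-centered data) decomposes the log-normalized
matrices. The decomposition is deterministic up to sign; signs are fixed so
each component's largest-magnitude loading is positive. Component selection
applies two rules in order: reject components contributing ≤ `min_var`
(default 0.05 — "more than 5%" is strict, a component at exactly 5% is
rejected); then reject components whose scores separate the two sample
groups (patient vs PDX, or human vs mouse). The separation test is not
specified in the source analysis; we use a two-sided Wilcoxon rank-sum on
scores with BH correction across the variance-surviving components (a
t-test alternative is available). Variance is tested first because it is
parameter-free and cheap; the order is configurable in effect since both
rejection reasons are reported.

Gene-set enrichment per component ranks genes by signed loading and computes
the preranked weighted Kolmogorov–Smirnov running-sum score (weight =
|loading|). The running sum is piecewise linear, so its extrema lie just
before or at hit positions; both candidate sets are evaluated, and an exact
tie between a positive and a negative extremum of equal magnitude (possible
at rational values independent of the weights) is resolved to the earlier
ranking position. The null is gene-label permutation with
p = (1 + #{|ES~perm~| ≥ |ES~obs~|}) / (1 + n~perm~), so the smallest
attainable p is 1/(n~perm~ + 1); p-values are BH-corrected across sets.
Sets intersecting the universe in fewer than 5 genes are skipped and
reported. Permutation p-values are mildly conservative because rational ES
values can tie; calibration stays within the nominal level (measured ~1.2%
rejection at a 1% KS check).

Proteomics: proteins with a missing rate strictly below 34% are kept (a
protein missing exactly 34% of samples is dropped); imputation initializes
missing cells at row means and iterates rank-`r` SVD reconstruction of the
row-centered matrix until the largest change at a missing cell is below
`tol` (default 1e-5 on the log-intensity scale, far below measurement noise)
or `max_iter` (1000). Observed cells are never modified; the default rank is
2, a required modeling choice the user should revisit for real data.

## Doubling time

Td = 1/slope of the least-squares line on (day, log2 volume) over the
observations inside the exponential window (inclusive bounds, default
200–400 mm³). Deciding window membership on raw measured volumes is biased
under multiplicative noise: near the window edges, points are included or
excluded according to the *sign of their measurement error*, which flattens
the slope — we measured a systematic +6% doubling-time bias at 5% noise.
Membership is therefore refined on the fitted curve (refit until the
membership set is a fixed point, `refine_window = 0` restores the naive
rule). The estimate is invariant to time shifts and — jointly with the
window — to volume rescaling. Degenerate inputs are flagged
(`too_few_points`, `nonpositive_slope`), never silently fitted.

## The synthetic-data generator

Every pipeline input is generated with recorded ground truth, because the
patient data this kind of study rests on are not publicly depositable. The
generator emulates, per patient: shared / relapse-gained / PDX-private
variant strata (defaults 10 / 5 / 3) with evidence fields drawn so a
configurable fraction fails each filter rule; full segmentations with
planted copy-number categories; five-tool fusion tables with planted
consensus survivors, non-survivors of each kind (too few tools; zero
junction reads) and rescue cases; and negative-binomial (dispersion 0.2)
low-rank expression.

The expression model plants: 200 ME genes (of 2,000) with patient means
50–500 and hard zeros in the PDX human fraction (an optional leakage
parameter lifts the zeros for robustness checks); a species factor loading
+1 on patient and −1 on PDX samples (amplitude 1, loading sd 0.3); a
biological factor shared per patient across all of that patient's samples
(loading sd 0.5); and a rank-3 per-patient ME program expressed coherently
by the patient sample and the mouse fraction of that patient's PDX, which is
what makes same-model samples mutual nearest neighbors in the merged
cross-species space. The factor strengths were fixed once so that the
generator meets its own contract — both planted factors carry more than 5%
of the variance (measured 12–58% across seeds), while the species factor
stays a *latent* axis rather than planting genuinely PDX-absent genes that
would contaminate the ME definition. Growth curves follow
V(t) = v₀·2^(t/Td) with mean-one multiplicative lognormal noise
(coefficient of variation `noise_cv`), volumes being positive and
measurement error proportional. Defaults follow the eight-patient design
with one patient sample, one subcutaneous PDX human fraction and one mouse
fraction per patient (8 per group).

Deliberately **not** emulated: sequencing error and quality profiles, real
genome sequence composition, alignment and quantification artifacts,
caller-specific error modes, clonal structure beyond the three planted
strata, non-exponential growth phases. Passing tests therefore demonstrate
the correctness of the rules and estimators under the stated generative
model, not robustness to every artifact of real data.

## Problem sizes and determinism

The shipped checks run on: 2,000 read pairs over 50 kb genomes (read
partitioning); 1,000 random variant calls spanning all threshold boundaries;
an exhaustive copy-number sweep (CN 0–10 × four lengths); ~600-row fusion
tables; 20 cohort seeds of 2,000 genes × 24 samples (ME recovery, component
selection); 500 null draws at 200 permutations (enrichment calibration);
20 × 400-protein matrices (imputation); 20 growth curves sampled every 0.1
day — fine enough that sampling error (~3%) sits inside the 5% recovery
contract. Every generator takes an integer seed and restores the caller's
RNG state; identical seeds give byte-identical output files, and
`run_pipeline()` writes a manifest with MD5 checksums of every output so
end-to-end determinism is checkable by re-running.

## Known limitations

* The k-mer index is for synthetic-scale references; real hg19/mm10 indexing
  needs a disk-backed structure.
* The ME-gene test assumes NB counts with per-group dispersion and
  independent genes; correlated ME programs inflate neither error rate badly
  in the planted model, but real data deserve a dedicated DE framework and
  the thresholds (`alpha`, `min_fold`, `absent_max_mean`) should be tuned.
* The fusion-type rule is an interpretation of three labels; frame and
  transcript-level consequences are out of scope.
* The separation test with 8 vs 8 samples has limited power for subtle
  species effects; a component must separate groups fairly cleanly to be
  rejected.
* Jaccard distances treat all alterations equally; no weighting by
  functional impact.
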