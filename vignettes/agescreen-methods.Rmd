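---
title: "Methods: screening transcriptional regulators of aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening transcriptional regulators of aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agescreen)
```

# Overview

`agescreen` implements a computational screen for transcription factors that
regulate aging, built from four statistical components that can be used
together or independently:

1. **ChIP-seq target calling and enrichment screening** — binding sites from a
   multi-factor compendium are filtered to *factor-specific* sites, assigned
   to genes by peak summit, and each factor's target set is tested for overlap
   enrichment with a label set (e.g. age-regulated genes).
2. **Rank-products differential expression** — replicated 3'-tag RNA-seq
   counts of a knockdown vs control are ranked by per-replicate fold-change;
   genes with consistently extreme ranks are called at a permutation-derived
   percent-false-positive (PFP) threshold.
3. **k-mer motif enrichment** — sequence words enriched in the cores of
   binding sites relative to flanking sequence, with a Fisher–Yates shuffled
   control.
4. **Gene-set expression shifts** — coordinate up/down movement of a tissue
   gene set's fold-change distribution (Kolmogorov–Smirnov), plus ΔΔCt qPCR
   utilities.

A synthetic-data module generates genomes, binding-site compendia, count
matrices and motif-planted sequences with recorded ground truth, so every
stage is testable without external downloads.

# Coordinate conventions

All intervals are **0-based half-open** internally. BED-like input is native;
GFF3 (1-based closed) is converted on read. The TSS of a minus-strand
transcript is `end - 1`, the biologically 5' base. Site significance is
stored as −log10(q), so the conventional q-value < 10⁻⁵ cutoff is a stored
value ≥ 5; readers convert raw-probability dialects on ingestion. A single
internal convention avoids off-by-one drift between the interval arithmetic
of the specificity filter, the assignment windows and sequence extraction.

# Factor-specific binding sites

Multi-factor ChIP-seq compendia contain HOT (highly occupied target) regions
bound by a large fraction of all assayed factors; such promiscuous sites are
poor predictors of factor-specific regulation. A site of factor *t* is kept
as factor-specific when

* its significance is at least `q_min` (default 5, i.e. q ≤ 10⁻⁵), and
* no base inside the site is covered by more than `max_other` (default 8)
  **distinct other factors**.

Distinctness is at the factor level: multiple sites, or assays of the same
factor at different developmental stages, count once at a base. The
implementation sums per-factor binary run-length coverages, so the value at
each base is exactly the number of distinct factors there; per-site maxima
are read off with interval views. Unit and acceptance tests compare this
against a dense per-base brute-force count.

# Summit-based target assignment

Each binding site is represented by its summit (the point of maximal read
density). A site is assigned to every transcript whose gene body contains the
summit, and to every transcript whose upstream window contains it. The
upstream window runs strand-aware from the TSS over distances of **strictly
less than** `upstream_max` (default 3000 bp; a summit at exactly 3 kb is not
assigned) and is truncated at the nearest boundary of a transcript belonging
to a *different* gene, so only the intergenic stretch up to the neighbour is
used. A neighbouring gene overlapping the TSS empties the window. Gene-level
targets are the union over transcripts.

# Overlap enrichment and the screen

Target/label overlap is tested on the 2×2 contingency table over a gene
universe (default: all genes in the annotation; a user-supplied assayed-gene
list can replace it). The exact hypergeometric (Fisher) tail is used unless
both the observed and expected overlap exceed 5, in which case the classical
chi-square approximation without continuity correction applies; degenerate
tables (an empty margin) always use the exact path. The default p-value is
the one-sided enrichment tail, since the screen asks only about enrichment;
a two-sided option doubles it with a cap at 1. Fold enrichment is
`(overlap/targets) / (labels/universe)`.

`screen_regulators()` runs the chain per dataset, excluding datasets with
fewer than `min_sites` (default 100) significant sites, and flags candidates
at `p < alpha` (default 10⁻⁵).

# Rank-products differential expression

For a balanced paired design (here triplicate treatment vs control):

1. **Major isoform**: for multi-isoform genes, only the transcript with the
   highest mean count across all samples is kept (ties: lexicographically
   smallest transcript id).
2. **Expression filter**: keep genes with ≥ `min_reads` (default 10) in
   *every* column of at least one condition; add a pseudocount of 1 to every
   retained cell.
3. **Ranks**: per replicate pair *i*, fold-change `fc = treatment_i /
   control_i` per gene; the down analysis ranks ascending (rank 1 = most
   down-regulated), the up analysis descending. Ties get average ranks — a
   deterministic choice; the rank product remains well defined.
4. **Rank product**: `RP_g = ∏_i r_{g,i}`; small RP means consistent extreme
   regulation.
5. **Permutation statistics**: each replicate's rank column is independently
   permuted `n_perm` times (default 10 000). With `c_g` the number of null
   per-gene RPs (pooled over genes and permutations) at or below `rp_g`:
   * `e_value = c_g / n_perm` — expected null count at or below this RP;
   * `p_rp = (c_g/G + 1) / (n_perm + 1)` — smoothed per-gene null
     probability;
   * `pfp = e_value / position` with `position` the 1-based rank of `rp_g`
     in the RP-sorted list (ties share the maximal position), then made
     monotone non-decreasing down the list (step-up), so the reported gene
     list at any cutoff is contiguous.
6. **Calls**: a gene is called in a direction when `pfp ≤ pfp_cutoff`
   (default 0.10) *and* its rank is in the top third (`≤ floor(G/3)`,
   non-strict at the boundary) in that direction in **every** replicate;
   genes failing only this replicate-consistency requirement are reported
   separately.

Both directions are computed in a single pass over shared permutation draws;
this halves cost and makes label-swap symmetry exact (swapping condition
labels swaps the up and down call sets bit-for-bit, which the tests assert).
One seed governs the whole fit; derived sub-streams keep independent
generators reproducible. Rank matrices are coerced to doubles before products
are formed, since integer rank products overflow 32-bit arithmetic already at
about 1300 genes with three replicates.

Fold-changes are computed on pseudocounted raw counts without library-size
normalisation: ranking within a replicate is invariant to any per-replicate
scale factor (up to pseudocount effects), so normalisation would not change
ranks for equal-depth libraries; a per-million option exists but is off by
default.

## Exactness and calibration

For small problems the permutation statistics can be checked exactly: with
*G* genes and *k* replicates, the expected null count at threshold *t* is
`G · P(∏ of k iid uniform{1..G} ranks ≤ t)`, enumerable over the `G^k` rank
combinations. This aggregation is identical to literal enumeration of all
`(G!)^k` column-permutation configurations because, for a fixed gene, each
rank combination occurs in exactly `((G-1)!)^k` of them; the test suite
proves the identity by literal enumeration at `G = 3` and then validates the
sampler at `G = 5` (all 1 728 000 configurations, within binomial error at
10 000 permutations).

On *exchangeable* complete nulls the call procedure behaves like a
Benjamini–Hochberg step-up at the PFP level per direction. A caveat the tests
document: under negative-binomial noise with a broad spread of gene means,
low-count genes have high-variance fold-changes, so a gene's ranks are
positively correlated across replicates — a dependence the column permutation
destroys. The pooled E-value is then mildly anti-conservative at the extreme
tail, and a complete-null dataset yields at least one (false) call more often
than the nominal level suggests, though the absolute false-call count stays
well below one gene per dataset and pooled false-discovery rates in the
validation runs remain far under the nominal 10%. This is intrinsic to the
rank-product statistic under heteroscedastic noise, not a property of this
implementation; the replicate-consistency filter trims but does not remove
it.

# k-mer motif enrichment

Around each summit a **core** window `[summit − w/2, summit + w/2)` (default
w = 100) and two abutting **flanks** (default 200 bp each) are extracted;
sites whose combined window would cross a chromosome boundary are dropped
(not truncated) so all sites share window denominators. Every overlapping
k-mer window is counted (default k = 7); windows containing N are skipped.
With both-strand counting (the default, as in conventional motif searches)
each window is scanned on both strands and pooled with its reverse complement
under the lexicographically smaller key, doubling the window denominator, so
enrichment of a word and of its reverse complement are identical by
construction.

Per k-mer, the 2×2 table of matching vs non-matching windows in core vs
flank gives a one-sided hypergeometric enrichment p-value; fold is the ratio
of per-window frequencies (a word absent from the flanks has infinite fold,
with the p-value still computed from the table). Window counts rather than
per-site presence populate the table by default — frequency ratios are what a
fold-enrichment of all k-mers means — and a presence/absence mode is
available as a flag. `shuffle_control()` Fisher–Yates-shuffles each core
independently (flanks untouched), preserving per-core nucleotide composition
exactly while destroying positional signal: planted-motif enrichment should
collapse toward fold 1 against this control, which the acceptance test
verifies by pooling counts over 20 regenerated replicates (pooling both
numerator and denominator keeps the small expected per-replicate hit counts
from dominating the ratio).

# Expression shifts and qPCR ratios

Per replicate pair, `lfc = log2((trt + 1)/(ctrl + 1))` is centred by
subtracting the replicate's mean over all genes; the per-gene summary is the
average centred value. Mean-centering removes global shifts — e.g.
compositional effects when a handful of extremely abundant transcripts (such
as vitellogenins) change — which is precisely the quantity of interest when
asking whether a tissue's genes move coordinately. A set's shift is tested
with a two-sample KS against the **complement** (keeping the samples
disjoint; set-vs-all is available), with direction from the difference in
medians. The threshold summary reports the percentage of set genes with
linear fold-change at or above 1.25 (inclusive).

ΔΔCt ratios use a single reference gene:
`ΔΔCt = (Ct_t,a − Ct_ref,a) − (Ct_t,b − Ct_ref,b)`, ratio `2^(−ΔΔCt)`. An
undetected target is assigned the cycle ceiling (default Ct 40) and the
result is flagged as a bound, not an estimate; an undetected reference is an
error.

# The synthetic-data generators

All generators are pure functions of their parameters and a mandatory seed
(the caller's RNG state is untouched).

* `simulate_genome()` places non-overlapping single-transcript genes with
  gamma-distributed lengths, random strands and multinomially distributed
  intergenic gaps; sequence is i.i.d. uniform A/C/G/T.
* `simulate_tf_collection()` emulates a 57-factor compendium: a `hot_fraction`
  of each factor's sites fall at shared loci (jittered ±25 bp per factor so
  per-base co-binding varies), the rest are factor-private with summits
  uniform inside randomly chosen gene bodies. One planted factor's private
  target genes enter the label set at `planted_tf_enrichment` times the
  background rate (deterministic rounding, so realised enrichment is within
  rounding of the request); all other factors are independent of the labels.
* `simulate_counts()` draws gene means from a log-normal (sdlog 1.5, a
  realistic inter-gene spread for tag counts), scales to the library size,
  multiplies planted genes' treatment means by `2^(±lfc)`, and draws
  negative-binomial counts with a shared dispersion (variance
  `μ + φμ²`, default φ = 0.1) — the standard overdispersed model for tag
  counts. Planted genes are sampled uniformly across the expression range,
  deliberately including genes below the detectability floor so the
  expression filter's interaction with calling is exercised.
* `plant_motif()` overwrites one motif copy at a uniform offset in exactly
  `round(fraction · n)` cores, recording sites and offsets.

What the generators do **not** emulate: real genome composition and repeat
structure, fragment-level read sampling, positional read-density profiles
within peaks, isoform structure (one transcript per gene), batch effects, or
the aging time course itself. Passing tests therefore demonstrate the
statistical machinery under the stated noise models, not performance on real
libraries.

# Validation problem sizes

The test suite validates: permutation statistics against exhaustive
enumeration at G = 5, k = 3; interval operations against brute-force oracles
on 1000 random instances each; the full screen on ten 57-factor compendia
(500 sites each, 30% HOT, 3-fold planted enrichment of an 1100-gene label set
in a 16 000-gene universe); DE null calibration on fifty 2000-gene null
matrices and recovery on ten 7333-gene matrices (the gene count of a typical
filtered 3'-tag experiment) with 100 + 100 planted genes at |log2FC| = 2 and
10⁶ reads per sample; motif recovery at 30% planting in 400 cores with
20-replicate shuffle pooling; and KS calibration with 200 null 300-gene draws
from a 5000-gene profile. Recovery sensitivity is measured among planted
genes that pass the expression filter: genes below the read floor in both
conditions never enter the analysis, and at this depth about 15% of the
uniformly planted genes sit below it by design; overall sensitivity including
those undetectable genes is reported alongside by the acceptance script.
Validation fits use 1000 permutations to keep runtimes modest; the analysis
default remains 10 000.

# Known limitations

* Rank-product PFP is anti-conservative on complete nulls with strongly
  heteroscedastic fold-changes (see calibration above).
* E-value resolution is `1/n_perm`; very small PFPs need large `n_perm`.
* The chi-square branch of the enrichment test is an approximation; near the
  observed/expected = 5 boundary the exact and approximate p-values differ
  slightly, and the test records which branch was used.
* The screen treats each factor×stage dataset independently; no multiple-
  testing correction is applied across the compendium beyond the stringent
  default alpha.
* Motif enrichment is word-based; degenerate motifs split across several
  k-mers and position-weight-matrix discovery is out of scope.
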