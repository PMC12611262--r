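---
title: "Methods: compartment profiling and the organ-permissive switch statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment profiling and the organ-permissive switch statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organotropism)
```

This vignette is the package's own account of its models and the
numerical and design choices behind them. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The compartment caller

The pipeline starts from a per-chromosome contact matrix binned at 250 kb
(the package's working resolution; any bin size is accepted). Four stages
follow, each an exported function so intermediates can be inspected.

**Iterative correction.** Hi-C coverage per bin confounds mappability,
restriction density and copy number with genuine contact frequency. We
balance the matrix with a symmetric Sinkhorn-style iteration: divide by
the outer product of the row marginals normalized to mean one, repeat
until the coefficient of variation of the unmasked row sums falls below
`tol = 1e-6` (cap `max_iter = 200`; non-convergence is flagged, not
fatal). For strictly positive matrices the balanced form is unique up to
a scalar, which is why an independent alternating-scaling oracle must
agree with it — the property the test suite checks. Two practical
choices: bins whose marginal is below 10% of the median marginal are
masked before iterating (ultra-sparse rows destabilize balancing and
carry no usable signal), and the output is rescaled to preserve the
input's total count so downstream scaling is well-defined.

**Scaling.** Every chromosome is then scaled so its unmasked
upper-triangle total (diagonal included) equals 1M, putting chromosomes
of different sizes and depths on one footing before eigenvector analysis.

**Observed over expected.** Contact frequency decays roughly as a power
law in genomic distance; compartment structure is the deviation from that
decay. Each entry is divided by the mean contact at its distance
(mean over unmasked pairs at that `|i - j|`, with distance taken from bin
ordinals so permuting storage order permutes the output identically).
Distances whose mean is zero have no defined ratio; since such entries
carry no signal we set them to the O/E null value 1 before the
correlation step rather than propagate NA into `cor()`.

**Eigenvector and orientation.** The compartment track is the leading
principal component of the Pearson correlation matrix of O/E columns —
the correlation step sharpens the checkerboard into a near rank-one sign
pattern. The eigenvector is returned unit-norm and unoriented: an
eigenvector's global sign is arbitrary. Orientation multiplies the track
by ±1 so its correlation with an A-compartment covariate (gene density
per bin, `gene_density()`, in real data; for synthetic panels the
indicator of constitutively-A bins, which is where the generator places
genes) is non-negative; a correlation below 0.1 in magnitude is flagged
as ambiguous. Discrete calls follow the sign convention A = positive,
B = negative; an exactly zero value has no defined sign and maps to NA
rather than being forced into either class. PC1 is the default; an
`"auto"` policy choosing among the first three components the one best
correlated with the covariate exists for chromosomes where a batch or
arm-level effect captures the first component, but it is off by default
because the planted-truth simulations never need it.

## Cross-cell-type profiling

Genome-wide tracks from many cell types are stacked into a cell-types ×
bins matrix; any bin that is NA (masked) in at least one cell type is
dropped so every entity sees the same features. Similarity between cell
types is Pearson's r across bins, converted to the distance 1 − r and
clustered with Ward linkage (`stats::hclust(method = "ward.D2")`, i.e.
Ward's criterion applied to the supplied distances). PCA is feature-wise
mean-centered without unit-variance scaling: compartment eigenvector
values share one scale, and scaling would inflate noisy bins. PCA on
continuous eigenvector values rather than discretized A/B labels keeps
compartment strength information; the discrete calls remain available for
the switch statistic. Component signs are fixed deterministically (the
largest-magnitude loading is made positive) so runs are reproducible, but
note what this does and does not give: a principal axis is identified
only up to sign, so a planted gradient is recovered as an *ordering* —
tests therefore check the magnitude of the rank correlation with the
planted EMT parameter, not its sign.

The top-k positive and negative loading bins (k = 100 by default, the
scale at which a 200-region signature is a small fraction of a genome)
are extracted with ties broken by feature ordinal, mapped to genes by
strand-agnostic half-open interval overlap (via GenomicRanges), and
compared between analyses with the asymmetric overlap fraction
|reference ∩ query| / |reference|.

## The organ-permissive switch statistic

For one organ system, each bin gets a pair state: the normal-cell letter
followed by the cancer-cell letter (AA, AB, BA, BB). When a subtype group
has several cancer lines, the consensus rule keeps a bin only if every
line yields the identical non-NA pair state — the strictest reading of
between-member consistency; a majority variant exists behind a flag.
Crossing the primary-organ pair state with a secondary organ's yields 16
categories `XY_ZW`. Two are organ-permissive: `AB_BB` and `BA_AA`, where
the primary cancer leaves its tissue-of-origin state for the state the
secondary organ holds in normal and cancer alike. These are distinct from
cancer-shared changes (`AB_AB`, `BA_BA`), and the same code computes that
fraction by substituting the label set.

The permissive fraction divides the permissive count by the number of
bins whose *primary* pair state is AB or BA — reading "fraction of the
compartment alterations in the primary cancer" literally; a
per-informative-bin denominator is exposed as an option, and per-category
percentages on both bases are always reported.

Comparing organs raises a bias: a secondary organ whose localized cancers
themselves reshuffle compartments offers more opportunity for spurious
`XY_ZW` coincidences. The adjustment estimates, per secondary organ,
p(TA|NA) — the probability that a bin A in that organ's normal cells is
still A in its localized cancer (and p(TB|NB) for B), taking the minimum
over available cell lines; each probability is subtracted from one and
multiplied with the corresponding permissive percentage: (1 − p(TA|NA))
with %BA_AA and (1 − p(TB|NB)) with %AB_BB. The pairing of each weight
with the category whose secondary state is the *stable* one is
implemented exactly as published even though its direction is not
self-explanatory; a sensitivity flag swaps to p-weighting. Adjusted and
unadjusted values are always reported side by side, and cross-organ
comparisons are restricted to bins informative in every panel so the
organs share one denominator basis.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` plants a deliberately transparent genome: alternating
A/B blocks with geometric lengths (mean 8 bins ≈ 2 Mb, matching the
multi-megabase alternation of real compartment tracks without fitting any
dataset); a disjoint partition of bins into per-organ *eligible* bins
(where that secondary organ's normal epithelium holds the opposite
state — 5% by default, the same order as the few hundred of ~12,000
genome-wide 250 kb bins at which two epithelia differ), *EMT* bins (10%)
that flip monotonically as a line's EMT parameter passes a per-bin
threshold, and *free* bins where each cancer line flips independently at
5%. Metastatic lines additionally adopt the target organ's state at
eligible bins with probability 0.5, localized lines 0.1 — the planted
contrast the recovery tests quantify. Because the three planted
mechanisms act on disjoint bin sets, every bin has exactly one planted
class per (normal, cancer) pair, which is what makes ground-truth
bookkeeping exhaustive rather than heuristic.

Contacts are Poisson draws around
`C · (|i−j|+1)^(−α) · (1 ± δ)` (same/different state), α = 1, δ = 0.3, with
C set so the expected upper-triangle total is the configured depth (1e6
per chromosome by default — a realistic per-chromosome valid-pair count
for a moderately sequenced experiment at 250 kb). Poisson rather than
negative-binomial keeps the oracle analytic; overdispersion would lower
effective depth without changing any planted expectation. Expression is
log-normal baseline (log2 mean 6, sd 1.5) with signature genes shifted
linearly in the EMT parameter by ±2 log2 units across the gradient and
negative-binomial noise (dispersion 0.1). Signature genes are placed in
constitutively-A free bins and switch bins receive only expression-flat
genes — the decoupling of transcription-EMT from compartment-EMT regions
is therefore a *design* of the generator, and the orthogonality test
shows the pipeline reports it faithfully, not that real genomes must
behave this way. The generator has no TADs, loops, copy-number changes,
translocations or single-cell sparsity; passing tests demonstrate
correctness of the statistics on compartment-scale structure, not
robustness to those confounders.

All randomness derives from one integer seed through named substreams
(label-hashed, one per cell type and stage), so adding a cell type never
perturbs another's draws.

## Problem sizes used in validation

The test suite and acceptance script run at sizes chosen to make the
statistics well-conditioned while staying desk-scale: one 400-bin
chromosome for caller recovery (20 replicates); five 400-bin chromosomes
with half the genome organ-divergent — 1000 eligible bins — for the
end-to-end metastatic-vs-localized contrast at planted rates 0.5 vs 0.1;
two-chromosome panels with a lung target and a brain decoy for cross-organ
specificity; 8-cell-type primary panels (normal + 3 localized + 4
metastatic) for the EMT gradient; and three-chromosome panels with the
full 232/193-gene signatures for the orthogonality analysis. The elevated
divergence in the end-to-end setting concentrates eligible bins so that a
four-figure eligible count fits in a small synthetic genome; the planted
rates are unaffected.

## Known limitations

- The orientation covariate (gene density) assumes gene-dense chromatin
  is A-prone; chromosomes where that correlation is weak are flagged
  ambiguous rather than silently oriented.
- The enrichment score is a deliberately specified KS-random-walk
  statistic, not a numerical clone of kernel-density GSVA
  implementations; orderings agree on planted gradients (a property the
  tests check) but absolute values may differ from other software.
- nnPCA uses sequential Hotelling deflation with a deterministic clipped-
  PC initialization; projected power iteration converges to a stationary
  point of the constrained variance problem, which for the near rank-one
  structures scored here coincides with the global axis, but no global
  optimality is guaranteed in general.
- Descriptive fractions only: the package reports permissive fractions
  and adjusted percentages without significance tests, mirroring the
  descriptive nature of the statistic it implements.
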