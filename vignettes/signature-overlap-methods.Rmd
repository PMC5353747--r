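---
title: "Rank-based overlap testing of differential expression signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based overlap testing of differential expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigoverlap)
```

## The problem

A recurring question in psychiatric and addiction transcriptomics is
whether the adult diseased brain resembles the immature brain — so-called
*pseudo-immaturity* or *dematuration*. Operationally this is asked by
comparing two differential-expression signatures: one from a
disease-versus-control contrast (for example alcoholic versus control
hippocampus) and one from a developmental contrast (infant versus adult)
on an independent dataset, often on a different microarray platform or
even a different species. If the two signatures share many more genes
than chance predicts, and the shared genes predominantly change in the
*same* direction, the disease transcriptome looks immature.

sigoverlap implements that comparison end to end: signature
construction, cross-species orthologue mapping, a rank-based running
Fisher overlap test with a four-way directional decomposition,
derivation of the concordant ("positively correlated") gene set, and a
partition of that set across three cell-type developmental signatures.

## Signature construction

Expression values are taken on the log2 scale. For each feature the two
group means are compared:

* **Signed fold change.** With ratio $r = 2^{\bar x_{\text{num}} -
  \bar x_{\text{den}}}$, the signed fold change is $r$ when $r \ge 1$
  and $-1/r$ otherwise. The magnitude is therefore always at least 1 and
  the sign encodes direction; a ratio of exactly 1 maps to $+1$. The
  numerator group is the infant (development) or patient (disease)
  group, so positive means "higher in the immature/diseased state".
* **p-value.** A two-sided Welch unequal-variance t-test. Commercial
  array pipelines say only "t-test"; Welch is the safer default when
  group variances differ and agrees with the pooled test when they do
  not. Features in which both groups are constant and equal get $p = 1$
  by convention rather than an error, so degenerate synthetic features
  flow through as non-significant.
* **Thresholds.** A feature enters the signature when
  $|\mathrm{FC}| > f$ and $p < \alpha_0$, both *strict* inequalities,
  with defaults $f = 1.2$ and $\alpha_0 = 0.05$ (uncorrected) — the
  conventional lowest-sensitivity settings for commercial microarray
  platforms. The fold-change threshold is configurable per dataset
  (e.g. 1.3 for a deeper developmental series).
* **Ranking.** The overlap test is rank-based, so the ordering must be
  deterministic: ascending p-value, ties broken by descending
  $|\mathrm{FC}|$, then lexicographic gene id.
* **Probe collapse.** When the platform reports probes, one result per
  gene is kept: the probe with the smallest p-value, ties by larger
  $|\mathrm{FC}|$, then lexicographic probe id. Gene identifiers are
  uppercased and trimmed so cross-dataset joins are reliable.

## Orthologue mapping and the background universe

Cross-species comparisons translate one signature through a two-column
orthologue table. One-to-many orthologues fan out (each target inherits
the source's statistics); many-to-one collisions are resolved by the
smallest p-value, which preserves the strongest evidence without
double-counting a target gene. Unmapped genes are dropped and the result
is re-ranked.

Every hypergeometric test needs a background population $N$. The
package's default is the orthologue-mapped intersection of the two
platforms' measured genes — the set of genes that *could* have appeared
in both signatures. A union-based background is available as an option;
it is more liberal (larger $N$ inflates enrichment), which is why
intersection is the default.

## The running Fisher test

The overlap statistic between two ranked signatures is a scan of
one-sided hypergeometric (Fisher) enrichment tails over matched ranked
prefixes:

1. Choose cutoff pairs. By default the scan takes 10 matched fractional
   cutoffs at the deciles of the shorter signature: at fraction $f_i =
   i/10$ the prefixes are the top $\lceil f_i n_q \rceil$ query genes
   and top $\lceil f_i n_r \rceil$ reference genes. When the shorter
   signature has fewer than 10 entries, every rank is scanned; a full
   per-rank scan is available via `cutoff_scheme = "per-rank"`.
2. At each cutoff pair, compute $P(X \ge k)$ for the prefix overlap $k$
   under the hypergeometric$(N, c_q, c_r)$ null.
3. Report the smallest tail, Bonferroni-corrected by the number of
   cutoffs scanned and capped at 1.

The exact scan granularity and correction used by the proprietary
correlation engines that popularised this statistic are not published;
the formulation above is a deterministic, oracle-checkable choice that
is faithful to the "repeated Fisher tests over ranked prefixes" idea,
and the cutoff scheme is pluggable. Consequently p-values printed by
such services are not expected to be reproduced digit-for-digit; counts,
directions and partition arithmetic are.

Overlap counts and gene lists are always reported at full signature
length, so the scan only affects the p-value. Swapping query and
reference leaves the overlap count unchanged; the p-value can differ
slightly because the ceilings in step 1 act on different lengths — a
documented asymmetry of prefix-matched scanning.

### Directional decomposition

Each signature splits into its up- and down-regulated halves (relative
order preserved), and the four direction pairs — (up,up), (down,down),
(up,down), (down,up) — are each tested with the same running Fisher
procedure. The four overlap sets are disjoint and partition the
undirected overlap. All four tests keep the *full* universe $N$ as
background: the published count tables that motivate this decomposition
partition the total overlap against a common background, and a
direction-restricted background would make the four p-values mutually
incomparable. Significance of the four tests is assessed at
$\alpha / 4$ (0.0125 at $\alpha = 0.05$); dataset-pair multiplicity is
corrected separately at the pipeline level with $\alpha / m$, $m$ taken
from the run configuration.

A comparison is classified **positive** when more shared genes are
concordant ((up,up) + (down,down)) than discordant, **negative** when
reversed, and **mixed** on a tie.

## Concordant biosets and cell-type contributions

The *concordant bioset* is the union of the (up,up) and (down,down)
overlap gene sets with the shared direction recorded — the genes whose
disease change mirrors their developmental change. Partitioning this
bioset across three cell-type developmental signatures (fast-spiking
interneurons, astrocytes, oligodendrocytes in the motivating analyses)
asks which cell type's maturation program the disease signature
resembles most:

* every bioset gene falls in exactly one of the $2^3 = 8$ membership
  regions (7 intersection regions plus a none-region);
* a gene is "specific to" a cell type when it lies in exactly one set;
* each set's marginal equals the sum of its four covering regions;
* percentages are computed as $100 \, k / |B|$ and rounded **half-up**
  to one decimal. Base R's `round()` rounds halves to even, which
  changes reported values exactly at the half boundary; half-up is the
  convention under which published contribution tables recompute
  exactly.
* per-cell-type direction concordance counts how many shared genes have
  the same direction in the bioset and in the cell-type signature.

## The synthetic-data generator

Real analyses of this kind rest on public microarray series; the
package instead ships a generator that emulates the statistical
structure the analysis assumes, so every stage is testable offline:

* per-gene baseline log2 intensities $\mathcal N(7, 1)$ with independent
  within-group noise of sd 0.5 — a realistic residual spread for
  RMA-summarised arrays, and large enough that two-group tests at
  $n = 10$ per group have high but not trivial power at the default
  effect size;
* a **shared program** (default 100 genes) shifted by 1.5 log2 units in
  both datasets, in the same direction with probability
  `concordant_fraction` (default 1);
* **dataset-specific programs** (default 50 genes each, disjoint) so
  signatures are not pure overlap; the defaults give signatures of
  roughly 150 genes over a 10,000-gene platform;
* three **cell-type modules** with configurable sizes and overlap
  fractions with the shared program (defaults make the FS-like module
  the dominant contributor); module genes drawn from the shared program
  inherit the development-side direction;
* an identity-like **orthologue table** with seeded one-to-many fan-out
  and missing-entry fractions;
* a **truth record** (planted memberships and directions) serialized
  alongside the data so recovery is scored against ground truth, never
  re-inferred.

Everything is reproducible bit-for-bit from the mandatory seed. The
generator deliberately does *not* simulate probe-level artifacts, batch
effects, post-mortem covariates, or correlated gene-gene noise; passing
recovery tests on these data shows the pipeline's arithmetic and
calibration are right, not that any particular biological dataset will
behave as cleanly.

## Numerical and testing choices

* Hypergeometric tails come from `stats::phyper` and are validated
  against an independent binomial-coefficient summation oracle
  exhaustively for universes up to $N = 20$, and that oracle in turn
  against full draw enumeration for small $N$.
* Tails are clamped into $(0, 1]$; a tail at the support floor is
  exactly 1.
* The vectorised Welch test is checked row-by-row against
  `stats::t.test`.
* Calibration: across 1,000 pairs of independent random 100-gene
  signatures over $N = 2000$, the fraction of running Fisher
  $p < 0.05$ stays below 0.07 (the scan correction is conservative
  because prefix tails are positively dependent; observed rates are
  near 0.01).
* Recovery: across 200 simulated studies at the default configuration,
  the derived bioset recovers at least 80% of planted concordant genes
  with correct directions, the overlap $p$ falls below $10^{-3}$, and
  the correlation classifies positive, in at least 95% of replicates.
  These problem sizes (10,000 genes, 10 samples per group) were chosen
  as representative desk-scale study conditions.

## Limitations

* The running Fisher formulation is one member of a family; services
  using different scan granularities or corrections will give different
  p-values for the same inputs (counts and gene sets agree).
* The background-universe definition materially affects p-values and is
  an explicit modelling choice, not an estimated quantity.
* The generator's independence assumptions understate the correlation
  structure of real expression data; empirical type-I error on real
  null comparisons may differ from the simulated calibration.
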