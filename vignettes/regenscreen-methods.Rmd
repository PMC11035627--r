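---
title: "Methods: regeneration-specificity screening and the developmental-shift statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regeneration-specificity screening and the developmental-shift statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenscreen)
```

## The scientific setting

Amphibian limb regeneration is widely thought to *recapitulate development*:
after wound healing and blastema formation, the regenerate re-runs much of
the transcriptional program of the embryonic limb bud. regenscreen
implements the comparative-transcriptomics computations used to probe that
idea in *Xenopus*:

1. a **three-step screen** over a fixed 12-condition bulk RNA-seq design
   that ranks genes by how *regeneration-specific* their expression is,
   culminating in an integer 0–8 specificity score; and
2. a **developmental-shift concordance statistic** that quantifies, for a
   perturbation of the adult blastema (e.g. induced expression of a
   candidate regulator), what fraction of affected genes moved *toward*
   the developmental limb-bud expression state.

Both computations sit on a small statistical substrate — TPM/CPM
normalization, log/z-score transforms, an exact negative-binomial (NB)
two-group test with Benjamini–Hochberg (BH) correction, and a
Wilcoxon-based single-cell marker test — that the package also provides.

## The 12-condition design

`default_design()` encodes the study layout: developing limbs sampled at
four timepoints in two axial regions (distal `devD1..devD4`, proximal
`devP1..devP4`) and regenerating limbs at two timepoints in the same
regions (`regD1`, `regD2`, `regP1`, `regP2`), each in triplicate. Each
regeneration condition is matched to a *corresponding* development
condition by tissue stage and shape — `regD1~devD1`, `regD2~devD2`,
`regP1~devP3`, `regP2~devP4`. The proximal pairings deliberately cross
timepoint indices: the stump of a regenerating limb resembles a *later*
proximal developmental stage, so pairing is by similarity, not by index.
Only the corresponding pairs are ever compared; regP samples are not
contrasted against devP1/devP2.

## The three-step screen

Given a gene × sample count table, a sample sheet, and gene lengths:

* **Screen 1** tests every gene within each of the four corresponding
  pairs (exact NB test, below) and keeps genes with raw `p < 0.05` in at
  least one pair. The union rule is the weakest reading of "differential
  within a corresponding pair" and is the default (`screen1_rule =
  "union"`); requiring all four pairs is available (`"all"`). Raw p rather
  than FDR is used at this step, matching the screen's original
  formulation; the threshold is exposed as `alpha`.
* **Screen 2** keeps genes *significantly higher* distally than proximally
  during regeneration in at least one of the stage-matched contrasts
  (`regD1` vs `regP1`, `regD2` vs `regP2`; `screen2_rule = "any"`, with
  `"both"` available). The direction requirement is strict: a gene higher
  in the stump is excluded no matter how significant.
* **Screen 3** assigns the specificity score. For each gene, each of the
  two regeneration-distal condition means (replicate-mean TPM) is compared
  against each of the four development-distal condition means; every
  strictly greater comparison contributes one point, for a maximum of
  2 × 4 = 8. Ties at equal means score nothing, which makes the
  constant-gene case well-defined. An optional `score_mode =
  "significant"` awards a point only when the corresponding contrast is
  also significant at `p < 0.05`; the default is the literal mean rule.

Ranking within a score is by the worst-case **relative margin**
`min over r of [log2(mean_r + 1) − log2(max_d mean_d + 1)]`, then by gene
id. The margin is deliberately on the log scale: an absolute-TPM margin
makes the ranking abundance-weighted, so a noisy, highly expressed gene
that barely clears the dev-distal means can outrank a genuinely
regeneration-specific gene of modest expression. On simulated data with
planted regeneration-specific genes the absolute margin demotes several
planted genes below abundance-driven false positives, while the relative
margin separates them cleanly; the log-scale margin is therefore the
package default. The point score itself is unaffected by this choice.

`run_screen_pipeline()` chains the three steps and guarantees nesting:
scored ⊆ screen-2 ⊆ screen-1 ⊆ all genes.

## Differential expression on counts

`de_test()` implements an exact conditional NB test:

* **Library-size normalization** uses median-of-ratios size factors
  against the geometric-mean reference (the DESeq convention), falling
  back to total-count scaling when fewer than 50 genes have all-positive
  counts — the degenerate-input path is defined rather than accidental.
* **Dispersion** is a single per-contrast value estimated by pooled method
  of moments on the normalized counts (`E[var] = μ + φμ²`, corrected for
  the sampling variance of the mean), floored at `1e-4`. With thousands of
  genes the pooled estimate is tight; tagwise shrinkage is out of scope.
* **The test** conditions on the total of the (rounded) normalized group
  sums. For NB variables with a common mean and dispersion, the group-B
  sum given the total follows a negative-hypergeometric (beta-binomial)
  law with shapes `n_a/φ`, `n_b/φ`, free of the unknown mean. The
  two-sided p-value is the "doubletail" sum of all outcome probabilities
  no larger than the observed one. Totals up to 20 000 are enumerated
  exactly (via a two-`lgamma` identity when the group sizes are equal);
  beyond that the same conditional law is approximated by a
  continuity-corrected Gaussian, where the discrete distribution is
  effectively continuous and the approximation error is far below any
  decision threshold used here.
* **Fold changes** are `log2((mean_B + 0.5)/(mean_A + 0.5))` on normalized
  counts; the 0.5 pseudocount keeps log-ratios finite at zero counts.
* Genes with zero counts in every column are excluded from the BH family
  and reported with `p = fdr = 1`, keeping the tested family well-defined.

A Welch t-test on `log2(normalized count + 1)` is available as
`method = "t"` for speed; because `de_test()` operates on counts without
gene lengths, the log-CPM scale is used (gene-length division would cancel
within a gene anyway, so the test statistic is unchanged for shared
lengths). On null NB data (3 vs 3, dispersions 0.01–0.5) the exact test's
empirical type-I error sits near the nominal 5 % (measured 4–6 % across
seeds in the acceptance suite); low-count genes make it mildly
conservative, as expected for a discrete exact test.

`bh_adjust()` exposes the standard step-up BH adjustment (delegating to
`stats::p.adjust`); the test suite verifies it against an independent
quadratic-time oracle.

## The shift analysis

The reference contrast is single-cell: limb-bud cells (`reference`) versus
froglet blastema cells (`contrast`). `sc_find_markers()` CPM-normalizes per
cell and applies a two-sided Wilcoxon rank-sum test per gene, implemented
as the tie- and continuity-corrected normal approximation (vectorized; it
matches `stats::wilcox.test` to ~1e-8 on small cases). A gene passes as a
marker when (i) BH FDR < 0.01, (ii) the natural-scale fold change
`(mean CPM_ref + 1)/(mean CPM_con + 1)` exceeds 2 in either direction —
the fold threshold is read on the natural scale, equivalently
`|log2FC| > 1` — and (iii) it is detected in at least 10 % of cells *in
both populations*. The both-population reading follows the stated "in each
cell population" criterion; the common tool convention (either population)
is available via `pct_rule = "either"`. The pseudocount of 1 in the fold
bounds log-ratios; the exact pseudocount used by upstream tools is not
standardized, and the choice only matters for genes near the threshold.

`zscore_profiles()` subsamples 1000 cells per population without
replacement (a single stated seed), z-scores each gene's `log2(CPM+1)`
across the pooled 2000 cells, and reports the per-population mean
z-scores. Because the z-scoring is pooled,
`n_ref·z̄_ref + n_con·z̄_con = 0` holds per gene — a checked invariant.

The perturbation contrast is bulk: `bulk_deg_tg()` runs `de_test()`
(control vs transgenic) and keeps genes at FDR < 0.01 with the sign of the
Tg-over-control fold change as the perturbation direction. The DE engine
here is the package's exact NB test: the quantity being reproduced is the
intersection-and-concordance statistic, not any particular DE
implementation, and the engine is pluggable (`method = "t"`).

`shift_consistency()` intersects passing markers with the Tg DEG set and
calls a gene **concordant** when the two signs agree — i.e. the transgene
moved it toward the limb-bud state. The headline statistic is the fraction
of concordant genes among the common set; sign agreement only, with no
magnitude weighting, because the scientific claim is directional. With an
empty intersection the fraction is reported as `NA` with a warning rather
than a silent 0.

## Projection utilities

`pca_samples()` is SVD-based PCA with samples as observations over a gene
subset (typically z-scored DEGs), with a deterministic sign convention
(largest-magnitude loading positive per component) so output files are
bit-stable. `gene_panel_heatmap_values()` reproduces, for an explicit
patterning-gene panel, exactly the values `log_z()` would give restricted
to that panel — an identity the tests assert.

## The synthetic-data generators

The generators produce data with the statistical structure the analysis
assumes, with planted ground truth for every downstream stage. They are
pure functions of `(params, seed)`: one master seed per dataset,
per-column sub-seeds derived deterministically, so identical inputs give
bitwise-identical outputs regardless of generation order.

* **Counts** are NB with `variance = μ + φμ²`; `φ = 0` degenerates to
  Poisson, a testable limit. The default `φ = 0.1` is a typical bulk
  RNA-seq biological-replicate dispersion; no dispersion estimate is
  published for the motivating datasets, so this is a package default, not
  a data-derived value.
* **Bulk** (`simulate_bulk()`): baseline relative abundances are
  log-uniform over three orders of magnitude, library sizes log-normal
  with mean 1e6 and CV 0.1, three replicates per condition. Planted
  classes: `regspecific` genes elevated (default 8-fold) only in
  `regD1`/`regD2`; `distal_shared` genes elevated in all distal columns of
  both processes (patterning genes shared by development and
  regeneration); `proximal` genes elevated in all proximal columns. Gene
  lengths are log-uniform over 200–10 000 nt and emitted alongside the
  counts, since TPM needs them and annotation is out of scope.
* **Single cell** (`simulate_sc()`): two populations, log-normal capture
  depths (mean 2000 counts/cell, CV 0.3), optional extra Bernoulli
  dropout. Planted markers draw their baseline abundance from the
  expressed part of the range (weights 10–1000): a marker is by definition
  a detectably expressed gene, and a "marker" planted at one count per
  hundred cells would be undetectable by construction rather than by
  statistical failure.
* **Paired shift data** (`simulate_shift_pair()`): `n_common_genes`
  (default 2000, the scale of the 7-dpa common set) are differential in
  both the single-cell and the bulk Tg contrast; each gets a random
  single-cell direction, and with probability `concordance_rate` the Tg
  effect (default 2 log2 units at 4 vs 4 replicates) points the same way.
  400 cells per population keep the Wilcoxon powerful while holding the
  whole generator + analysis cycle to a few seconds.

What the generators do *not* emulate: batch effects, gene–gene
correlation, multi-lineage single-cell structure, ambient RNA, or
length-dependent quantification bias. Passing tests therefore demonstrate
that the implementation recovers planted truth under the assumed model,
not that the model captures every feature of the motivating datasets.

## Numerical choices and problem sizes

* z-scores use the population (n-denominator) standard deviation, the
  heatmap convention; constant genes map to zero rather than NaN.
* TPM/CPM columns sum to 1e6 within 1e-9 relative tolerance; all-zero
  columns stay zero with a warning.
* The exact-test enumeration limit (20 000) and the Gaussian tail beyond
  it were chosen so a 5000-gene, 6-sample contrast runs in a few seconds
  with no visible effect on calibration.
* The test and acceptance suites run the screen at its design scale
  (5000 genes, 20 planted regeneration-specific, 10 seeds) and the shift
  recovery at 2000 common genes over 10 seeds; the whole suite completes
  in a couple of minutes on one core. These sizes are the package's
  validation conditions, chosen to make Monte-Carlo tolerances (binomial
  standard errors around 0.01) meaningful.

## Known limitations

* The DE test uses a common dispersion per contrast; genes with atypical
  dispersion are tested at the pooled value (edgeR-style tagwise
  moderation is deliberately out of scope).
* Marker detection assumes two pre-QC'd cell populations; doublet removal
  and clustering are upstream concerns.
* The screen's survivor counts depend on data scale and noise; only the
  structure of the screen (nesting, score bounds, planted-gene recovery)
  is validated, not any particular survivor count from the motivating
  study, which would require re-running from the archived reads.
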