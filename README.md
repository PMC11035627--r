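# regenscreen

Comparative-transcriptomics toolkit for asking how limb regeneration
re-runs the developmental program — and which genes do so in a
*regeneration-specific* way.

## The problem

In *Xenopus*, a regenerating larval limb blastema re-establishes much of
the limb bud's transcriptional state. Two computations make that idea
quantitative:

**1. The regeneration-specificity screen.** Bulk RNA-seq covers a fixed
12-condition design: developing limbs at four stages × {distal, proximal}
(`devD1..devD4`, `devP1..devP4`) and regenerating limbs at two stages ×
{distal, proximal} (`regD1..regP2`), in triplicate. Each regeneration
condition has a *corresponding* development condition matched by tissue
stage (`regD1~devD1`, `regD2~devD2`, `regP1~devP3`, `regP2~devP4`). The
screen proceeds in three steps:

1. genes differential (raw p < 0.05, exact negative-binomial test) within
   at least one corresponding pair;
2. of those, genes significantly higher in the distal blastema than the
   proximal stump during regeneration;
3. for survivors, a specificity score
   `S(g) = Σ_{r ∈ {regD1,regD2}} Σ_{d ∈ {devD1..devD4}} 1[ TPM̄_r(g) > TPM̄_d(g) ]`,
   an integer 0–8 counting how many regeneration-vs-development distal
   comparisons favour regeneration. Genes are ranked by score, ties broken
   by the worst-case log-scale margin.

**2. The developmental-shift statistic.** Given (a) single-cell markers
separating developing limb-bud cells from froglet blastema cells (Wilcoxon
rank-sum on CPM; FDR < 0.01, fold change > 2, detected in ≥ 10 % of cells
in each population) and (b) bulk DEGs between transgenic and control
blastema (FDR < 0.01), the statistic is the fraction of genes in the
intersection whose transgene-induced direction of change matches the
limb-bud-vs-blastema direction — the fraction of the perturbation's effect
that points *toward the developmental state*.

A synthetic-data module (`simulate_bulk()`, `simulate_sc()`,
`simulate_shift_pair()`) generates negative-binomial datasets with planted
ground truth for every stage, so the whole pipeline is testable without
downloading anything.

## Worked example

```r
library(regenscreen)

# a 1000-gene dataset with 8 planted regeneration-specific genes
sim <- simulate_bulk(bulk_sim_params(n_genes = 1000, n_planted_regspecific = 8,
                                     n_planted_distal_shared = 20,
                                     n_planted_proximal = 20), seed = 42)
fit <- run_screen_pipeline(sim$counts, sim$samples, sim$lengths, top_k = 10)
glance(fit)
#> # A tibble: 1 × 5
#>   n_genes n_screen1 n_screen2 n_scored max_score
#>     <int>     <int>     <int>    <int>     <int>
#> 1    1000       193        30       30         8
head(tidy(fit), 3)
#> # A tibble: 3 × 6
#>   gene_id score margin  rank passed_screen1 passed_screen2
#>   <chr>   <int>  <dbl> <int> <lgl>          <lgl>
#> 1 g00362      8   2.77     1 TRUE           TRUE
#> 2 g00847      8   2.61     2 TRUE           TRUE
#> 3 g00599      8   2.61     3 TRUE           TRUE
```

1000 genes shrink to 193 after screen 1 and 30 after screen 2; the top of
the ranking is the maximal score 8 (both regeneration-distal means above
all four development-distal means), and all 8 planted
regeneration-specific genes land in the top 10. `autoplot(fit)` draws the
score distribution.

The shift statistic on a paired single-cell + transgenic-bulk simulation
with a planted 80 % concordance rate:

```r
shift <- simulate_shift_pair(shift_sim_params(n_common_genes = 500,
                                              n_null_genes = 200,
                                              n_cells_per_population = 300),
                             seed = 42)
rep <- shift_consistency(sc_find_markers(shift$sc$counts, shift$sc$cells),
                         bulk_deg_tg(shift$bulk$counts, shift$bulk$samples))
rep
#> <shift_report> |DEG_bl-dev| = 500, |DEG_Tg| = 501, common = 500, concordance = 0.814
```

The estimated concordance (0.814) recovers the planted rate within
binomial noise; `tidy(rep)` gives the per-gene direction table and
`autoplot(rep)` the fold-change scatter coloured by concordance.

See `vignette("regenscreen-methods")` for the model, its assumptions, and
every numerical choice.

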