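# cellstab

Linking predicted protein stability changes to cellular abundance,
degradation and pathogenicity.

## What this is for

Many disease-causing missense variants do not break a protein's active
site — they destabilise its fold, and the cell's protein quality control
(PQC) machinery degrades the partially unfolded product. When that is the
mechanism, a computable quantity — the predicted change in folding free
energy on mutation, ΔΔG (kcal/mol, positive = destabilising) — becomes a
predictor of steady-state abundance, half-life, complex formation,
residual function, and pathogenicity. `cellstab` is for researchers who
have per-variant ΔΔG predictions from structure-based calculators (and,
optionally, a multiple sequence alignment) and want to run that chain of
inference end to end. The bundled example dataset is a 24-variant panel of
human MSH2, the mismatch-repair protein mutated in Lynch syndrome.

At its core are three components:

1. **A two-state thermodynamic model.** With folding free energy
   ΔG = RT ln([Unf]/[Fold]) (negative = folded), a mutant has
   ΔG_Mut = ΔG_WT + ΔΔG and fraction folded
   f(ΔΔG) = 1/(1 + exp((ΔG_WT + ΔΔG)/RT)). Steady-state abundance
   relative to wild type is f(ΔΔG)/f(0); percent survival under a
   selective challenge interpolates between a folded and an unfolded
   anchor variant. The one free parameter, the *effective* cellular
   stability ΔG_WT, is estimated by least squares with a seeded
   case-resampling bootstrap (`fit_dg_wt()`, `fit_survival()`,
   `degradation_threshold()`).
2. **A covariation scorer.** A pairwise maximum-entropy (Potts) model of
   a sequence alignment, E(s) = Σᵢ hᵢ(sᵢ) + Σᵢ<ⱼ Jᵢⱼ(sᵢ,sⱼ), fit by
   L2-regularised pseudolikelihood, with the independent-site
   conservation model as baseline. Variants are scored by the
   wild-type-minus-mutant log-likelihood difference (positive = damaging)
   (`fit_potts()`, `fit_independent()`, `score_variants()`,
   `sample_msa()`).
3. **Evaluation machinery.** Mann-Whitney AUC/ROC with tie half-credit,
   leave-one-out threshold accuracy, one-sided bootstrap and exact/Monte
   Carlo permutation group tests, correlation, and allele-frequency bin
   summaries (`roc_curve()`, `loo_accuracy()`, `bootstrap_group_diff()`,
   `permutation_group_diff()`, `frequency_vs_ddg()`).

Alongside these sit parsers/aggregators for saturation-mutagenesis ΔΔG
tables (replicate-within-chain averaging, lowest-k-of-n energies,
heat-map export with display capping) and fully seeded synthetic-data
generators (`synthetic_config()`, `gen_ddg_matrix()`, `gen_phenotypes()`,
`gen_labels()`, `gen_frequencies()`) that emulate the statistical
structure the analysis assumes, so every estimator is validated by
parameter recovery without any external download.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `augment()` on fitted objects, `autoplot()` on fits and ROC
curves.

## Worked example

Reanalysing the bundled MSH2 panel and recovering a known effective
stability from synthetic abundance data:

```r
library(cellstab)
library(dplyr)

t1 <- msh2_variants()

# disease-linked variants are far more destabilised than average
subset_mean_ddg(t1, patient_found)
#> # A tibble: 1 × 3
#>       n mean_ddg sem_ddg
#>   <int>    <dbl>   <dbl>
#> 1     9     9.13    2.29

# variants that still bind MSH6 are only mildly destabilised
subset_mean_ddg(t1, msh6_interaction == "yes")
#> # A tibble: 1 × 3
#>       n mean_ddg sem_ddg
#>   <int>    <dbl>   <dbl>
#> 1    18     5.12    1.45

# stable variants (ddG < 3 kcal/mol) live longer than destabilised ones
v <- msh2_variants(include_wt = FALSE)
bootstrap_group_diff(v$half_life_h[v$ddg < 3],
                     v$half_life_h[v$ddg >= 3], seed = 1)
#> group test (mean_diff, one_sided (mean_a > mean_b)): statistic = 6.625,
#>   p = 0.0021 (n = 10000 resamples)

# recover a known effective stability from synthetic abundance data
cfg <- synthetic_config(seed = 1, dg_wt_true = -3.0)
ph  <- gen_phenotypes(tibble(variant = v$variant, ddg = v$ddg),
                      cfg, include_wt = FALSE)
fit <- fit_dg_wt(ph, n_bootstrap = 1000, seed = 2)
fit
#> abundance fit: dG_WT = -3.10 +/- 0.13 kcal/mol (bootstrap sd, n = 1000, seed 2)
#>   25-75%: [-3.18, -3.03]   2.5-97.5%: [-3.37, -2.86]

degradation_threshold(fit)
#> # A tibble: 1 × 4
#>   threshold_ddg lo_95 hi_95 boundary
#>           <dbl> <dbl> <dbl> <lgl>
#> 1          3.11  2.87  3.37 FALSE
```

Reading the numbers: the nine patient-found variants average
ΔΔG ≈ 9 kcal/mol against ≈ 5 kcal/mol for variants that retain MSH6
binding; variants below 3 kcal/mol of destabilisation have roughly twice
the half-life of those above it (one-sided bootstrap p ≈ 0.002); the fit
recovers the configured ΔG_WT = −3.0 kcal/mol within its bootstrap error;
and a destabilisation of ~3.1 kcal/mol is enough to halve the
steady-state level — the practical degradation threshold.

See `vignette("stability-and-cellular-fate")` for the models,
assumptions, numerical choices, and what the synthetic generators do and
do not emulate.

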