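---
title: "From predicted stability changes to cellular fate: the models behind cellstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From predicted stability changes to cellular fate: the models behind cellstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellstab)
library(dplyr)
```

## The problem

Missense variants of uncertain significance are the central obstacle to
using gene panels diagnostically. For proteins under surveillance by the
cellular protein quality control (PQC) system — the mismatch-repair factor
MSH2, mutated in Lynch syndrome, is the motivating example bundled with
this package — many disease alleles do not destroy an active site. They
destabilise the fold, the PQC machinery recognises the partially unfolded
protein, and the proteasome removes it. If that is the dominant mechanism,
then a purely computational quantity, the predicted change in folding free
energy (ΔΔG, kcal/mol, positive = destabilising), should predict cellular
abundance, turnover, complex formation, residual function, and ultimately
pathogenicity. `cellstab` packages the chain of analyses needed to test
and exploit that idea.

## The two-state thermodynamic model

The core model treats each protein as two-state: folded or unfolded, with
folding free energy ΔG. We use the folding sign convention

> ΔG = RT ln([Unf]/[Fold]),  negative ΔG = mostly folded,

so a mutant has ΔG~Mut~ = ΔG~WT~ + ΔΔG and equilibrium fraction folded

> f(ΔΔG) = 1 / (1 + exp((ΔG~WT~ + ΔΔG)/RT)).

One sometimes sees the relation printed with the opposite sign on the
logarithm while stable proteins are still assigned negative ΔG; we fixed
the convention above because it is the only one under which a negative
effective ΔG~WT~, a drop in abundance beyond ΔΔG ≈ −ΔG~WT~, and a
monotone decreasing level–ΔΔG curve are all simultaneously true.

Two cellular observables are tied to f:

* **steady-state abundance** relative to wild type is assumed proportional
  to fraction folded: `predicted_level(ddg) = f(ddg)/f(0)`;
* **residual function**, read out as percent cell survival under a
  DNA-alkylating challenge, interpolates between two anchor measurements:
  `s(ddg) = s_unf + (s_fold − s_unf) · predicted_level(ddg)`. The folded
  anchor is the wild type (fully functional mismatch repair, so cells
  die: low survival) and the unfolded anchor a variant destabilised
  enough to have lost all function (cells survive).

The single free parameter in each case is the *effective* wild-type
stability ΔG~WT~ — effective because it absorbs interactions with partner
proteins and the vigilance of the PQC system, and need not equal the
in-vitro stability. `fit_dg_wt()` and `fit_survival()` estimate it by
ordinary least squares on the linear abundance / survival scale
(densitometry ratios and colony counts live on linear scales, and the
data are too few to support a heteroscedastic error model).

### Numerical choices

* The 1-D objective is minimised with `stats::optimize` on a bounded
  interval, default [−15, +5] kcal/mol; estimates within 10⁻⁴ of a bound
  are flagged (`at_bound`). The tests verify equality with an exhaustive
  grid search at 10⁻³ kcal/mol resolution.
* Constants default to R = 1.987×10⁻³ kcal/(mol·K) and T = 310.15 K
  (37 °C culture); both are arguments, and 302.15 K reproduces the 29 °C
  condition used in temperature-shift experiments.
* Uncertainty is a nonparametric case-resampling bootstrap: resample
  variants with replacement at full dataset size, refit, report the
  standard deviation of the bootstrap estimates plus 25–75 and 2.5–97.5
  percentile bands (the interquartile band matches the convention of
  plotting a central band around the fitted curve). 5,000 refits by
  default; all resampling is seeded. A subsampling mode
  (`resampling = "subsample"`, fraction 0.8 without replacement) is
  provided because "random subsets" can also be read that way, but with
  replacement is the default: it is the standard bootstrap and requires
  no extra tuning parameter.
* The wild type enters the fit as a data point (ΔΔG = 0, level 1) only
  if the caller includes that row — nothing is injected silently.
* `degradation_threshold()` reports the ΔΔG at which predicted level
  falls to one half, solved by `stats::uniroot` at 10⁻⁹ tolerance and
  propagated through every bootstrap draw. A wild type with ΔG~WT~ ≥ 0
  (not mostly folded) makes "half the wild-type level" degenerate; the
  result is flagged `boundary` rather than suppressed.

```{r thermo-example}
m <- thermo_model(dg_wt = -3.1)
fraction_folded(m, 0)       # a stable wild type is ~99% folded
predicted_level(m, 3.1)     # +3.1 kcal/mol halves the steady-state level
degradation_threshold(-3.1)
```

## Covariation scoring of variants

Independently of structure, a deep multiple sequence alignment constrains
which substitutions a fold tolerates. `cellstab` implements the pairwise
maximum-entropy (Potts) family:

> E(s) = Σ~i~ h~i~(s~i~) + Σ~i<j~ J~ij~(s~i~, s~j~),

with the independent-site model (all J = 0, fields = log column
frequencies) as the conservation baseline. A variant's score is the
wild-type-minus-mutant energy difference with all other positions fixed
to the query sequence — positive = damaging. Scores are invariant under
gauge transformations; models are stored in the zero-sum gauge.

Choices a user may care about:

* **Alphabet**: 21 states (20 amino acids + gap) during fitting; variants
  are scored only at non-gap query columns, and positions outside the
  alignment return `NA` ("no prediction"), never 0.
* **Fitting**: L2-regularised pseudolikelihood, one multinomial logistic
  regression per column (asymmetric fit, coupling blocks symmetrised
  afterwards), L-BFGS-B with projected-gradient tolerance 10⁻⁵;
  non-convergence is an error carrying the residual gradient norm, not a
  warning. Defaults λ_h = λ_J = 0.01 per block are conventional
  magnitudes for pseudolikelihood DCA-type fits.
* **Sequence weights**: the usual inverse-neighbour weighting at 80%
  identity (`compute_weights`) corrects phylogenetic redundancy in real
  alignments. For synthetic alignments Gibbs-sampled from a known model
  the rows are independent draws, so the recovery experiments use
  `uniform_weights()` — reweighting i.i.d. samples only adds estimation
  noise.
* **Sampling**: `sample_msa()` is a single-chain Gibbs sampler (default
  200 burn-in sweeps, thinning 5), seeded; it exists so that fitting can
  be validated by parameter recovery rather than against any particular
  published alignment, whose depth and filtering are rarely reported.

The recovery experiment the tests run: sample 2,000 sequences from a
known L = 8, 4-state model containing one strongly coupled column pair,
refit by pseudolikelihood, and compare all 24 single-substitution scores
of the query. Spearman correlation with the true-model scores is ≥ 0.9
and the planted pair carries the largest coupling Frobenius norm. Small L
and alphabet keep this inside a few CPU-seconds while exercising every
code path that a protein-scale fit would use.

## Evaluation machinery

* `roc_curve()` computes AUC as the normalised Mann-Whitney U with ties
  half-credited (verified against `wilcox.test` on random inputs), and
  the curve by threshold sweep. Orientation flags let predictors where
  *low* scores mean damaging join the same comparison.
* `loo_accuracy()` is leave-one-out threshold classification: the
  threshold maximising balanced accuracy on the training fold classifies
  the held-out variant; candidates are observed scores, midpoints between
  adjacent scores, and +∞; among ties the smallest wins, and scores at
  the threshold classify pathogenic (screening-conservative).
* `bootstrap_group_diff()` is the one-sided resampled comparison of group
  means; `permutation_group_diff()` enumerates all label assignments
  exactly when there are at most 10⁵ of them, else uses seeded
  Monte-Carlo with the add-one correction; two-sided by default. The
  bundled panel's half-life contrast is one-sided (the claim is
  directional: stable variants live longer); interaction and turnover
  contrasts are two-sided.
* Variants with ΔΔG exactly at a group boundary (the panel's L75K at
  3.0 kcal/mol) belong to the high/destabilised group: boundaries are
  `>= cutoff` throughout.
* `correlation_r2()` reports the squared Pearson correlation with the
  two-sided t-transform p-value; `frequency_vs_ddg()` summarises ΔΔG
  quartiles per allele-frequency bin (type-7 quantiles, empty bins
  reported with n = 0 rather than dropped).

## What the synthetic generators emulate — and what they do not

All end-to-end claims in the test suite run on data from
`synthetic_config()` + `gen_*()`, seeded and pure. Defaults, chosen once
to resemble saturation-mutagenesis datasets of globular proteins:

| knob | default | why |
|---|---|---|
| ΔΔG bulk | Normal(0.5, 0.8²) kcal/mol | most substitutions are nearly neutral |
| ΔΔG tail | 2 + Gamma(2, 3) kcal/mol | destabilising right tail |
| tail probability | 0.35 buried / 0.08 exposed | packing dominates destabilisation |
| burial fraction | 0.3 | typical globular core |
| proline penalty | +2 kcal/mol | backbone constraint |
| ΔG~WT~ (truth) | −3.0 kcal/mol | marginal effective stability |
| level noise | lognormal σ = 0.15 | multiplicative blot error |
| survival noise | ±5 points, clipped | colony-count error |
| half-life map | t½ = 19 h · (0.15 + 0.85 · level) | monotone, saturating |
| label noise | 0.1 flip probability | imperfect clinical labels |
| allele frequency | log10 f = −3 − 0.5·max(ΔΔG,0) + N(0,1) | selection against unstable alleles |

These reproduce the *statistical shape* the analysis assumes: a
near-zero bulk with a destabilising tail whose dataset mean lands between
1 and 3 kcal/mol, abundances that follow the two-state curve, labels that
are thresholded stability plus noise, and common alleles that look
stable. They deliberately do **not** model: prediction error of any
specific energy function, local (sub-global) unfolding, PQC recognition
of specific degrons, variants that are functionally dead but stable
(active-site mutations), or linkage between positions. Passing recovery
tests therefore demonstrates that the estimators are correct and well
calibrated under the model's own assumptions — not that the two-state
assumption holds for any particular protein; for real data that case
must be made by the fit quality itself.

The half-life map in particular is a device for exercising the group
tests, not a kinetic model of degradation; turnover is analysed
statistically, never mechanistically.

## Problem sizes and determinism

The shipped tests use: the bundled 24-variant MSH2 panel for all
reanalysis checks; 855 positions (16,245 variants) for saturation-scale
counts; n = 24 with 200 bootstrap refits × 50 seeds for abundance
recovery (observed |bias| < 0.2 kcal/mol, 95%-band coverage ≥ 90%);
n = 8 × 50 seeds for survival recovery; 2,000 sequences for the
covariation recovery. These sizes make the full suite run in well under
a minute of fitting time while leaving every estimator's error visibly
smaller than the scientific tolerances quoted. Every stochastic routine
takes an explicit seed and is bit-reproducible given one; nothing draws
from an unseeded stream.

## Known limitations

* The abundance model saturates: once a variant is destabilised well past
  −ΔG~WT~, predicted level is ~0 and additional ΔΔG carries no
  information — fits are driven by the variants near the transition.
* The survival fit inherits its scale entirely from two anchor
  measurements; anchor noise propagates into ΔG~WT~ and equal anchors are
  refused as degenerate.
* Pseudolikelihood fitting at full protein scale (L ≈ 10³, q = 21) is
  outside the intended envelope of this pure-R implementation; the
  design target is alignments of up to a few hundred columns.
* The bundled panel transcribes half-lives at integer-hour precision;
  group statistics quoted from it carry that granularity.
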