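---
title: "Methylation aging analysis and epigenetic clocks with methylAging"
author: "methylAging authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation aging analysis and epigenetic clocks with methylAging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylAging)
```

## Scope and model

methylAging analyses aging signatures in DNA methylomes profiled by
long-read modified-base calling, covering both N6-methyladenine (6mA, mod
code `a`) and 5-methylcytosine (5mC, mod code `m`). The unit of observation
is a site x modification x strand record from an 18-column bedMethyl
pileup table: a valid read count, a modified read count, and their ratio,
the methylation fraction. Strands are never collapsed — 6mA carries no
palindromic-context constraint, so plus- and minus-strand calls at the same
position are distinct sites. Coordinates are 0-based half-open throughout,
and the printed percent column of a pileup is always recomputed from counts
so rounding never propagates.

The analysis chain is:

1. **Ingestion and filtering** (`readBedMethyl`, `filterCoverage`,
   `buildMethylMatrix`). Sites below the coverage threshold (default 10X)
   are removed per sample; the multi-sample matrix keeps only sites
   observed in *every* sample — dropping incomplete sites rather than
   imputing them avoids fabricating signal at the very small cohort sizes
   this design targets. The container is a `MethylExperiment`
   (a `RangedSummarizedExperiment` with `fraction` and `coverage` assays).
2. **Differential methylation** (`callDMS`). Replicate counts are pooled
   within each group and each site is tested with a two-sided Fisher's
   exact test on the modified/canonical 2x2 table, with
   Benjamini-Hochberg FDR control per modification channel (default
   q < 0.05). The effect size is old-group minus young-group pooled
   fraction, so positive means hypermethylation with age. A beta-MAP score
   (posterior mode difference under a uniform prior) is carried as a
   descriptive effect-confidence summary. Pooling mirrors count-based
   differential callers and maximizes the information in ~150 reads per
   group; a per-replicate Welch t-test is available as a sensitivity
   option (`method = "ttest"`).
3. **Entropy** (`siteEntropy`, `entropyProfile`). Binary Shannon entropy
   per site, base 2 so values normalize to [0, 1]; a sample's methylomic
   entropy is the mean over a site set (genome-wide or DMS-restricted).
   Because the sample statistic is a plain mean of per-site normalized
   entropies, the base-2 per-site form composes to the same genome-
   normalized quantity used in the epigenetic-aging literature; natural
   log is available behind a flag.
4. **Rate of change** (`siteRegressionAll`, `meanROC`). Per-site OLS of
   methylation level (percent) on age in weeks; sites are retained when
   the slope p-value is below 0.05 and R² exceeds a threshold. Both 0.65
   (the default) and 0.5 are conventional choices; the threshold is a
   parameter and neither value is treated as canonical.
5. **Clocks** (`trainClock` and friends). Three penalized linear clocks:
   elastic net (alpha = 0.5) on genome-wide levels, ridge (alpha = 0) on
   DMS levels, elastic net on DMS entropies. Training uses nested
   leave-one-out cross-validation on the training split only: the outer
   loop produces unbiased cross-validated metrics (MAE in days, MRE as a
   percent of chronological age, Pearson r) and per-fold feature counts;
   the inner loop selects the penalty by leave-one-out MSE. The final
   model is refit on all training samples at the penalty chosen by a
   full-training LOOCV. Keeping the held-out test split outside every fit
   is what makes the test metrics honest at n = 15; running LOOCV across
   all 15 samples and also testing on 5 of them would leak.
6. **Significance, stability, deceleration**. A permutation test (default
   100 shuffles of the ages, full nested procedure rerun each time,
   add-one p estimator so p is never 0) guards against the tiny-n clock
   looking good by chance. Feature-selection stability is the CV (%) of
   nonzero-feature counts across outer folds (sample-SD convention,
   population-SD also reported; ridge models return 0 with an explanatory
   flag since they select nothing). `ageDecelerationTest` applies a
   trained clock to treated and control arms of equal chronological age
   and tests the predicted-age shift with the gated group comparison.

The gated comparison (`compareGroups`) runs one-way ANOVA with Tukey HSD
when every group passes Shapiro normality and mean-centered Levene
homoscedasticity at alpha = 0.05, otherwise Kruskal-Wallis with pairwise
Wilcoxon tests, BH-adjusted. The branch taken is data-driven and always
reported; BH is used for the nonparametric post hoc for consistency with
the differential-methylation procedure.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_cov` | 10 | minimum valid reads per site and sample (X) |
| `fdr` | 0.05 | BH q-value threshold for DMS |
| `roc_p`, `roc_r2` | 0.05, 0.65 | ROC retention filters |
| `n_train` | 10 of 15 | stratified training-split size |
| alpha | 0.5 / 0 | elastic-net / ridge mixing, fixed per clock type |
| penalty path | 100 values, `1e-4` ratio | log-spaced from the all-zero elastic-net solution down |
| `n_perm` | 100 | permutations for clock significance |

Penalty ties in the inner CV break toward the larger penalty (sparser
model). Features are standardized inside each fit and coefficients
back-transformed, the norm for penalized clocks where level scales differ
across sites. Zero-variance columns (e.g. sites with zero modified reads
in every training sample) are dropped with a warning before fitting: they
carry no age information and break standardization.

## The synthetic cohort generator

No public cohort at this design scale exists for both modifications, so
`simulateCohort` generates one with known truth. Defaults are the study
conditions the package is validated under:

* 3 age groups (7, 21, 35 days), n = 5 per group; optional treatment arms
  at 35 days modelled purely as an *effective-age offset* (a rejuvenated
  arm's methylome is generated at `age - offset`). Arms default to the
  same n as the age groups: with 3-per-arm designs the nonparametric post
  hoc branch (minimum two-sided rank p = 0.1 at 3 vs 3) can never reach
  significance, which would make a real rejuvenation undetectable by
  construction whenever the gate selects that branch.
* 2,000 sites per channel. 10% are **clock sites**: baselines from
  Beta(1.5, 73.5) floored at 0.005 (mean ~2%, matching the sparse
  methylation background) drifting on the logit scale; the per-site slope
  prior is Normal(1.32, 2.04) percent per week for the 6mA-like channel
  (Normal(0.61, 3) for 5mC-like), applied as the fraction-scale
  derivative at the midpoint age. The low baselines are a power
  consideration as much as a realism one: at 30X and five samples per
  group, a ~1.3 %/week drift is resolvable against binomial read noise
  only where the baseline itself is low. The recorded truth slope is the
  secant of the latent mean trajectory across the age range — exactly the
  linear trend a per-site OLS estimates — so rate-of-change recovery
  measures estimation error, not parameterization mismatch.
* 10% are **entropy sites**: baselines from Beta(2, 8) truncated at 0.45,
  whose Beta-distributed per-sample fractions both lose precision with
  age (phi falling from ~51 to ~16 across the age range, floor 8) and
  drift in mean toward 0.5 (35% of the remaining distance at the oldest
  age). Both ingredients are needed: binary entropy is concave, so a
  mean-preserving increase in dispersion alone *lowers* expected entropy;
  the age-increasing entropy observed at differential sites in real aging
  methylomes comes from methylation moving toward intermediate levels,
  with dispersion adding the stochastic component. The closed form
  `expectedSiteEntropy` (digamma identities for Beta expectations) lets
  tests verify that the cohort-average expected entropy is monotone in
  age without simulation.
* The stable background is a mixture 0.97·Beta(0.5, 30) + 0.03·Beta(5, 5),
  tuned so the read-weighted global level of the background sits near
  2-3%. Because drifting sites are enriched ~200,000-fold relative to a
  real genome (where hundreds of DMS sit among tens of millions of
  sites), the cohort-wide global level is somewhat higher and rises
  slightly with age; interpret the generator as a desk-scale concentrate
  of the aging signal, not a genome emulator.
* Read depth is negative-binomial (mean 30, size 10, so SD ~ 11X,
  overdispersed relative to Poisson as real per-sample coverages are),
  and observed counts are Binomial(n_valid, fraction).

What passing tests on this generator do **not** show: robustness to
alignment and basecalling artifacts, sequence-context or regional
correlation structure between sites (sites are independent here),
batch effects, or genuinely nonlinear age trajectories. The generator is
a statistical emulator of per-site drift, dispersion and depth — no more.

## Numerical choices and degenerate inputs

* Fisher p-values use the standard two-sided enumeration rule (tables as
  or less probable than observed, with the usual 1 + 1e-7 tolerance), and
  the vectorized path is tested against full hypergeometric enumeration.
* Rows with zero valid coverage are dropped at parse time (fraction
  undefined) and counted; rows with more modified than valid reads are
  rejected with a warning.
* Constant sites in ROC regressions get slope 0, R² 0 and NA p — never
  retained, never silently averaged.
* An empty ROC retention set yields a flagged undefined result rather
  than zero. BH needs at least two tested sites; fewer is an error.
* Clock predictions are not clamped; a negative predicted age is
  reported as-is.
* All randomness flows through explicit seeds; package functions restore
  the caller's RNG state.

## Validation problem sizes

The test suite exercises the full design (2,000 sites, 15 samples, 20
replicate cohorts) for clock recovery, rate-of-change recovery, empirical
FDR and rejuvenation detection. Null calibration of the permutation test —
101 nested-LOOCV runs per replicate — uses 100-site single-channel null
cohorts across its 20 replicates; calibration of a type-I property does
not depend on feature count the way power properties do, and this keeps
the suite proportionate. Unit tests use small hand-built matrices whose
expected values are computed by independent oracles (hypergeometric
enumeration, brute-force step-up BH, normal-equation OLS via `lm`,
rank-formula Kruskal-Wallis, closed-form MAP and entropy).

## Known limitations

* Channels are analysed strictly separately; no integrated 6mA + 5mC
  clock is attempted.
* Differential methylation is site-level only; no regional segmentation
  or covariate adjustment.
* The pooled-count Fisher test ignores between-replicate overdispersion;
  the t-test option trades power for robustness to it.
* With n = 10 training samples, inner-loop penalty selection is noisy;
  the sparser-model tie-break and the permutation test are the guards,
  not a cure.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(
    input_mode = "simulate",
    sim_config = simulationConfig(
        treatment_arms = c(control = 0, rapamycin = 10)),
    n_perm = 100, seed = 1,
    out_dir = "methylaging_out")
report <- runPipeline(cfg)
```

The written `report.json` contains, per channel: global levels (read- and
site-weighted), DMS counts with direction proportions and the 2x2
chi-squared across channels, genome-wide and DMS-restricted entropy with
the gated group tests, mean ROC, clock train-CV and test metrics with
permutation p and stability CV, and the per-arm deceleration table.
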