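---
title: "Comparing single-center and multi-center designs for prognostic signature studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing single-center and multi-center designs for prognostic signature studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

High-dimensional prognostic models (gene signatures predicting a clinical
outcome) require two independent cohorts: a discovery cohort to select genes
and estimate coefficients, and an external validation cohort to measure
performance. Cohorts assembled in a single clinical center (SC) share one
processing environment — one batch pattern — and are homogeneous; cohorts
pooled across multiple centers (MC) superimpose several batch patterns.
Which kind of data should be used for which role? `centersim` answers this
by direct simulation of the complete workflow, because the answer depends on
properties (signal strength, signal spread, sample size) that interact with
feature selection in ways no closed form captures.

## The generating model and its assumptions

Expression of gene $g$ for sample $i$ of center $j$ is

$$x_{ijg} = \alpha_g + a_{ij}\,\tilde\beta_g + \gamma_{jg}
  + \sum_{l=1}^{m} b_{jgl} Z_{ijl} + \delta_{jg}\,\epsilon_{ijg},
  \qquad y_{ij} = a_{ij} + \eta_{ij},\; \eta_{ij}\sim N(0,\sigma_y^2).$$

Both the covariates and the outcome are noisy functions of an unobserved
continuous true state $a_{ij} \sim N(0,1)$ — the model's key structural
assumption, distinct from the usual regression view of $y$ as a function of
$x$. A center's batch pattern is the triple $(\gamma_{j\cdot}, b_{j\cdot\cdot},
\delta_{j\cdot})$: additive per-gene shifts, loadings of $m$ latent factors
that induce center-specific gene–gene correlation, and per-gene noise
rescaling. All three are drawn freshly for every center of every cohort, so
discovery and validation centers never share a batch pattern. An SC cohort
is simply a cohort with one center.

The model deliberately excludes case-mix differences and center-varying
signal strength: centers differ only through outcome-independent noise
structure. Conclusions therefore apply to batch-type center effects, not to
heterogeneity of the patient populations themselves.

### Parameters, defaults, and why

| parameter | meaning | default |
|---|---|---|
| `beta_mean` ($\tilde\beta$) | mean effect size of informative genes (unitless; expression is on an arbitrary standardized scale) | 0.25 |
| `n_inf` | number of informative genes | 300 (30% of genes) |
| `N_g` | genes per sample | 1000 |
| `N_s` | samples per cohort (discovery and validation alike) | 100 |
| `N_c` | centers in an MC cohort | 8 |
| `n_min` | minimum samples per center | 10 (5 in the sample-size sweep, to allow $N_s = 40$) |
| `m` | latent factors per center | 5 |
| `sigma_y` | SD of outcome observation noise | 0.1 (10% of the unit true-state SD) |

All random model quantities ($\alpha, a, \gamma, b, Z, \delta, \epsilon$)
are standard normal, which keeps the parameter count minimal. Effect sizes
are graded linearly, $\tilde\beta_g = 2\tilde\beta(1 - g/(n_{inf}+1))$ for
$g \le n_{inf}$: informative genes range from nearly $2\tilde\beta$ down to
nearly 0, so every signature faces a mix of strong and marginal signals, and
the mean over informative genes is exactly $\tilde\beta$.

Samples are allocated to centers by giving each center `n_min` samples and
distributing the remainder independently and uniformly.

Within one Monte-Carlo iteration the four cohorts (SC/MC × discovery/
validation) share the basal levels $\alpha_g$ and the effect sizes: these
represent gene-level biology, which does not change between cohorts of the
same study. Batch parameters and all sample-level draws are independent
across cohorts. (Whether the original design shared $\alpha_g$ within an
iteration is not documented anywhere; we treat it as biology and share it.
Between iterations everything is redrawn.)

## The pipeline

1. **Per-sample standardization** — every sample (row) is centered and
   scaled to unit SD. We use the sample-SD convention (divisor $N_g-1$,
   matching `scale()`); the choice is immaterial downstream but is fixed and
   documented because idempotence tests depend on it.
2. **Batch correction** — MC cohorts are adjusted by parametric
   empirical-Bayes location/scale correction (ComBat; Johnson et al. 2007),
   implemented in `combat_correct()`: gene-wise standardization against the
   batch-size-weighted grand mean and pooled residual variance, batch-wise
   location/scale estimates, normal/inverse-gamma priors with
   method-of-moments hyperparameters, the standard fixed-point iteration
   (tolerance `1e-4`), and back-transformation. No covariates are included
   (the outcome is not protected — the tool's default) and no reference
   batch is used. Validation cohorts are corrected with their own labels,
   independently of discovery. The implementation reproduces the standard
   tool to machine precision on a frozen reference fixture and an
   independent naive reimplementation to below `1e-6`.
3. **Model fitting** — lasso (`glmnet`) on the corrected discovery data,
   10-fold CV with fold assignment drawn from the iteration's RNG stream,
   penalty chosen by the one-standard-error rule: the *largest* penalty
   whose CV error is within one SE (computed across fold means, divisor
   $\sqrt K$) of the minimum — ties on the grid resolve to stronger
   penalization by construction. The penalty path is glmnet's default
   (100 values, `lambda.min.ratio` 0.01 for $n < p$); we kept the tool's
   defaults rather than a deeper path because the quantities being
   reproduced were generated with those defaults. An empty signature is a
   legitimate, retained outcome.
4. **Scoring** — each signature is applied to both validation cohorts.
   MSPE uses predictions on the *normalized but uncorrected* validation
   expression: the MSPE estimates the prediction error for single future
   samples, and a single sample cannot be batch-corrected. SV and CS use
   the corrected validation data. Empty signatures score FDR 1, SV 0, CS 0,
   and their MSPE is that of the constant intercept. Degenerate constant
   predictions short-circuit to SV 0 and CS 0 regardless of cause. The SV
   test is a one-sided Pearson correlation test ($H_1: \rho > 0$, $t$
   distribution) — Pearson matches the linear-model context; the original
   description says only "one-sided correlation test".

All iterations enter the reported averages — excluding empty-signature
iterations after the fact would bias the comparison. Conditional summaries
(`supplementary_summaries()`) report non-empty frequency, mean signature
length and scores given non-emptiness, with `NA` (not zero) for cells where
every signature is empty.

## Scenarios and aggregation

Three sweeps, each varying one factor: signal strength
$\tilde\beta \in [0, 0.5]$; number of informative genes
$n_{inf} \in [1, 1000]$ at constant total signal
$\sum_g \tilde\beta_g = 75$ (so $\tilde\beta = 75/n_{inf}$); sample size
$N_s \in [40, 500]$ at $\tilde\beta = 0.125$. Scores are aggregated as
means with SEM and normal-approximation 99% intervals
(mean $\pm\, 2.576\,$SEM); the CI construction is our choice — the original
construction is not documented — and its coverage is property-tested.

## The estimator-quality experiment

The MSPE from a validation cohort estimates the expected squared prediction
error of single future samples. To measure the quality of that estimator,
`mspe_estimator_quality()` approximates the truth by Monte-Carlo: fresh
samples, *each one its own center* with an independently drawn batch
pattern, normalized, never corrected. The estimator under study is the MSPE
from one validation cohort; its squared error
$(\mathrm{MSPE}_{estim} - \mathrm{MSPE}_{approx})^2$ is averaged over many
independent validation cohorts per discovery fit. SC validation estimates
the truth with much larger squared error than MC validation — the only
respect in which the choice of validation design matters.

A numerical note: for a sample with its own freshly drawn iid N(0,1)
loadings $b_{gl}$, the factor term $\sum_l b_{gl} Z_l$ is distributed,
gene-wise independently, as $\sqrt{\sum_l Z_l^2}\,N(0,1)$. The approximation
sampler draws that form directly — an exact equivalence, not an
approximation — which cuts RNG cost by two thirds.

## Reproducibility and numerical conventions

One root seed drives everything: per-iteration child seeds are derived with
`iteration_seeds()` and each iteration reseeds the RNG, so runs are
bit-reproducible and invariant to the worker count. Result CSVs store
doubles at full precision (round trips better than 1e-12). Degenerate
inputs fail loudly with classed conditions: constant samples cannot be
standardized, single-batch input cannot be ComBat-corrected, constant
outcomes cannot be fitted.

## What the synthetic world does and does not establish

The generator emulates the heterogeneity structure of multi-site microarray
data: per-center mean shifts, correlation patterns and variance rescaling,
all independent of the outcome. It does not emulate case-mix differences,
center-varying effect sizes, non-normal expression distributions, censored
or binary outcomes, or technical artifacts such as missingness — so a green
test certifies the pipeline's behavior under batch-type center effects
only. Reduced-repetition reproductions (200 instead of 1000 iterations per
grid point in the test suite) widen Monte-Carlo bands by $\sqrt 5$;
tolerances scale accordingly and were fixed before the runs. The
estimator-quality acceptance check runs at 60 iterations × 5000
approximation samples × 20 validation sets to respect the test-time budget;
the acceptance script uses 100 iterations × 5000 samples.

## Known limitations

* Continuous outcomes only; most prognostic models in practice are Cox or
  logistic. The center-effect structure does not depend on the outcome
  type, but absolute score levels would differ.
* The lasso path and CV conventions follow one tool's defaults; other
  implementations' 1-SE choices can differ by a grid point on near-flat CV
  curves.
* `delta_jg` is drawn N(0,1) as specified even though a negative scale
  factor is unusual — the noise it multiplies is symmetric, so only
  $|\delta|$ matters, and we keep fidelity to the stated model rather than
  folding the sign.
* The between-design contrasts at reduced repetitions are stable, but
  individual score levels in the steep transition region
  ($\tilde\beta \approx 0.1$–$0.2$) carry visible Monte-Carlo error.
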