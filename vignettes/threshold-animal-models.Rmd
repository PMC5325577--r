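---
title: "Threshold animal models for ordinal joint scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold animal models for ordinal joint scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thram)
```

## The model

Hip and elbow screening scores are ordered categories: hips are graded 1
(excellent) to 7 (severe dysplasia), elbows 1 (normal) to 4 (degenerative
joint disease grade III). `thram` models each score as the discretisation
of an unobserved continuous *liability*. For trait $m$ on dog $n$,

$$
y_{nm} = \mu_m + \mathrm{sex}_{im} + \beta_m\,\mathrm{age}_n +
\mathrm{year}_{km} + a_{nm} + e_{nm},
$$

where $y_{nm}$ is the liability, $\mathrm{sex}$ is a male-minus-female
contrast, age at evaluation (months) enters linearly, year of evaluation is
categorical (first observed year as reference), $a_{nm}$ is the additive
genetic effect and $e_{nm}$ the residual. The observed score is the number
of cutpoints below the liability, plus one. With a probit link the residual
is standard normal, so per trait the residual variance is fixed at 1 and

$$
h^2_m = \frac{g_m}{g_m + 1}, \qquad
r_g = \frac{g_{he}}{\sqrt{g_h\,g_e}},
$$

with $\operatorname{var}(\mathbf a) = G_0 \otimes A$ for the pedigree
numerator relationship matrix $A$ and the genetic (co)variance matrix
$G_0$. Dogs scored on both joints additionally carry a residual
correlation $r_{he}$; dogs scored on one joint contribute only that
trait's liability.

Breeding values are reported on the liability (probit) scale. They are
relative quantities: a lower EBV predicts lower transmitted disease
liability, but no specific score category.

## Priors and the chain

Fixed effects have independent normal priors with mean zero and variance
$e^{10}$ — effectively flat. $G_0$ has an inverse-Wishart prior with scale
$V\nu$ and degree-of-belief $\nu$ (mode $V\nu/(\nu+2)$); the defaults are
$V = I$ and $\nu = 0.002$, a diffuse, nearly scale-invariant choice. The
residual correlation carries the same inverse-Wishart form, constrained so
that $R_0$ stays positive definite.

The Gibbs sampler augments the latent liabilities and cycles through:

1. truncated-normal liability draws bounded by the cutpoints of each
   record's observed category (conditioned, for doubly-scored dogs, on the
   other trait's liability via $r_{he}$);
2. a *single joint draw* of all fixed effects and all animal effects from
   the sparse mixed-model equations, using the Henderson–Quaas sparse
   $A^{-1}$ — one supernodal Cholesky refactorisation per iteration with a
   symbolic analysis computed once;
3. a conjugate inverse-Wishart draw of $G_0$ with scale
   $V\nu + \mathbf a' A^{-1}\mathbf a$ and degrees $\nu + n$;
4. random-walk Metropolis updates of the free cutpoints (a Cowles-style
   block: the acceptance ratio integrates the liabilities out, then they
   are redrawn), with step sizes adapted during burn-in to a 20–50%
   acceptance rate and frozen afterwards;
5. Metropolis updates of the residual (co)variance parameters.

The default schedule runs 100,000 rounds with 20,000 burn-in and thinning
interval 20, storing 4,000 samples. Heritabilities and genetic
correlations are computed sample-wise and summarised as posterior means
and SDs, so the reported $h^2$ is the posterior mean of $g/(g+1)$, not the
transform of the posterior-mean $g$.

## Identification: why two cutpoints are anchored internally

A threshold model is identified only up to the location and scale of the
liability axis. The conventional constraint — first cutpoint at 0,
residual variance at 1 — leaves the likelihood almost flat along a ridge
on which the genetic variance, the remaining cutpoints and all location
effects inflate together, whenever the data only weakly pin the residual
fraction (few thousand records, few categories, heavy category
imbalance). Chains then drift: in development we observed the genetic
variance growing monotonically with cutpoints and intercept inflating in
proportion while category probabilities barely changed.

`thram` therefore runs the chain in the Sorensen-style anchored
parameterisation — first cutpoint 0, *second cutpoint 1*, residual
variances free — which pins the scale to the observable spacing of the
first two thresholds. Every stored draw is rescaled analytically to the
conventional unit-residual parameterisation (divide the liability axis of
trait $m$ by its residual SD), so all reported quantities — $g$, $h^2 =
g/(g+1)$, $r_g$, cutpoints, fixed effects and EBVs — are on the standard
scale, with the first cutpoint at 0 and residual variance exactly 1 in
every stored sample. The two parameterisations describe the same model;
the anchoring only decides which coordinates the sampler random-walks in.

A per-trait parameter-expansion move (a Metropolis rescaling of an animal
effect block together with the matching rows of $G_0$) is included to
speed mixing of variance components near the boundaries $h^2 \to 0$ and
$h^2 \to 1$, where the conditional-conjugate update alone is a slow random
walk.

Degenerate inputs are rejected before sampling: a trait with a single
observed category, records referencing animals absent from the pedigree,
or scores outside their trait's range. If a numeric Cholesky of the
mixed-model equations fails, an escalating diagonal jitter (starting at
1e-10 of the diagonal maximum) is applied and counted in the fit object.

## Convergence checks

A chain is accepted when every monitored series (variance components,
residual correlation, fixed effects) has lag-1 autocorrelation below 0.1
among stored samples, shows no trend (a Geweke comparison of the first 10%
against the last 50% with spectral-density standard errors; $|z| \ge 2$
flags), and passes a moment-based normality screen (|skewness| > 1 or
|excess kurtosis| > 2 flags, reported but not gating). The 0.1 rule and
the trend rule gate the pipeline: `run_pipeline()` withholds summaries
when they fail unless forced. The trend and normality criteria are
deliberate operationalisations of what is usually a visual inspection of
trace plots.

## The synthetic-data generator

No public registry data exist, so the package ships a forward simulator
that reproduces the statistical structure the model assumes: a
multi-generation pedigree with non-overlapping cohorts, founder breeding
values from $N(0, G_0)$, offspring as the parental mean plus a Mendelian
deviation with variance $\tfrac12 G_0 (1 - (F_s+F_d)/2)$, liabilities
assembled exactly per the model equation with unit residuals (correlated
$r_{he}$ across traits), ordinal scores via fixed cutpoints, uniform
evaluation ages on 24–120 months, and per-trait voluntary-participation
missingness. Optional truncation selection keeps the most favourable
fraction of candidate parents by observed score (or true breeding value),
for either sex or both, producing the declining genetic trend that the
trend and four-path analyses quantify.

Default conditions, chosen once for realism: 300 founders plus three
cohorts of 400 (≈1,500 animals, the scale of the recovery experiments);
60 sires and 150 dams per generation (strong popular-sire usage); hip
category frequencies 12/43/33/4/4/3/1% (mostly good/fair, ~8% dysplastic,
1% severe); elbow frequencies 80/10/6/4% (20% dysplastic, matching
high-prevalence breeds; most real breeds are lower still); hips always
scored and elbows on 70% of dogs, reflecting the several-fold difference
in submission counts; genetic correlation 0.5 and residual correlation
0.2 when both traits are simulated; sex, age and year effects zero by
default so that recovery experiments isolate the genetic parameters.

What the generator does *not* emulate: overlapping generations,
score-dependent ascertainment (owners withholding poor radiographs — an
optional flag exists but is off by default so recovery tests are
unbiased), body-weight covariates, and the four component lesions behind
the composite elbow grade. Passing recovery tests on synthetic data
therefore show the estimator is correct for the model's own data-generating
process, not that real registry data satisfy that process.

## What is recoverable at this scale — and what is not

With ≈1,500 animals the 7-category hip trait is informative: univariate
recovery is within a few hundredths across the 0.1–0.8 heritability
range. The 4-category elbow trait with an 80% "normal" category is far
less informative, and two consequences of the diffuse priors follow at
this sample size:

- near a boundary truth (e.g. 0.9) the posterior is wide with a genuine
  probability spike at $h^2 \to 1$, so posterior means run a few
  hundredths high;
- at moderate truths the likelihood is nearly flat over a wide
  heritability range, and the nearly scale-invariant $\nu = 0.002$ prior
  (≈ equal mass per decade of variance) pulls the posterior mean toward
  zero. In bivariate fits a collapsed elbow variance leaves the genetic
  correlation prior-dominated: the implied inverse-Wishart prior on
  $r_g$ has density $\propto (1-r_g^2)^{-3/2}$, concentrating near
  $\pm 1$.

These are properties of the model-plus-prior at desk scale, confirmed
against independent implementations (an MCMC oracle and an exact
quadrature posterior on family designs), not sampler artifacts; with the
registry-scale record counts the likelihood dominates and they vanish.
They are documented here because parameter-recovery experiments at
moderate sample sizes must be read with them in mind.

## Numerical choices

- Dense $A$ is refused above 5,000 animals; the sparse inverse is always
  available and is the path the sampler uses.
- Tabular-method $A$, Meuwissen–Luo inbreeding and Henderson–Quaas
  $A^{-1}$ with full inbreeding adjustment; unknown parents are treated as
  unrelated base-population founders.
- Positive-definiteness is checked by Cholesky success; mixed-model
  equations may receive a logged diagonal jitter of 1e-10.
- Cutpoint, residual-correlation and parameter-expansion step sizes adapt
  every 50 burn-in iterations by a multiplicative rule targeting ~35%
  acceptance; adaptation stops at the end of burn-in so the stored chain
  is a valid fixed-kernel Markov chain.
- Loess smoothing of genetic trends uses span 0.75 and degree 2 without
  robustness iterations; four-path quadratic fits are ordinary least
  squares with birth years centred at their mean for conditioning.
- Ties in truncation selection are broken by an independent uniform draw,
  so selection intensity is independent of record order.

## Known limitations

- Single-chain inference; no Gelman–Rubin multi-chain diagnostics.
- The sire-versus-dam pathway comparison is a permutation test on
  grand-parental group means; it is one reasonable interpretation of a
  pathway contrast, not a uniquely defined test.
- Breeding values have no absolute scale; only contrasts and trends are
  interpretable.
- Animal-effect samples are summarised by running means/SDs unless full
  storage is requested, so posterior quantiles of individual EBVs are not
  available by default.
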