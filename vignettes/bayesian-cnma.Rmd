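---
title: "Bayesian component network meta-analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian component network meta-analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many networks of randomized trials compare *complex interventions*:
treatments assembled from elementary components (psychoeducation, cognitive
restructuring, exposure, a drug, a delivery format, ...). A standard network
meta-analysis (NMA) treats every distinct combination as its own node, which
fragments the evidence and says nothing about which ingredient does the
work. Component network meta-analysis (CNMA) instead writes the effect of a
combination as the sum of component effects,
$\theta_T = \sum_{q \in T} d_q$, so the same $d_q$ is informed by every
trial that varies component $q$. This buys three things: components can be
ranked, disconnected networks can still be pooled when they share
components, and the model can score combinations never tested in a trial.

The additivity assumption is strong. Components may act synergistically or
antagonistically, and with $N_c$ components there are $N_c(N_c-1)/2$
candidate two-way interaction terms $d_{p.q}$ — far too many to estimate
freely in a typical network. `bcnma` therefore implements Bayesian variable
selection for the interaction terms: **stochastic search variable
selection** (SSVS, a spike-and-slab prior with per-term inclusion
indicators) and the **Bayesian LASSO** (double-exponential shrinkage), plus
one-stage joint models that combine aggregate data (AD) with individual
participant data (IPD) and allow component-covariate effect modification.

## Model family

All models share the random-effects second level
$\delta_i \sim N(\theta_Y - \theta_X,\ \tau^2)$ for a study comparing
combinations $X$ and $Y$, with a common heterogeneity SD $\tau$ across
comparisons. The layers are:

* **Treatment-level NMA** (`fit_ad(..., ad_model_spec("treatment"))`): one
  parameter per distinct combination; the first combination in canonical
  order is the reference and fixed at zero.
* **Additive CNMA** (`ad_model_spec("component", "none")`):
  $\theta_T = \sum_{q \in T} d_q$.
* **CNMA with interactions** (`"full"`): $\theta_T$ additionally includes
  $d_{p.q}$ for every admitted pair $\{p, q\} \subseteq T$, under vague
  normal priors.
* **SSVS** (`"ssvs"`): each admitted $d_{p.q}$ gets the two-component
  mixture prior
  $\pi(d_{p.q} \mid I_{p.q}) = (1 - I_{p.q})\,N(0, \eta^2) +
  I_{p.q}\,N(0, g^2\eta^2)$, $I_{p.q} \sim \mathrm{Bernoulli}(p_{p.q})$.
  The indicator is part of the MCMC state, so a *different model* is in
  force at every iteration; the posterior mean of $I_{p.q}$ is the
  inclusion frequency reported by `ssvs_inclusion_summary()`.
* **Bayesian LASSO** (`"lasso"`): $\pi(d_{p.q}) =
  \frac{\lambda}{2} e^{-\lambda |d_{p.q}|}$, with $\lambda$ random.
* **Joint AD+IPD models** (`fit_joint()`): AD studies contribute
  $y_i \sim N(\delta_i, s_i^2)$ (optionally
  $y_i \sim N(\delta_i + \beta'\bar{x}_i, s_i^2)$, a meta-regression over
  centered study-mean covariates); IPD studies contribute patient-level
  records $y_{ik} \sim N(\alpha_i + \beta'x_{ik} +
  (\sum_{q \in t_{ik}}\gamma_q - \sum_{q \in t_{i0}}\gamma_q)'x_{ik} +
  \delta_{i,\mathrm{arm}},\ \sigma_i^2)$ (Bernoulli-logit for binary
  outcomes). The two evidence types share $\tau$ and the $d$'s: the
  marginal AD and conditional IPD estimates are pooled as exchangeable.
  $\gamma_q$ is the effect-modification vector of component $q$ — the
  change in the benefit of adding $q$ per unit of each covariate.

Likelihoods for aggregate data: normal on contrast-level relative effects
(any continuous scale: MD, SMD, logOR, logRR, logHR), binomial-logit on
arm-level events/size, or normal on arm-level mean/SD/size. Arm-level
models carry one vague baseline parameter per study; inference is only ever
about relative effects. Zero cells need no continuity correction under the
binomial likelihood.

### Multi-arm studies

A $k$-arm study contributes $k-1$ random relative effects with the
exchangeable covariance $\tau^2$ on the diagonal and $\tau^2/2$ off it
(`multiarm_re_covariance()`), the standard structure that gives every
pairwise comparison within the study heterogeneity variance $\tau^2$. The
samplers use its sequential-conditional decomposition (arm $k$ conditions
on the deviations of arms $2..k-1$), which avoids matrix inversion inside
the MCMC. For *contrast-level* multi-arm studies the observed $y$'s also
share the reference arm's sampling error; if `ref_se` is recorded the
induced covariance $\mathrm{ref\_se}^2$ enters a multivariate normal
likelihood, otherwise the contrasts are treated as independent and the fit
records a note — the magnitude of that approximation grows with the
reference arm's share of the sampling variance.

## Priors and tuning parameters

Defaults in `prior_config()` (all on the modelling scale of the outcome):

| parameter | default | notes |
|---|---|---|
| $d_q$ | $N(0, 10^2)$ | vague; all main effects |
| baselines $\mu_i$, $\alpha_i$ | $N(0, 10^2)$ | arm-level / IPD intercepts |
| $\tau^2$ | $LN(-1.67, 1.472^2)$ | informative, empirically based for log-OR outcomes; half-normal and uniform alternatives on $\tau$ for other scales |
| $\eta$ (spike SD) | $N(0, 10^{-2})$ truncated to $\eta > 0$ | or fixed via `eta_fixed` |
| $g$ (slab ratio) | 100 | slab SD $= g\eta$ |
| $P(I_{p.q} = 1)$ | 0.5 | equiprobable; per-pair overrides via `pairs.csv` |
| $\lambda^{-1}$ | $U(0, 5)$ | half-normal $N(0,100)I(0,)$ alternative, or fixed $\lambda$ |
| $\beta$, unshrunk $\gamma$ | $N(0, 10^2)$ | |
| $\sigma$ | $U(0, 10)$ | per-study or common |

Guidance for $\eta$: choose it so that $N(0, \eta^2)$ is "practically
zero" for the outcome — e.g. if interactions below 0.5 are clinically
unimportant, $\eta \sim N(0, 10^{-2})$; pushing $\eta$ toward 0 makes the
sampler inefficient, and $g$ too large lends support to absurd values. A
scale cannot be negative, so the $\eta$ prior is truncated at zero.
Equiprobable inclusion (0.5) makes every interaction subset a priori
equally likely, which implicitly favours models containing half the pairs;
pre-selecting plausible pairs by expert opinion (excluding impossible ones
outright, elevating likely ones to, say, 0.8) is both statistically and
scientifically better, and is exactly what the per-pair
`prior_inclusion` column supports.

### The conditional Laplace prior on $\gamma$

With 17 components and 4 covariates a joint model carries 68 $\gamma$
coefficients; shrinking them improves generalizability. For continuous
outcomes `gamma_shrinkage = "conditional-laplace"` uses a Laplace prior
conditioned on the residual variance, which yields unimodal posteriors but
*requires a common $\sigma$ across IPD studies* (the package enforces
this). Two exponent conventions circulate for this prior, differing in
whether the rate is $\lambda/\sigma^2$ or $\lambda/\sigma$; only the
latter is correctly normalized by the constant $\lambda/(2\sigma)$ (the
former integrates to $\sigma$, not 1, under that constant — the quadrature
check in the test suite documents this). `bcnma` implements both:
`laplace_convention = "sigma2"` (default) and `"park-casella"`. The
sampler always uses the properly normalized double exponential with the
chosen rate. This prior cannot be used for the AD interaction terms, where
no common $\sigma^2$ exists — AD studies each carry their own $s_i^2$.

## Estimability

Which $d$'s a network identifies is a property of its design. The stacked
contrast rows (one per non-reference arm per study; entries $\pm 1$ per
component, analogous entries per admitted pair) determine everything: a
linear combination of parameters is estimable iff it lies in the row
space. Two classic failures: components always co-administered (only their
sum is identified) and a component present or absent in *all* arms of every
study that uses it (its column is identically zero — e.g. a background
drug therapy given to both arms). `estimability()` computes the numerical
rank by SVD — singular values below $10^{-8}$ times the largest are
treated as zero, a safe tolerance for 0/±1 design entries — and reports
the null-space directions with component labels. Inestimable directions
are *reported, not dropped*: the Bayesian fit proceeds (proper priors keep
the posterior proper), with the caveat, printed on the fit, that
posteriors in flat directions simply reproduce their priors. Relative
effects between combinations actually compared in trials are always
estimable by construction. Interaction columns are restricted to two-way
pairs by default; higher orders would be estimable only in implausibly
rich designs.

## Centering and prediction

All covariates are centered by their grand means at assembly: the pooled
mean over IPD patients (AD study means are shifted by the same constants),
or the mean of study means when only aggregate covariates exist. The
constants are stored in the dataset and in every fit, so (a) $d$-based
contrasts are conditional effects *at the covariate means*, and (b)
`relative_effect(fit, A, B, profile = ...)` can center a raw patient
profile consistently and add
$(\sum_{q \in A}\gamma_q - \sum_{q \in B}\gamma_q)'x$ draw by draw —
the engine behind patient-specific effect calculators
(`prediction_table()` produces the profile × comparison grid such an
application needs). Sign convention: positive effects (OR > 1) favour the
first combination on the outcome's natural direction; whether that is good
depends on whether the outcome is a benefit (remission) or a harm (symptom
score).

## Missing covariates

The IPD models require complete covariates. The supported workflow is
multiple imputation performed upstream: the `ipd.csv` schema takes an
`imputation` column with stacked pre-imputed copies; `fit_joint()` fits
each copy separately (seeds `seed + m`) and `mix_imputation_draws()` pools
by concatenating draws — with $m$ fits of $n$ draws the mixed posterior
has $mn$ draws and its mean is the average of per-fit means. Generating
the imputations is deliberately out of scope.

## Sampling and reproducibility

Models are expressed as JAGS code generated by the package and sampled via
`rjags`; SSVS indicators are updated within the chain (Gibbs), so each
iteration carries its own interaction subset. Every fit requires a seed;
per-chain RNGs are derived from it deterministically, so identical inputs
reproduce draws bit for bit. The CLI writes a manifest (config hash, data
hashes, seed, settings, version) with every artifact. Convergence is
summarized by split-$\widehat{R}$ (each chain halved) and effective sample
size; fits warn when $\max \widehat{R} > 1.01$. For real networks we
recommend the heavy-duty default of 4 chains × 30000 kept iterations
after 10000 burn-in (`mcmc_control()`); the package's own tests and the
acceptance script use 2 chains and 1–2 thousand kept iterations on small
synthetic networks, which those problem sizes comfortably support (the
slowest-mixing quantities are flat, inestimable directions, for which the
tests use longer thinned runs).

## The synthetic-data generator

`synthetic_truth()` fixes a complete generative scenario so every model
can be validated by parameter recovery without external data. The default
scenario — 6 components, 40 two-arm plus 5 three-arm studies, contrast
SEs uniform on [0.15, 0.35], $\tau = 0.3$, main effects
$(0.8, -0.5, 0.3, 0, 0.6, -0.2)$, and a single true synergy
$d_{c1.c2} = 1$ — is sized like a moderate evidence base on a
standardized-effect scale, large enough that the true interaction is
detectable and small enough that selection fits run in seconds. The
combination pool mixes singletons and combinations so all main effects and
the true pair are estimable. IPD defaults add 8 two-arm studies × 120
patients, $\sigma = 1$, a standard-normal and a Bernoulli(0.5) covariate
(a severity score and a binary demographic), $\beta = (0.5, -0.3)$ and one
non-zero effect modification ($\gamma_{c1,x_1} = 0.4$).

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about real data: selective reporting and
small-study effects; non-normal random effects; inconsistency between
direct and indirect evidence; correlation between components and trial
populations (effect modification confounded with component assignment);
within- vs across-study separation of covariate interactions; and
missingness mechanisms (covariates are generated complete).

## Numerical and design choices

* Component codes are case-insensitive, stored lower-case; combination
  order is canonicalized to catalog order so design matrices — and
  therefore draws — are reproducible across runs.
* Reference arms: first listed arm (AD), earliest combination in canonical
  order (IPD). The models' posteriors are invariant to these choices; the
  conventions only make output deterministic.
* The treatment-level model fixes the first combination's $d$ (and
  $\gamma$ row) at zero; the component level needs no constraint beyond
  the priors.
* SSVS with `g` close to 1 collapses the mixture to $N(0, \eta^2)$
  regardless of the indicator, giving an additive-plus-small-noise model —
  a useful continuity check, enforced in the tests.
* Imputation mixing concatenates chains rather than averaging summaries,
  so any functional of the mixed posterior (not just means) is available.
* Joint fits accept contrast-level aggregate studies; arm-level aggregate
  evidence should be fitted with `fit_ad()` or collapsed to contrasts
  before entering a joint model.

## Known limitations

$\beta$ and $\gamma$ are common across studies (no random effects on
them), exchangeable component effects are not implemented, within- and
across-study components of covariate interactions are not separated, and
no automatic recoding is offered to repair inestimable designs — the
package reports the problem and leaves the remedy (merging components,
excluding pairs) to the analyst. Model choice diagnostics (Q statistics,
DIC across interaction subsets) are out of scope; the selection priors
*are* the model-choice mechanism.

```{r}
library(bcnma)
truth <- synthetic_truth()
ds <- simulate_ad(truth, seed = 1)
fit <- fit_ad(ds, ad_model_spec("component", "ssvs"),
              mcmc_control(2000, 600, 2), seed = 1)
ssvs_inclusion_summary(fit)
relative_effect(fit, "c1 + c2", "c3")
```
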