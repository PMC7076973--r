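---
title: "Methods: MNAR sensitivity analysis with elicited expert priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MNAR sensitivity analysis with elicited expert priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnarsens)
```

# The model

## Pattern-mixture factorisation and the sensitivity parameter

Consider a two-arm cluster-randomised trial with a baseline period and
an intervention period, and a bounded patient-reported outcome `y`
measured once per patient. Some patients do not return the
questionnaire. The pattern-mixture factorisation splits each arm's
outcome distribution by response pattern: pattern 1 (observed) and
pattern 2 (missing). For pattern 1 the arm mean is estimable from the
data; for pattern 2 it is taken to be the pattern-1 mean **plus an
offset Δ**, allowed to differ by randomised arm. The arm's overall mean
is the pattern-weighted average

$$\mu_a = (1-p_a)\,\mu_{a,1} + p_a\,(\mu_{a,1} + \Delta_a)
        = \mu_{a,1} + p_a \Delta_a ,$$

where $p_a$ is the arm's empirical missingness proportion. Δ is not
identified by the data — the missing outcomes integrate out of the
likelihood — so its distribution must come from outside the trial:
from expert opinion.

Two consequences of non-identification shape the implementation:

* the posterior of all observed-pattern parameters is exactly the
  posterior of the observed-data mixed model, regardless of the Δ
  prior; and
* the posterior of Δ equals its prior.

The sampler therefore fits the observed-pattern model by MCMC and draws
Δ from the configured prior for every kept iteration. This is
numerically equivalent to the textbook formulation in which missing
outcomes are imputed as latent nodes with mean shifted by Δ, but avoids
carrying thousands of latent variables through the chain.

## The observed-pattern model

For observed outcome $y_{ij}$ of patient $i$ in cluster $j$:

$$y_{ij} = \beta_0 + \beta_p\,\mathrm{period}_{ij}
  + \beta_t\,(\mathrm{period}_{ij}\times\mathrm{arm}_j)
  + x_{ij}^\top\gamma + u_j + \varepsilon_{ij},$$

with $u_j \sim N(0,\tau^2)$ cluster random intercepts and
$\varepsilon_{ij}\sim N(0,\sigma^2)$. The treatment effect of interest
is the treatment-by-period interaction $\beta_t$. The covariates
$x_{ij}$ default to the three elicitation covariates (gender, age
group, anxiety) when present; the set is configuration-driven
(`fit_config(covariates = ...)`).

The Gaussian likelihood is used untruncated even though the outcome
scale is bounded, as is conventional for PROM totals; marginal means
are linear in the parameters either way, and no undocumented truncation
is imposed on the analysis side.

## The reported treatment effect

The MNAR treatment effect is the pattern-weighted contrast of arm means
in the intervention period, net of the baseline-period contrast. Since
baseline-period patients in *both* arms receive usual care, their
offset is $\Delta_{ctl}$, giving per draw

$$\tilde\beta_t = \beta_t
  + p_{int}^{IP}\Delta_{int} - p_{ctl}^{IP}\Delta_{ctl}
  - \bigl(p_{int}^{BL} - p_{ctl}^{BL}\bigr)\Delta_{ctl}.$$

With a point mass at zero this is exactly the MAR analysis; shifting
the intervention-arm Δ by $+5$ moves the intervention marginal mean by
$p_{int}^{IP}\times 5$ and leaves the control arm untouched. Both
properties are verified by the test suite. `marginal_arm_mean()`
exposes the per-arm draws $\mu_{a,1} + p_a\Delta_a$ directly, where
$\mu_{a,1}$ is the model mean over the cell's observed-pattern
patients (average design row plus the cell-weighted cluster effects).

# Representing expert opinion

## The (truncated) split normal

An expert's uncertainty about a *mean* is unimodal even when the
patient-level outcome is not, so a parametric unimodal family suffices;
but a symmetric family is too restrictive near the ends of a bounded
scale. The elicitation primitive is the split normal with mode $m$,
left sd $\sigma_L$ and right sd $\sigma_R$: two half-normal kernels
sharing their height at the mode,

$$f(x) \propto \exp\!\left(-\frac{(x-m)^2}{2\sigma_{L}^2}\right)
  \ (x<m), \qquad
  \exp\!\left(-\frac{(x-m)^2}{2\sigma_{R}^2}\right)\ (x\ge m),$$

truncated to the outcome bounds and renormalised
(truncate-and-renormalise, not shift or reflect, so the mode slider
keeps its meaning). Useful closed forms, all used as test oracles: the
unbounded normalising constant is $\sqrt{\pi/2}(\sigma_L+\sigma_R)$;
the mass below the mode is $\sigma_L/(\sigma_L+\sigma_R)$; the mean is
$m + \sqrt{2/\pi}(\sigma_R-\sigma_L)$. Sampling is by analytic
inverse-CDF, exact on bounded supports with no rejection step. The
degenerate "no uncertainty" case is a dedicated `point_mass()` class,
not a tiny-sd split normal, so quadrature never sees near-singular
kernels; this is also what makes the MAR reduction (Δ ≡ 0) exact.

## Translating to the Δ scale

Experts answer on the outcome presentation scale, against a vertical
"anchor" arrow marking the responder mean for the arm. The Δ prior is
the elicited distribution shifted by minus the anchor; truncation
bounds shift with it (bounds [0, 51] and anchor 15 give Δ support
[−15, 36]). Anchors are explicit inputs (`anchor_table()`), because in
a live study they come from an early-recruitment sample rather than the
final trial table; `compute_anchors()` is the convenience for synthetic
pipelines.

## Coupling the two arms

Each expert also answers a question about the relationship between the
two arms. The joint prior over $(\Delta_{ctl},\Delta_{int})$ couples
the two elicited marginals through a Gaussian copula with one
dependence parameter in $(-1,1)$. This preserves the elicited marginals
exactly and reduces the between-arm relationship to a single
interpretable number; 0 gives independent arms. The default of 0.5 —
experts who think control-arm non-responders do badly usually think the
same of intervention-arm non-responders — is configurable per study
(`dependence =` everywhere it matters), since the exact elicited form
of the relationship is study-specific. This one-parameter family is a
deliberate design choice; richer copulas are out of scope.

## Subgroups, pooling and extremes

Opinions are elicited for three patient subgroups (A: female, younger,
anxious; B: male, older, anxious; C: male, younger, not anxious). How
subgroup elicitations enter the analysis prior is genuinely open; the
default is the least-assumption choice of an equal-weight within-expert
mixture over subgroups, with `subgroup_weights` exposed for anything
else (e.g. weighting by subgroup prevalence).

Experts are pooled by **linear opinion pooling on the density scale
with equal weights**: the pooled prior is the mixture of per-expert
joint priors, i.e. a mixture of bivariate split normals. Pooling is
therefore idempotent for a single expert, order-invariant, and
pointwise linear — all asserted to near machine precision in the tests.
Sampling from the pool is component-then-value, which scales to
many-expert panels without evaluating the pooled density.

The *most sceptical* / *most enthusiastic* experts are the argmin /
argmax over the high-confidence group of the probability that the
non-responder mean is better under the intervention (lower for symptom
severity, higher for quality of life), computed by Monte Carlo with a
fixed seed; ties break lexicographically by expert id so selection is
deterministic.

## Screening and categorisation

A response is *unusable* when the fraction of moved sliders falls
strictly below 0.5 (a response exactly at the threshold is kept — the
boundary convention is documented on `screen_unusable()`), or when a
reviewer has flagged free-text evidence of misunderstanding. Otherwise
it is *usable with high confidence* iff all three reviewer flags
(engagement evidence, quantitative/qualitative consistency,
cross-subgroup consistency) are true, else *usable*. Screening
dominates reviewer flags. The criteria are fixed in configuration
before the analysis runs, not adjusted after seeing the data; dual
review is represented by per-reviewer records plus a resolved record,
and a disagreement without a resolution is an error, never silently
averaged.

# Outcome scales

`pss_scale()` carries the published PSS-SR severity bands (0 "none",
1–10 mild, 11–20 moderate, 21–35 moderate to severe, 36–51 severe);
integer edges belong to the printed ranges, non-integer scores to the
covering half-open interval.

`eq5d_index()` scores a five-dimension, five-level EQ-5D-5L health
state as intercept minus per-level decrements, times 100 for the
presentation scale, rounded to the nearest integer for display (full
precision is retained when `display = FALSE`). The packaged default
table is a **synthetic UK-style value set**: the exact published tariff
behind the tool's displayed numbers is not redistributable, so the
packaged table is constructed to be monotone within each dimension and
calibrated to the documented anchors — full health 1.00, worst state
−0.28, all-moderate state 0.615 (displaying 62). Its name is recorded
in the table's metadata, and any value set can be supplied as a
`dimension, level, decrement` CSV with an intercept row.

# The sampler

Metropolis-within-Gibbs on the observed-pattern model:

* coefficients β: conjugate Gibbs under independent $N(0, 100^2)$
  priors (sd configurable; wide relative to outcome scales of order
  10–100);
* cluster effects $u_j$: conjugate Gibbs;
* σ and τ: random-walk Metropolis on the log scale under half-Cauchy
  priors (scales 20 and 10; configurable), with Robbins–Monro
  adaptation toward 0.44 acceptance **during burn-in only** — the
  proposal scales are frozen afterwards so the kept chain is a genuine
  Markov chain;
* Δ: drawn from the configured prior per kept iteration
  (component-then-value for mixtures; constant for point masses and
  fixed offsets).

Defaults: 2 chains × 2500 iterations, 1000 burn-in, thin 1. Chains are
seeded deterministically from the configuration seed, so identical
configurations give bit-identical draws. Convergence is flagged (never
silently enforced) when split-$\hat R$ of the treatment effect exceeds
1.05 or its effective sample size falls below 400 — standard practice,
made explicit because nothing in the model dictates a threshold.
Summaries report the posterior mean, equal-tailed 95% credible
interval, $P(\text{favours intervention})$ with exact ties counted a
half, and a kernel-density grid max-normalised for the density-strip
display (darkness proportional to density, darkest at the mode, fading
to the background at the minimum).

Degenerate inputs are handled explicitly: constant draws yield a
single-point density grid and a [c, c] interval; an arm with no
observed outcomes is an inestimable-model error; fewer than 1000 kept
draws is an insufficient-sample error.

# The synthetic-data generators

`generate_trial()` emulates the motivating design: 24 clusters
randomised 1:1 (ICUs), ~60 patients per cluster per period, a PSS-SR
outcome with usual-care baseline mean 18, period effect −1, treatment
effect −2, covariate effects (gender 2, age 1.5, anxiety 4), cluster sd
2, residual sd 8, and a 20% target missingness — the anticipated loss
to follow-up. Outcomes are drawn from the observed-pattern model with
out-of-bounds residuals resampled (so generating means stay
interpretable); missingness is logistic in the covariates and
(optionally) the latent outcome, with the intercept solved numerically
so the marginal rate hits the target exactly in expectation; finally
the missing records' latent outcomes are mean-shifted within each
(treatment-received, period) cell so the realized non-responder mean
equals the responder mean plus the true offset Δ* — the exact
pattern-mixture semantics. The truth sidecar records every generating
parameter plus `marginal_effect`, the pattern-weighted effect implied
by Δ* and the realized missingness, which is the estimand the MNAR
analysis targets (assessing recovery against the raw interaction alone
would conflate the estimand with the offset).

`generate_experts()` scatters elicited modes around true non-responder
means, draws slider sds from a log-normal pair with a configurable
right/left asymmetry factor (1.2 by default, so the asymmetric
machinery is exercised away from the symmetric special case), and
produces designated fractions of unusable (unmoved sliders) and
high-confidence experts. The default panel of 59 experts with ~39%
high confidence mirrors the scale of a realistic elicitation exercise.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: item-level questionnaire structure, free-text
rationale content, informatively varying cluster sizes, non-Gaussian
outcome shapes (floor effects at 0 are only approximated by
resampling), and experts whose biases are correlated with each other
or with the truth. Parameter-recovery results say the machinery is
self-consistent under its own assumptions, not that elicited opinion is
accurate — which is unknowable by design and is exactly why the output
is a labelled sensitivity analysis rather than a single estimate.

# Problem sizes and numerical choices

The test suite and the acceptance script use deliberately modest
problem sizes chosen as the smallest that make the checks sharp:
single-fit checks on trials of 20 clusters × 13 patients × 2 periods
(n = 520) with 2 × 2500 iterations; coverage over 25 replicates with
2 × 1800 iterations and a widened binomial tolerance of [80%, 100%]
(a 95% interval at 25 replicates has sd ≈ 4.4 points); Monte-Carlo
probabilities at n = 10^5 with agreement asserted within 3 standard
errors of an independent quadrature oracle. Quadrature tolerances are
1e−10 (`integrate`) against closed forms at 1e−8 or better; mixture
linearity is asserted at 1e−12.

# Known limitations

* The Gaussian copula coupling is a stand-in for whatever between-arm
  relationship question a study actually asks; only its single
  dependence parameter is exposed.
* Δ defaults to one offset per arm; the subgroup-specific elicitation
  is pooled within expert before analysis. Mapping patients to
  subgroup-specific offsets by covariates would require a documented
  nearest-subgroup rule and is not implemented.
* The packaged value set is synthetic (anchor-calibrated), suitable for
  the worked example and pipeline testing; substantive health-economic
  scoring should supply the licensed national tariff as a CSV.
* Missingness proportions are the per-cell empirical fractions, not
  modelled probabilities.
* Continuous outcomes only; binary and survival outcomes, multiple
  imputation approximations and tipping-point searches are out of
  scope.
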