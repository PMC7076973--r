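# mnarsens

Sensitivity analysis for randomised trials whose patient-reported
outcomes may be **missing not at random (MNAR)**, using expert opinion
elicited as (truncated) split-normal distributions and propagated
through a Bayesian pattern-mixture model.

## The problem

Trials with patient-reported outcome measures (PROMs) routinely analyse
missing outcomes under a missing-at-random (MAR) assumption. For PROMs
this is often implausible: the patients who do not return a
questionnaire tend to differ in their unobserved health status from
those who do. A principled sensitivity analysis asks clinical experts
how different the *mean* outcome of non-responders is likely to be from
that of responders, and re-estimates the treatment effect under those
opinions.

`mnarsens` implements that workflow for a two-arm cluster-randomised
trial with a baseline and an intervention period:

1. **Pattern-mixture model.** Within each randomised arm, the mean
   outcome of the missing pattern is the observed-pattern mean plus an
   offset Δ. The arm-specific offsets (Δ_ctl, Δ_int) cannot be
   estimated from the data; they are the sensitivity parameters that
   receive expert priors.
2. **Elicitation primitive.** An expert's opinion about a mean outcome
   on a bounded scale (PSS-SR 0–51; EQ-5D-5L utility ×100 on −28–100)
   is a *truncated split normal*: mode `m`, left sd σ_L, right sd σ_R,
   renormalised over the scale bounds. With σ_L = σ_R it is the normal
   distribution.
3. **Evaluation and pooling.** Responses are screened for unmoved
   sliders and reviewer-flagged misunderstanding, categorised
   *unusable* / *usable* / *usable with high confidence*, and pooled by
   equal-weight linear opinion pooling on the density scale, giving a
   mixture of bivariate split normals over (Δ_ctl, Δ_int). The *most
   sceptical* and *most enthusiastic* high-confidence experts are the
   ones with the lowest and highest probability that the non-responder
   mean favours the intervention.
4. **Analysis.** A Gaussian linear mixed model (cluster random
   intercepts, period effect, treatment-by-period interaction as the
   effect of interest, elicitation covariates) is fitted to the
   observed pattern by Metropolis-within-Gibbs; Δ is drawn from its
   prior each iteration and enters through the pattern-weighted
   contrast `β_t + p_miss(int)·Δ_int − p_miss(ctl)·Δ_ctl` (plus a
   baseline-imbalance correction). Point-mass-zero priors reproduce the
   MAR analysis exactly. Each scenario is summarised by the posterior
   mean, equal-tailed 95% credible interval, the posterior probability
   the outcome favours the intervention, and a density-strip figure.

Synthetic generators for trials (with a calibrated logistic MNAR
mechanism) and expert panels make every stage testable without any
external data.

## Worked example

```r
library(mnarsens)

od <- "example_run"
cmd_simulate(list(outdir = od, seed = 11,
  trial   = list(n_clusters = 24, patients_per_cluster = 30,
                 delta_true = c(usual_care = 2, intervention = 6)),
  experts = list(n_experts = 20, fraction_unusable = 0.1,
                 fraction_high_confidence = 0.4)))

res <- cmd_analyse(list(
  trial = file.path(od, "trial.csv"),
  responses = file.path(od, "responses.csv"),
  evaluations = file.path(od, "evaluations.csv"),
  anchors = file.path(od, "anchors.csv"),
  outdir = od, seed = 11,
  fit = list(chains = 2, iter = 2500, burnin = 1000)))

print(res$table[, c("scenario", "mean", "cri_lower", "cri_upper",
                    "p_favours_intervention")], digits = 3)
```

prints

```
                scenario  mean cri_lower cri_upper p_favours_intervention
1          complete_case -1.47     -3.13     0.194                  0.960
2                    MAR -1.47     -3.13     0.194                  0.960
3          pooled_usable -1.59     -4.47     1.314                  0.865
4 pooled_high_confidence -1.78     -4.87     1.000                  0.893
5         most_sceptical -1.28     -3.81     1.392                  0.836
6      most_enthusiastic -2.46     -5.34     0.273                  0.961
```

Reading the table: the outcome is PSS-SR-like (lower is better), so
negative treatment effects favour the intervention. The MAR and
complete-case rows coincide here because the observed-pattern model
conditions on the same covariates in both. The MNAR rows re-weight the
arm means by each arm's missingness fraction under the expert Δ priors:
the credible intervals widen (the data carry no information about Δ)
and the posterior probability that the intervention is favourable moves
with the experts' scepticism or enthusiasm. The run directory also
contains `summary.json`, one `strip_<scenario>.pdf` density strip per
row, and a `run.log` recording the seed, configuration hash and every
default applied.

Smaller building blocks are exported individually — e.g.
`split_normal()`, `mixture_pool()`, `eq5d_index(health_state(3,3,3,3,3))`
(which displays `62`), `severity_band(15)` (`"moderate"`),
`pool_experts()`, `fit_pattern_mixture()` — see the help pages and the
methods vignette in `vignettes/`.

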