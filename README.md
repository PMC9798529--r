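# aromat — adaptive Bayesian odor detection threshold testing

Olfactory dysfunction is common and consequential, yet smell is rarely
tested outside the lab: classic detection-threshold protocols (ascending
method of limits, staircases) are accurate but slow, while fast
identification tests confound sensory ability with memory and vocabulary.
`aromat` implements the engine of a rapid, self-administered
detection-threshold test: a disposable card of 17 peel-and-burst odorant
labels paired with an adaptive Bayesian algorithm that reaches a threshold
estimate in 8 yes/no trials. It is written for psychophysicists and
clinical-olfaction researchers who want to study, re-parameterise, or
extend such tests in simulation.

## The model

Each trial asks "can you smell the scent?" about one label — either an
odorant at nominal log10 concentration *x* (the card spans 8 concentrations
from 0 down to −3.5 in half-log steps; 0 ≡ 30% w/w phenylethyl alcohol) or
a blank. A yes/no task confounds sensitivity with willingness to say YES,
so the observer model is a signal-detection psychometric function with two
inferred parameters, the log threshold log τ and the decision criterion λ:

    γ(λ) = Φ(−λ)                                (false-alarm probability)
    P(YES | x) = γ + (1 − γ) · Φ((x − log τ)/s)  (odorant; fixed slope s = 0.5)
    P(YES | blank) = γ

The curve crosses the midpoint between its floor γ and ceiling 1 exactly at
x = log τ, which is the reported threshold. Inference is by grid Bayesian
updating under weakly informative priors log τ ~ N(−3, 100) and
λ ~ N(1, 0.5) (second argument read as variance). After each response the
next label is chosen greedily to minimise the *expected* posterior SD of
log τ, weighting the YES/NO branches by their posterior-predictive
probabilities — blanks are eligible, which is what lets the criterion be
separated from sensitivity. The test always stops after 8 trials. Because
the decision tree only depends on the response history, all 2^8 paths are
precompiled into a lookup table (254 decision entries, 256 terminal
estimates) so a deployed device needs no computation.

Scoring follows ASTM E679 extreme-value rules: all-YES-to-odorant sessions
(with NO on blanks) are imputed at the lowest concentration − 1 log unit
(−4.5), all-NO sessions at the highest + 1 (1.0). Sessions also carry
false-alarm flags (YES to the first blank; YES to all blanks) and a QC
class (posterior SD cutoff for indeterminate response patterns).

A virtual-participant simulator (sex/age effects, classical-twin familial
structure with plantable broad-sense heritability, COVID-history labels,
test–retest) and the corresponding cohort analyses (two-way ANOVA + Tukey
HSD, floor-proportion χ², Falconer heritability H² = 2(R_MZ − R_DZ) with
Fisher-z uncertainty, logistic-propensity 1:1 matching, ANCOVA + two-sample
KS, Pearson test–retest) make the whole pipeline testable end to end
without data collection.

## Worked example

```r
library(aromat)
card <- default_card()
obs  <- virtual_observer(log_tau = -2.4, lambda = 1.6, seed = 2024)
s    <- run_session(observer_responder(obs), card)
summary(s)
```

```
Adaptive odor threshold session
  trials: 8
  label sequence:  1 13 6 16 8 3 2 14
  responses:       Y N Y Y Y N Y Y
  log10 threshold (posterior mean): -2.387
  standard error  (posterior SD):   0.496
  criterion: 1.143 (false-alarm prob 0.127)
  reported threshold: -2.387   QC: DETERMINATE
  false alarms: first blank = FALSE ; all blanks = FALSE
```

The observer's true threshold was −2.4; after 8 adaptive trials the
posterior mean is −2.39 with an SE of 0.50 log10 units (about half a card
step), the estimated criterion 1.14 implies a 13% false-alarm probability,
and no imputation rule fired, so the reported threshold is the posterior
mean. `coef()`, `predict()`, `plot()` and `residuals()` work on the fitted
session like on any model object; `fit_session()` refits a recorded trial
log; `compile_lookup()` + `run_session_table()` reproduce the online engine
exactly.

For a full synthetic study (cohort → sessions → statistics report):

```r
cmd_simulate("results/study", config = cohort_config(seed = 1))
```

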