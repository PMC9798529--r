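---
title: "Methods: the adaptive Bayesian odor-threshold engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive Bayesian odor-threshold engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromat)
```

This vignette is the package's own account of the science it implements:
the observer model and its assumptions, the numerical choices behind the
grid posterior and the greedy policy, what the simulator does and does not
emulate, and where the design was genuinely open.

## The test card

The instrument is a card of 17 single-use odorant labels (ids 0–16).
Label 0 is an unscored blank used to familiarise the participant with the
card's background odor. Among labels 1–16, two are blanks and fourteen
carry phenylethyl alcohol at 8 nominal concentrations ("rungs") spaced in
half-log (0.5 log10) steps; the highest rung is denoted 0.0 on the nominal
log10 scale (30% w/w) and the lowest is −3.5, so the ladder spans 3.5
orders of magnitude — roughly the normosmic range for this odorant. The
extreme rungs appear once, each intermediate rung twice; the duplicates and
blanks are what make response bias identifiable. The specific
label-to-rung permutation is not behaviourally meaningful (the algorithm
sees rung values, not positions), so the package fixes one
version-controlled assignment with the starting label 1 on the
intermediate rung −1.5.

## Observer model

A yes/no detection task confounds sensitivity with the willingness to say
YES. The package therefore models the YES probability as a
guess-rate-floored probit with two inferred parameters — log threshold
$\log\tau$ and criterion $\lambda$:

$$\gamma(\lambda) = \Phi(-\lambda), \qquad
P(\mathrm{YES}\mid x) = \gamma + (1-\gamma)\,
\Phi\!\left(\frac{x - \log\tau}{s}\right), \qquad
P(\mathrm{YES}\mid \mathrm{blank}) = \gamma.$$

Properties that motivate this form:

* the blank response rate is governed by $\lambda$ alone, in
  signal-detection style;
* the curve crosses the midpoint between its floor $\gamma$ and ceiling 1
  exactly at $x = \log\tau$, so the halfway-point definition of the
  reported threshold coincides with the model parameter;
* it has exactly the two inferred parameters that the priors name.

The slope $s$ is a fixed configuration constant, default 0.5 log10 units
(one card step), not inferred: with 8 binary trials there is no usable
information to estimate a third parameter, and freeing the slope would
leak variance into the threshold estimate. There is no lapse parameter
(ceiling fixed at 1) for the same parsimony reason; a strongly lapsing
observer instead surfaces through the QC path as an inconsistent pattern.
Whether the originally deployed instrument used a probit, logistic or
other link is not knowable from the outside; no bit-level equivalence with
any deployed app is claimed, only with the structure described above.

## Priors and the posterior grid

Priors are independent normals: $\log\tau \sim N(-3, 100)$ and
$\lambda \sim N(1, 0.5)$, with the second argument read as a **variance**
(SD 10 and ≈0.707). The SD-10 threshold prior is genuinely weak — over the
plausible range it is nearly flat — which matches its "weakly informative"
role; both hyperparameters are exposed in `prior_config()` so the
SD reading can be configured if desired.

The joint posterior lives on a fixed rectangular grid,
$\log\tau \in [-7.5, 1.5]$ step 0.05 (181 nodes) and
$\lambda \in [-1, 3]$ step 0.1 (41 nodes). Two considerations fixed the
threshold axis:

* it must span the ASTM imputation range (−4.5 to 1.0) with margin, so
  extreme but non-imputed sessions are not clipped;
* it is **symmetric about the prior mean −3**. A near-flat prior truncated
  to an asymmetric window acquires the window's midpoint as its mean; a
  symmetric window keeps the discretised prior mean at exactly −3, so a
  zero-trial session summarises to the stated prior. The criterion axis is
  likewise symmetric about its prior mean 1.

Updating multiplies node masses by the Bernoulli likelihood and
renormalises; updates are pure functions (no mutation), which lets the
lookup-table compiler branch cheaply on a shared parent grid. Mass is
conserved to 1e−10 per update, and doubling the grid resolution moves
point estimates by less than 0.02 log10 units on fixed sessions — the grid
is comfortably inside its discretisation-error budget. The point estimate
is the posterior **mean** of $\log\tau$ and the uncertainty the posterior
SD: both are stable on grids, and the SD matches the instrument's
"standard error" language (a MAP/curvature pair would be noisier under
coarse discretisation).

## Adaptive policy and the lookup table

Trial 1 is always label 1. Thereafter the policy computes, for every label
still on the card (blanks included), the expected posterior SD of
$\log\tau$ after sniffing it,

$$E[\mathrm{SE}] = p_\mathrm{yes}\,\mathrm{SE}(\cdot\mid\mathrm{YES}) +
(1-p_\mathrm{yes})\,\mathrm{SE}(\cdot\mid\mathrm{NO}),$$

with $p_\mathrm{yes}$ the posterior-predictive YES probability, and picks
the minimiser. The objective is deliberately the SD of the
**threshold marginal**, not joint entropy: the criterion is a nuisance
parameter, and the quantity whose uncertainty the test reports is the
threshold. Ties (duplicate rungs give exactly equal objectives) are broken
toward the lowest label id; this determinism is what makes the policy
compilable. The policy is myopic (one-step lookahead); with a fixed
8-trial horizon the gains from non-myopic planning are small and the
deployed-style lookup table requires determinism, not optimality.

Because the next label depends only on the response history, the complete
tree is precompiled: 254 decision entries (histories of length 1–7) and
256 terminal entries (complete histories) carrying the posterior
mean/SD, the ASTM-finalised threshold, the QC class and the false-alarm
flags. The table is serialised as JSON stamped with card and prior
fingerprints, and the loader rejects mismatches. Table-driven and online
sessions agree exactly on label sequences and to 1e−9 on estimates over
all 256 paths (this is asserted in the test suite).

## Scoring

ASTM E679-style extreme-value rules, derived from the card's ladder rather
than hard-coded: YES to every odorant received plus NO to every blank
received imputes `min(ladder) − 1` (−4.5 by default); NO on every trial
imputes `max(ladder) + 1` (1.0). A YES on a blank voids the floor rule —
that pattern is inconsistency, not supersensitivity — while the ceiling
rule ignores blanks because NO on a blank is correct behaviour. The
"indeterminate response pattern" exclusion used in field practice has no
published operationalisation; the package defines INDETERMINATE as
posterior SE above a configurable cutoff (default 1.0 log10 units), which
is monotone in evidence quality and testable. This cutoff is a stand-in,
clearly labelled as such.

## The simulator: what it emulates and what it does not

Virtual observers hold true $(\log\tau, \lambda)$ and a private seeded
uniform stream, so sessions replay exactly. Cohorts are generated from an
additive model on true log thresholds: grand mean −2.06, a −0.50 log10
sex effect (females more sensitive), centred age-bin offsets giving
young-vs-old = −0.94 and middle-vs-old = −0.61 log10 units, an optional
COVID-history effect (default 0 at 15% prevalence), plus a familial and a
unique Gaussian component with combined SD 1.0. These defaults are the
field conditions the engine is designed for; the residual SD of 1.0 is
consistent with the ~12% floor fraction such cohorts show, and observer
criteria are drawn $N(1.5, 0.5^2)$ so the mean blank false-alarm
probability $\Phi(-\lambda)$ sits near the ~7.5% seen in field use.

Twin structure follows the classical model under which Falconer's formula
is consistent: MZ co-twins share the full familial component, DZ co-twins
share a component with half the familial variance, so
$H^2 = 2(r_{MZ} - r_{DZ})$ recovers the planted share of familial
variance. Test–retest runs two sessions per observer with fresh response
randomness; day-to-day jitter of the true threshold defaults to 0, so
sub-unity reliability isolates the instrument's 8-trial measurement error.
No within-subject day-to-day variance is published for such tests; any
jitter chosen to match a particular field reliability would be a
calibration exercise, so none is baked in.

What the simulator does **not** emulate: realistic demographic sampling,
specific anosmias and odorant-specific genetics, lapses/malingering,
learning or fatigue across trials, label cross-contamination, and
non-Gaussian threshold distributions. Passing recovery tests therefore
demonstrates the internal consistency of the engine under its own
generative assumptions — not field validity.

## Statistical analyses

The cohort analyses are the standard tools, called through base R and
`car`: two-way fixed-effects ANOVA (`aov`/`lm`, type II sums of squares by
default — appropriate for the unbalanced cohorts the simulator produces,
configurable to type I), `TukeyHSD` on age bins, uncorrected Pearson χ²
for the 2×2 floor-proportion contrast, `glm`-based logistic propensity
scores with greedy 1:1 nearest-neighbour matching without replacement (no
caliper by default), type II ANCOVA `threshold ~ covid + sex + age` with
age continuous, asymptotic two-sample KS, and Pearson test–retest
correlation.

Falconer uncertainty uses the Fisher transformation:
$\mathrm{Var}(z) = 1/(n-3)$ per correlation, delta-method back-transformed
to $\mathrm{Var}(r) \approx (1-r^2)^2/(n-3)$ and propagated as
$\mathrm{Var}(H^2) = 4(\mathrm{Var}(r_{MZ}) + \mathrm{Var}(r_{DZ}))$; the
named approach fixes no formula in the literature it comes from, so this
standard route is fixed here and documented. The MZ-vs-DZ comparison is a
z test on Fisher-z scores with pair counts as sample sizes; whether such a
test should be read one- or two-sided is convention-dependent, so both p
values are reported with two-sided primary. On the rounded field
correlations 0.46/0.19 with 143/37 pairs this machinery reproduces the
familiar numbers: $H^2 = 2(0.46-0.19) = 0.54$ (unrounded inputs give
0.55), SEs ≈ 0.07/0.16, SE of $H^2$ ≈ 0.36, one-sided p ≈ 0.055.

Age bins are the closed intervals 18–37, 38–57, 58–77 (equal 20-year
widths); ages outside them are excluded by construction in the simulator.

## Problem sizes and numerical checks

The test suite and acceptance script use sizes chosen to make Monte-Carlo
error small relative to each check's tolerance: effect-recovery pipelines
use four replicate cohorts of 500 per group (a single cohort's
true-difference sampling SD is already ~0.063, a third of the ±0.15
recovery band, so replication averages it down rather than widening the
band); heritability recovery uses 2000+2000 twin pairs (SE of $H^2$
≈ 0.05); the type-I-error check uses 500 replicates of a ~480-person
cohort (binomial SE ≈ 1%). Lookup-table/online equivalence is exhaustive
over all 256 paths, not sampled.

Two empirical behaviours of the instrument worth knowing: interior
thresholds are recovered with |median bias| < 0.15 log10 units from 8
trials, and the extreme-value imputations slightly **amplify** group
differences when group means sit near the ladder ends (imputed values lie
beyond the tested range), which is visible as a small upward shift in the
recovered young-vs-old contrast. Both are properties of the design being
modelled, not artifacts of this implementation.

## Known limitations

* The functional form and numerical scheme of any deployed instrument are
  not public; equivalence is claimed only with the described structure.
* The INDETERMINATE cutoff is an operationalisation, not a published rule.
* The policy is myopic and the stopping rule fixed at 8 trials; variable
  stopping on an uncertainty criterion is out of scope.
* Cohort-level reported quantities from any particular field study (false
  alarm rates, test–retest r, group means) depend on that cohort's
  composition and are not reproduced here — the package recovers planted
  effects under its own generative model instead.
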