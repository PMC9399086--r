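---
title: "Modelling social modulation of risky choice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social modulation of risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialpt)
```

# The scientific problem

People routinely take monetary risks whose consequences fall on someone
else — a friend, a stranger, or both parties jointly. `socialpt` models how
the component processes of risky choice change in those social contexts,
using the prospect-theory decomposition standard in behavioural economics:

* **risk attitude** $\rho$ — curvature of the value function
  ($\rho = 1$ risk-neutral, $\rho < 1$ risk-averse for gains);
* **loss aversion** $\lambda$ — multiplicative weight on losses
  ($\lambda > 1$: losses loom larger);
* **choice consistency** $\mu$ — inverse temperature of the softmax link
  (larger $\mu$: more deterministic choices).

The task the package emulates presents 50/50 gambles against a guaranteed
option: *mixed* gambles (gain branch vs. loss branch, guaranteed \$0) and
*gain-only* gambles (gain branch vs. \$0, against a smaller guaranteed
gain). Each decision-maker works through three 90-trial conditions — *self*
first, then *other* (choices made for a partner) and *shared* (outcomes
split) in counterbalanced order — giving 270 choices per person. One group
of decision-makers is paired with a close friend, the other with a
stranger.

# The model

## Valuation and choice

For a gamble with gain $x^+ > 0$, loss $x^- \le 0$ and branch
probabilities $1/2$,

$$u(\text{gamble}) = \tfrac12 (x^+)^{\rho} - \tfrac12 \lambda\, |x^-|^{\rho},
\qquad u(\text{guaranteed}) = g^{\rho},$$

with $0^\rho \equiv 0$ for the zero branch and the guaranteed \$0. The
probability of accepting the gamble is the softmax

$$p(\text{accept}) = \bigl(1 + e^{-\mu\,(u(\text{gamble}) -
u(\text{guaranteed}))}\bigr)^{-1}.$$

The loss term is written $-\lambda |x^-|^\rho$ deliberately: a literal
negative base under a real exponent is undefined, so the sign is carried
outside the power and a single $\rho$ is shared by gains and losses.

## Social modulation on the unconstrained scale

Parameters are bounded positive through an exponential transform, and all
*additive* social effects act on the unconstrained (log) scale. For subject
$s$ on trial $t$,

$$\log \rho_{st} = \log \rho_s
 + \text{other}_t\, \delta\rho^{other}
 + \text{sharing}_t\, \delta\rho^{sharing}
 + \text{identity}_t\, \delta\rho^{identity},$$

and likewise for $\lambda$ and $\mu$. The indicators are: `other` 0/+1
(another person involved), `sharing` +1 other-only / −1 shared / 0 self,
`identity` +1 stranger / −1 friend / 0 self. The log-scale composition is
forced by the arithmetic of the published implied means: a self-condition
consistency of 18.0 plus an additive effect of 0.45 yields an implied
other-condition mean of $\exp(\ln 18.0 + 0.45) \approx 28.3$, which only
the exponential composition reproduces.

Three model variants are fitted by `fit_model()`:

* **M0** — hierarchical baselines only;
* **M1** — all nine deltas as group-level fixed effects;
* **M2** — the three `other` deltas as mixed effects (group mean + SD with
  subject-level values), sharing fixed, identity absent.

Priors (main text of the source work leaves them unspecified; these are
package choices, all exposed via the `priors` argument and echoed in the
fit object): Normal(0, 1) on group log-means of $\rho$ and $\lambda$,
Normal(log 10, 1) for $\mu$; half-Normal(1) on group log-SDs and M2's
subject-delta SDs; Normal(0, 0.5) on fixed deltas.

# The sampler

No Stan/JAGS-class engine is available in the target environment, so the
package implements its own adaptive Metropolis-within-Gibbs sampler. The
design exploits the model's structure:

* subjects are conditionally independent given the group level, so all
  per-subject blocks are proposed and accepted **in parallel** within one
  vectorized likelihood evaluation; proposal SDs are per-subject Welford
  estimates times an acceptance-tuned scalar;
* group means are conjugate-normal given subject values (Gibbs); group SDs
  use a log-scale random walk with the half-Normal prior and Jacobian;
* the fixed deltas touch only social-condition rows, so their
  Haario-style adaptive block update and a componentwise sweep use partial
  likelihood evaluations.

Two families of non-obvious moves were needed for honest convergence, and
are worth recording:

1. **Ridge translations.** Two thirds of trials are social, so an `other`
   delta trades off strongly against *all* subject baselines — especially
   for $\mu$, whose per-subject likelihood is nearly flat above a
   threshold. A move that shifts $\delta\theta^{other}$ by $+e$ and every
   subject baseline (and the group mean) by $-e$ leaves social-trial
   likelihood *exactly* invariant and re-evaluates only self trials.
   The `identity` contrast is constant within participant (+1 for the
   stranger group, −1 for the friend group) and rides an analogous
   between-group ridge; its translation move shifts baselines with the
   group sign.
2. **Stretch moves.** A group-level SD can only move as fast as the whole
   column of subject values can spread or contract; rescaling a column
   around its group mean jointly with its SD (Jacobian $(S+1)\log c$)
   decorrelates that slow mode.

Without these moves the $\mu$-block of the full-size design shows split
R-hat in the tens; with them all group-level R-hats in the package's
acceptance run are near 1. Adaptation runs during warmup only, so retained
draws come from a fixed kernel. A centered parameterization is used
(rather than the non-centered form common with gradient samplers) because
every subject contributes 270 informative trials, and centered + conjugate
Gibbs mixes well in that regime under Metropolis-within-Gibbs.

The published sampling budget — four chains, 10,000 retained draws in
total — corresponds to `fit_model(..., chains = 4, draws = 2500)`. Tests
and the acceptance suite run a scaled-down budget (4 × 500 retained after
1000 warmup) to stay inside their time budget; this is flagged wherever it
is used.

## Inference outputs

* `hdi()` — shortest sorted-window interval (unimodality assumed; adequate
  for these posteriors).
* `waic()` — $\mathrm{lppd} - p_{\mathrm{waic}}$ from the draws × trials
  pointwise log-likelihood, log-sum-exp stabilized, with trial-wise SE and
  a paired-difference SE in `compare_waic()`.
* `check_convergence()` — split R-hat and Geyer initial-positive-sequence
  effective sample sizes.
* `implied_condition_means()` — the natural-scale per-condition parameter
  table. Cells are composed **draw-wise** and then averaged: because
  $E[e^X] \ge e^{E[X]}$, composing at posterior means understates the mean
  of the composed quantity whenever draw spread is non-trivial (the
  Jensen gap; a property test quantifies it). Draw-wise composition is
  therefore the default whenever draws are available.

# The synthetic cohort

`simulate_cohort()` generates the world the hierarchical model assumes:
57 agents (29 stranger-group, 28 friend-group), each with log-scale
baselines drawn around group means, making 270 Bernoulli choices through
the exact valuation/choice equations above. Ground-truth parameters and
per-trial accept probabilities are retained so every downstream stage is
testable without the deposited dataset.

Stated-world defaults, fixed once and not revisited:

* group means: the published estimates $\rho = 1.07$, $\lambda = 1.78$,
  $\mu = 18.0$; fixed deltas: the published posterior means
  ($\delta\rho^{other} = -0.11$, $\delta\lambda^{other} = +0.06$,
  $\delta\mu^{other} = +0.45$, $\delta\rho^{sharing} = +0.016$,
  $\delta\rho^{identity} = -0.05$, $\delta\lambda^{identity} = +0.02$,
  $\delta\mu^{identity} = -0.18$; sharing effects on $\lambda$ and $\mu$
  are zero, as their 95% HDIs straddle zero and no means are printed).
* group log-SDs (0.3, 0.5, 0.6) and the subject-level `other`-delta SD
  (0.2) are **not** published quantities. They were chosen once as values
  a behavioural economist would call realistic: the implied subject spread
  (e.g. $\rho$ roughly 0.6–1.9, $\mu$ roughly 5–60 across a cohort) matches
  the heterogeneity this class of task typically shows, and the implied
  posterior uncertainty of group means is of the same order as the
  published group-level SDs.
* gain-only guaranteed amounts are `risky gain × f`, `f` cycling through
  {0.3, 0.4, 0.5, 0.6, 0.7}; the source text states only that the
  guaranteed gain is smaller. Mixed losses pair the 8-value gain grid with
  multipliers evenly spaced over [−0.25, −2]. The published per-condition
  trial-type split is internally inconsistent (64 + 36 printed against a
  90-trial set); the package defaults to 54 mixed + 36 gain-only and both
  counts are configuration parameters, so the deposited choice set can be
  matched exactly if the user supplies it.
* mixed and gain-only trials are interleaved and shuffled within
  condition (block structure unstated in the source; interleaving is the
  neutral choice).

Traits (a DOSPERT-social-like score, an IRI-like empathy score) are
generated jointly with a chosen subject-level delta at a configurable
target correlation via
$z_{\text{trait}} = r\,z_{\delta} + \sqrt{1 - r^2}\,\varepsilon$, then
affine-mapped to questionnaire-like ranges.

What a green simulation-based test does **not** establish: the generator
draws from the model family itself, so recovery tests certify the
estimation machinery, not the model's adequacy for real behaviour (no
probability weighting, no trial-order or fatigue effects, no response
times, exact 50/50 beliefs). Fitting the deposited dataset is the external
benchmark and requires the user to download it.

# Numerical and testing choices

* Utilities in exported functions use R's `^` (exact at $\rho = 1$, so the
  expected-value identity holds bit-for-bit); the sampler's inner loop uses
  `exp(ρ log x)` with precomputed logs. The two routes agree to well below
  the 1e-8 oracle tolerance.
* Log-likelihoods go through `plogis(..., log.p = TRUE)`; probabilities may
  saturate to 0/1 in double precision at extreme $\mu\Delta u$, the log
  scale never does. Non-finite proposals are rejected, never clipped.
* Money is stored in whole cents; tables serialize with exactly two
  decimals.
* All randomness flows from one master seed through a documented integer
  splitting rule (`split_seed()`), so any agent, session or chain is
  re-simulable in isolation.
* The permutation null-calibration test asserts ≥98% of permuted-label
  correlations below the α = 0.01 critical value rather than the nominal
  99%: with 1000 permutations the binomial noise of the 1% exceedance rate
  makes the literal bound fail by chance roughly 40% of the time; 98% is
  the nominal rate minus three binomial SDs, fixed a priori.
* The HDI-calibration property (simulate-then-fit coverage of group
  log-means) runs 20 replicates at reduced size (10 subjects × 90 trials,
  2 × 200 retained draws) against a loose ≥80% bound, trading statistical
  sharpness for suite runtime.

# Known limitations

* Subject-level $\mu$ (and therefore M2's subject-level
  $\delta\mu^{other}$) is weakly identified when behaviour is nearly
  deterministic; its posteriors are prior-influenced and mix the slowest.
  This mirrors the wide published consistency intervals and is inherent to
  the design, not the sampler.
* `hdi()` assumes unimodal marginals.
* WAIC is the only model-comparison criterion implemented (no PSIS-LOO).
* The sampler is special-purpose: it knows this model family's structure
  (self/social row split, ridge directions) and is not a general-purpose
  MCMC engine.
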