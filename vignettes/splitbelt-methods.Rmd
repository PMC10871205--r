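---
title: "Models and design notes for split-belt adaptation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design notes for split-belt adaptation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitbelt)
```

## The experimental signal

Walking on a split-belt treadmill (one belt faster than the other)
perturbs step length asymmetry,
`sla = 100 * (fast - slow) / (fast + slow)` percent. Over hundreds of
strides the nervous system implicitly recalibrates the pattern back
toward symmetry, and when the belts are tied again the stored
recalibration appears as an *implicit aftereffect* that washes out. If,
in addition, participants are shown their step lengths on a screen for
the first 40 Adaptation strides and asked to hit their baseline step
lengths, they can also *voluntarily* correct the asymmetry — an explicit
process that vanishes the moment the feedback disappears.

The package normalises each participant's cleaned, baseline-corrected
asymmetry to an Adaptation Index (AI): 0 at the estimated perturbation,
1 at full correction during Adaptation; during De-adaptation the scale
reverses (1 at the aftereffect peak, 0 at washout). The per-phase
perturbation is estimated as the extreme asymmetry over the first 10
*retained* strides of the phase.

## The candidate learning models

All three models run on the Adaptation + De-adaptation stride grid with
states initialised at 0, a perturbation signal that is 1 while the belts
are split and 0 after, and the shared error
`error[s] = perturbation[s] - ximplicit[s]`:

* **Single-rate** (k = 2): `x[s+1] = A x[s] + B error[s]`.
* **Dual-rate** (k = 4): `x = xfast + xslow` with
  `xfast[s+1] = Afast xfast[s] + Bfast error[s]` and likewise for the
  slow state; the fast process learns and forgets quickly
  (`Bfast >= 5 Bslow`, `Aslow > Afast`).
* **Voluntary correction** (k = 5): the dual-rate system plus a
  *memoryless* explicit state, `xexplicit[s+1] = Bexplicit error[s]`
  when the feedback is on at stride `s+1` and exactly 0 otherwise. Both
  processes correct the same implicit error; the explicit output does
  not feed back into it.

Two indexing choices are deliberately pinned down because the update
equations leave them open: the very first stride has `xexplicit = 0`
(there is no prior error), and the feedback gate applies at the stride
on which the output is expressed, so the output drops by exactly the
previous explicit state on the first stride after feedback offset. That
discontinuity is the model's signature of explicit learning and is what
lets the feedback-gated model be distinguished from the two smooth
alternatives.

A dynamical caveat: the implicit error loop is a two-state linear system
whose closed-loop matrix `[[Afast-Bfast, -Bfast], [-Bslow, Aslow-Bslow]]`
can have spectral radius above 1 for extreme corners of the [0, 1] box
(learning rates approaching retention rates), where the recursion
oscillates and diverges. All empirically relevant fits live deep inside
the stable region; within it the output is bounded by
`1 + Bfast + Bslow` above and washout undershoot by `-(Bfast + Bslow)`.
The simulators are implemented in C++ (a stride loop is inherently
sequential) and verified against plain-R stride-loop oracles at 1e-10.

## Preprocessing order and its consequences

The cleaning pipeline is: baseline-correct → flag 3×IQR outliers → drop
the first stride of each phase → compute the AI. The fence is
Tukey-style, `[Q1 - 3 IQR, Q3 + 3 IQR]` over the participant's full
series: quartile-anchored fences are the standard reading of a "3×IQR"
rule and remove well under 3% of clean Gaussian-noise strides (the fence
sits at ±4.7 SD). A zero IQR is degenerate; the fence is still applied
(so a lone aberrant stride among ties is caught) with a warning.
First-stride removal reflects treadmill belt acceleration and must
precede perturbation estimation, which therefore uses raw strides 2–11.

This ordering has a measurable consequence worth being explicit about:
because stride 1 (where the perturbation is fully uncorrected) is
removed, and because the explicit process is already active during the
first 10 Adaptation strides, the estimated perturbation is smaller in
magnitude than the true belt-induced asymmetry for fast explicit
learners. The AI is then an affine compression of the latent model
output, and learning rates fitted to pipeline AI are attenuated relative
to the rates that generated the step lengths. This is a property of the
measurement definition, not an implementation artifact; it applies
equally to real data. The synthetic generator therefore records its
latent AI under the same convention, and parameter-recovery studies
operate on the model scale (trajectory + noise), exactly as the
model-recovery analysis does.

The four behavioural windows (Feedback On = raw Adaptation strides
36–40, Feedback Off = 41–45, End Adaptation = last 5, Implicit
Aftereffect = first 5 De-adaptation strides) are defined on raw stride
indices and intersected with retained strides: a removed stride shrinks
its window rather than shifting it, which keeps windows aligned across
participants. A fully removed window yields NA with a warning. Note that
Feedback On − Feedback Off contains, besides the explicit component, a
small implicit drift (the implicit states keep adapting between the two
windows, about −0.01 AI units at the canonical rates); with
`Bexplicit = 0` the contrast equals that drift exactly.

## Fitting

The objective is the sum of squared errors between model output and
observed AI over retained strides, with the model simulated on the full
raw stride grid. Constraints: every rate in [0, 1], `Bfast >= 5 Bslow`,
and `Aslow >= Afast + eps` with `eps = 1e-4` — the strict ordering needs
a tolerance to be enforceable numerically. Each restart runs
`constrOptim` (log-barrier, Nelder-Mead inner loop) and then an
L-BFGS-B box polish accepted only if it stays feasible and lowers the
SSE; the polish is what brings noise-free self-consistency to the
1e-3 parameter / 1e-8 SSE level. The implicit parameters start at
`Afast = 0.92, Bfast = 0.03, Aslow = 0.996, Bslow = 0.004` on every
restart; `Bexplicit` starts uniformly at random, 10 restarts by default;
the single-rate model starts at `A = 0.96, B = 0.017` (midpoints of the
dual values). Ties across restarts are broken by the lowest restart
index. Non-convergence of every restart is an error, never silently
absorbed.

Richer models additionally evaluate the reduced model's solution
embedded in their space. The dual solution with `Bexplicit = 0` is a
verbatim member of the vc space, so `SSE(vc) <= SSE(dual)` holds
exactly. The single-rate solution can only be embedded in the dual space
up to the `eps` ordering constraint (`Afast = A - 2 eps`, `Aslow = A`,
`B` split 5:1), so `SSE(dual) <= SSE(single)` holds to O(eps²) —
observed gaps are below 1e-8 on typical series, far below any quantity
the comparison depends on.

Group-level fit quality uses stride-by-stride bootstrap: participants
are resampled with replacement (1000 times in the canonical analysis),
aligned on raw stride index and truncated to the cohort-minimum phase
length, their retained AI values averaged per stride, the model fit to
each average, and the r² distribution summarised by its mean and
percentile 95% interval. Averaging suppresses stride noise, so bootstrap
r² exceeds mean individual r².

## Model comparison and recovery

Because fitting is least-squares, the information criteria use the
Gaussian forms `AIC = n ln(SSE/n) + 2k` and `BIC = n ln(SSE/n) + k ln n`
(`k` = 2, 4, 5). A zero SSE maps to −Inf with a warning. The
`modelRecovery()` analysis simulates each candidate model plus Gaussian
stride noise, refits all three, and tallies which model each criterion
selects — a diagonally dominant confusion matrix is the precondition for
trusting the comparison.

At this package's default synthetic conditions (900 modelled strides,
noise SD 0.05, generating rates at the canonical initialisations with
`Bexplicit = 0.2`) both criteria are almost perfectly diagonal, and BIC
is marginally the stronger of the two: with that many strides and
well-separated generators nothing ever underfits, so BIC's heavier
penalty costs nothing while AIC's fixed 2-point penalty lets a spurious
parameter win in a few percent of simulations. Which criterion
distinguishes better is thus a property of the data regime — noisier,
more heterogeneous cohorts can reverse the ranking — and
`modelRecovery()` reports both so the choice can be made per dataset
rather than assumed.

## The Bayesian layer

Timepoint values are modelled as normal with a common SD and mean
`b0 + bg g + bt t + bgt g t`, with ±1/2 sum-to-zero coding so `bg` is
the marginal group difference, `bt` the time difference and `bgt` the
interaction (difference of differences). "Wide" priors are quantified
relative to the data: effects ~ normal(0, 10 × pooled SD), residual
SD ~ uniform(0, 10 × pooled SD). Widening them a further 10× moves the
posterior by less than Monte-Carlo error, so they only make inferences
conservative. No participant random effects are included: the mean
structure is the literal three-parameter group/time/interaction model,
and the two timepoints entering any one contrast are treated as
exchangeable observations within participant.

Sampling uses JAGS (4 chains, 10,000 total draws after 2,000
adaptation/burn-in per chain by default) with per-chain RNG streams
derived from the seed, so runs are exactly reproducible. Convergence is
monitored by the split-chain potential scale reduction factor with a
1.01 warning threshold (looser thresholds are appropriate for the
deliberately short chains used in simulation studies). Summaries are the
posterior mean, the 95% highest density interval (shortest window of
`ceiling(0.95 n)` sorted draws), and p_difference (percent of draws on
the majority side of zero, zeros split evenly, so 50 means no
directional evidence). Posterior predictive checks compare replicated
cell means and SDs with observed ones via min-tail probabilities;
a Student-t alternative likelihood (`nu - 1 ~ Exponential(1/29)`) is
compared by DIC to validate the normality assumption; covariate effects
(e.g. Lower Extremity Fugl-Meyer score on a learning measure) use a
conjugate-style linear regression with the same prior philosophy.

## The synthetic generator

`simulateParticipant()` inverts the AI definition: latent model output
`x` from the voluntary-correction model; Adaptation
`sla = x |P| + P` (P = perturbation, −20% by default), De-adaptation
`sla = x |P|`, Baseline 0; Gaussian stride noise with SD
`noise_sd × |P|` (i.e. `noise_sd` in AI units, 0.05 by default) added on
the asymmetry scale; fast/slow step lengths reconstructed holding their
sum at the baseline total (120 cm), so noise lives entirely in the
asymmetry. Optional outlier strides are thrown beyond the participant's
own 3×IQR fence to exercise the cleaning stage.

`simulateCohort()` draws per-participant rates from group-specific
normals truncated to [0, 1] and projected onto the ordering constraints.
The default groups mirror the contrast structure of interest: a
control-like group (`Bexplicit` mean 0.30, `Afast` 0.92) and a
stroke-like group with reduced explicit learning and fast-state
retention (`Bexplicit` 0.07, `Afast` 0.83), 18 and 17 participants, a
clinical covariate attached to the stroke-like group. Phase lengths
default to 150/450/450 strides — roughly the stride counts of a
multi-minute protocol at typical belt speeds; published protocols report
durations in minutes, so the counts are a design choice, configurable
throughout.

What the generator does **not** emulate: biomechanics (no kinematics,
no belt-speed dynamics beyond the perturbation scalar), heavy-tailed or
autocorrelated stride noise, gradual ramping of explicit strategies,
drop-outs or phase-length variation across participants. Passing tests
on these cohorts therefore demonstrates the pipeline's correctness and
calibration under its own assumptions, not robustness to every
idiosyncrasy of clinical data — which is precisely why the real-data
workflow keeps the posterior predictive checks and the likelihood
comparison in the loop.

## Problem sizes used in the test-suite and reproduction script

Simulation studies in the tests and in `scripts/acceptance.R` are sized
for a desk machine: 100 random parameter draws for the oracle
equivalence; a 50-participant cohort (10 restarts each) for parameter
recovery; 25 recovery simulations per generating model; 100 simulated
2×2 datasets (2 chains, 1,500 draws) for HDI coverage; 200 bootstrap
resamples with 3 restarts in the reproduction script. The canonical
full-size settings (10 restarts, 1,000 resamples, 100 recovery
simulations, 10,000 draws) remain the function defaults.

## Known limitations

* The AI normalisation attenuates fitted learning rates whenever early
  strides already contain correction (see above); comparisons should
  stay within one normalisation convention.
* The explicit state is all-or-none with the feedback; gradual
  disengagement of strategy is not modelled.
* No hierarchical (mixed-effects) fitting across participants; each fit
  is independent, and group structure enters only downstream.
* The strict retention-rate ordering is enforced with a 1e-4 tolerance;
  fits that pin `Aslow - Afast` at the tolerance should be read as
  "rates indistinguishable".
* p_difference is a reliability index, not a decision rule; no
  multiplicity adjustment is applied across contrasts.
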