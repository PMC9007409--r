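---
title: "Methods: estimating reward and likelihood weighting in go-before-you-know reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating reward and likelihood weighting in go-before-you-know reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

In a go-before-you-know reaching task, a participant must launch a planar
reach toward two candidate targets before learning which one is correct. Two
qualitatively different strategies are available: commit early to one target
(a *direct* reach) or launch between the targets and steer after the reveal
(an *intermediate* reach). Each target carries two kinds of desirability —
an exogenous monetary reward and an endogenous success likelihood (how often
that target turns out to be correct) — and the two can be placed in
opposition. The question this package operationalizes is *how strongly each
strategy weighs likelihood against reward*, summarized by a frequency weight
$w_f \in [0, 1]$ (reward weight $w_r = 1 - w_f$).

The package implements the full estimation stack:

1. **Kinematics** — movement onset by a tangential-velocity criterion
   (0.05 m/s for the two-target layouts, 0.02 m/s for the five-target
   layout), initial reach direction as the velocity-vector angle 100 ms
   after onset, and the per-experiment exclusion rules (initial direction
   beyond 45° or 75° from the midline; movement-time limits of 1000, 650 and
   2500 ms).
2. **Classification** — *temporal* for the two-target layouts: the reach is
   direct iff the instantaneous heading first enters the angular window
   subtended by either target (`T_commit`) strictly before the reveal time
   plus a 60 ms perceptual delay; *geometric* for the five-target layout:
   intermediate iff the path intercepts the central rectangle. Outcomes are
   typed hit / choice error / motor error from minimum path distances to the
   correct and incorrect target centres (hit radius 1.5 cm = target radius
   plus cursor radius).
3. **Bias estimation** — initial directions aligned so the more-rewarded
   side is positive, pooled across participants, and fit per condition with
   a two-component Gaussian mixture (direct reaches; the rewarded-side
   mixing proportion is the choice bias `D_choice`) and a single Gaussian
   (intermediate reaches; the mean is `I_bias`). Uncertainty comes from a
   participant-level bootstrap: 75% of participants sampled per iteration,
   1000 iterations, invalid iterations dropped and counted.
4. **Weight estimation** — ordinary least squares of bias on the raw ratio
   along each *pure* axis (reward varying at likelihood 1:1, and vice
   versa), then a grid search over $w_f \in [0,1]$ (step 0.001) minimizing
   the squared error of $w_f\,L(f) + (1-w_f)\,R(r)$ against the biases
   observed in *mixed* conditions (both ratios ≠ 1). One weight per
   bootstrap iteration (pooled designs) or per participant (five-target
   design); distributions compared against 0.5 and between strategies with
   t and Kolmogorov–Smirnov tests.
5. **Subjective value** — the neuroeconomic reading
   $SV_i = P_i R_i^{\alpha}$, bias $\propto SV_1/SV_2$: dividing the bias by
   the likelihood ratio isolates a power law in the reward ratio, fit by
   log–log OLS. Intermediate biases are first rescaled onto the unit range
   (angle / 45° + 0.5).
6. **Risk attitude** — a linear point of equivalence (clamped to 5–20
   cents) and a logistic psychometric fit of gamble choice on the reward
   difference, whose 0.5 crossing is the indifference point.
7. **Parameter recovery** — the generative simulation validating the weight
   estimator (below).

# The synthetic-data generator

Because the estimation stack is the deliverable, the package ships a
generator that produces kinematic sessions with *known* ground truth.

**Condition biases.** The generator realizes the estimand directly: on pure
axes the per-condition bias follows a straight line in the raw ratio
(defaults are the group-level slopes observed in the blockwise-frequency
experiment: −0.04 and +0.01 per unit ratio for the direct choice bias,
−0.37° and +0.12° for the intermediate bias), and in mixed conditions the
bias is exactly $w_f\,L(f) + (1-w_f)\,R(r)$. This makes the generating
$w_f$ identifiable by construction — the estimator applied to noiseless
biases returns it exactly — so end-to-end recovery error isolates sampling
noise and pipeline distortions rather than model mismatch. (The
parameter-recovery module instead uses the expected-value-product generative
model described below, which has a small structural estimator bias of its
own; keeping the two generative models in their respective roles is a
deliberate design choice.)

**Choices and trajectories.** Strategy is Bernoulli($p_{int}$) per trial,
independent across trials. A direct reach draws its target by a Bernoulli
against the condition's choice probability and launches at the target
direction plus Gaussian angular noise (`motor_sd_deg`, default 2°, about
0.7 cm endpoint scatter at 20 cm — typical of rapid planar reaches); from
movement start the heading homes on the *chosen* target with a slow
(200 ms) exponential time constant, so the launch noise survives in the
100 ms initial-direction probe while the endpoint converges on the target,
as online feedback correction does in practice. An intermediate reach
launches at the condition's mean intermediate direction plus the same noise
and keeps that heading until `reaction_ms` (default 200 ms) after the
reveal, then homes on the revealed target with a fast (40 ms) constant. The
speed profile is a symmetric minimum-jerk bell whose peak comfortably
exceeds the task's 0.3 m/s requirement; the reveal triggers when the hand
passes 4 cm or 0.1 m/s (two-target layouts) or crosses the central
rectangle (five-target layout).

A constant-rate heading interpolation toward the instantaneous target
direction was tried first and discarded: because the target direction drifts
away as the hand advances, a fixed rate chosen at turn onset can fail to
intercept the target. The proportional (exponential) correction always
converges and produces the same commit-time structure.

**What the generator does not emulate.** Reaction-time variability,
trial-to-trial strategy dynamics, biomechanical anisotropies, online
corrections on *choice-error* trials, and participant idiosyncrasies beyond
the profile parameters. Passing tests therefore show that the estimation
stack is correct and well calibrated under the task's stated design — not
that it is robust to every pathology of real kinematic data.

**Sampling rate.** The generator defaults to 100 Hz (hardware records at
1000 Hz); every threshold is expressed in rate-independent units and the
kinematic estimators use central finite differences over a ±2-sample
window, so the choice only affects temporal resolution. Tests use 50–100 Hz
to stay fast.

# Numerical choices

* **EM mixture fit.** Means initialized at the two aligned target
  directions, SD 10°, equal proportions; convergence at 1e−6 on the
  log-likelihood; SD floor 0.25°. A fit is invalid when the component means
  are closer than 5° or a proportion falls below 0.02. Because that start is
  already in the global basin for well-separated reach modes, jittered
  restarts (up to 20) are attempted only when the first fit is invalid;
  unconditional multi-starts inside a 1000-iteration bootstrap would cost
  runtime without changing any fixture result.
* **Bootstrap.** 75% of participants *without* replacement (a literal
  reading of resampling a "subset"); with-replacement sampling is available
  via `replace = TRUE`. Minimum 10 pooled trials per fit; iterations with
  any failed fit are dropped and counted, never silently.
* **Weight grid.** Step 0.001 on [0, 1]; ties resolve to the smaller
  weight. The closed-form least-squares solution in $w_f$ exists for this
  linear model and serves as an independent oracle in the tests; the grid is
  the shipped path because it clamps to the interpretable domain by
  construction.
* **Mixed-condition SSE** is unweighted, one term per condition.
* **Exponent fit.** Log–log OLS (exact on noiseless power laws); points
  with nonpositive bias are dropped with a count. Direct biases enter as raw
  proportions, matching the rescaled intermediate range.
* **Psychometric fits.** The linear point of equivalence regresses the 0/1
  sure-bet indicator trialwise (a binned option was considered and left
  out: at the assay's trial counts the two give near-identical crossings).
  The logistic indifference fit detects complete separation (non-converged
  or extreme coefficients) and refits with two half-weight
  pseudo-observations at the design extremes, flagged.
* **Angles** live in (−180, 180], boundary ties toward positive; alignment
  re-signs so the more-rewarded side is positive, with the counterbalance
  label carrying the orientation in equal-reward blocks (the frequent side
  is always the opposite side, hence negative).
* **End of motion** is the first post-peak dwell of ≥50 ms below the onset
  threshold, else the last sample. Borderline onsets (a local speed minimum
  within 20 ms of the crossing) are flagged — the algorithmic stand-in for
  the visual onset verification used with real recordings.
* **Commit-time degeneracies.** Samples with the hand inside a target's
  hit disc (undefined window) or at rest (undefined heading) are skipped.
  A commit exactly at reveal + 60 ms counts as intermediate (strict
  "before"). The same 60 ms delay applies to both two-target layouts.

# The parameter-recovery module

The recovery harness validates the weight estimator with its own generative
model: the preference for the more frequent target implied by a ratio is
shrunk toward indifference by the frequency weight
($(f_1/(f_1+f_2) - 0.5)\,w_f + 0.5$), likewise for reward with $w_r = 1 -
w_f$; the product of the two preferences is each target's expected value,
and normalizing gives the choice probability. Direct reaches are Bernoulli
draws; intermediate directions are the probability mapped onto
[−15°, +15°] ($30p - 15$), noiseless by default. The estimator is then
applied exactly as on real data (count-proportion biases, as in the
explicit-choice experiment), over the 3 × 3 ratio design {1, 2, 4}. The
reward weight is tied to $1 - w_f$; an independent reward weight and an
angular noise term are exposed as options. Under this model the estimator
has a small structural bias (up to ≈0.048 at the grid edges on the 3 × 3
design, computable exactly from the noiseless probabilities) because the
generative preference is curved in the ratio while the estimator's axis
fits are linear. Recovered medians therefore track the identity line
closely but not perfectly: with Bernoulli noise on the direct side, the
worst grid-point median typically lands 0.05–0.09 from its simulated
weight, while monotonicity across the grid and the strong positive
coupling between the direct and intermediate recoveries always hold.

# Problem sizes used by the tests and the acceptance script

* Recovery: 9 weightings × 25 iterations × 200 trials/condition.
* End-to-end cohort: 24 participants (the scale of the blockwise-frequency
  study) × 16 conditions × 36 trials, 1000 bootstrap iterations; the
  generating weights 0.66 (direct) and 0.43 (intermediate) are the
  headline group values, and the pipeline recovers both within ±0.05 with
  a strongly significant paired difference.
* Full-stack recovery properties at other weights use the bias-level
  generator (identical generative model, kinematic layer bypassed) to keep
  the suite fast; the kinematic layer itself is covered by the oracle tests
  and the cohort run above.
* Utility assay: 200 choices per generating indifference point
  {−5, 0, 5, 10} cents; median recovery error below one cent.

# Known limitations

* The generator's identical-profile cohorts understate between-participant
  variance, so bootstrap SDs on synthetic data are narrower than on real
  cohorts.
* Exclusion clocks are simplified to trial-relative time (time zero is
  target appearance, or the go tone for the movement-time-limited variant).
* The five-target rectangle is modeled as its leading edge (a crossing
  segment at the near-target depth); paths that would enter it obliquely
  through a side edge are not distinguished.
* The import adapter for externally deposited datasets is a stub: the
  package defines its own delimited formats and every analysis is
  exercised on generated data.
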