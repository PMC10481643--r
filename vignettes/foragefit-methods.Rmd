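---
title: "Models and methods behind foragefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foragefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and what the package computes

`foragefit` analyses the four-odor serial choice task: a food-restricted
mouse repeatedly chooses among four scented pots, of which exactly one odor
(odor 1, "O1") is rewarded, while odor 2 carries an innate preference in
untrained animals. A phase ends when 8 of the last 10 completed choices are
correct. Trials without a choice within 3 minutes are omissions; two
consecutive omissions trigger a free-reward reminder trial, and four
omission pairs disqualify the animal. The task is run twice: an acquisition
phase (learning the odor-reward rule) and, a day later, a test phase
(re-expressing it, typically under a drug manipulation).

The package provides (i) these task rules as reusable primitives, (ii) a
generative simulator of agents performing the task, (iii) the
reinforcement-learning likelihood of observed sessions, (iv) hierarchical
Bayesian estimation with WAIC model comparison, credible-interval group
contrasts and posterior-predictive checks, (v) descriptive behavioral
summaries, and (vi) a rotation-bias scoring pipeline for pose-tracked
head/torso/tail-base coordinates used to validate unilateral manipulations.

## The choice model

Each odor $i$ carries a value $Q(O_i)$. After a choice, only the chosen
odor's value is updated by a reward prediction error with learning rate
$\alpha \in (0,1)$:

$$Q_{t+1}(c_t) = Q_t(c_t) + \alpha\,\delta_t, \qquad
  \delta_t = r_t - Q_t(c_t), \qquad
  r_t = \begin{cases} 100 & \text{rewarded} \\ 0 & \text{otherwise.}\end{cases}$$

Choice probabilities are a softmax over current values with inverse
temperature $\beta \ge 0$:

$$P(c_t = O_i) = \frac{e^{\beta Q_t(O_i)}}{\sum_j e^{\beta Q_t(O_j)}}.$$

Both parameters are phase-specific: $(\alpha_{acq}, \alpha_{test},
\beta_{acq}, \beta_{test})$, with the derived phase changes
$\Delta\alpha = \alpha_{test}-\alpha_{acq}$ and
$\Delta\beta = \beta_{test}-\beta_{acq}$. Four variants lie on the lattice
of phase sharing (`shared`, `alpha_only`, `beta_only`, `full`) and are
compared by WAIC. Innate odor preferences enter as initial values
$[v_1..v_4]$ shared by every animal and group.

Omission and reminder trials contribute no likelihood term: there is no
generative account of omissions in the model, and reminder trials use an
unscented, always-rewarded pot.

### Why each phase starts from the initial values

Softmax choice depends on values only through $\beta Q$; on the 0--100
reward scale an animal that ends acquisition with $Q(O_1)\approx100$ and
near-zero competitors makes essentially no errors for any
$\beta \gtrsim 0.06$. If those values were carried into the test phase,
test-phase behavior would contain no learning signal at all:
$\alpha_{test}$ would be unidentifiable and phase-specific models could
never be distinguished from shared ones. Observed test phases, by contrast,
show renewed choices of the innately preferred odor and variable
choices-to-criterion — the behavior of an animal re-expressing the rule
from its innate starting point, not of one executing saturated values. The
package therefore resets values to $[v_1..v_4]$ at the phase boundary by
default; `task_config(carry_over_values = TRUE)` restores strict
carry-over for sensitivity analyses.

### Identifiability

Two structural facts shape the priors and parameterization:

* Softmax probabilities are invariant to adding a constant to all values,
  so $[v_1..v_4]$ is identified only up to a shift. The fit anchors the
  vector to mean zero (three free components).
* With rewards of 100, $\beta$ is well informed only roughly within
  $[0.005, 0.06]$: above that, choice saturates and the data bound $\beta$
  only from below. Group-level $\beta$ posteriors therefore acquire long
  right tails — worth remembering when reading contrasts.

## Hierarchical structure and priors

Per-animal parameters are drawn from group-level distributions, non-centred
for sampler geometry:

* $\mathrm{logit}\,\alpha_{k,p} = \mu^{(\alpha)}_{g,p} +
  \sigma^{(\alpha)}_{g,p} z_{k,p}$, with $z \sim N(0,1)$;
* $\log \beta_{k,p} = \mu^{(\beta)}_{g,p} + \sigma^{(\beta)}_{g,p} z_{k,p}$;
* hypermeans: $\mu^{(\alpha)} \sim N(0, 1.5)$ (logit scale),
  $\mu^{(\beta)} \sim N(\log 0.05, 1.5)$ (log scale, centred where the
  0--100 value scale puts plausible inverse temperatures);
* hyperscales: half-normal with unit scale;
* shared values: $v_i \sim N(0, 25)$ (value units), mean-anchored.

All of these are configurable through `prior_control()`. $\Delta\alpha$ and
$\Delta\beta$ are derived per posterior draw, never primitive parameters,
and group contrasts are computed per draw on the natural scale before
taking central credible intervals.

Per-animal acquisition and test parameters are modelled as independent
given their group hyperparameters; a within-animal correlation structure is
a possible extension the data here cannot strongly inform.

## Sampling and diagnostics

Inference is adaptive Metropolis-within-Gibbs, implemented in C++: a joint
random-walk proposal over each animal's local effects (evaluating only that
animal's likelihood), scalar proposals for each group hyperparameter
(evaluating only that group's likelihood), and a joint proposal for the
shared values. Proposal scales adapt toward acceptance targets (0.44
scalar, 0.30 block) in batches of 50 during warmup only, so the retained
draws come from a fixed kernel. Defaults are 4 chains of 1000 warmup + 1000
draws; the chain seeds derive deterministically from one master seed, and a
fixed seed reproduces the posterior exactly.

Convergence is summarized by split-chain R-hat and an
autocorrelation-based effective sample size per parameter; fits warn when
key parameters exceed R-hat 1.01 or fall below 400 effective draws. The
point-wise log-likelihood matrix (draws x completed trials) feeds WAIC:
$\mathrm{lppd} = \sum_t \log \tfrac1S \sum_s e^{\ell_{s,t}}$ computed with
log-sum-exp, $p_{\mathrm{WAIC}} = \sum_t \mathrm{Var}_s(\ell_{s,t})$, and
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$.

## The synthetic cohort generator

`simulate_cohort()` is the package's generative twin of the study: animals
drawn from group hyper-distributions perform the full task under the model
above, with the 8-of-10 criterion, 3-minute omissions (value-independent
Bernoulli, default 3% per trial), reminder insertion and disqualification.
Defaults encode the study conditions: 4 odors, reward 100, innate
preference as initial values $(0, 25, 0, 0)$, criterion-terminated phases.
Fixed-length phases (`stop_at_criterion = FALSE`) support recovery studies
at a constant number of trials per animal.

Quadrant entries — the serial pot visits before the dig — are generated by
an explicitly invented process (value-guided visit order with logistic dig
acceptance) so that single-entry statistics are exercisable; entries never
enter the likelihood. When the simulator has already drawn the softmax
choice, the entry walk is conditioned to end at that pot, keeping the
choice process exactly softmax.

What the generator does *not* emulate: omissions driven by motivation or
drug state, latency structure beyond a lognormal placeholder, arena
geometry, and session-to-session drift. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to real-data
misspecification.

## Study designs used by the validation suite

The test suite fixes these scales (chosen once, with the reasoning below):

* **Parameter recovery** — 20 replicate cohorts of 2 groups x 20 animals,
  30 completed trials per phase; generating hypermeans
  $\alpha = 0.45/0.55$, $\beta = 0.02/0.03$ (inside the identifiable
  range), hyper-scales 0.25; reduced sampling (2 chains, 800+1000). The
  "separated" group's test-phase $\beta$ sits three standard errors of the
  fitted group difference above the control; that standard error
  (log-scale ~0.165) was calibrated from null-separation fits of the same
  design, which is the only way to give "k standard errors" operational
  meaning for a nonlinear hierarchical estimator.
* **Model recovery** — 10 cohorts of 14 animals, 35 trials per phase from
  the `full` model with $\alpha = 0.20/0.65$, $\beta = 0.02/0.045$:
  phase differences large enough that a correct method should find them,
  with both phases inside the informative $\beta$ range.
* **Posterior-predictive check** — five near-greedy animals
  ($\beta = 0.3$, initial values favouring the rewarded odor) whose
  behavior is essentially deterministic, so the observed and the
  100-simulations-per-animal predicted choices-to-criterion must agree
  within a couple of trials if the fit-simulate loop is coherent.
* **Credible-interval calibration** — equal-hyperparameter groups must
  yield spurious $\Delta\beta$ detections at roughly the nominal 5% rate.

## Rotation-bias scoring

The pipeline mirrors standard post-tracking practice for cylinder rotation
assays at 15 frames/s:

1. **Imputation** — missing node coordinates take the nearest-in-time
   present value (ties to the earlier frame).
2. **Smoothing** — Savitzky-Golay filter per coordinate (degree 3, window
   15); the first 5 frames are dropped as unstable capture.
3. **Heading** — egocentric head vector = head minus torso per frame; the
   rotation series is the wrapped frame-to-frame heading difference in
   $(-180, 180]$ degrees per frame, so crossings of the angular
   discontinuity report their true small increment. Degenerate head-torso
   vectors and residual jumps beyond 90 deg/frame are treated as artifacts
   and replaced by the nearest valid angle; the series is then
   Gaussian-smoothed ($\sigma = 3$ frames, reflected boundaries).
4. **Moving state** — a frame moves iff (tail-base displacement > 0.4 px
   and |angle| > 0.5 deg) or |angle| > 2 deg (robust head swings).
   Displacement is computed on smoothed coordinates; angle thresholds are
   in degrees per frame and compared on absolute value.
5. **Score** — bias = net signed rotation over moving frames divided by
   total unsigned rotation over moving frames (in $[-1, 1]$; positive is
   counterclockwise in image coordinates), plus a net rotation rate in
   degrees per minute. Both are reported; ipsi/contralateral labelling is a
   reporting-time relabelling given the injected hemisphere.

Frame rate is metadata of the input, never inferred from frame counts. The
synthetic pose generator produces a rigid three-node body rotating at a
known drift with Gaussian coordinate noise and random missingness — enough
to validate sign and magnitude recovery, but deliberately free of
locomotion, wall interactions, or tracking-failure bursts.

## Numerical choices and degenerate inputs

* Softmax and log-sum-exp use max subtraction throughout; very large
  $\beta Q$ cannot overflow.
* The sampler clamps $\log\beta$ draws to $\pm 25$ — far outside the
  prior's support in practice, purely a floating-point guard.
* `first_criterion_trial` on an empty sequence returns "never"; sessions
  of only omissions have log-likelihood 0 with an empty pointwise vector.
* Criterion-censored sessions are flagged, never dropped; disqualified
  animals keep their completed trials in the likelihood.
* Entry generation floors Plackett-Luce weights at $10^{-12}$ so steep
  value slopes cannot produce an empty support.
* WAIC requires at least two draws (the trial-wise variance is undefined
  otherwise) and refuses single-draw input.

## Limitations

Omissions are modelled as value-independent noise; latencies are
placeholders; the entry process is invented plumbing. $\beta$ above the
saturation range is reported but only weakly constrained by data, and the
natural-scale group contrasts inherit that skew. The sampler is a
random-walk scheme: posterior tails mix more slowly than a gradient-based
sampler would, which the effective-sample-size diagnostics make visible;
raising `draws` is the straightforward remedy for publication-grade runs.
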