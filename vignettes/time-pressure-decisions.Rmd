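---
title: "Modelling perceptual decisions under time pressure with satdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceptual decisions under time pressure with satdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`satdm` is a simulation and fitting toolbox for studying how decision
makers trade speed against accuracy when time is costly.  It covers the
whole loop of a typical deadline / decaying-reward experiment on
sequentially revealed evidence: generating the task, simulating a
subject with any of seven sequential-sampling decision models, fitting
speed–accuracy tradeoff (SAT) curves and decision models to the
resulting choices and response times (RT), and running the standard
behavioral analyses.  This vignette explains the models, the numerical
choices, and what the package's validation suite does and does not
establish.

## The task generator

Three task regimes are emulated, plus a pre-test:

* **Deadline task (exp1).**  Six hard deadlines of 0.7–4.2 s in 0.7 s
  steps (schedules 1–6), randomized within blocks: 10 blocks of 36
  trials, each deadline six times per block.  The stimulus is a stream
  of colored dots drawn with replacement: a new dot every 50 ms (20 Hz),
  each dot visible for 2.0 s, the dominant color drawn with probability
  `q` (0.57 by default, the 57:43 ratio).  The first dot appears at
  trial onset, so the number of visible dots ramps up to 40 at two
  seconds and stays there — the sampling phase is not specified by the
  design, and pinning the first dot at t = 0 is the convention that
  makes the 40-dot steady state hold from exactly 2 s.  The dominant
  color is re-randomized red/green with probability 1/2 on every trial.
  Correct choices earn 60 points, errors lose 60; a miss (no response
  before the deadline) loses 60 points, extending the pre-test's
  explicit miss rule to the deadline task.
* **Decaying-reward task (exp2).**  The same stimulus, but instead of a
  deadline the gain for a correct response decays linearly from its
  initial value (50 or 100 points, randomized) to zero, and the loss
  for an error mirrors it symmetrically; both clip at zero once
  reached.  Decay starts not at trial onset but at the rise point of
  the subject's SAT (see below), so that responding immediately is
  never optimal.  The decay is proportional: the on-screen arc shows
  the *fraction* of the initial value remaining, so a 50-point and a
  100-point trial of the same schedule reach zero at the same time and
  share the same optimal response time.  A miss scores 0 points — the
  reward has fully decayed by then (the design leaves this case open;
  we adopt the zero-outcome convention).  Blocks contain each (initial
  value × decay rate) cell three times.
* **Time-dependent gambling (exp3).**  No dot stream: the win
  probability at accept-time t is the subject's SAT value P(t), and the
  stake decays exactly as in exp2.  This is the mathematically
  equivalent control without sensory integration.  The simulated
  subject's accept time is the commitment time of its decision model.
* **Pre-test.**  A 3 × 3 grid of dot ratios (60:40, 57:43, 54:46 — one
  ratio per block, cycling) and time windows (0.7, 2.1, 3.5 s), 9
  blocks of 36 trials.

Reproducibility: one integer session seed spawns a deterministic
substream per (block, trial), so identical inputs give byte-identical
sessions, and adding analyses never perturbs the stimulus draws.

## The speed–accuracy tradeoff model

Accuracy as a function of deliberation time is modelled with a shifted
exponential (modified Weibull) curve,

$$P(\bar t) = c + (1 - c)\,\beta\,[1 - e^{-(\bar t - \delta)/\lambda}],$$

with chance level $c = 0.5$, rise point $\delta$ (s), slope constant
$\lambda$ (s), and asymptote scale $\beta \in [0, 1]$ ($\beta = 1$ for
the per-schedule variant; the pooled ten-bin variant frees $\beta$, so
the plateau is $c + (1-c)\beta$).  For $\bar t < \delta$ the bracket is
negative; $P$ is clamped at $c$, since $\delta$ is by definition where
performance rises above chance.  Fitting maximizes the *binomial*
likelihood of the per-bin correct counts — the data are counts, and
this weights bins by their trial numbers automatically.  The
constraints $\delta > 0.2$ and $\lambda > 0.001$ are enforced by
bounded quasi-Newton (L-BFGS-B) from eight deterministic multi-starts
on a log-spaced grid; ties break toward the lowest $\delta$, and fits
pinned at a constraint (or with $\delta$ beyond the observed RTs — no
SAT signal in range) are flagged rather than silently returned.

```{r}
library(satdm)
bins <- data.frame(bin = 1:6, mean_rt = c(0.3, 0.6, 0.9, 1.4, 2.2, 3.3),
                   n_trials = 500,
                   n_correct = c(260, 320, 370, 410, 430, 440))
fit_sat(bins, "eq1")
```

## The expected-gain model of response time

For a decaying-reward schedule an ideal decision maker responding at
mean time $\bar t$ expects

$$EG(\bar t) = G(\bar t, 1)\,P(\bar t) + G(\bar t, 0)\,[1 - P(\bar t)],$$

where $G(t, 1) = \max(0, G_s - b\,(t - t_0)_+)$ and $G(t, 0)$ is its
negative mirror.  The optimal mean RT is the argmax, found by grid
search (1 ms default) because reward clipping makes $EG$ only piecewise
smooth; ties break toward the earlier time, and the grid is capped at
$\delta + 45\lambda$, beyond which the SAT is flat to machine precision
and $EG$ strictly decreases.  The model is parameter-free given the SAT
and the schedule.  By default the response time is treated as exactly
$\bar t$ (delta dispersion); a Gaussian dispersion of width $\sigma$
(e.g. the subject's pooled RT SD) is available, integrated by
Gauss–Legendre quadrature over $\pm 4\sigma$.

`design_decay_rates()` inverts the model to construct the decaying
reward schedules: for accuracy targets linearly spaced between 0.55 and
the subject's maximum (e.g. 0.55, 0.63, …, 0.95 for a 0.95 plateau), it
bisects on the relative decay rate until $P(\bar t_{\mathrm{opt}})$
hits each target within $10^{-3}$ (the inner argmax uses a 0.1 ms grid
so the round trip stays within that tolerance — neither resolution is
prescribed by the design, both are this package's choices).

## The seven decision models

All models integrate a scalar decision variable x by Euler–Maruyama
(default step 1 ms) with Gaussian increments of variance
$c^2\,\mathrm{d}t$:

1. **basic** — $\mathrm{d}x = A\,\mathrm{d}t + c\,\mathrm{d}W$, commit
   at $|x| \ge B_k$ (threshold free per schedule k throughout).
2. **variant_drift** — as basic with $A$ drawn once per trial from
   $\mathcal N(A, \sigma_A)$; produces errors slower than correct
   responses because long trials are enriched in low-drift draws.
3. **collapsing** — fixed drift against the bound
   $B_k e^{-t/\lambda_k}$.
4. **leak** — $\tau\,\mathrm{d}x = -x\,\mathrm{d}t + A\,\mathrm{d}t +
   c\,\mathrm{d}W$, taken literally, so the effective drift is
   $(A - x)/\tau$ and the effective noise scale $c/\tau$.
5. **urgency** — the readout $y = x\,U(t)$ with $U(t) = u\,t$ (rising
   linearly from zero, zero intercept) is compared with $B_k$.  This is
   implemented as the equivalent moving bound $B_k / U(t)$ on x; the
   two formulations agree path-for-path.
6. **leak_urgency** — leaky integration first, then the urgency
   multiplication (the composition order is not dictated by the
   dynamics; we filter first).
7. **attractor** — escape dynamics in the tri-stable potential
   $G(x) = b_k(x^2 - \beta x^4 + \gamma x^6)$ (defaults $\beta = 4$,
   $\gamma = 3$):
   $\mathrm{d}x = [-G'(x) + (U(t) + F(t))x + A]\,\mathrm{d}t +
   c\,\mathrm{d}W$.  The equation has no separate stimulus term, so
   evidence enters as the additive tilt $+A$ that deepens the correct
   well.  The model commits when $|x|$ passes the inner inflection
   point of the outer wells (the larger root of $G'' = 0$, independent
   of $b$) — a commitment criterion has to be chosen, and the
   inflection is where the dynamics accelerate into the choice well.
   $F(t)$ is a step of amplitude $10 \times \max |G'|$ switching on
   50 ms before the deadline, forcing escape from the central state.

Trials that do not commit before the deadline are recorded as misses
and excluded from model fitting (the sign-of-x assignment for
non-committed trials is deliberately not used).

Two numerical points matter.  First, discrete-time simulation of
absorbing boundaries is biased by $O(\sqrt{\mathrm{d}t})$ because
within-step excursions are missed; the simulator removes this with a
Brownian-bridge crossing correction each step, so simulated
first-passage laws match the continuous-time model (validated against
the closed-form Wiener absorption probability).  Second, halving the
step changes simulated accuracy by well under half a percentage point
at the reference parameters (checked in the test suite).

### Stimulus-driven mode and the interrogation readout

By default the drift is constant within trial (signed toward the
dominant color), matching the fitting setup.  For kernel analyses the
simulator can instead be driven by the stimulus: either each newly
revealed dot contributes one evidence impulse ("sample" mode), or the
momentary drift follows the signed color fraction of the currently
*visible* dots ("pool" mode, `drift_from_stimulus()`).  Kernel
*validation* uses sample mode with an interrogation readout (sign of x
at the deadline, `simulate_interrogation()`): with absorbing bounds the
evidence conditioned on a choice sums to the threshold, which distorts
regression kernels near the response for any integrator — even a
perfect one — and in pool mode a dot's integrated weight grows with its
age while it remains visible, so neither canonical kernel prediction
(flat for perfect integration, exponential with constant tau for leak)
is testable in those regimes.

## Fokker–Planck fitting

Model predictions for fitting come from propagating the decision
variable's probability density with a conservative Crank–Nicolson
scheme on a fixed grid with absorbing edges (Thomas tridiagonal solves;
the factorization is reused across steps whenever the drift is
time-independent).  The delta initial condition is smoothed by eight
fully implicit (Rannacher) start-up steps.  Moving bounds (collapsing,
and urgency expressed as $B/U(t)$) are handled by absorbing, each step,
the density beyond the instantaneous bound — with *partial-cell
weighting*, so the absorbed flux is continuous in the bound value and
likelihoods stay smooth in threshold parameters (binary masking makes
the objective a staircase and breaks finite-difference gradients).
Remaining density plus cumulative absorbed flux equals one to machine
precision by construction; a violation above $10^{-4}$ raises a
resolution error.  Trial-to-trial drift variability is integrated out
with 11-node Gauss–Hermite quadrature (7 in fitting).  Default
resolutions are 1 ms × 301 points, refined to 0.25 ms × 601 points for
the moving-bound families whose masking converges linearly in the step;
with these settings the first-passage laws of all seven families agree
with $10^5$-trial simulations to better than 0.01 in sup-norm (test
suite).

Fitting targets are per-schedule summaries in five equal-count quantile
RT bins (quantile bins cannot be empty): proportion correct, mean RT,
SD of RT, each with a Gaussian error.  The error variances are the
standard summary-statistic choices — binomial $p(1-p)/n$ for the
proportion, $\mathrm{SD}^2/n$ for the mean, $\mathrm{SD}^2/(2n)$ for
the SD (delta method).  Non-committed mass is discarded and the
remainder renormalized.  The evidence noise $c$ is fixed during fitting
(it only sets the unit of evidence: scaling $A$, $c$ and the thresholds
together leaves behaviour unchanged), as is the urgency slope $u = 1$
(only $B_k/u$ is identifiable when thresholds are free per schedule).
Optimization is `nlminb` on log-parameters from deterministic
moment-based multi-starts (10 by default); the winner is selected
deterministically, so permuting the start order cannot change the
result.  Models are compared by $AIC = 2k - 2\log L$.

## Behavioral analyses

* **Deadline proximity** (`proximity_performance`): accuracy in five
  equal-width RT bins over [0, deadline], with an OLS slope and
  two-sided t-test; numerically exact fits are special-cased.
* **RT matching** (`rt_match`): adjacent schedules are compared at
  equal mean RT by keeping the trials in the overlap of the two RT
  ranges and trimming smallest-RT trials from the faster and largest-RT
  trials from the slower set.  The trimming depths are chosen by exact
  search (the trimmed means are monotone in depth, so this is
  O(n log n)) to make the two means as close as possible; a
  step-by-step greedy descent over the same moves can stall in local
  minima well above that optimum, which is why the exact search is
  used.  The result cannot be improved by any further single removal.
* **Evidence kernels** (`evidence_kernel`): per-schedule logistic
  regression of choice (red = 1) on the proportion of red dots with
  onsets in each 200 ms window counting back from the response (tiled,
  not overlapping).  Windows reaching before trial onset are centered
  at the chance proportion; weights are reported normalized by the
  maximum absolute weight; separation triggers a flagged ridge fit
  (penalty $10^{-3}$).  `kernel_decay_constant()` fits
  $a\,e^{-t/\tau}$ on the raw weight scale with the amplitude profiled
  out — log-linear fitting is biased upward by the noisy tail.
* **Conditional RT statistics** (`conditional_rt_stats`):
  correct-vs-error differences in *normalized* RT (RT divided by the
  trial's available time, which makes schedules comparable — the term
  is used without definition in the source designs), previous-outcome
  and previous-schedule effects on median RT, each with an exact
  two-sided sign test across subjects and Cohen's d on the paired
  differences.

## Validation studies and their scope

The test suite runs everything end-to-end on synthetic data.  Problem
sizes were chosen so each study is statistically decisive yet quick:
$10^5$ trials for first-passage comparisons, $10^4$ trials per schedule
for behavioral signatures and kernels, $10^4$ trials per bin for SAT
recovery, and 50 replicates of 1000 trials × 4 schedules for model
recovery.

The model-recovery study generates data from the leak-plus-urgency
model in an *identifiable* regime — $\tau = 0.45$ s, thresholds rising
with the available time, four schedules spanning 0.7–4.2 s — chosen by
a design computation: on noiseless predictions the generating family
outfits its nearest competitor by ≈1200 AIC at these trial counts,
whereas with a weak leak ($\tau = 0.6$) the margin shrinks to ≈150 and
sampling noise can flip single replicates.  Replicate data are drawn
from the model's first-passage distribution at the fitting resolution
(`fp_sample`), so the study isolates model discrimination by AIC;
agreement between that distribution and trial-level simulation is
established separately by the sup-norm comparison.

What passing these studies does *not* show: the generator contains no
perceptual front-end (no luminance, eccentricity or crowding effects),
no motor or timing jitter, no learning, fatigue or across-subject
heterogeneity, and its stimulus law is exactly binomial.  Conclusions
about real subjects require real data; the synthetic sessions establish
that the estimators recover what they claim to recover when their
assumptions hold.

## Known limitations

* The leak equation is taken literally, so $\tau$ rescales the noise as
  well as the drift; other conventions rescale only the drift.
* Binned summary likelihoods discard within-bin shape information; with
  five bins per schedule, families differing only in fine RT shape are
  compared on coarse features.
* The attractor model is the one-dimensional reduction; no spiking or
  two-pool rate dynamics are implemented.
* Time-varying-reward (exp2) sessions are simulated and analyzed, but
  decision models are fitted only to deadline-task data — the mapping
  from decaying rewards onto bounds or drifts is deliberately left
  open.
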