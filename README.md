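# satdm

Sequential-sampling decision models and speed–accuracy tradeoffs under
time pressure.

## What this package is for

When deliberation is costly — because a deadline looms or the reward
shrinks while you think — how long should you integrate evidence before
committing, and how long do decision makers actually take?  `satdm` is
an R toolbox for studying these questions with simulation-based
experiments on two-alternative color-discrimination tasks: a stream of
red/green dots revealed at 20 Hz, decisions under six levels of time
pressure imposed either as hard deadlines (0.7–4.2 s) or as gains and
losses that decay linearly to zero, plus a mathematically equivalent
time-dependent gamble that requires no sensory integration.

It is aimed at computational cognitive scientists and psychophysicists
who want to (a) generate fully synthetic sessions from a known
decision process, (b) fit and compare mechanistic models of the choice
and response-time (RT) data, and (c) run the standard behavioral
analyses on either synthetic or real trial tables (plain CSV, one row
per trial).

## The models at its core

**Speed–accuracy tradeoff (SAT).**  Accuracy as a function of mean RT
is the shifted-exponential (modified Weibull) curve

    P(t) = c + (1 - c) beta [1 - exp(-(t - delta)/lambda)],  P >= c,

with chance level c = 0.5, rise point `delta`, slope constant
`lambda`, and asymptote scale `beta` (fixed at 1 for per-schedule
fits).  Fitting maximizes the binomial likelihood of binned correct
counts under the constraints delta > 0.2 s, lambda > 0.001 s.

**Optimal response time.**  For a reward decaying linearly from G_s at
rate b (clipped at zero), an ideal observer responding at time t earns
`EG(t) = G(t,1) P(t) + G(t,0) (1 - P(t))`; the optimal mean RT is the
argmax of EG.  The model has no free parameters beyond the SAT, and
inverting it (`design_decay_rates`) constructs decay rates whose optima
sit at prescribed accuracies — the procedure used to tailor the
decaying-reward schedules.

**Seven decision models.**  Trial-level simulation
(`simulate_trials`) and Fokker–Planck first-passage prediction
(`fp_propagate`) for: the basic drift-diffusion model
`dx = A dt + c dW` with per-schedule thresholds; trial-variant drift
`A ~ N(A, sd_A)`; a collapsing bound `B exp(-t/lambda)`; leaky
integration `tau dx = -x dt + A dt + c dW`; urgency gating
`y = x * u t` against a fixed bound; leak plus urgency; and a
tri-stable attractor `dx = [-G'(x) + (U + F) x + A] dt + c dW` with
`G(x) = b (x^2 - beta x^4 + gamma x^6)`.  Models are fitted to binned
choice/RT summaries by a Gaussian summary likelihood and compared with
`AIC = 2k - 2 logL`.

**Behavioral analyses.**  Deadline-proximity accuracy with a slope
test, RT matching of adjacent schedules, psychophysical evidence
kernels (200 ms logistic-regression windows), correct-vs-error and
sequential RT effects with exact sign tests and Cohen's d.

## A worked example

Simulate a deadline-task session from a known subject, estimate its
SAT, and design decaying-reward schedules for it:

```r
library(satdm)
subject <- reference_models()$basic       # basic DDM, thresholds rising
session <- simulate_session(subject, "exp1", seed = 7)
nrow(session)                             # 360 trials, 10 blocks x 36

sat_points <- bin_by_schedule(session)
sat_points
#>   bin   mean_rt n_trials n_correct
#> 1   1 0.2806275       51        38
#> 2   2 0.5530577       52        44
#> 3   3 0.8390000       58        46
#> 4   4 1.0001321       53        42
#> 5   5 1.4749636       55        44
#> 6   6 1.5306667       54        46

sat <- fit_sat(sat_points, "eq1")
sat
#> <sat_params eq1> c = 0.50, delta = 0.200 s, lambda = 0.911 s, beta = 1.000
#>   logLik = -22.750 (boundary fit)
```

One bin per schedule: under the shortest deadline this subject answers
in 0.28 s on average and is right 75% of the time, improving to 85% by
1.5 s.  The fitted rise point sits at its 0.2 s constraint and the fit
is flagged (`boundary fit`): a diffusion subject is already above
chance at its fastest responses, so the rise point is not resolvable
from these data — the flag is the package telling you so.

```r
rates <- design_decay_rates(sat, acc_hi = 0.90)
round(as.numeric(rates), 2)
#> [1] 506.86 185.69 100.28  60.29  36.35  19.54
round(attr(rates, "achieved"), 4)
#> [1] 0.5500 0.6201 0.6904 0.7602 0.8299 0.9001
```

Six decay rates (points/s at a 100-point initial reward), steepest
first: under the fastest decay the optimal strategy yields only 55%
accuracy, under the slowest 90% — the linearly spaced targets, each hit
to within 10^-3.  The optimal mean RTs and the expected gain at the
optimum follow directly:

```r
sch2 <- make_schedules("exp2", decay_rates = as.numeric(rates), sat = sat)
round(vapply(1:6, function(k) optimal_mean_rt(sat, sch2[k, ]), 0), 3)
#> [1] 0.296 0.450 0.637 0.870 1.183 1.667
expected_gain(0.637, sat, sch2[3, ])
#> [1] 21.4
```

So under the third schedule an ideal observer with this SAT waits
0.64 s and expects about 21 of the initial 100 points.  See the
vignette (`vignettes/time-pressure-decisions.Rmd`) for the model
equations, fitting machinery, and the validation studies.

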