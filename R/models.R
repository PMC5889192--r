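# Trial-level stochastic simulation of the seven sequential-sampling
# decision models: six drift-diffusion variants and a tri-stable
# attractor with urgency.  The Euler-Maruyama core lives in src/sim.cpp;
# boundary crossings use a Brownian-bridge continuity correction so the
# simulated first-passage law matches the continuous-time model rather
# than the time-discretized one.

MODEL_FAMILIES <- c("basic", "variant_drift", "collapsing", "leak",
                    "urgency", "leak_urgency", "attractor")

.family_code <- function(family) match(family, MODEL_FAMILIES)

#' Specify a sequential-sampling decision model
#'
#' Families and their dynamics (x is the decision variable, W a Wiener
#' process; noise increments have variance `noise^2 dt`):
#' \describe{
#'   \item{basic}{`dx = A dt + noise dW`; commit at `|x| >= bound`.}
#'   \item{variant_drift}{as basic, with the drift drawn once per trial
#'     from `Normal(A, drift_sd)`.}
#'   \item{collapsing}{as basic against the collapsing bound
#'     `bound * exp(-t / collapse)`.}
#'   \item{leak}{`tau dx = -x dt + A dt + noise dW` (low-pass filtered
#'     evidence); fixed bound.}
#'   \item{urgency}{the readout `y = x U(t)` with `U(t) = urgency * t`
#'     (rising linearly from zero) is compared to the fixed bound --
#'     equivalent to the time-varying bound `bound / U(t)` on x.}
#'   \item{leak_urgency}{leaky integration first, then the urgency
#'     multiplication.}
#'   \item{attractor}{`dx = [-G'(x) + (U(t) + F(t)) x + A] dt + noise dW`
#'     with the tri-stable potential `G(x) = barrier (x^2 - beta x^4 +
#'     gamma x^6)`; `F` steps on at `forcing_onset` before the deadline
#'     (default `deadline - 0.05 s`) to force commitment, and the model
#'     commits when `|x|` passes the inner inflection point of the outer
#'     potential wells (see [attractor_geometry()]).}
#' }
#'
#' `bound` (and the attractor `barrier`) may be a vector with one value
#' per schedule level, reflecting thresholds that adapt to time
#' pressure.
#'
#' @param family One of `r paste(MODEL_FAMILIES, collapse = ", ")`.
#' @param A Mean drift (evidence/second); its sign is set by the
#'   stimulus in stimulus-driven mode.
#' @param noise Diffusion scale of the evidence (per sqrt-second).
#' @param bound Decision threshold(s), scalar or per-schedule vector.
#' @param drift_sd Trial-to-trial drift SD (variant_drift).
#' @param collapse Collapse time constant in seconds (collapsing).
#' @param tau Leak time constant in seconds (leak families).
#' @param urgency Urgency slope in 1/second (urgency families and
#'   attractor).
#' @param barrier Attractor barrier scale(s) `b`, scalar or per-schedule.
#' @param beta,gamma Quartic and sextic potential coefficients.
#' @param forcing_amp Amplitude of the forcing step; default
#'   `10 * max |G'|` over the central region.
#' @param forcing_onset Onset of the forcing step, seconds before the
#'   deadline (default 0.05).
#' @param dt Euler integration step in seconds (default 1 ms).
#' @return A `model_spec` object.
#' @export
model_spec <- function(family, A = 0.3, noise = 0.5, bound = 1,
                       drift_sd = NULL, collapse = NULL, tau = NULL,
                       urgency = NULL, barrier = NULL, beta = 4,
                       gamma = 3, forcing_amp = NULL,
                       forcing_onset = 0.05, dt = 1e-3) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (noise <= 0) stop("'noise' must be positive", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  need <- function(x, nm) {
    if (is.null(x)) {
      stop(sprintf("family '%s' requires '%s'", family, nm), call. = FALSE)
    }
    if (any(x <= 0)) stop(sprintf("'%s' must be positive", nm),
                          call. = FALSE)
    x
  }
  spec <- list(family = family, A = A, noise = noise, dt = dt)
  if (family == "attractor") {
    spec$barrier <- need(barrier %||% 2, "barrier")
    spec$beta <- beta
    spec$gamma <- gamma
    geom <- attractor_geometry(1, beta, gamma)
    spec$x_commit <- geom$x_commit
    spec$urgency <- urgency %||% 1
    if (spec$urgency < 0) stop("'urgency' must be >= 0", call. = FALSE)
    spec$forcing_amp <- forcing_amp  # resolved per barrier at run time
    spec$forcing_onset <- forcing_onset
  } else {
    if (any(bound <= 0)) stop("'bound' must be positive", call. = FALSE)
    spec$bound <- bound
    if (family == "variant_drift") spec$drift_sd <- need(drift_sd, "drift_sd")
    if (family == "collapsing") spec$collapse <- need(collapse, "collapse")
    if (family %in% c("leak", "leak_urgency")) spec$tau <- need(tau, "tau")
    if (family %in% c("urgency", "leak_urgency")) {
      spec$urgency <- need(urgency %||% 1, "urgency")
    }
  }
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  extras <- setdiff(names(x), c("family", "A", "noise", "dt"))
  vals <- vapply(extras, function(nm) {
    paste0(nm, " = ", paste(signif(unlist(x[[nm]]), 4), collapse = "/"))
  }, character(1))
  cat(sprintf("<model_spec %s> A = %g, noise = %g, dt = %g\n  %s\n",
              x$family, x$A, x$noise, x$dt, paste(vals, collapse = ", ")))
  invisible(x)
}

#' Geometry of the tri-stable attractor potential
#'
#' For `G(x) = b (x^2 - beta x^4 + gamma x^6)` with `beta^2 > 3 gamma`,
#' the potential has a central well at 0, barriers at `+/- x_barrier`,
#' and outer wells at `+/- x_well`.  The model commits to a choice when
#' `|x|` passes `x_commit`, the inner inflection point of the outer
#' wells (the larger root of `G''(x) = 0`), which is independent of the
#' barrier scale `b`.
#'
#' @param b Barrier scale (does not affect the critical points).
#' @param beta,gamma Potential coefficients.
#' @return List with `x_barrier`, `x_well`, `x_commit`, `depth` (barrier
#'   height above the central well for the given `b`).
#' @export
attractor_geometry <- function(b = 1, beta = 4, gamma = 3) {
  if (beta^2 <= 3 * gamma) {
    stop("potential is not tri-stable: need beta^2 > 3 gamma", call. = FALSE)
  }
  # G'(x) = 2 b x (1 - 2 beta x^2 + 3 gamma x^4)
  disc <- sqrt(beta^2 - 3 * gamma)
  x_barrier <- sqrt((beta - disc) / (3 * gamma))
  x_well <- sqrt((beta + disc) / (3 * gamma))
  # G''(x) = 2 b (1 - 6 beta x^2 + 15 gamma x^4)
  d2 <- sqrt((3 * beta)^2 - 15 * gamma)
  x_commit <- sqrt((3 * beta + d2) / (15 * gamma))
  G <- function(x) b * (x^2 - beta * x^4 + gamma * x^6)
  list(x_barrier = x_barrier, x_well = x_well, x_commit = x_commit,
       depth = G(x_barrier) - G(0))
}

# Maximum |G'(x)| over the central region [0, x_commit]; sets the default
# forcing amplitude.
attractor_max_slope <- function(b, beta, gamma) {
  geom <- attractor_geometry(b, beta, gamma)
  xs <- seq(0, geom$x_commit, length.out = 400)
  max(abs(b * xs * (2 - 4 * beta * xs^2 + 6 * gamma * xs^4)))
}

#' Momentary drift implied by the visible dots
#'
#' Returns `gain * (n_dominant - n_other) / (n_dominant + n_other)` from
#' the dots visible at time `t`; at the 57:43 steady state (40 dots) the
#' expected momentary drift is `gain * 0.14`.
#'
#' @param stream A [generate_stimulus()] object.
#' @param t Time(s) within the trial.
#' @param gain Evidence gain.
#' @return Drift in evidence/second (dominant-positive).
#' @export
drift_from_stimulus <- function(stream, t, gain) {
  vc <- visible_counts(stream, t)
  gain * (vc$n_dominant - vc$n_other) / (vc$n_dominant + vc$n_other)
}

# Pack family parameters for the C++ simulator / FP solver, resolving
# per-schedule vectors (bound, barrier) at the given level.
model_pars <- function(model, level = 1L, deadline = NULL) {
  pick <- function(x) if (length(x) >= level) x[[level]] else x[[1]]
  pars <- list(A = model$A, c = model$noise)
  if (model$family == "attractor") {
    b <- pick(model$barrier)
    pars$b <- b
    pars$beta <- model$beta
    pars$gamma <- model$gamma
    pars$u <- model$urgency
    pars$Famp <- model$forcing_amp %||%
      (10 * attractor_max_slope(b, model$beta, model$gamma))
    pars$Fonset <- if (is.null(deadline)) Inf else
      max(0, deadline - model$forcing_onset)
    pars$xcommit <- model$x_commit
  } else {
    pars$B <- pick(model$bound)
    if (model$family == "variant_drift") pars$sA <- model$drift_sd
    if (model$family == "collapsing") pars$lambda <- pick(model$collapse)
    if (model$family %in% c("leak", "leak_urgency")) pars$tau <- model$tau
    if (model$family %in% c("urgency", "leak_urgency")) {
      pars$u <- model$urgency
    }
  }
  pars
}

#' Simulate decision trials
#'
#' Simulates `n` independent trials of `model` under one schedule by
#' Euler-Maruyama integration with Brownian-bridge boundary crossing.
#' Uses R's random number generator: call `set.seed()` for
#' reproducibility.
#'
#' @param model A [model_spec()].
#' @param schedule One row of a `schedule_spec` (its `deadline` caps the
#'   response time and its `level` selects per-schedule thresholds).
#' @param n Number of trials.
#' @param drift_mat Optional `n x K` matrix of momentary drift values
#'   (stimulus-driven mode), column k applying on
#'   `[(k-1) drift_dt, k drift_dt)`.
#' @param drift_dt Time resolution of `drift_mat` columns (seconds).
#' @param bridge Apply the within-step bridge crossing correction
#'   (default `TRUE`).
#' @return A data frame with `choice` (1 upper / -1 lower / 0 none),
#'   `rt` (seconds, `NA` when the bound was not crossed before the
#'   deadline), and `crossed`.
#' @export
simulate_trials <- function(model, schedule, n, drift_mat = NULL,
                            drift_dt = 0.05, bridge = TRUE) {
  deadline <- schedule$deadline[1]
  if (model$dt >= deadline) {
    stop("integration step 'dt' must be smaller than the deadline",
         call. = FALSE)
  }
  level <- schedule$level[1] %||% 1L
  pars <- model_pars(model, level, deadline)
  dm <- drift_mat %||% matrix(numeric(0), 0, 0)
  if (nrow(dm) > 0 && nrow(dm) != n) {
    stop("'drift_mat' must have one row per trial", call. = FALSE)
  }
  res <- sim_trials_cpp(.family_code(model$family), as.integer(n), pars,
                        deadline, model$dt, dm, drift_dt, bridge)
  data.frame(choice = res$choice, rt = res$rt, crossed = res$choice != 0L,
             x_final = res$x_final)
}

#' Simulate interrogation-style (fixed-duration) decisions
#'
#' Integrates the model's decision variable without absorbing bounds and
#' reads out the choice as its sign at `duration`.  This readout
#' isolates the model's temporal integration kernel from the stopping
#' rule, which makes it the appropriate generative regime for validating
#' psychophysical-kernel estimation: with bound crossing, the evidence
#' conditioned on a choice sums to the threshold, which distorts the
#' regression weights near the response for any integrator.
#'
#' @inheritParams simulate_trials
#' @param duration Integration time in seconds (the common response
#'   time of all trials).
#' @return Data frame with `choice` (1 / -1), `rt` (= `duration`), and
#'   `x_final`.
#' @export
simulate_interrogation <- function(model, duration, n, drift_mat = NULL,
                                   drift_dt = 0.05) {
  free <- model
  if (model$family == "attractor") {
    stop("interrogation readout is defined for the diffusion families",
         call. = FALSE)
  }
  free$bound <- Inf
  sim <- simulate_trials(free, flat_schedule_internal(duration), n,
                         drift_mat = drift_mat, drift_dt = drift_dt,
                         bridge = FALSE)
  data.frame(choice = ifelse(sim$x_final >= 0, 1L, -1L), rt = duration,
             crossed = TRUE, x_final = sim$x_final)
}

flat_schedule_internal <- function(deadline) {
  data.frame(level = 1L, deadline = deadline)
}

#' Simulate a single trial, optionally keeping the trajectory
#'
#' Thin wrapper over [simulate_trials()]; with `keep_path = TRUE` the
#' unabsorbed decision-variable path is also recorded (for diagnostics;
#' simulated with an independent noise draw from the same stream).
#'
#' @inheritParams simulate_trials
#' @param stream Optional [generate_stimulus()] stimulus; when given,
#'   the momentary drift is taken from the newest sample
#'   (`gain * (+1/-1)` on the dominant-positive axis).
#' @param gain Evidence gain for stimulus-driven mode.
#' @param keep_path Record the trajectory on the full time grid.
#' @return A one-row data frame as in [simulate_trials()], with an
#'   optional `path` attribute (`data.frame(t, x)`).
#' @export
simulate_trial <- function(model, schedule, stream = NULL, gain = 1,
                           keep_path = FALSE, bridge = TRUE) {
  dm <- NULL
  ddt <- 0.05
  if (!is.null(stream)) {
    dv <- gain * ifelse(stream$is_dominant, 1, -1)
    dm <- matrix(dv, nrow = 1L)
    ddt <- stream$sample_interval
  }
  out <- simulate_trials(model, schedule, 1L, drift_mat = dm,
                         drift_dt = ddt, bridge = bridge)
  if (keep_path) {
    deadline <- schedule$deadline[1]
    pars <- model_pars(model, schedule$level[1] %||% 1L, deadline)
    path <- sim_path_cpp(.family_code(model$family), pars, deadline,
                         model$dt, if (is.null(dm)) numeric(0) else dm[1, ],
                         ddt)
    attr(out, "path") <- data.frame(
      t = seq(0, by = model$dt, length.out = length(path)), x = path)
  }
  out
}

#' Reference parameterizations of the seven models
#'
#' Model specifications used for the diagnostic simulations: parameters
#' are chosen so that each family expresses its characteristic behaviour
#' on the six deadline schedules (accuracies in the 60-85% range,
#' response times spread over the available time).  Thresholds increase
#' with the available time, reflecting boundaries that adapt to time
#' pressure.
#'
#' @return Named list of [model_spec()] objects.
#' @export
reference_models <- function() {
  B <- c(0.30, 0.45, 0.55, 0.65, 0.70, 0.75)
  list(
    basic = model_spec("basic", A = 0.3, noise = 0.5, bound = B),
    variant_drift = model_spec("variant_drift", A = 0.3, noise = 0.5,
                               bound = B, drift_sd = 0.3),
    collapsing = model_spec("collapsing", A = 0.3, noise = 0.5,
                            bound = 1.6 * B, collapse = 0.7 * (1:6)),
    leak = model_spec("leak", A = 0.3, noise = 0.5,
                      bound = pmin(B, 0.55), tau = 0.6),
    urgency = model_spec("urgency", A = 0.3, noise = 0.5,
                         bound = B * 0.7 * (1:6) * 0.8, urgency = 1),
    leak_urgency = model_spec("leak_urgency", A = 0.3, noise = 0.5,
                              bound = pmin(B, 0.55) * 0.7 * (1:6) * 0.8,
                              tau = 0.6, urgency = 1),
    attractor = model_spec("attractor", A = 0.4, noise = 0.35,
                           barrier = c(0.8, 0.9, 1.0, 1.1, 1.15, 1.2),
                           urgency = 1.2)
  )
}

#' Diagnostic behavioral signatures of a model
#'
#' Simulates `n_per_schedule` trials per schedule and computes the three
#' diagnostic tables: the per-schedule speed-accuracy point (mean RT and
#' accuracy of committed trials), accuracy in five deadline-proximity
#' bins with the regression slope test, and RT-matched accuracy for
#' adjacent schedule pairs.  Non-committed trials are discarded.
#'
#' @param model A [model_spec()].
#' @param schedules A `schedule_spec`.
#' @param n_per_schedule Trials per schedule (>= 1000 recommended).
#' @param seed Integer seed.
#' @return List of data frames `sat`, `proximity`, `rt_matched`.
#' @export
model_signatures <- function(model, schedules, n_per_schedule = 1e4,
                             seed = 1L) {
  recs <- lapply(seq_len(nrow(schedules)), function(i) {
    sch <- schedules[i, , drop = FALSE]
    set.seed(derive_seed(seed, i, 0L))
    sim <- simulate_trials(model, sch, n_per_schedule)
    ok <- sim$crossed
    # Upper crossings are correct: drift is signed toward the dominant
    # color in constant-drift mode.
    data.frame(level = sch$level, deadline = sch$deadline,
               rt = sim$rt[ok], correct = sim$choice[ok] == 1L)
  })
  sat_tab <- do.call(rbind, lapply(recs, function(r) {
    data.frame(level = r$level[1], deadline = r$deadline[1],
               n = nrow(r), mean_rt = mean(r$rt),
               p_correct = mean(r$correct))
  }))
  prox <- do.call(rbind, lapply(recs, function(r) {
    # Early proximity bins can be empty for slow-committing models;
    # proximity_performance drops them, which is expected here.
    pp <- suppressWarnings(
      proximity_performance(r, deadline = r$deadline[1]))
    data.frame(level = r$level[1], slope = attr(pp, "slope"),
               p_value = attr(pp, "p_value"))
  }))
  pairs <- seq_len(nrow(schedules) - 1L)
  rtm <- do.call(rbind, lapply(pairs, function(i) {
    fast <- recs[[i]]; slow <- recs[[i + 1L]]
    m <- rt_match(fast$rt, slow$rt)
    data.frame(
      pair = sprintf("%d-%d", fast$level[1], slow$level[1]),
      gap = m$gap, n_fast = length(m$keep_fast),
      n_slow = length(m$keep_slow),
      acc_fast = mean(fast$correct[m$keep_fast]),
      acc_slow = mean(slow$correct[m$keep_slow]))
  }))
  list(sat = sat_tab, proximity = prox, rt_matched = rtm)
}
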