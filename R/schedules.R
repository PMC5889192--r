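# Task synthesis: time-pressure schedules, dot-stimulus streams, decaying
# reward functions, and fully synthetic sessions.

#' Build the time-pressure schedules of one experiment
#'
#' Experiment 1 imposes hard deadlines of 0.7, 1.4, 2.1, 2.8, 3.5 and
#' 4.2 s (schedules 1 to 6); the pre-test uses the subset 0.7, 2.1 and
#' 3.5 s.  Experiments 2 and 3 replace the deadline with a gain/loss that
#' decays linearly to zero at one of six rates; the rates can be supplied
#' directly or tailored from a fitted speed-accuracy tradeoff (SAT)
#' function via [design_decay_rates()].
#'
#' For decaying-reward schedules the stored `decay_rate` is in points per
#' second at the reference `initial_reward`; trials with a different
#' initial reward scale the rate proportionally (the on-screen arc decays
#' as a fixed fraction of the initial value per second), so the time at
#' which the reward reaches zero -- the schedule's `deadline` column --
#' does not depend on the initial reward.
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`, `"pretest"`.
#' @param sat A [sat_params()] object; required for exp2/exp3 when
#'   `decay_rates` is not given (rates are then designed from the SAT),
#'   and also supplies the decay onset (its rise point `delta`).
#' @param decay_rates Optional numeric vector of 6 decay rates
#'   (points/second at `initial_reward`).
#' @param initial_reward Reference initial reward in points (default 100).
#' @param decay_onset Time at which the reward starts to decay (seconds).
#'   Defaults to `sat$delta` when a SAT is supplied, otherwise 0.
#' @return A `schedule_spec` data frame, one row per schedule, ordered by
#'   level.
#' @export
make_schedules <- function(experiment = c("exp1", "exp2", "exp3", "pretest"),
                           sat = NULL, decay_rates = NULL,
                           initial_reward = 100, decay_onset = NULL) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    out <- data.frame(experiment = "exp1", level = 1:6,
                      deadline = 0.7 * (1:6), initial_reward = NA_real_,
                      decay_rate = NA_real_, decay_onset = NA_real_)
  } else if (experiment == "pretest") {
    out <- data.frame(experiment = "pretest", level = 1:3,
                      deadline = c(0.7, 2.1, 3.5), initial_reward = NA_real_,
                      decay_rate = NA_real_, decay_onset = NA_real_)
  } else {
    if (is.null(decay_rates)) {
      if (is.null(sat)) {
        stop("exp2/exp3 schedules need either 'decay_rates' or 'sat'",
             call. = FALSE)
      }
      decay_rates <- design_decay_rates(sat, initial_reward = initial_reward)
    }
    if (length(decay_rates) != 6L || any(!is.finite(decay_rates)) ||
        any(decay_rates <= 0)) {
      stop("'decay_rates' must be 6 positive rates (points/second)",
           call. = FALSE)
    }
    if (is.null(decay_onset)) {
      decay_onset <- if (!is.null(sat)) sat$delta else 0
    }
    stop_if_not_scalar(decay_onset, "decay_onset")
    if (decay_onset < 0) stop("'decay_onset' must be >= 0", call. = FALSE)
    # Faster decay = greater time pressure = lower level index, matching
    # the deadline ordering of Experiment 1 (level 1 is most pressured).
    rates <- sort(decay_rates, decreasing = TRUE)
    out <- data.frame(experiment = experiment, level = 1:6,
                      deadline = decay_onset + initial_reward / rates,
                      initial_reward = initial_reward, decay_rate = rates,
                      decay_onset = decay_onset)
  }
  class(out) <- c("schedule_spec", "data.frame")
  out
}

#' Generate a sequentially revealed dot stimulus
#'
#' Dots are drawn with replacement: each sample takes the dominant color
#' with probability `q`.  One new dot appears every `sample_interval`
#' seconds (20 Hz by default), starting at trial onset (t = 0), and stays
#' visible for `persistence` seconds.
#'
#' @param q Probability that a sample is the dominant color, in (0.5, 1).
#' @param duration Trial duration in seconds.
#' @param dominant_color `"red"`, `"green"`, or `NULL` to assign red or
#'   green with equal probability.
#' @param sample_interval Seconds between samples (default 0.050).
#' @param persistence Seconds each dot stays visible (default 2.0).
#' @return A `stimulus_stream` object: onset times, colors, and the
#'   generating parameters.
#' @export
generate_stimulus <- function(q, duration, dominant_color = NULL,
                              sample_interval = 0.05, persistence = 2.0) {
  stop_if_not_scalar(q, "q")
  stop_if_not_scalar(duration, "duration")
  if (q <= 0.5 || q >= 1) stop("'q' must lie in (0.5, 1)", call. = FALSE)
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  if (is.null(dominant_color)) {
    dominant_color <- if (stats::runif(1) < 0.5) "red" else "green"
  }
  dominant_color <- match.arg(dominant_color, c("red", "green"))
  other <- if (dominant_color == "red") "green" else "red"
  n <- floor(duration / sample_interval + 1e-9) + 1L
  onset <- (seq_len(n) - 1L) * sample_interval
  is_dom <- stats::runif(n) < q
  structure(list(q = q, dominant_color = dominant_color,
                 sample_interval = sample_interval, persistence = persistence,
                 duration = duration, onset = onset,
                 color = ifelse(is_dom, dominant_color, other),
                 is_dominant = is_dom),
            class = "stimulus_stream")
}

#' @export
print.stimulus_stream <- function(x, ...) {
  cat(sprintf(
    "<stimulus_stream> %d samples @ %.0f Hz, dominant %s (q = %.2f), %.2f s\n",
    length(x$onset), 1 / x$sample_interval, x$dominant_color, x$q,
    x$duration))
  invisible(x)
}

#' Count dots visible at a given time
#'
#' A dot with onset `s` is visible on the half-open interval
#' `[s, s + persistence)`.  Under the default 20 Hz sampling and 2 s
#' persistence the visible count grows to 40 dots at two seconds into the
#' trial and stays there.
#'
#' @param stream A [generate_stimulus()] object.
#' @param t Time(s) in seconds, within `[0, duration]`.
#' @return Data frame with one row per `t`: `n_dominant`, `n_other`.
#' @export
visible_counts <- function(stream, t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be nonnegative", call. = FALSE)
  }
  if (any(t > stream$duration + 1e-9)) {
    stop("'t' beyond stream duration", call. = FALSE)
  }
  res <- vapply(t, function(ti) {
    vis <- stream$onset <= ti + 1e-12 &
      ti < stream$onset + stream$persistence - 1e-12
    c(sum(stream$is_dominant[vis]), sum(vis & !stream$is_dominant))
  }, numeric(2))
  data.frame(t = t, n_dominant = res[1, ], n_other = res[2, ])
}

#' Reward available at time t under a decaying-reward schedule
#'
#' The gain for a correct response starts at the trial's initial value
#' and decreases linearly once the decay onset has passed; the loss for
#' an incorrect response mirrors it with opposite sign.  Both are clipped
#' at zero: once the gain or loss reaches 0 it stays at 0.
#'
#' @param t Response time(s) in seconds.
#' @param correct Logical: reward for a correct (`TRUE`) or incorrect
#'   (`FALSE`) response.
#' @param schedule One row of an exp2/exp3 `schedule_spec`.
#' @param initial_reward Trial initial reward; defaults to the schedule's
#'   reference value.  The decay rate scales proportionally.
#' @return Signed reward in points.
#' @export
reward_at <- function(t, correct, schedule, initial_reward = NULL) {
  if (!schedule$experiment[1] %in% c("exp2", "exp3")) {
    stop("reward_at() applies to decaying-reward schedules (exp2/exp3) only",
         call. = FALSE)
  }
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  gs <- initial_reward %||% schedule$initial_reward[1]
  b <- schedule$decay_rate[1] * gs / schedule$initial_reward[1]
  tau <- pmax(0, t - schedule$decay_onset[1])
  if (isTRUE(correct[1])) pmax(0, gs - b * tau) else pmin(0, -gs + b * tau)
}

#' Session design of one experiment
#'
#' Experiment 1: 10 blocks of 36 trials, each block containing all six
#' deadline schedules six times.  Experiments 2 and 3: 10 blocks of 36
#' trials, each (initial reward x decay rate) combination three times per
#' block.  Pre-test: 9 blocks of 36 trials over a 3 (dot ratio) x 3 (time
#' window) grid, each block at a single ratio cycling 60:40, 57:43,
#' 54:46, with the three windows appearing equally often within a block.
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`, `"pretest"`.
#' @return A `session_design` list: `n_blocks`, `trials_per_block`, and a
#'   per-block condition grid.
#' @export
session_design <- function(experiment = c("exp1", "exp2", "exp3",
                                          "pretest")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    grid <- data.frame(level = rep(1:6, each = 6), initial_reward = NA_real_)
    n_blocks <- 10L
  } else if (experiment == "pretest") {
    grid <- data.frame(level = rep(1:3, each = 12), initial_reward = NA_real_)
    n_blocks <- 9L
  } else {
    grid <- expand.grid(level = 1:6, initial_reward = c(50, 100),
                        rep = 1:3)[, c("level", "initial_reward")]
    n_blocks <- 10L
  }
  structure(list(experiment = experiment, n_blocks = n_blocks,
                 trials_per_block = nrow(grid), block_grid = grid),
            class = "session_design")
}

# Dot ratios used in the pre-test blocks, cycling across blocks.
pretest_ratios <- function() c(0.60, 0.57, 0.54)

# Momentary stimulus-driven drift on the red-positive axis, one value per
# sample interval.  mode "sample": only the newest dot carries evidence
# (+gain red, -gain green).  mode "pool": evidence is the signed
# proportion of red among currently visible dots (see
# drift_from_stimulus() for the dominant-positive convention).
stim_drift_vector <- function(stream, gain, mode = c("sample", "pool")) {
  mode <- match.arg(mode)
  red <- stream$color == "red"
  if (mode == "sample") {
    return(gain * ifelse(red, 1, -1))
  }
  n <- length(stream$onset)
  vapply(seq_len(n), function(k) {
    t <- stream$onset[k]
    vis <- stream$onset <= t + 1e-12 &
      t < stream$onset + stream$persistence - 1e-12
    gain * (sum(red[vis]) - sum(!red[vis])) / sum(vis)
  }, numeric(1))
}

#' Simulate a full synthetic session
#'
#' A decision model (see [model_spec()]) plays the role of the subject:
#' every designed trial is simulated, producing one behavior record
#' (choice, response time, reward outcome).  Trials where the model does
#' not commit before the deadline are recorded with choice `"none"` and
#' the no-response penalty (-60 points in exp1/pre-test; 0 points in
#' exp2/exp3, where the reward has fully decayed).
#'
#' Per-trial random-number substreams are derived deterministically from
#' `seed` and the (block, trial) index, so identical inputs give
#' byte-identical sessions.
#'
#' @param model A [model_spec()].
#' @param experiment `"exp1"`, `"exp2"`, `"exp3"`, or `"pretest"`.
#' @param schedules Optional `schedule_spec`; built by [make_schedules()]
#'   when omitted (exp2/exp3 then require `sat`).
#' @param sat [sat_params()]; required for exp3 (win probability at the
#'   accept time) and for building exp2/exp3 schedules when `schedules`
#'   is not given.
#' @param seed Integer session seed.
#' @param q Dominant-color probability of the dot stimulus (default 0.57,
#'   the 57:43 ratio; the pre-test overrides it per block).
#' @param subject_id Identifier stored in the records.
#' @param stimulus_mode `"constant"` (drift fixed at the model's `A`,
#'   signed toward the dominant color), `"sample"` (momentary drift from
#'   each newly revealed dot; used for kernel analyses), or `"pool"`
#'   (momentary drift from the visible-dot proportion).
#' @param gain Evidence gain for the stimulus-driven modes.
#' @param keep_streams Attach the generated stimulus streams (as
#'   attribute `"streams"`) for stimulus-based analyses.
#' @return A data frame of behavior records, one row per trial.
#' @export
simulate_session <- function(model, experiment, schedules = NULL, sat = NULL,
                             seed = 1L, q = 0.57, subject_id = "sim01",
                             stimulus_mode = c("constant", "sample", "pool"),
                             gain = 1, keep_streams = FALSE) {
  stimulus_mode <- match.arg(stimulus_mode)
  design <- session_design(experiment)
  experiment <- design$experiment
  if (is.null(schedules)) {
    schedules <- make_schedules(experiment, sat = sat)
  }
  if (nrow(schedules) != max(design$block_grid$level)) {
    stop("schedules do not match the design grid", call. = FALSE)
  }
  if (experiment == "exp3" && is.null(sat)) {
    stop("exp3 sessions need 'sat' for the win probability", call. = FALSE)
  }
  has_stim <- experiment != "exp3"
  recs <- vector("list", design$n_blocks * design$trials_per_block)
  streams <- if (keep_streams && has_stim) list() else NULL
  idx <- 0L
  for (b in seq_len(design$n_blocks)) {
    set.seed(derive_seed(seed, b, 0L))
    ord <- sample.int(design$trials_per_block)
    grid <- design$block_grid[ord, , drop = FALSE]
    q_block <- if (experiment == "pretest") {
      pretest_ratios()[((b - 1L) %% 3L) + 1L]
    } else {
      q
    }
    for (tr in seq_len(design$trials_per_block)) {
      idx <- idx + 1L
      lev <- grid$level[tr]
      sch <- schedules[schedules$level == lev, , drop = FALSE]
      avail <- sch$deadline
      gs_trial <- grid$initial_reward[tr]
      set.seed(derive_seed(seed, b, tr))
      stream <- NULL
      sim <- if (has_stim) {
        stream <- generate_stimulus(q_block, avail)
        if (stimulus_mode == "constant") {
          simulate_trials(model, sch, n = 1L)
        } else {
          dv <- stim_drift_vector(stream, gain, stimulus_mode)
          simulate_trials(model, sch, n = 1L,
                          drift_mat = matrix(dv, nrow = 1L),
                          drift_dt = stream$sample_interval)
        }
      } else {
        simulate_trials(model, sch, n = 1L)
      }
      crossed <- sim$choice[1] != 0L
      rt <- if (crossed) sim$rt[1] else NA_real_
      if (experiment == "exp3") {
        choice <- if (crossed) "accept" else "none"
        correct <- if (crossed) {
          stats::runif(1) < sat_probability(rt, sat)
        } else {
          NA
        }
        reward <- if (!crossed) 0 else {
          reward_at(rt, correct, sch, initial_reward = gs_trial)
        }
        stim_ref <- NA_character_
      } else {
        if (crossed) {
          up_color <- if (stimulus_mode == "constant") {
            stream$dominant_color
          } else {
            "red"  # stimulus-driven drift lives on the red-positive axis
          }
          dn_color <- if (up_color == "red") "green" else "red"
          choice <- if (sim$choice[1] == 1L) up_color else dn_color
          correct <- choice == stream$dominant_color
        } else {
          choice <- "none"
          correct <- NA
        }
        reward <- if (experiment %in% c("exp1", "pretest")) {
          if (!crossed) -60 else if (correct) 60 else -60
        } else {
          if (!crossed) 0 else {
            reward_at(rt, correct, sch, initial_reward = gs_trial)
          }
        }
        stim_ref <- sprintf("b%02dt%02d", b, tr)
        if (!is.null(streams)) streams[[stim_ref]] <- stream
      }
      recs[[idx]] <- data.frame(
        subject_id = subject_id, block_index = b, trial_index = idx,
        experiment = experiment, level = lev, deadline = avail,
        initial_reward = gs_trial, dot_ratio = if (has_stim) q_block
                                               else NA_real_,
        choice = choice, correct = correct, rt = rt,
        reward_outcome = reward, stimulus_ref = stim_ref,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (!is.null(streams)) attr(out, "streams") <- streams
  out
}

#' Read and write trial tables and stimulus streams
#'
#' Trial tables are plain CSV, one row per trial with the behavior-record
#' columns; stimulus streams go to a sidecar CSV with one row per dot
#' (`trial_id`, `onset_s`, `color`).
#'
#' @param records Behavior-record data frame from [simulate_session()].
#' @param file Path to a CSV file.
#' @return `read_trials` returns the trial data frame; the writers return
#'   their input invisibly.
#' @export
write_trials <- function(records, file) {
  out <- records
  attr(out, "streams") <- NULL
  utils::write.csv(out, file, row.names = FALSE)
  invisible(records)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname write_trials
#' @param streams Named list of `stimulus_stream` objects (attribute
#'   `"streams"` of a simulated session).
#' @export
write_streams <- function(streams, file) {
  rows <- lapply(names(streams), function(id) {
    s <- streams[[id]]
    data.frame(trial_id = id, onset_s = s$onset, color = s$color,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(streams)
}

#' @rdname write_trials
#' @export
read_streams <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  split_d <- split(d, d$trial_id)
  lapply(split_d, function(s) {
    s <- s[order(s$onset_s), ]
    list(onset = s$onset_s, color = s$color)
  })
}
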