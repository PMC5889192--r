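# Fokker-Planck first-passage prediction, the Gaussian summary
# likelihood on five RT bins, model fitting, and AIC comparison.

#' Propagate the decision-variable density of a model
#'
#' Solves the one-dimensional Fokker-Planck equation for the model's
#' decision variable by Crank-Nicolson on a fixed spatial grid with
#' absorbing boundaries.  Time-varying bounds (collapsing boundary, and
#' the urgency readout, equivalent to the bound `bound / U(t)` on x) are
#' handled by zeroing the density beyond the instantaneous bound and
#' booking it as absorbed flux.  Trial-to-trial drift variability is
#' integrated out by Gauss-Hermite quadrature (11 nodes).  The scheme is
#' conservative: remaining density plus cumulative absorbed flux equals
#' 1 to within 1e-6 at every step (checked; a larger violation raises a
#' resolution error).
#'
#' Upper-boundary flux corresponds to correct choices (the drift `A` is
#' signed toward the correct alternative).
#'
#' @param model A [model_spec()].
#' @param schedule One row of a `schedule_spec`.
#' @param dt Time step in seconds.  Default 1 ms; families with a moving
#'   bound (collapsing, urgency, leak_urgency) default to 0.25 ms because
#'   the bound masking converges linearly in the step size.
#' @param n_x Number of spatial grid points (default 301; 601 for the
#'   moving-bound families).
#' @param horizon Propagation horizon in seconds; defaults to the
#'   schedule deadline (longer horizons are useful for limits).
#' @return An `fp_state` object: `times`, `flux_up`, `flux_lo` (mass
#'   absorbed per step), `mass_remaining`, `x`, `p_final`.
#' @export
fp_propagate <- function(model, schedule, dt = NULL, n_x = NULL,
                         horizon = NULL) {
  moving <- model$family %in% c("collapsing", "urgency", "leak_urgency")
  dt <- dt %||% if (moving) 2.5e-4 else 1e-3
  n_x <- n_x %||% if (moving) 601L else 301L
  if (n_x %% 2L == 0L) n_x <- n_x + 1L  # grid must carry a node at x = 0
  deadline <- horizon %||% schedule$deadline[1]
  level <- schedule$level[1] %||% 1L
  pars <- model_pars(model, level, deadline)
  n_steps <- as.integer(floor(deadline / dt + 1e-9))
  times <- seq_len(n_steps) * dt
  fam <- model$family
  cc <- pars$c

  run <- function(A_val) {
    if (fam %in% c("basic", "variant_drift", "collapsing")) {
      dfam <- 0L; dpars <- list(A = A_val); D <- cc^2 / 2
      L <- pars$B
      bound <- if (fam == "collapsing") {
        pars$B * exp(-times / pars$lambda)
      } else {
        rep(Inf, n_steps)
      }
    } else if (fam %in% c("leak", "leak_urgency")) {
      dfam <- 1L; dpars <- list(A = A_val, tau = pars$tau)
      s <- cc / pars$tau; D <- s^2 / 2
      if (fam == "leak") {
        L <- pars$B
        bound <- rep(Inf, n_steps)
      } else {
        bound <- pars$B / (pars$u * times)
        env <- abs(A_val) + 6 * s * sqrt(pars$tau / 2) + 0.5
        L <- 1.1 * max(pmin(bound, env))
        bound <- pmin(bound, Inf)
      }
    } else if (fam == "urgency") {
      dfam <- 0L; dpars <- list(A = A_val); D <- cc^2 / 2
      bound <- pars$B / (pars$u * times)
      env <- abs(A_val) * times + 6 * cc * sqrt(times) + 0.5
      L <- 1.1 * max(pmin(bound, env))
    } else { # attractor
      dfam <- 2L
      dpars <- list(A = A_val, b = pars$b, beta = pars$beta,
                    gamma = pars$gamma, u = pars$u, Famp = pars$Famp,
                    Fonset = pars$Fonset)
      D <- cc^2 / 2
      L <- pars$xcommit
      bound <- rep(Inf, n_steps)
    }
    fp_propagate_cpp(dfam, dpars, D, -L, L, as.integer(n_x), dt, n_steps,
                     bound, 8L)
  }

  if (fam == "variant_drift") {
    gh <- pracma::gaussHermite(11)
    w <- gh$w / sqrt(pi)
    acc <- NULL
    for (i in seq_along(gh$x)) {
      r <- run(pars$A + sqrt(2) * pars$sA * gh$x[i])
      if (is.null(acc)) {
        acc <- r
        acc$flux_up <- w[i] * r$flux_up
        acc$flux_lo <- w[i] * r$flux_lo
        acc$mass_remaining <- w[i] * r$mass_remaining
        acc$p_final <- w[i] * r$p_final
      } else {
        acc$flux_up <- acc$flux_up + w[i] * r$flux_up
        acc$flux_lo <- acc$flux_lo + w[i] * r$flux_lo
        acc$mass_remaining <- acc$mass_remaining + w[i] * r$mass_remaining
        acc$p_final <- acc$p_final + w[i] * r$p_final
      }
    }
    res <- acc
  } else {
    res <- run(pars$A)
  }

  cons <- abs(1 - (res$mass_remaining +
                     cumsum(res$flux_up + res$flux_lo)))
  if (max(cons) > 1e-4) {
    stop(sprintf(
      "density propagation lost mass (max violation %.2e): grid too coarse",
      max(cons)), call. = FALSE)
  }
  structure(list(times = res$times, flux_up = res$flux_up,
                 flux_lo = res$flux_lo,
                 mass_remaining = res$mass_remaining, x = res$x,
                 p_final = res$p_final, dt = dt,
                 conservation_error = max(cons), family = fam,
                 level = level, deadline = deadline),
            class = "fp_state")
}

#' @export
print.fp_state <- function(x, ...) {
  cat(sprintf(
    "<fp_state %s> horizon %.2f s, P(cross) = %.4f (up %.4f), cons.err %.1e\n",
    x$family, x$deadline, sum(x$flux_up + x$flux_lo), sum(x$flux_up),
    x$conservation_error))
  invisible(x)
}

#' First-passage summaries in RT bins
#'
#' Conditional on crossing before the deadline (the non-crossing mass is
#' discarded and the remainder renormalized), computes per RT bin the
#' proportion of correct (upper-boundary) crossings and the mean and SD
#' of the crossing time.  Bins with no predicted mass are flagged and
#' carry `NA` summaries.
#'
#' @param fp An `fp_state` from [fp_propagate()].
#' @param bin_edges Bin edges in seconds (length `n_bins + 1`, covering
#'   the deadline range); defaults to five equal-mass quantile edges of
#'   the predicted first-passage distribution.
#' @param n_bins Number of bins when `bin_edges` is `NULL`.
#' @return Data frame (`bin`, `p_correct`, `mean_rt`, `sd_rt`, `mass`,
#'   `flagged`).
#' @export
predict_summaries <- function(fp, bin_edges = NULL, n_bins = 5) {
  ftot <- fp$flux_up + fp$flux_lo
  m <- sum(ftot)
  if (m <= 0) stop("no crossing mass before the deadline", call. = FALSE)
  # Flux absorbed during step j is booked at the step midpoint.
  tmid <- fp$times - fp$dt / 2
  if (is.null(bin_edges)) {
    cdf <- cumsum(ftot) / m
    probs <- seq(0, 1, length.out = n_bins + 1L)
    idx <- vapply(probs[-c(1, n_bins + 1L)], function(p) {
      which(cdf >= p)[1]
    }, integer(1))
    bin_edges <- c(0, fp$times[idx], fp$deadline)
  }
  nb <- length(bin_edges) - 1L
  bin <- pmin(pmax(findInterval(tmid, bin_edges,
                                rightmost.closed = TRUE), 1L), nb)
  out <- do.call(rbind, lapply(seq_len(nb), function(k) {
    sel <- bin == k
    mk <- sum(ftot[sel])
    if (mk < 1e-12 * m) {
      return(data.frame(bin = k, p_correct = NA_real_, mean_rt = NA_real_,
                        sd_rt = NA_real_, mass = 0, flagged = TRUE))
    }
    tt <- tmid[sel]
    mu <- sum(tt * ftot[sel]) / mk
    v <- sum(tt^2 * ftot[sel]) / mk - mu^2
    data.frame(bin = k, p_correct = sum(fp$flux_up[sel]) / mk,
               mean_rt = mu, sd_rt = sqrt(max(v, 0)), mass = mk / m,
               flagged = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Sample trials from a first-passage distribution
#'
#' Draws `n` committed trials from the first-passage law of an
#' `fp_state`: a step is drawn with probability proportional to its
#' absorbed flux, the response time is jittered uniformly within the
#' step, and the choice is correct with the step's conditional
#' upper-boundary probability.  Useful for parametric recovery studies
#' where the generating distribution and the fitted likelihood should
#' share the same numerical resolution.
#'
#' @param fp An `fp_state` from [fp_propagate()].
#' @param n Number of trials to draw.
#' @return Data frame with `rt` and `correct`.
#' @export
fp_sample <- function(fp, n) {
  ft <- fp$flux_up + fp$flux_lo
  m <- sum(ft)
  if (m <= 0) stop("no crossing mass to sample from", call. = FALSE)
  idx <- sample.int(length(ft), n, replace = TRUE, prob = ft)
  data.frame(rt = fp$times[idx] - stats::runif(n) * fp$dt,
             correct = stats::runif(n) < fp$flux_up[idx] / ft[idx])
}

#' Observed choice/RT summaries in quantile RT bins
#'
#' For each schedule, splits the committed trials into `n_bins`
#' equal-count quantile bins of RT and records the proportion correct,
#' the mean and SD of RT, and the trial count -- the fitting target of
#' the summary likelihood.
#'
#' @param records Data frame with columns `level`, `rt`, `correct`
#'   (rows with `NA` rt are discarded).
#' @param n_bins Number of RT bins per schedule (default 5).
#' @return Data frame (`level`, `bin`, `p_correct`, `mean_rt`, `sd_rt`,
#'   `n`) with attribute `edges` (named list of per-level bin edges).
#' @export
summarize_records <- function(records, n_bins = 5) {
  rec <- records[!is.na(records$rt), , drop = FALSE]
  if (!is.null(rec$choice)) rec <- rec[rec$choice != "none", , drop = FALSE]
  levs <- sort(unique(rec$level))
  edges <- list()
  out <- do.call(rbind, lapply(levs, function(l) {
    r <- rec[rec$level == l, , drop = FALSE]
    e <- unique(stats::quantile(r$rt, probs = seq(0, 1,
                                                  length.out = n_bins + 1L),
                                names = FALSE))
    e[1] <- 0
    e[length(e)] <- e[length(e)] + 1e-9
    edges[[as.character(l)]] <<- e
    bin <- pmin(pmax(findInterval(r$rt, e, rightmost.closed = TRUE), 1L),
                length(e) - 1L)
    do.call(rbind, lapply(seq_len(length(e) - 1L), function(k) {
      rr <- r[bin == k, , drop = FALSE]
      data.frame(level = l, bin = k, p_correct = mean(rr$correct),
                 mean_rt = mean(rr$rt), sd_rt = stats::sd(rr$rt),
                 n = nrow(rr))
    }))
  }))
  rownames(out) <- NULL
  structure(out, edges = edges)
}

#' Gaussian summary log-likelihood
#'
#' Sum over (schedule, bin) cells of Gaussian log-densities of the
#' observed proportion correct, mean RT, and SD of RT around the model's
#' predictions.  Error variances are the standard summary-statistic
#' choices: binomial `p (1 - p) / n` for proportions, `sd^2 / n` for the
#' mean, and `sd^2 / (2 n)` for the SD (delta method).  Cells whose
#' prediction is flagged (no predicted mass) are excluded.
#'
#' @param predicted Data frame with columns `level`, `bin`, `p_correct`,
#'   `mean_rt`, `sd_rt` and optionally `flagged`.
#' @param observed Output of [summarize_records()] (same bin structure).
#' @return Log-likelihood (scalar).
#' @export
summary_loglik <- function(predicted, observed) {
  key <- function(d) paste(d$level, d$bin)
  if (!all(key(observed) %in% key(predicted))) {
    stop("predicted and observed summaries have different structure",
         call. = FALSE)
  }
  pred <- predicted[match(key(observed), key(predicted)), , drop = FALSE]
  flagged <- if (!is.null(pred$flagged)) pred$flagged else
    !is.finite(pred$mean_rt)
  ll <- 0
  for (i in seq_len(nrow(observed))) {
    if (flagged[i]) next
    o <- observed[i, ]; p <- pred[i, ]
    ph <- min(max(o$p_correct, 1 / (2 * o$n)), 1 - 1 / (2 * o$n))
    sdo <- max(o$sd_rt, 1e-3, na.rm = TRUE)
    ll <- ll +
      stats::dnorm(o$p_correct, p$p_correct,
                   sqrt(ph * (1 - ph) / o$n), log = TRUE) +
      stats::dnorm(o$mean_rt, p$mean_rt, sdo / sqrt(o$n), log = TRUE) +
      stats::dnorm(o$sd_rt, p$sd_rt, sdo / sqrt(2 * o$n), log = TRUE)
  }
  ll
}

# ---- Fast fitting path -----------------------------------------------------
# The optimizer evaluates the summary likelihood thousands of times, so
# the per-evaluation work is stripped to direct calls into the C++
# solver with everything level-independent precomputed once.

# Per-level precomputation: step grid, bin assignment of each step
# midpoint, and the observed summaries with their Gaussian error SDs.
prep_fit_level <- function(level, schedule, observed, edges, ctl) {
  n_steps <- as.integer(floor(schedule$deadline[1] / ctl$fp_dt + 1e-9))
  times <- seq_len(n_steps) * ctl$fp_dt
  tmid <- times - ctl$fp_dt / 2
  e <- edges[[as.character(level)]]
  nb <- length(e) - 1L
  bin <- pmin(pmax(findInterval(tmid, e, rightmost.closed = TRUE), 1L), nb)
  obs <- observed[observed$level == level, , drop = FALSE]
  obs <- obs[order(obs$bin), , drop = FALSE]
  ph <- pmin(pmax(obs$p_correct, 1 / (2 * obs$n)), 1 - 1 / (2 * obs$n))
  sdo <- pmax(obs$sd_rt, 1e-3)
  list(level = level, deadline = schedule$deadline[1], n_steps = n_steps,
       times = times, tmid = tmid, bin = bin, nb = nb, obs = obs,
       sd_p = sqrt(ph * (1 - ph) / obs$n), sd_m = sdo / sqrt(obs$n),
       sd_s = sdo / sqrt(2 * obs$n))
}

# Negative summary log-likelihood of one parameter vector, all levels.
fit_nll <- function(family, th, preps, ctl, geom = NULL) {
  nll <- 0
  A <- th[["A"]]
  cc <- ctl$noise
  for (p in preps) {
    lev <- p$level
    Bk <- if (family == "attractor") NULL else th[[paste0("B", lev)]]
    if (family %in% c("basic", "variant_drift", "collapsing")) {
      dfam <- 0L; D <- cc^2 / 2; L <- Bk
      bound <- if (family == "collapsing") {
        Bk * exp(-p$times / th[[paste0("lambda", lev)]])
      } else rep(Inf, p$n_steps)
      dp <- list(A = A)
    } else if (family %in% c("leak", "leak_urgency")) {
      tau <- th[["tau"]]
      s <- cc / tau; D <- s^2 / 2
      dfam <- 1L; dp <- list(A = A, tau = tau)
      if (family == "leak") {
        L <- Bk; bound <- rep(Inf, p$n_steps)
      } else {
        bound <- Bk / p$times  # u fixed at 1 during fitting
        env <- abs(A) + 6 * s * sqrt(tau / 2) + 0.5
        L <- 1.1 * max(pmin(bound, env))
      }
    } else if (family == "urgency") {
      dfam <- 0L; D <- cc^2 / 2; dp <- list(A = A)
      bound <- Bk / p$times
      env <- abs(A) * p$times + 6 * cc * sqrt(p$times) + 0.5
      L <- 1.1 * max(pmin(bound, env))
    } else {
      b <- th[[paste0("b", lev)]]
      dfam <- 2L; D <- cc^2 / 2; L <- geom$x_commit
      dp <- list(A = A, b = b, beta = geom$beta, gamma = geom$gamma,
                 u = th[["u"]], Famp = 10 * b * geom$unit_max_slope,
                 Fonset = max(0, p$deadline - 0.05))
      bound <- rep(Inf, p$n_steps)
    }
    if (family == "variant_drift") {
      gh <- ctl$gh
      fu <- fl <- numeric(p$n_steps)
      for (i in seq_along(gh$x)) {
        r <- fp_propagate_cpp(dfam, list(A = A + sqrt(2) * th[["sA"]] *
                                           gh$x[i]),
                              D, -L, L, ctl$n_x, ctl$fp_dt, p$n_steps,
                              bound, 8L)
        fu <- fu + gh$wn[i] * r$flux_up
        fl <- fl + gh$wn[i] * r$flux_lo
      }
    } else {
      r <- fp_propagate_cpp(dfam, dp, D, -L, L, ctl$n_x, ctl$fp_dt,
                            p$n_steps, bound, 8L)
      fu <- r$flux_up; fl <- r$flux_lo
    }
    ft <- fu + fl
    m <- sum(ft)
    if (!is.finite(m) || m < 1e-6) return(1e8)
    sums <- rowsum(cbind(ft, fu, ft * p$tmid, ft * p$tmid^2), p$bin)
    got <- as.integer(rownames(sums))
    mk <- sums[, 1]
    keep <- mk >= 1e-12 * m
    if (!any(keep)) return(1e8)
    pc <- sums[keep, 2] / mk[keep]
    mu <- sums[keep, 3] / mk[keep]
    v <- pmax(sums[keep, 4] / mk[keep] - mu^2, 0)
    rows <- match(got[keep], p$obs$bin)
    o <- p$obs[rows, ]
    nll <- nll - sum(
      stats::dnorm(o$p_correct, pc, p$sd_p[rows], log = TRUE) +
        stats::dnorm(o$mean_rt, mu, p$sd_m[rows], log = TRUE) +
        stats::dnorm(o$sd_rt, sqrt(v), p$sd_s[rows], log = TRUE))
  }
  if (!is.finite(nll)) return(1e8)
  nll
}

# Free-parameter layout per family: all parameters are positive and are
# optimized on the log scale.  The urgency slope is not separately
# identifiable from per-schedule thresholds (only bound/u enters the
# moving bound), so it is fixed at 1 during fitting.
family_par_names <- function(family, n_lev) {
  bnd <- paste0("B", seq_len(n_lev))
  switch(family,
         basic = c("A", bnd),
         variant_drift = c("A", "sA", bnd),
         collapsing = c("A", paste0("lambda", seq_len(n_lev)), bnd),
         leak = c("A", "tau", bnd),
         urgency = c("A", bnd),
         leak_urgency = c("A", "tau", bnd),
         attractor = c("A", "u", paste0("b", seq_len(n_lev))))
}

# Build a model_spec from a named positive-parameter vector.
theta_to_model <- function(family, th, noise, dt) {
  n_lev <- sum(grepl("^(B|b)[0-9]+$", names(th)))
  if (family == "attractor") {
    model_spec("attractor", A = th[["A"]], noise = noise,
               barrier = unname(th[paste0("b", seq_len(n_lev))]),
               urgency = th[["u"]], dt = dt)
  } else {
    model_spec(family, A = th[["A"]], noise = noise,
               bound = unname(th[paste0("B", seq_len(n_lev))]),
               drift_sd = if (family == "variant_drift") th[["sA"]],
               collapse = if (family == "collapsing") {
                 unname(th[paste0("lambda", seq_len(n_lev))])
               },
               tau = if (family %in% c("leak", "leak_urgency")) th[["tau"]],
               urgency = if (family %in% c("urgency", "leak_urgency")) 1,
               dt = dt)
  }
}

#' Turn a fit result into a simulable model specification
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param dt Integration step for subsequent simulation.
#' @return A [model_spec()] with the fitted parameters (noise and, where
#'   applicable, the urgency slope at their values fixed during
#'   fitting).
#' @export
fit_to_model <- function(fit, dt = 1e-3) {
  theta_to_model(fit$family, unlist(fit$params), fit$control$noise, dt)
}

# Deterministic multi-start grid built from quick moment heuristics on
# the observed summaries.
fit_starts <- function(family, observed, schedules, noise, n_starts) {
  levs <- sort(unique(observed$level))
  stats_lev <- do.call(rbind, lapply(levs, function(l) {
    o <- observed[observed$level == l, ]
    data.frame(level = l,
               p = sum(o$p_correct * o$n) / sum(o$n),
               mrt = sum(o$mean_rt * o$n) / sum(o$n))
  }))
  p <- pmin(pmax(stats_lev$p, 0.55), 0.95)
  lgt <- log(p / (1 - p))
  # Wiener moments: P = 1/(1+exp(-2AB/c^2)), E[T] ~ (B/A) tanh(AB/c^2).
  BoverA <- stats_lev$mrt / tanh(lgt / 2)
  AB <- noise^2 * lgt / 2
  A0 <- sqrt(mean(AB / BoverA))
  B0 <- AB / A0
  mults <- expand.grid(mA = c(0.4, 0.7, 1, 1.5, 2.5),
                       mE = c(0.5, 1, 2))
  mults <- mults[order(abs(log(mults$mA)) + abs(log(mults$mE))), ]
  mults <- mults[seq_len(min(n_starts, nrow(mults))), , drop = FALSE]
  n_lev <- length(levs)
  lapply(seq_len(nrow(mults)), function(i) {
    mA <- mults$mA[i]; mE <- mults$mE[i]
    th <- c(A = A0 * mA)
    if (family == "variant_drift") th <- c(th, sA = 0.5 * A0 * mE)
    if (family == "leak") th <- c(th, tau = 0.5 * mE)
    if (family == "leak_urgency") th <- c(th, tau = 0.5 * mE)
    if (family == "attractor") th <- c(th, u = 1 * mE)
    if (family == "collapsing") {
      th <- c(th, setNames(schedules$deadline[seq_len(n_lev)] * mE,
                           paste0("lambda", seq_len(n_lev))))
    }
    if (family == "attractor") {
      th <- c(th, setNames(rep(2 * mE, n_lev),
                           paste0("b", seq_len(n_lev))))
    } else if (family %in% c("urgency", "leak_urgency")) {
      # Bound on y = x U(t): scale the basic-DDM bound by u * E[T].
      th <- c(th, setNames(pmax(B0, 0.05) * stats_lev$mrt * mE,
                           paste0("B", seq_len(n_lev))))
    } else {
      th <- c(th, setNames(pmax(B0, 0.05) * ifelse(family == "collapsing",
                                                   1.5, 1),
                           paste0("B", seq_len(n_lev))))
    }
    th
  })
}

#' Fit a decision model to observed summaries
#'
#' Maximizes the Gaussian summary likelihood over the family's free
#' parameters (drift, per-schedule thresholds, and the family's shape
#' parameters) with bounded quasi-Newton optimization from a grid of
#' deterministic multi-starts; the model predictions come from
#' [fp_propagate()].  The evidence noise scale is fixed (it sets the
#' unit of evidence and is not identifiable jointly with drift and
#' thresholds), as is the urgency slope during fitting (only
#' threshold/urgency ratios are identifiable).
#'
#' @param family Model family name.
#' @param observed Output of [summarize_records()] covering all
#'   schedules, with its `edges` attribute.
#' @param schedules The `schedule_spec` the records came from.
#' @param control List of optimizer and solver settings: `n_starts`
#'   (default 10), `maxit` (default 300), `fp_dt` (default 2 ms), `n_x`
#'   (default 121), `noise` (default 0.5), `dt` unused by FP fitting.
#' @return A `fit_result`: `family`, `params` (named list), `logL`, `k`,
#'   `AIC`, `converged`.
#' @export
fit_model <- function(family, observed, schedules, control = list()) {
  family <- match.arg(family, MODEL_FAMILIES)
  ctl <- utils::modifyList(list(n_starts = 10L, maxit = 300L, fp_dt = 2e-3,
                                n_x = 121L, noise = 0.5, gh_nodes = 7L),
                           control)
  if (ctl$n_x %% 2L == 0L) ctl$n_x <- ctl$n_x + 1L
  edges <- attr(observed, "edges")
  if (is.null(edges)) stop("'observed' lacks its bin-edge attribute",
                           call. = FALSE)
  levs <- sort(unique(observed$level))
  if (!all(schedules$level %in% levs)) {
    stop("'observed' must cover every schedule", call. = FALSE)
  }
  par_names <- family_par_names(family, length(levs))
  preps <- lapply(levs, function(l) {
    prep_fit_level(l, schedules[schedules$level == l, , drop = FALSE],
                   observed, edges, ctl)
  })
  gh <- pracma::gaussHermite(ctl$gh_nodes)
  ctl$gh <- list(x = gh$x, wn = gh$w / sqrt(pi))
  geom <- NULL
  if (family == "attractor") {
    g <- attractor_geometry(1, 4, 3)
    geom <- list(beta = 4, gamma = 3, x_commit = g$x_commit,
                 unit_max_slope = attractor_max_slope(1, 4, 3))
  }
  objective <- function(lth) {
    th <- as.list(setNames(exp(lth), par_names))
    v <- try(fit_nll(family, th, preps, ctl, geom), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e8)
    v
  }

  starts <- fit_starts(family, observed, schedules, ctl$noise,
                       ctl$n_starts)
  if (!is.null(ctl$start_permutation)) {
    starts <- starts[ctl$start_permutation]
  }
  runs <- lapply(starts, function(th0) {
    stats::nlminb(log(th0), objective,
                  control = list(iter.max = ctl$maxit,
                                 eval.max = ctl$eval_max %||%
                                   (3L * ctl$maxit)))
  })
  vals <- vapply(runs, function(r) r$objective, numeric(1))
  # Deterministic winner selection, independent of start ordering.
  ord <- order(vals, vapply(runs, function(r) sum(r$par), numeric(1)))
  best <- runs[[ord[1]]]
  if (!is.finite(best$objective) || best$objective >= 1e8) {
    stop("all optimization starts failed for family ", family,
         call. = FALSE)
  }
  th <- setNames(exp(best$par), par_names)
  k <- length(th)
  logL <- -best$objective
  structure(list(family = family, params = as.list(th), logL = logL,
                 k = k, AIC = 2 * k - 2 * logL,
                 converged = best$convergence == 0L,
                 n_starts = length(starts), control = ctl),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s> logL = %.2f, k = %d, AIC = %.2f%s\n",
              x$family, x$logL, x$k, x$AIC,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' @param fits List of `fit_result` objects.
#' @return Data frame (`family`, `k`, `logL`, `AIC`, `delta_AIC`) sorted
#'   by ascending AIC.
#' @export
compare_models <- function(fits) {
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$family, k = f$k, logL = f$logL, AIC = f$AIC)
  }))
  out <- out[order(out$AIC), ]
  out$delta_AIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}
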