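# Speed-accuracy tradeoff (SAT): modified Weibull psychometric functions
# fit to binned choice accuracy by binomial maximum likelihood.

#' Speed-accuracy tradeoff parameters
#'
#' The per-schedule SAT is `P(t) = c + (1 - c) [1 - exp(-(t - delta)/lambda)]`
#' (variant `"eq1"`); the pooled ten-bin variant adds an asymptote scale,
#' `P(t) = c + (1 - c) beta [1 - exp(-(t - delta)/lambda)]` (variant
#' `"eq4"`), whose plateau is `c + (1 - c) beta`.  For `t < delta` the
#' bracket is negative and `P` is clamped at the chance level `c`:
#' `delta` is by definition the time at which performance rises above
#' chance.
#'
#' @param delta Rise point in seconds (> 0.2).
#' @param lambda Slope constant in seconds (> 0.001).
#' @param beta Asymptote scale in `[0, 1]` (fixed at 1 for `"eq1"`).
#' @param c Chance-level probability (0.5 for two-alternative choice).
#' @param variant `"eq1"` or `"eq4"`.
#' @return A `sat_params` object.
#' @export
sat_params <- function(delta, lambda, beta = 1, c = 0.5,
                       variant = c("eq1", "eq4")) {
  variant <- match.arg(variant)
  stop_if_not_scalar(delta, "delta")
  stop_if_not_scalar(lambda, "lambda")
  stop_if_not_scalar(beta, "beta")
  if (delta <= 0.2) stop("'delta' must be > 0.2 s", call. = FALSE)
  if (lambda <= 0.001) stop("'lambda' must be > 0.001 s", call. = FALSE)
  if (beta < 0 || beta > 1) stop("'beta' must be in [0, 1]", call. = FALSE)
  if (variant == "eq1" && beta != 1) {
    stop("variant 'eq1' fixes beta = 1", call. = FALSE)
  }
  structure(list(c = c, delta = delta, lambda = lambda, beta = beta,
                 variant = variant),
            class = "sat_params")
}

#' @export
print.sat_params <- function(x, ...) {
  cat(sprintf(
    "<sat_params %s> c = %.2f, delta = %.3f s, lambda = %.3f s, beta = %.3f\n",
    x$variant, x$c, x$delta, x$lambda, x$beta))
  if (!is.null(attr(x, "logLik"))) {
    cat(sprintf("  logLik = %.3f%s\n", attr(x, "logLik"),
                if (isTRUE(attr(x, "boundary"))) " (boundary fit)" else ""))
  }
  invisible(x)
}

#' Probability of a correct response at mean response time t
#'
#' @param t Mean response time(s), seconds.
#' @param params A [sat_params()] object.
#' @return Probabilities, clamped at the chance level below `delta`.
#' @export
sat_probability <- function(t, params) {
  p <- params$c + (1 - params$c) * params$beta *
    (1 - exp(-(t - params$delta) / params$lambda))
  pmax(p, params$c)
}

#' Bin trials into speed-accuracy points
#'
#' `bin_by_schedule()` forms one bin per time-pressure schedule (level);
#' `bin_pooled()` splits all response times into `n_bins` non-overlapping
#' equal-width bins.  Each bin records the mean RT, the trial count and
#' the number correct; trials without a committed choice are excluded.
#'
#' @param records Behavior records (see [simulate_session()]).
#' @param n_bins Number of pooled RT bins (default 10).
#' @return A `binned_performance` data frame: `bin`, `mean_rt`,
#'   `n_trials`, `n_correct`, ordered by mean RT.
#' @export
bin_by_schedule <- function(records) {
  rec <- records[!is.na(records$rt) & records$choice != "none", , drop = FALSE]
  if (nrow(rec) == 0L) stop("no committed trials to bin", call. = FALSE)
  levs <- sort(unique(rec$level))
  out <- do.call(rbind, lapply(levs, function(l) {
    r <- rec[rec$level == l, ]
    data.frame(bin = l, mean_rt = mean(r$rt), n_trials = nrow(r),
               n_correct = sum(r$correct))
  }))
  out <- out[order(out$mean_rt), ]
  rownames(out) <- NULL
  class(out) <- c("binned_performance", "data.frame")
  out
}

#' @rdname bin_by_schedule
#' @export
bin_pooled <- function(records, n_bins = 10) {
  rec <- records[!is.na(records$rt) & records$choice != "none", , drop = FALSE]
  if (nrow(rec) == 0L) stop("no committed trials to bin", call. = FALSE)
  edges <- seq(min(rec$rt), max(rec$rt), length.out = n_bins + 1L)
  edges[length(edges)] <- edges[length(edges)] + 1e-9
  bin <- findInterval(rec$rt, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  keep <- sort(unique(bin))
  out <- do.call(rbind, lapply(keep, function(k) {
    r <- rec[bin == k, ]
    data.frame(bin = k, mean_rt = mean(r$rt), n_trials = nrow(r),
               n_correct = sum(r$correct))
  }))
  out <- out[order(out$mean_rt), ]
  rownames(out) <- NULL
  class(out) <- c("binned_performance", "data.frame")
  out
}

# Binomial log-likelihood of binned accuracies under a SAT curve.
sat_loglik <- function(theta, binned, variant, c_level = 0.5) {
  par <- list(c = c_level, delta = theta[1], lambda = theta[2],
              beta = if (variant == "eq4") theta[3] else 1,
              variant = variant)
  p <- sat_probability(binned$mean_rt, par)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(stats::dbinom(binned$n_correct, binned$n_trials, p, log = TRUE))
}

#' Fit a SAT function by maximum likelihood
#'
#' Maximizes the binomial log-likelihood of the per-bin correct counts
#' under the Weibull SAT curve, with the fitting constraints
#' `delta > 0.2` and `lambda > 0.001`.  Optimization is bounded
#' quasi-Newton (L-BFGS-B) from a deterministic grid of multi-starts;
#' ties are broken toward the lowest `delta`.  A fit that lands on a
#' parameter boundary or fails to converge is flagged (attribute
#' `"boundary"` / `"converged"`) rather than silently returned.
#'
#' @param binned A `binned_performance` table (at least 3 bins for
#'   `"eq1"`, 4 for `"eq4"`).
#' @param variant `"eq1"` (2 free parameters) or `"eq4"` (adds the
#'   asymptote scale `beta`).
#' @param c Chance-level probability.
#' @return A [sat_params()] object with attributes `logLik`,
#'   `converged`, `boundary`.
#' @export
fit_sat <- function(binned, variant = c("eq1", "eq4"), c = 0.5) {
  variant <- match.arg(variant)
  need <- if (variant == "eq1") 3L else 4L
  if (nrow(binned) < need) {
    stop(sprintf("need >= %d bins for variant '%s'", need, variant),
         call. = FALSE)
  }
  lower <- c(0.2, 0.001, if (variant == "eq4") 0)
  upper <- c(max(binned$mean_rt) + 2, 50, if (variant == "eq4") 1)
  deltas <- exp(seq(log(0.21), log(max(0.5, max(binned$mean_rt))),
                    length.out = 4))
  lams <- exp(seq(log(0.05), log(2), length.out = 2))
  starts <- expand.grid(delta = deltas, lambda = lams)
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    th0 <- c(starts$delta[i], starts$lambda[i],
             if (variant == "eq4") 0.8)
    stats::optim(th0, function(th) -sat_loglik(th, binned, variant, c),
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  # Best log-likelihood; near-ties resolved by the lowest delta.
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-8)
  cand <- cand[order(vapply(fits[cand], function(f) f$par[1], numeric(1)))]
  fit <- fits[[cand[1]]]
  th <- fit$par
  out <- structure(list(c = c, delta = th[1], lambda = th[2],
                        beta = if (variant == "eq4") th[3] else 1,
                        variant = variant),
                   class = "sat_params")
  attr(out, "logLik") <- -fit$value
  attr(out, "converged") <- fit$convergence == 0L
  # Boundary / degenerate fits: a parameter pinned at its constraint, or
  # a rise point at or beyond the observed RTs (no SAT signal in range).
  attr(out, "boundary") <- th[1] <= lower[1] + 1e-6 ||
    th[2] <= lower[2] + 1e-6 || th[2] >= upper[2] - 1e-6 ||
    th[1] >= max(binned$mean_rt)
  out
}
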