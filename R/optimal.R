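# Expected-gain model of the optimal response time under decaying
# reward, and the inverse problem of designing decay rates that place
# the optimum at prescribed accuracy targets.

#' Expected gain of responding at mean time t
#'
#' An ideal decision maker facing a decaying-reward schedule earns
#' `G(t, 1)` with probability `P(t)` (the SAT value) and `G(t, 0)`
#' otherwise.  With `dispersion = "delta"` the response occurs at exactly
#' the planned mean time; with `"gaussian"` the planned time is
#' normally dispersed around the mean with SD `sigma` and the gain is
#' integrated by Gauss-Legendre quadrature over +/- 4 sigma (truncated at
#' t = 0).  The model has no free parameters beyond the SAT and the
#' schedule.
#'
#' @param t Mean response time(s), seconds.
#' @param sat A [sat_params()] object.
#' @param schedule One row of an exp2/exp3 `schedule_spec`.
#' @param dispersion `"delta"` or `"gaussian"`.
#' @param sigma Response-time dispersion (seconds) for `"gaussian"`.
#' @return Expected gain in points.
#' @export
expected_gain <- function(t, sat, schedule,
                          dispersion = c("delta", "gaussian"),
                          sigma = NULL) {
  dispersion <- match.arg(dispersion)
  eg_point <- function(tt) {
    p <- sat_probability(tt, sat)
    reward_at(tt, TRUE, schedule) * p +
      reward_at(tt, FALSE, schedule) * (1 - p)
  }
  if (dispersion == "delta") {
    return(eg_point(t))
  }
  stop_if_not_scalar(sigma, "sigma")
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  gl <- pracma::gaussLegendre(61, -4, 4)
  w <- gl$w * stats::dnorm(gl$x)
  w <- w / sum(w)  # renormalize for the +/- 4 sigma truncation
  vapply(t, function(tb) {
    tt <- pmax(0, tb + sigma * gl$x)
    sum(w * eg_point(tt))
  }, numeric(1))
}

#' Optimal mean response time for a schedule
#'
#' Grid-search argmax of the expected gain over `[0, deadline]` (the
#' reward-zero time); the expected gain is piecewise smooth because of
#' reward clipping, so a grid search is used rather than derivatives.
#' Ties break toward the smaller time.
#'
#' @inheritParams expected_gain
#' @param grid_step Grid resolution in seconds (default 1 ms).
#' @return Optimal mean RT in seconds.  If the gain curve is entirely
#'   flat at zero the result is 0 with attribute `degenerate = TRUE`.
#' @export
optimal_mean_rt <- function(sat, schedule,
                            dispersion = c("delta", "gaussian"),
                            sigma = NULL, grid_step = 1e-3) {
  dispersion <- match.arg(dispersion)
  # Beyond delta + 45 lambda the SAT is flat to machine precision, so
  # the expected gain is strictly decreasing there (the decay term
  # dominates); the argmax cannot lie beyond that point.  Capping the
  # grid keeps slowly decaying schedules tractable.
  t_hi <- min(schedule$deadline[1],
              sat$delta + 45 * sat$lambda + 8 * (sigma %||% 0))
  grid <- seq(0, t_hi, by = grid_step)
  eg <- expected_gain(grid, sat, schedule, dispersion, sigma)
  if (all(eg == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  grid[which.max(eg)]
}

#' Design reward decay rates hitting prescribed accuracy targets
#'
#' Inverts the expected-gain model: for each of `n_levels` accuracy
#' targets linearly spaced between `acc_lo` and `acc_hi`, finds by
#' bisection the decay rate whose optimal mean response time lands where
#' the SAT equals the target (within `tol`).  With a plateau accuracy of
#' 0.95 and the defaults this gives targets 0.55, 0.63, 0.71, 0.79,
#' 0.87, 0.95.
#'
#' @param sat A [sat_params()] object (monotone SAT).
#' @param n_levels Number of schedules to design (default 6).
#' @param acc_lo Lowest target accuracy (default 0.55).
#' @param acc_hi Highest target accuracy; defaults to the SAT plateau
#'   `c + (1 - c) beta` (capped slightly below it for attainability).
#' @param initial_reward Reference initial reward (points).
#' @param tol Tolerance on the achieved accuracy (default 1e-3).
#' @return Decay rates in points/second at `initial_reward`, ordered
#'   from the lowest to the highest target accuracy, with attributes
#'   `targets` and `achieved`.
#' @export
design_decay_rates <- function(sat, n_levels = 6, acc_lo = 0.55,
                               acc_hi = NULL, initial_reward = 100,
                               tol = 1e-3) {
  plateau <- sat$c + (1 - sat$c) * sat$beta
  if (is.null(acc_hi)) acc_hi <- min(plateau - 5e-3, 0.95)
  if (acc_hi > plateau + 1e-12) {
    stop(sprintf("'acc_hi' (%.3f) exceeds the SAT plateau (%.3f)",
                 acc_hi, plateau), call. = FALSE)
  }
  targets <- seq(acc_lo, acc_hi, length.out = n_levels)
  t0 <- sat$delta
  achieved_p <- function(rel_rate) {
    sch <- data.frame(experiment = "exp2", level = 1L,
                      deadline = t0 + 1 / rel_rate,
                      initial_reward = initial_reward,
                      decay_rate = rel_rate * initial_reward,
                      decay_onset = t0)
    topt <- optimal_mean_rt(sat, sch, grid_step = 1e-4)
    sat_probability(topt, sat)
  }
  rates <- vapply(seq_along(targets), function(k) {
    a <- targets[k]
    if (a >= plateau - 1e-9) {
      stop(sprintf("target accuracy %.3f for level %d is at or above the SAT plateau",
                   a, k), call. = FALSE)
    }
    # Bracket: faster decay -> earlier optimum -> lower accuracy.
    lo <- 1e-3; hi <- 1
    while (achieved_p(hi) > a && hi < 1e4) hi <- hi * 2
    while (achieved_p(lo) < a && lo > 1e-8) lo <- lo / 2
    for (i in 1:80) {
      mid <- sqrt(lo * hi)
      p <- achieved_p(mid)
      if (abs(p - a) < tol / 2) return(mid)
      if (p > a) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-10) break
    }
    sqrt(lo * hi)
  }, numeric(1))
  achieved <- vapply(rates, achieved_p, numeric(1))
  structure(rates * initial_reward, targets = targets, achieved = achieved)
}
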