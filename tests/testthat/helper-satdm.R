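# Shared fixtures and small oracles used across test files.

# Empirical first-passage CDF evaluated on a time grid (fast ECDF).
ecdf_on_grid <- function(rts, times, n_total) {
  findInterval(times + 1e-12, sort(rts)) / n_total
}

# Sup-norm distance between an fp_state and a Monte-Carlo sample of the
# same model (upper and lower unconditional first-passage CDFs).
fp_mc_supnorm <- function(fp, sim) {
  n <- nrow(sim)
  up <- abs(cumsum(fp$flux_up) -
              ecdf_on_grid(sim$rt[sim$choice == 1L], fp$times, n))
  lo <- abs(cumsum(fp$flux_lo) -
              ecdf_on_grid(sim$rt[sim$choice == -1L], fp$times, n))
  max(up, lo)
}

# Closed-form two-boundary Wiener process oracles (symmetric bounds +/-a,
# drift A, diffusion c): absorption probability and mean decision time.
wiener_p_upper <- function(A, a, c) 1 / (1 + exp(-2 * A * a / c^2))
wiener_mean_dt <- function(A, a, c) (a / A) * tanh(A * a / c^2)

# A deadline-only schedule row for direct model simulation.
flat_schedule <- function(deadline, level = 1L) {
  data.frame(level = level, deadline = deadline)
}

# Generate binned SAT observations from a known curve (binomial counts).
make_sat_bins <- function(params, t_bins, n_per_bin) {
  p <- sat_probability(t_bins, params)
  data.frame(bin = seq_along(t_bins), mean_rt = t_bins,
             n_trials = n_per_bin,
             n_correct = rbinom(length(t_bins), n_per_bin, p))
}
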