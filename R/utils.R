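# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a deterministic per-trial RNG seed from a session seed and the
# (block, trial) index, so adding or reordering downstream analyses never
# perturbs the stimulus or decision noise of a given trial.  Kept below
# 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, block, trial) {
  s <- (as.double(seed) %% 2147483647) * 48271 +
    as.double(block) * 99991 + as.double(trial) * 101
  as.integer(s %% 2147483629L) + 1L
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Exact two-sided sign test on paired differences (zeros dropped).
sign_test <- function(diffs) {
  d <- diffs[!is.na(diffs) & diffs != 0]
  n <- length(d)
  if (n == 0L) return(list(n = 0L, n_positive = 0L, p_value = NA_real_))
  k <- sum(d > 0)
  list(n = n, n_positive = k,
       p_value = stats::binom.test(k, n, p = 0.5,
                                   alternative = "two.sided")$p.value)
}

# Cohen's d for paired differences.
cohens_d <- function(diffs) {
  d <- diffs[!is.na(diffs)]
  if (length(d) < 2L || stats::sd(d) == 0) return(NA_real_)
  mean(d) / stats::sd(d)
}
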