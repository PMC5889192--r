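# Behavioral statistics: deadline-proximity performance, RT matching
# across adjacent schedules, psychophysical evidence kernels, and
# conditional / sequential response-time effects.

#' Performance as a function of proximity to the deadline
#'
#' Splits response times into `n_bins` equal-width bins over
#' `[0, deadline]`, computes the probability of a correct response per
#' bin, and tests whether performance declines toward the deadline by
#' ordinary least squares of bin accuracy on bin-center RT (two-sided
#' t-test on the slope).  Empty bins are dropped with a warning.
#'
#' @param records Data frame with columns `rt` and `correct` (committed
#'   trials only; rows with `NA` rt are ignored).
#' @param deadline Available time in seconds; defaults to
#'   `records$deadline[1]`.
#' @param n_bins Number of proximity bins (default 5).
#' @return Data frame (`bin`, `t_center`, `n`, `p_correct`) with
#'   attributes `slope`, `se`, `p_value`.
#' @export
proximity_performance <- function(records, deadline = NULL, n_bins = 5) {
  rec <- records[!is.na(records$rt), , drop = FALSE]
  deadline <- deadline %||% rec$deadline[1]
  if (nrow(rec) < n_bins) {
    stop("need at least 'n_bins' trials", call. = FALSE)
  }
  edges <- seq(0, deadline, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(rec$rt, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  tab <- do.call(rbind, lapply(seq_len(n_bins), function(k) {
    r <- rec[bin == k, , drop = FALSE]
    data.frame(bin = k, t_center = (edges[k] + edges[k + 1]) / 2,
               n = nrow(r),
               p_correct = if (nrow(r)) mean(r$correct) else NA_real_)
  }))
  if (any(tab$n == 0L)) {
    warning(sprintf("%d empty proximity bin(s) dropped", sum(tab$n == 0L)))
    tab <- tab[tab$n > 0L, , drop = FALSE]
  }
  slope <- se <- p <- NA_real_
  if (nrow(tab) >= 3L) {
    fit <- stats::lm(p_correct ~ t_center, data = tab)
    sm <- suppressWarnings(summary(fit))$coefficients
    if (nrow(sm) == 2L) {
      slope <- sm[2, 1]; se <- sm[2, 2]
      if (is.na(se) || se < 1e-10) {
        # Numerically exact fit: flat accuracy has no trend to test; a
        # perfect nonzero line is unambiguous.
        se <- 0
        p <- if (abs(slope) < 1e-10) 1 else 0
      } else {
        p <- sm[2, 4]
      }
    }
  }
  structure(tab, slope = slope, se = se, p_value = p)
}

#' Match mean response times between two adjacent schedules
#'
#' Keeps, from a faster and a slower schedule, the trials whose RT lies
#' in the overlap of the two RT ranges (at or above the slower
#' schedule's minimum and at or below the faster schedule's maximum),
#' then trims by removing the smallest-RT trials from the faster set and
#' the largest-RT trials from the slower set, to the trimming depths
#' that make the two mean RTs as close to each other as possible.  The
#' optimal depth pair is found exactly (the slow-set trimmed mean is
#' monotone in its depth, so a binary search runs in `O(n log n)`); the
#' result therefore cannot be improved by any further single removal.
#' Ties are broken toward fewer removals.
#'
#' @param fast,slow Response times (numeric vectors) of the
#'   higher-pressure and lower-pressure schedule, or data frames with an
#'   `rt` column.
#' @return List with `keep_fast`, `keep_slow` (indices into the original
#'   inputs), `gap` (achieved absolute mean-RT difference), and
#'   `overlap` (`FALSE` when the RT ranges do not overlap, in which case
#'   the kept sets are empty).
#' @export
rt_match <- function(fast, slow) {
  if (is.data.frame(fast)) fast <- fast$rt
  if (is.data.frame(slow)) slow <- slow$rt
  fast_ok <- which(!is.na(fast))
  slow_ok <- which(!is.na(slow))
  lo <- suppressWarnings(min(slow[slow_ok]))
  hi <- suppressWarnings(max(fast[fast_ok]))
  kf <- fast_ok[fast[fast_ok] >= lo & fast[fast_ok] <= hi]
  ks <- slow_ok[slow[slow_ok] >= lo & slow[slow_ok] <= hi]
  if (length(kf) == 0L || length(ks) == 0L) {
    return(list(keep_fast = integer(0), keep_slow = integer(0),
                gap = NA_real_, overlap = FALSE))
  }
  kf <- kf[order(fast[kf])]
  ks <- ks[order(slow[ks])]
  fv <- fast[kf]
  sv <- slow[ks]
  nf <- length(fv)
  ns <- length(sv)
  # Mean of the fast set after dropping its i smallest (i = 0..nf-1):
  # nondecreasing in i.  Mean of the slow set after dropping its j
  # largest: nonincreasing in j.
  mean_f <- (sum(fv) - c(0, cumsum(fv))[seq_len(nf)]) / (nf:1)
  mean_s <- cumsum(sv) / seq_len(ns)         # index m = ns - j kept
  best <- c(gap = abs(mean_f[1] - mean_s[ns]), i = 0L, j = 0L)
  for (i in seq_len(nf) - 1L) {
    m <- findInterval(mean_f[i + 1L], mean_s)  # mean_s ascending in m
    for (mm in unique(pmin(pmax(c(m, m + 1L), 1L), ns))) {
      g <- abs(mean_f[i + 1L] - mean_s[mm])
      j <- ns - mm
      if (g < best["gap"] - 1e-15 ||
          (abs(g - best["gap"]) <= 1e-15 && i + j < best["i"] + best["j"])) {
        best <- c(gap = g, i = i, j = j)
      }
    }
  }
  i <- best[["i"]]; j <- best[["j"]]
  list(keep_fast = if (i > 0) kf[-seq_len(i)] else kf,
       keep_slow = if (j > 0) ks[seq_len(ns - j)] else ks,
       gap = best[["gap"]], overlap = TRUE)
}

# Per-trial predictors for the evidence kernel: proportion of red dots
# with onsets in each 200 ms window counting back from the response.
# Windows that extend before the trial start are uninformative and are
# centered at the chance proportion (predictor 0 after centering).
kernel_design <- function(records, streams, bin_width = 0.2) {
  rec <- records[!is.na(records$rt) & records$choice %in% c("red", "green"), ,
                 drop = FALSE]
  if (nrow(rec) == 0L) stop("no committed color choices", call. = FALSE)
  n_win <- max(1L, floor(max(rec$rt) / bin_width + 1e-9))
  X <- matrix(0, nrow(rec), n_win)
  for (i in seq_len(nrow(rec))) {
    s <- streams[[rec$stimulus_ref[i]]]
    rt <- rec$rt[i]
    for (j in seq_len(n_win)) {
      w_hi <- rt - (j - 1) * bin_width
      w_lo <- rt - j * bin_width
      if (w_hi <= 0) break
      sel <- s$onset > w_lo - 1e-12 & s$onset <= w_hi + 1e-12
      if (any(sel)) {
        X[i, j] <- mean(s$color[sel] == "red") - 0.5
      }
    }
  }
  list(y = as.integer(rec$choice == "red"), X = X, n_windows = n_win)
}

#' Psychophysical evidence kernel
#'
#' Logistic regression of choice (red = 1, green = 0) on the proportion
#' of red dots presented in each 200 ms window preceding the response,
#' per schedule.  Weights are normalized by the maximum absolute weight.
#' If the regression separates, a ridge-penalized fit (penalty 1e-3) is
#' substituted and flagged.
#'
#' @param records Behavior records with stimulus references.
#' @param streams Named list of stimulus streams (attribute `"streams"`
#'   of a simulated session).
#' @param bin_width Window width in seconds (default 0.200).
#' @return Data frame (`window`, `t_before_choice`, `weight`,
#'   `weight_normalized`) with attributes `scale` (the normalization) and
#'   `ridged`.
#' @export
evidence_kernel <- function(records, streams, bin_width = 0.2) {
  kd <- kernel_design(records, streams, bin_width)
  ridged <- FALSE
  fit <- suppressWarnings(
    stats::glm(kd$y ~ kd$X, family = stats::binomial()))
  w <- stats::coef(fit)[-1L]
  if (!fit$converged || any(!is.finite(w)) || any(abs(w) > 50)) {
    ridged <- TRUE
    if (requireNamespace("glmnet", quietly = TRUE)) {
      rf <- glmnet::glmnet(kd$X, kd$y, family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = FALSE)
      w <- as.numeric(rf$beta)
    } else {
      w[!is.finite(w)] <- 0
      w <- pmin(pmax(w, -50), 50)
    }
  }
  scale <- max(abs(w))
  out <- data.frame(window = seq_along(w),
                    t_before_choice = (seq_along(w) - 0.5) * bin_width,
                    weight = as.numeric(w),
                    weight_normalized = if (scale > 0) as.numeric(w) / scale
                                        else as.numeric(w))
  structure(out, scale = scale, ridged = ridged)
}

#' Exponential decay constant of an evidence kernel
#'
#' Fits `w ~ a exp(-t / tau)` to the raw kernel weights by least squares
#' (the amplitude is profiled out analytically; the decay constant is
#' found on a log-spaced grid with local refinement).  Fitting on the
#' raw scale keeps the small, noisy tail weights from biasing the decay
#' estimate, unlike a log-linear fit.  Returns `Inf` when the best fit
#' is flat over the kernel's span (no decay resolvable).
#'
#' @param kernel Output of [evidence_kernel()].
#' @param tau_max Largest decay constant considered resolvable
#'   (default 3 x the kernel span); slower kernels return `Inf`.
#' @return Estimated decay constant in seconds.
#' @export
kernel_decay_constant <- function(kernel, tau_max = NULL) {
  w <- kernel$weight
  t <- kernel$t_before_choice
  if (length(w) < 3L || max(abs(w)) == 0) return(NA_real_)
  span <- max(t) - min(t)
  tau_max <- tau_max %||% (3 * span)
  rss <- function(tau) {
    phi <- exp(-t / tau)
    a <- sum(w * phi) / sum(phi * phi)
    sum((w - a * phi)^2)
  }
  taus <- exp(seq(log(0.02), log(tau_max), length.out = 400))
  vals <- vapply(taus, rss, numeric(1))
  i <- which.min(vals)
  if (i >= length(taus) - 1L) return(Inf)
  # Golden-section refinement around the grid minimum.
  lo <- taus[max(i - 1L, 1L)]; hi <- taus[min(i + 1L, length(taus))]
  opt <- stats::optimize(rss, c(lo, hi))
  opt$minimum
}

#' Conditional response-time statistics
#'
#' Per-schedule differences in (normalized) response time between
#' conditions, with an exact two-sided sign test across subjects and
#' Cohen's d.  Conditions:
#' \describe{
#'   \item{correct_vs_error}{mean normalized RT on correct minus
#'     incorrect trials (normalized RT = RT / available time).}
#'   \item{prev_outcome}{median RT after correct minus after incorrect
#'     trials (within block, by trial order).}
#'   \item{prev_schedule}{median RT after a lower-pressure (higher
#'     level) minus after a higher-pressure previous trial.}
#' }
#'
#' @param records Behavior records for one or more subjects
#'   (`subject_id` column).
#' @param condition One of `"correct_vs_error"`, `"prev_outcome"`,
#'   `"prev_schedule"`.
#' @param normalize Divide RTs by the trial's available time (default
#'   `TRUE` for `correct_vs_error`, `FALSE` otherwise).
#' @return Data frame with one row per schedule: mean difference across
#'   subjects, sign-test p-value, Cohen's d, and n subjects.  With a
#'   single subject the sign test is skipped (`NA`).
#' @export
conditional_rt_stats <- function(records,
                                 condition = c("correct_vs_error",
                                               "prev_outcome",
                                               "prev_schedule"),
                                 normalize = NULL) {
  condition <- match.arg(condition)
  normalize <- normalize %||% (condition == "correct_vs_error")
  rec <- records[!is.na(records$rt) & records$choice != "none", ,
                 drop = FALSE]
  rec$nrt <- if (normalize) rec$rt / rec$deadline else rec$rt
  subjects <- unique(rec$subject_id)
  levels_all <- sort(unique(rec$level))

  subj_diff <- function(r, level) {
    if (condition == "correct_vs_error") {
      a <- r$nrt[r$level == level & r$correct]
      b <- r$nrt[r$level == level & !r$correct]
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      return(mean(a) - mean(b))
    }
    # Sequential conditions: pair each trial with its predecessor in
    # trial order within block.
    r <- r[order(r$block_index, r$trial_index), , drop = FALSE]
    prev_same_block <- c(FALSE, diff(r$block_index) == 0)
    cur <- which(prev_same_block & r$level == level)
    if (length(cur) == 0L) return(NA_real_)
    prev <- cur - 1L
    if (condition == "prev_outcome") {
      a <- r$nrt[cur[r$correct[prev]]]
      b <- r$nrt[cur[!r$correct[prev]]]
    } else {
      a <- r$nrt[cur[r$level[prev] > level]]   # after lower pressure
      b <- r$nrt[cur[r$level[prev] < level]]   # after higher pressure
    }
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    stats::median(a) - stats::median(b)
  }

  out <- do.call(rbind, lapply(levels_all, function(l) {
    diffs <- vapply(subjects, function(s) {
      subj_diff(rec[rec$subject_id == s, , drop = FALSE], l)
    }, numeric(1))
    st <- if (length(subjects) > 1L) sign_test(diffs) else
      list(p_value = NA_real_)
    data.frame(level = l, mean_diff = mean(diffs, na.rm = TRUE),
               p_value = st$p_value, cohens_d = cohens_d(diffs),
               n_subjects = sum(!is.na(diffs)))
  }))
  rownames(out) <- NULL
  out
}
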