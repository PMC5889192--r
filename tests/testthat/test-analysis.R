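test_that("proximity bins match a brute-force recount and flat data give no slope", {
  set.seed(60)
  n <- 500
  rec <- data.frame(rt = runif(n, 0, 2.8), correct = runif(n) < 0.75)
  pp <- proximity_performance(rec, deadline = 2.8)
  edges <- seq(0, 2.8, length.out = 6)
  for (k in 1:5) {
    inbin <- rec$rt > edges[k] & rec$rt <= edges[k + 1] |
      (k == 1 & rec$rt <= edges[2])
    expect_equal(pp$n[pp$bin == k], sum(inbin))
    expect_equal(pp$p_correct[pp$bin == k], mean(rec$correct[inbin]))
  }
  # Exactly constant accuracy: zero slope, p = 1.
  rec2 <- data.frame(rt = rep(seq(0.2, 2.6, length.out = 10), each = 4),
                     correct = rep(c(TRUE, TRUE, TRUE, FALSE), 10))
  pp2 <- proximity_performance(rec2, deadline = 2.8)
  expect_equal(attr(pp2, "slope"), 0)
  expect_equal(attr(pp2, "p_value"), 1)
})

test_that("a planted accuracy decline is detected by the slope test", {
  set.seed(61)
  n <- 1000
  rt <- runif(n, 0, 2.8)
  p <- 0.85 - 0.1 * rt  # linearly decreasing accuracy
  rec <- data.frame(rt = rt, correct = runif(n) < p)
  pp <- proximity_performance(rec, deadline = 2.8)
  expect_lt(attr(pp, "slope"), 0)
  expect_lt(attr(pp, "p_value"), 0.05)
})

test_that("RT matching reproduces the hand-traceable toy cases", {
  # Identical multisets: full overlap, zero gap, nothing removed.
  m0 <- rt_match(c(0.5, 0.8, 1.1), c(0.5, 0.8, 1.1))
  expect_equal(m0$gap, 0)
  expect_equal(length(m0$keep_fast), 3L)
  expect_equal(length(m0$keep_slow), 3L)
  # Overlap filter keeps {0.6} and {0.6}.
  m1 <- rt_match(c(0.5, 0.6), c(0.6, 0.9))
  expect_equal(m1$gap, 0)
  expect_equal(m1$keep_fast, 2L)
  expect_equal(m1$keep_slow, 1L)
  # Disjoint ranges: flagged empty result.
  m2 <- rt_match(c(0.2, 0.3), c(1.5, 2.0))
  expect_false(m2$overlap)
  expect_length(m2$keep_fast, 0L)
})

test_that("RT matching attains the exhaustive prefix-removal optimum", {
  # Brute-force enumeration over every trimming-depth pair.
  exhaustive_gap <- function(fast, slow) {
    fast <- sort(fast); slow <- sort(slow)
    lo <- min(slow); hi <- max(fast)
    f <- fast[fast >= lo & fast <= hi]
    s <- slow[slow >= lo & slow <= hi]
    if (!length(f) || !length(s)) return(NA_real_)
    best <- Inf
    for (i in 0:(length(f) - 1L)) {       # drop i smallest fast
      for (j in 0:(length(s) - 1L)) {     # drop j largest slow
        g <- abs(mean(f[(i + 1):length(f)]) -
                   mean(s[seq_len(length(s) - j)]))
        best <- min(best, g)
      }
    }
    best
  }
  set.seed(62)
  for (rep in 1:20) {
    fast <- runif(sample(5:12, 1), 0.2, 1.6)
    slow <- runif(sample(5:12, 1), 0.6, 2.6)
    m <- rt_match(fast, slow)
    opt <- exhaustive_gap(fast, slow)
    if (is.na(opt)) {
      expect_false(m$overlap)
    } else {
      expect_equal(m$gap, opt, tolerance = 1e-9)
      # Local optimality: no further single removal can improve the gap.
      fv <- sort(fast[m$keep_fast]); sv <- sort(slow[m$keep_slow])
      if (length(fv) > 1L) {
        expect_gte(abs(mean(fv[-1L]) - mean(sv)), m$gap - 1e-12)
      }
      if (length(sv) > 1L) {
        expect_gte(abs(mean(fv) - mean(sv[-length(sv)])), m$gap - 1e-12)
      }
    }
  }
})

test_that("the sign test matches the exact binomial computation", {
  d <- c(rep(1, 15), rep(-1, 4))
  st <- satdm:::sign_test(d)
  expect_equal(st$p_value, 2 * pbinom(4, 19, 0.5), tolerance = 1e-12)
  expect_equal(st$n_positive, 15L)
})

test_that("conditional RT statistics find planted effects and not phantom ones", {
  make_subject <- function(id, shift) {
    n <- 240
    correct <- runif(n) < 0.7
    prev_correct <- c(FALSE, correct[-n])
    rt <- 1.4 + shift * prev_correct + rnorm(n, 0, 0.25)
    data.frame(subject_id = id, block_index = rep(1:4, each = 60),
               trial_index = 1:n, level = 3L, deadline = 2.1,
               choice = "red", correct = correct, rt = pmax(0.1, rt))
  }
  # Symmetric data: no effect.
  set.seed(63)
  rec0 <- do.call(rbind, lapply(1:12, make_subject, shift = 0))
  s0 <- conditional_rt_stats(rec0, "prev_outcome")
  expect_gt(s0$p_value, 0.05)
  # Planted +50 ms slowing after correct trials across 20 subjects.
  hits <- vapply(1:5, function(r) {
    rec <- do.call(rbind, lapply(1:20, function(i)
      make_subject(i, shift = 0.05)))
    s <- conditional_rt_stats(rec, "prev_outcome")
    s$p_value < 0.05 & s$mean_diff > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # Single subject: difference reported, sign test skipped.
  s1 <- conditional_rt_stats(make_subject(1, 0.3), "prev_outcome")
  expect_true(is.na(s1$p_value))
  expect_gt(s1$mean_diff, 0)
})

test_that("a planted previous-schedule effect is detected", {
  set.seed(67)
  mk <- function(id) {
    n <- 360
    level <- sample(1:6, n, replace = TRUE)
    prev <- c(3L, level[-n])
    # Slower after lower-pressure (higher-level) predecessors.
    rt <- 1.0 + 0.08 * (prev > 3) - 0.08 * (prev < 3) + rnorm(n, 0, 0.2)
    data.frame(subject_id = id, block_index = rep(1:10, each = 36),
               trial_index = 1:n, level = level, deadline = 2.8,
               choice = "red", correct = runif(n) < 0.75,
               rt = pmax(0.1, rt))
  }
  rec <- do.call(rbind, lapply(1:15, mk))
  s <- conditional_rt_stats(rec, "prev_schedule")
  s3 <- s[s$level == 3, ]
  expect_gt(s3$mean_diff, 0)
  expect_lt(s3$p_value, 0.05)
})

test_that("stimulus streams round-trip through the sidecar CSV", {
  m <- model_spec("basic", A = 0.5, noise = 0.5, bound = 0.3)
  rec <- simulate_session(m, "exp1", seed = 4L, keep_streams = TRUE)
  streams <- attr(rec, "streams")
  f <- tempfile(fileext = ".csv")
  write_streams(streams[1:5], f)
  back <- read_streams(f)
  expect_setequal(names(back), names(streams)[1:5])
  id <- names(streams)[1]
  expect_equal(back[[id]]$onset, streams[[id]]$onset)
  expect_equal(back[[id]]$color, streams[[id]]$color)
  unlink(f)
})

test_that("correct-vs-error differences use normalized RT", {
  set.seed(64)
  n <- 400
  mk <- function(id) {
    correct <- runif(n) < 0.7
    data.frame(subject_id = id, block_index = 1L, trial_index = 1:n,
               level = rep(c(1L, 6L), each = n / 2),
               deadline = rep(c(0.7, 4.2), each = n / 2), choice = "red",
               correct = correct,
               rt = rep(c(0.5, 3.0), each = n / 2) - 0.1 * correct)
  }
  rec <- do.call(rbind, lapply(1:6, mk))
  s <- conditional_rt_stats(rec, "correct_vs_error")
  # Correct responses are faster: negative normalized difference, and
  # normalization makes the two schedules comparable in magnitude.
  expect_true(all(s$mean_diff < 0))
  expect_equal(s$mean_diff[s$level == 1] / s$mean_diff[s$level == 6],
               (0.1 / 0.7) / (0.1 / 4.2), tolerance = 0.15)
})

test_that("stimulus-independent choices give near-zero kernel weights", {
  set.seed(65)
  n <- 3000
  K <- floor(1.4 / 0.05) + 1
  onsets <- (seq_len(K) - 1) * 0.05
  streams <- lapply(seq_len(n), function(i)
    list(onset = onsets,
         color = ifelse(runif(K) < 0.57, "red", "green")))
  names(streams) <- sprintf("t%04d", seq_len(n))
  rec <- data.frame(level = 2L, deadline = 1.4, rt = 1.4,
                    choice = sample(c("red", "green"), n, replace = TRUE),
                    stimulus_ref = names(streams),
                    stringsAsFactors = FALSE)
  kern <- evidence_kernel(rec, streams)
  expect_equal(nrow(kern), 7L)  # floor(1.4 / 0.2)
  expect_lt(max(abs(kern$weight)), 0.5)
})

test_that("pooled psychometric rises monotonically for the integrator and plateaus for leak", {
  sch <- flat_schedule(4.2)
  set.seed(66)
  basic <- simulate_trials(model_spec("basic", A = 0.15, noise = 0.3,
                                      bound = 0.8), sch, 2e4)
  leak <- simulate_trials(model_spec("leak", A = 0.15, noise = 0.3,
                                     bound = 0.8, tau = 0.3), sch, 2e4)
  tab <- function(sim) {
    rec <- data.frame(level = 1L, rt = sim$rt,
                      correct = sim$choice == 1L,
                      choice = ifelse(sim$crossed, "red", "none"))
    bin_pooled(rec[sim$crossed, ], 10)
  }
  tb <- tab(basic); tl <- tab(leak)
  # No significant decrease anywhere for the perfect integrator.
  se_pair <- function(t, i, j) {
    3 * sqrt(0.25 / t$n_trials[i] + 0.25 / t$n_trials[j])
  }
  pb <- tb$n_correct / tb$n_trials
  for (i in seq_len(nrow(tb) - 1L)) {
    expect_gt(pb[i + 1] - pb[i], -se_pair(tb, i, i + 1))
  }
  # Leak: the last two bins are statistically indistinguishable.
  pl <- tl$n_correct / tl$n_trials
  k <- nrow(tl)
  expect_lt(abs(pl[k] - pl[k - 1]), se_pair(tl, k - 1, k))
})
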