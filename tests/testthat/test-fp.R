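test_that("density propagation conserves mass at every step", {
  m <- model_spec("collapsing", A = 0.3, noise = 0.5, bound = 0.8,
                  collapse = 1.5)
  fp <- fp_propagate(m, flat_schedule(2.8), dt = 1e-3, n_x = 301)
  cons <- abs(1 - (fp$mass_remaining + cumsum(fp$flux_up + fp$flux_lo)))
  expect_lt(max(cons), 1e-6)
  expect_true(all(fp$p_final >= 0))
})

test_that("zero drift with symmetric bounds gives identical flux series", {
  m <- model_spec("basic", A = 0, noise = 0.6, bound = 0.7)
  fp <- fp_propagate(m, flat_schedule(2.1))
  expect_lt(max(abs(fp$flux_up - fp$flux_lo)), 1e-9)
})

test_that("basic-DDM absorption matches the closed-form Wiener law", {
  m <- model_spec("basic", A = 0.8, noise = 1, bound = 1.2)
  fp <- fp_propagate(m, flat_schedule(20))
  expect_lt(abs(sum(fp$flux_up) - wiener_p_upper(0.8, 1.2, 1)), 1e-3)
  tmid <- fp$times - fp$dt / 2
  ft <- fp$flux_up + fp$flux_lo
  mean_dt <- sum(tmid * ft) / sum(ft)
  expect_lt(abs(mean_dt / wiener_mean_dt(0.8, 1.2, 1) - 1), 0.01)
})

test_that("binned summaries of a uniform flux match the uniform moments", {
  dt <- 1e-4
  n <- 10000L
  fake <- structure(list(times = seq_len(n) * dt,
                         flux_up = rep(0.4 / n, n),
                         flux_lo = rep(0.4 / n, n),
                         mass_remaining = rep(0.2, n), dt = dt,
                         deadline = 1), class = "fp_state")
  ps <- predict_summaries(fake, bin_edges = seq(0, 1, by = 0.2))
  expect_equal(ps$p_correct, rep(0.5, 5))
  expect_equal(ps$mean_rt, seq(0.1, 0.9, by = 0.2), tolerance = 1e-6)
  expect_equal(ps$sd_rt, rep(0.2 / sqrt(12), 5), tolerance = 1e-6)
  # All mass in the first bin flags the rest.
  fake2 <- fake
  fake2$flux_up <- c(rep(0.5 / 1000, 1000), rep(0, 9000))
  fake2$flux_lo <- fake2$flux_up
  ps2 <- predict_summaries(fake2, bin_edges = seq(0, 1, by = 0.2))
  expect_false(ps2$flagged[1])
  expect_true(all(ps2$flagged[-1]))
})

test_that("predicted summaries match Monte-Carlo summaries of the same model", {
  m <- model_spec("basic", A = 0.3, noise = 0.5, bound = 0.6)
  sch <- flat_schedule(2.8)
  set.seed(50)
  sim <- simulate_trials(m, sch, 4e4)
  rec <- data.frame(level = 1L, rt = sim$rt,
                    correct = sim$choice == 1L)[sim$crossed, ]
  obs <- summarize_records(rec)
  fp <- fp_propagate(m, sch)
  pred <- predict_summaries(fp, bin_edges = attr(obs, "edges")[["1"]])
  expect_equal(pred$p_correct, obs$p_correct, tolerance = 0.02)
  expect_equal(pred$mean_rt, obs$mean_rt, tolerance = 0.02)
  expect_equal(pred$sd_rt, obs$sd_rt, tolerance = 0.06)
})

test_that("the summary likelihood behaves as a Gaussian quadratic form", {
  obs <- data.frame(level = 1L, bin = 1:2, p_correct = c(0.7, 0.8),
                    mean_rt = c(0.5, 1.2), sd_rt = c(0.2, 0.3),
                    n = c(60, 60))
  # Perfect prediction is the maximum.
  ll0 <- summary_loglik(obs, obs)
  pred <- obs
  pred$mean_rt[1] <- 0.55
  ll1 <- summary_loglik(pred, obs)
  expect_lt(ll1, ll0)
  pred2 <- obs
  pred2$mean_rt[1] <- 0.60   # doubled gap
  ll2 <- summary_loglik(pred2, obs)
  expect_equal(ll0 - ll2, 4 * (ll0 - ll1), tolerance = 1e-9)
  # Independent spreadsheet-style oracle for the full table.
  oracle <- 0
  for (i in 1:2) {
    p <- obs$p_correct[i]
    oracle <- oracle +
      dnorm(p, pred$p_correct[i], sqrt(p * (1 - p) / obs$n[i]),
            log = TRUE) +
      dnorm(obs$mean_rt[i], pred$mean_rt[i], obs$sd_rt[i] / sqrt(obs$n[i]),
            log = TRUE) +
      dnorm(obs$sd_rt[i], pred$sd_rt[i],
            obs$sd_rt[i] / sqrt(2 * obs$n[i]), log = TRUE)
  }
  expect_equal(ll1, oracle, tolerance = 1e-9)
  expect_error(summary_loglik(pred[1, ], obs), "different structure")
})

test_that("AIC follows its identity and ranking is ascending", {
  expect_equal(2 * 3 - 2 * (-10), 26)
  fits <- list(structure(list(family = "basic", k = 7, logL = -40,
                              AIC = 2 * 7 + 80), class = "fit_result"),
               structure(list(family = "leak", k = 8, logL = -30,
                              AIC = 2 * 8 + 60), class = "fit_result"))
  cmp <- compare_models(fits)
  expect_equal(cmp$family, c("leak", "basic"))
  expect_equal(cmp$delta_AIC, c(0, 18))
  expect_equal(cmp$AIC, 2 * cmp$k - 2 * cmp$logL)
})

test_that("model fitting recovers the generator and ignores start order", {
  # Two-schedule scaled-down fit of the basic DDM to its own FP
  # predictions (large nominal n so the summary likelihood is sharp).
  sch <- make_schedules("exp1")[c(2, 5), ]
  truth <- model_spec("basic", A = 0.35, noise = 0.5,
                      bound = c(0.45, 0.7))
  obs <- do.call(rbind, lapply(1:2, function(i) {
    fp <- fp_propagate(truth, transform(sch[i, ], level = i))
    ps <- predict_summaries(fp, n_bins = 5)
    data.frame(level = i, bin = ps$bin, p_correct = ps$p_correct,
               mean_rt = ps$mean_rt, sd_rt = ps$sd_rt, n = 2000)
  }))
  edges <- list()
  for (i in 1:2) {
    fp <- fp_propagate(truth, transform(sch[i, ], level = i))
    cdf <- cumsum(fp$flux_up + fp$flux_lo)
    cdf <- cdf / cdf[length(cdf)]
    idx <- vapply(seq(0.2, 0.8, by = 0.2),
                  function(p) which(cdf >= p)[1], integer(1))
    edges[[as.character(i)]] <- c(0, fp$times[idx], fp$deadline)
  }
  attr(obs, "edges") <- edges
  sch2 <- sch
  sch2$level <- 1:2
  ctl <- list(n_starts = 3L, maxit = 150L, fp_dt = 2e-3, n_x = 121L)
  fit <- fit_model("basic", obs, sch2, control = ctl)
  expect_equal(fit$k, 3)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logL)
  expect_equal(fit$params$A, 0.35, tolerance = 0.05)
  expect_equal(fit$params$B1, 0.45, tolerance = 0.05)
  expect_equal(fit$params$B2, 0.70, tolerance = 0.05)
  ctl2 <- c(ctl, list(start_permutation = c(3L, 1L, 2L)))
  fit2 <- fit_model("basic", obs, sch2, control = ctl2)
  expect_equal(unlist(fit2$params), unlist(fit$params), tolerance = 1e-6)
  expect_equal(fit2$logL, fit$logL, tolerance = 1e-6)
})
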