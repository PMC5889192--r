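test_that("schedule construction follows the experimental designs", {
  s1 <- make_schedules("exp1")
  expect_equal(s1$deadline, 0.7 * (1:6))
  expect_equal(s1$deadline[5], 3.5)
  expect_equal(s1$level, 1:6)
  sp <- make_schedules("pretest")
  expect_equal(sp$deadline, c(0.7, 2.1, 3.5))
  expect_error(make_schedules("exp2"), "decay_rates")
  expect_error(make_schedules("exp2", decay_rates = c(10, 20, 30, 40, 50)),
               "6 positive rates")
  s2 <- make_schedules("exp2", decay_rates = c(100, 80, 60, 40, 30, 20),
                       decay_onset = 0.4)
  expect_equal(s2$decay_rate, c(100, 80, 60, 40, 30, 20))
  # Reward-zero time grows as the decay slows.
  expect_true(all(diff(s2$deadline) > 0))
  expect_equal(s2$deadline, 0.4 + 100 / s2$decay_rate)
})

test_that("stimulus streams obey the sampling law", {
  expect_error(generate_stimulus(1.0, 1), "0.5, 1")
  expect_error(generate_stimulus(0.5, 1), "0.5, 1")
  set.seed(1)
  s <- generate_stimulus(0.57, 4.2, dominant_color = "red")
  expect_length(s$onset, 85)  # floor(4.2/0.05) + 1
  expect_equal(s$onset[1], 0)
  s2 <- generate_stimulus(0.57, 0.7)
  expect_length(s2$onset, 15)
  # Pooled dominant fraction within 3 binomial SEs of q over many streams.
  set.seed(7)
  n_streams <- 2000L
  draws <- replicate(n_streams, {
    st <- generate_stimulus(0.57, 0.7, dominant_color = "red")
    c(sum(st$is_dominant), length(st$is_dominant))
  })
  frac <- sum(draws[1, ]) / sum(draws[2, ])
  se <- sqrt(0.57 * 0.43 / sum(draws[2, ]))
  expect_lt(abs(frac - 0.57), 3 * se)
})

test_that("dominant color is re-randomized across trials", {
  set.seed(11)
  doms <- replicate(400, generate_stimulus(0.57, 0.7)$dominant_color)
  p_red <- mean(doms == "red")
  expect_gt(p_red, 0.4)
  expect_lt(p_red, 0.6)
})

test_that("visible dot counts grow to 40 and hold there", {
  set.seed(2)
  s <- generate_stimulus(0.57, 4.2)
  expect_error(visible_counts(s, -0.1), "nonnegative")
  vc0 <- visible_counts(s, 0)
  expect_equal(vc0$n_dominant + vc0$n_other, 1)  # first dot at onset
  vc1 <- visible_counts(s, 1.0)
  expect_equal(vc1$n_dominant + vc1$n_other, 21)
  # From persistence (2 s) on, the count is pinned at 40.
  for (t in c(2.5, 3.0, 4.2)) {
    vc <- visible_counts(s, t)
    expect_equal(vc$n_dominant + vc$n_other, 40)
  }
})

test_that("decaying reward follows the clipped linear rule", {
  sch <- make_schedules("exp2", decay_rates = c(100, 80, 60, 40, 30, 20),
                        decay_onset = 0.5)
  s <- sch[sch$decay_rate == 20, ]
  expect_error(reward_at(1, TRUE, make_schedules("exp1")[1, ]),
               "exp2/exp3")
  expect_equal(reward_at(0, TRUE, s), 100)
  # Worked case: G_s = 50, b = 20/s at 100 scales to 10/s at 50.
  expect_equal(reward_at(1.5, TRUE, s, initial_reward = 50),
               50 - 10 * 1.0)
  # Long after the zero time both gain and loss sit at 0.
  expect_equal(reward_at(100, TRUE, s), 0)
  expect_equal(reward_at(100, FALSE, s), 0)
  # Loss mirrors the gain.
  expect_equal(reward_at(2.5, FALSE, s), -(reward_at(2.5, TRUE, s)))
})

test_that("simulated sessions have the designed trial counts", {
  m <- model_spec("basic", A = 0.5, noise = 0.5, bound = 0.3)
  rec1 <- simulate_session(m, "exp1", seed = 5L)
  expect_equal(nrow(rec1), 360)
  counts <- table(rec1$block_index, rec1$level)
  expect_true(all(counts == 6))  # each schedule 6x per block
  recp <- simulate_session(m, "pretest", seed = 5L)
  expect_equal(nrow(recp), 324)
  expect_equal(length(unique(recp$block_index)), 9)
  expect_true(all(!is.na(recp$rt) | recp$choice == "none"))
  expect_true(all(rec1$rt[!is.na(rec1$rt)] <=
                    rec1$deadline[!is.na(rec1$rt)]))
})

test_that("exp2 sessions balance reward-by-rate cells and pay Eq-2 rewards", {
  m <- model_spec("basic", A = 0.5, noise = 0.5, bound = 0.3)
  sch <- make_schedules("exp2", decay_rates = c(100, 80, 60, 40, 30, 20),
                        decay_onset = 0.4)
  rec <- simulate_session(m, "exp2", schedules = sch, seed = 3L)
  expect_equal(nrow(rec), 360)
  cells <- table(rec$block_index, rec$level, rec$initial_reward)
  expect_true(all(cells == 3))  # each (G_s, b) pair 3x per block
  ok <- !is.na(rec$rt) & rec$correct
  i <- which(ok)[1]
  expect_equal(rec$reward_outcome[i],
               reward_at(rec$rt[i], TRUE, sch[sch$level == rec$level[i], ],
                         initial_reward = rec$initial_reward[i]))
})

test_that("exp3 gambles pay according to the SAT win probability", {
  m <- model_spec("basic", A = 0.5, noise = 0.5, bound = 0.3)
  sat <- sat_params(delta = 0.3, lambda = 0.5)
  sch <- make_schedules("exp3", decay_rates = c(100, 80, 60, 40, 30, 20),
                        decay_onset = 0.3)
  rec <- simulate_session(m, "exp3", schedules = sch, sat = sat,
                          seed = 9L)
  expect_equal(nrow(rec), 360)
  expect_true(all(rec$choice %in% c("accept", "none")))
  acc <- rec[rec$choice == "accept", ]
  # Wins pay the decayed stake, losses its mirror.
  for (i in head(which(acc$correct), 2)) {
    s <- sch[sch$level == acc$level[i], ]
    expect_equal(acc$reward_outcome[i],
                 reward_at(acc$rt[i], TRUE, s,
                           initial_reward = acc$initial_reward[i]))
  }
  # Empirical win rate tracks the SAT at the accept times.
  p_exp <- mean(sat_probability(acc$rt, sat))
  se <- sqrt(p_exp * (1 - p_exp) / nrow(acc))
  expect_lt(abs(mean(acc$correct) - p_exp), 4 * se)
})

test_that("sessions are byte-identical under the same seed", {
  m <- model_spec("basic", A = 0.5, noise = 0.5, bound = 0.3)
  a <- simulate_session(m, "exp1", seed = 77L)
  b <- simulate_session(m, "exp1", seed = 77L)
  attr(a, "streams") <- attr(b, "streams") <- NULL
  expect_identical(a, b)
  d <- simulate_session(m, "exp1", seed = 78L)
  expect_false(identical(a$rt, d$rt))
})

test_that("trial tables round-trip through CSV", {
  m <- model_spec("basic", A = 0.5, noise = 0.5, bound = 0.3)
  rec <- simulate_session(m, "pretest", seed = 2L)
  f <- tempfile(fileext = ".csv")
  write_trials(rec, f)
  back <- read_trials(f)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$rt, rec$rt)
  expect_equal(back$choice, rec$choice)
  unlink(f)
})
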