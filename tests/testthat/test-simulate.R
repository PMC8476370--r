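noise_free_params <- function(...) {
  participant_params(press_noise_sd = 0, press_error_prob = 0, ...)
}

test_that("the degenerate RT model returns the base press RT everywhere", {
  p <- noise_free_params(base_press_rt = 0.4, general_gain = 0, seq_gain = 0,
                         switch_cost = 0)
  rt <- simulate_press_rt(p, trial_index = 0:239, exposures_of_sequence = 0:239,
                          is_switch = rep(c(TRUE, FALSE), 120))
  expect_equal(rt, rep(0.4, 240))
})

test_that("noise-free RTs are non-increasing in trial index and exposures", {
  p <- noise_free_params(switch_cost = 0)
  rt_t <- simulate_press_rt(p, trial_index = 0:239,
                            exposures_of_sequence = rep(0, 240))
  expect_true(all(diff(rt_t) <= 0))
  rt_e <- simulate_press_rt(p, trial_index = rep(0, 80),
                            exposures_of_sequence = 0:79)
  expect_true(all(diff(rt_e) <= 0))
  expect_true(all(rt_t >= p$rt_floor))
})

test_that("simulated sequence RTs match the closed-form model expectation", {
  # noise-free blocked participant: rt_sum must equal the analytic
  # 8 * (base + G exp(-t/tau_g) + S exp(-e/tau_s) + switch) exactly
  a <- make_assignment("P1", "blocked", "blocked")
  d <- build_experiment_design("retention", 1, seed = 7)
  p1 <- d$participants[[1]]
  pars <- noise_free_params(base_press_rt = 0.3, general_gain = 0.1,
                            general_tau = 50, seq_gain = 0.08, seq_tau = 20,
                            switch_cost = 0.05, consolidation_offset = 0.02)
  sim <- simulate_participant(p1$assignment, p1$schedules, p1$sequences,
                              pars, seed = 3)
  srts <- sequence_rts(sim$trials)
  labs1 <- p1$schedules$day1$trials
  labs2 <- p1$schedules$day2$trials
  expo <- function(labs, prior) {
    stats::ave(rep(1, length(labs)), labs, FUN = cumsum) - 1 + prior
  }
  expected <- function(day, labs, prior) {
    t_idx <- (day - 1) * 240 + seq_along(labs) - 1
    sw <- c(FALSE, labs[-1] != labs[-length(labs)])
    8 * (0.3 + (day - 1) * 0.02 + 0.1 * exp(-t_idx / 50) +
           0.08 * exp(-expo(labs, prior) / 20) + 0.05 * sw)
  }
  expect_equal(srts$rt_sum[srts$day == 1], expected(1, labs1, 0),
               tolerance = 1e-12)
  expect_equal(srts$rt_sum[srts$day == 2], expected(2, labs2, 80),
               tolerance = 1e-12)
  # with noise, switch costs and the per-sequence term off, the noise-free
  # Day-1 series is strictly decreasing (pure nonspecific learning):
  # Mann-Kendall tau = -1 downstream. The sequence-specific term restarts
  # at each block/new label, so it is excluded from the monotonicity claim.
  pars2 <- noise_free_params(switch_cost = 0, seq_gain = 0)
  sim2 <- simulate_participant(p1$assignment, p1$schedules, p1$sequences,
                               pars2, seed = 4)
  s2 <- sequence_rts(sim2$trials)
  mk <- mann_kendall(s2$rt_sum[s2$day == 1])
  expect_equal(unname(mk$statistic["tau"]), -1)
})

test_that("error-free logs are perfectly accurate and perfect recall scores 1", {
  d <- build_experiment_design("retention", 1, seed = 8)
  p1 <- d$participants[[1]]
  sim <- simulate_participant(p1$assignment, p1$schedules, p1$sequences,
                              noise_free_params(explicit_k = 8), seed = 5)
  expect_true(all(sim$trials$correct))
  acc <- press_accuracy(sim$trials)
  expect_equal(acc$accuracy, c(100, 100))
  sc <- score_recall(sim$recall, p1$sequences[c("A", "B", "C")])
  expect_equal(sc$mean_score, 1.0)
  expect_equal(sc$items_per_sequence, 8)
  expect_identical(sc$learner_class, "explicit")
})

test_that("per-press accuracy tracks 1 - press_error_prob within binomial error", {
  d <- build_experiment_design("retention", 2, seed = 9)
  acc <- numeric(0)
  set.seed(99)
  for (p in d$participants) {
    sim <- simulate_participant(p$assignment, p$schedules, p$sequences,
                                participant_params(press_error_prob = 0.05))
    acc <- c(acc, press_accuracy(sim$trials)$accuracy)
  }
  n_press <- 1920
  se <- 100 * sqrt(0.05 * 0.95 / n_press)
  expect_true(all(abs(acc - 95) <= 4 * se))
})

test_that("the paper-like preset makes interleaved training less accurate on Day 1", {
  co <- simulate_cohort("retention", 13, preset = "paper-like", seed = 101)
  acc <- press_accuracy(co$trials, day = 1)
  tr <- vapply(co$design$participants,
               function(p) p$assignment$training_condition, "")
  names(tr) <- vapply(co$design$participants,
                      function(p) p$assignment$participant_id, "")
  a_int <- acc$accuracy[tr[acc$participant_id] == "interleaved"]
  a_blk <- acc$accuracy[tr[acc$participant_id] == "blocked"]
  expect_gte(length(a_int), 26)
  expect_lt(mean(a_int), mean(a_blk))
})

test_that("cohort simulation is byte-identical under a fixed seed", {
  co1 <- simulate_cohort("transfer", 2, preset = "transfer-like", seed = 77)
  co2 <- simulate_cohort("transfer", 2, preset = "transfer-like", seed = 77)
  expect_identical(co1$trials, co2$trials)
  expect_identical(co1$recalls, co2$recalls)
})

test_that("blocked training learns faster than interleaved under the paper-like preset", {
  co <- simulate_cohort("retention", 8, preset = "paper-like", seed = 55)
  srts <- sequence_rts(co$trials)
  d <- difference_scores(srts, co$design, warn = FALSE)
  l <- d[d$kind == "learning", ]
  expect_lt(mean(l$value[l$training_condition == "blocked"]),
            mean(l$value[l$training_condition == "interleaved"]))
  expect_lt(mean(l$value[l$training_condition == "blocked"]), 0)
})

test_that("the transfer-like preset yields positive transfer everywhere except BI", {
  co <- simulate_cohort("transfer", 20, preset = "transfer-like", seed = 66)
  d <- difference_scores(sequence_rts(co$trials), co$design, warn = FALSE)
  dm <- d[d$kind == "transfer", ]
  cm <- tapply(dm$value, dm$cell, mean)
  expect_true(all(cm[c("BB", "II", "IB")] < -0.25))
  expect_lt(abs(cm["BI"]), 0.25)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(participant_params(press_error_prob = 1.2), "press_error_prob")
  expect_error(participant_params(seq_gain = -0.1), "seq_gain")
  expect_error(participant_params(explicit_k = 9), "explicit_k")
})
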