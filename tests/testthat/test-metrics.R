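test_that("sequence RTs sum the eight presses and flag fully-correct trials", {
  log <- make_log(labels = c("A", "A", "B"), rt_sum = c(2.0, 2.4, 1.6),
                  wrong = c(FALSE, TRUE, FALSE))
  srt <- sequence_rts(log)
  expect_equal(nrow(srt), 3)
  expect_equal(srt$rt_sum, c(2.0, 2.4, 1.6))
  expect_identical(srt$correct, c(TRUE, FALSE, TRUE))
  # malformed press counts are rejected naming the trial
  expect_error(sequence_rts(log[-3, ]), "7 presses")
})

test_that("metrics are invariant to trial-log row order", {
  d <- build_experiment_design("retention", 1, seed = 12, reps = 10)
  p <- d$participants[[1]]
  sim <- simulate_participant(p$assignment, p$schedules, p$sequences,
                              participant_params(), seed = 6)
  srt1 <- sequence_rts(sim$trials)
  set.seed(1)
  shuffled <- sim$trials[sample(nrow(sim$trials)), ]
  srt2 <- sequence_rts(shuffled)
  expect_equal(srt1, srt2)
  expect_equal(press_accuracy(sim$trials), press_accuracy(shuffled))
})

test_that("per-day trial totals match the design", {
  d <- build_experiment_design("retention", 1, seed = 13)
  p <- d$participants[[1]]
  sim <- simulate_participant(p$assignment, p$schedules, p$sequences,
                              participant_params(), seed = 7)
  srt <- sequence_rts(sim$trials)
  expect_equal(sum(srt$day == 1), 240)
  expect_equal(sum(srt$day == 2), 240)
})

test_that("windows follow the day's schedule and use correct trials only", {
  # blocked: last 10 per sequence; hand-computable layout 12 trials/label
  labs <- rep(c("A", "B", "C"), each = 12)
  rt <- c(1:12, 21:32, 41:52) / 10
  rts <- make_rts(labels = labs, rt = rt)
  expect_equal(window_mean(rts, "blocked", 1, "last"),
               mean(c(3:12, 23:32, 43:52) / 10))
  expect_equal(window_mean(rts, "blocked", 1, "first"),
               mean(c(1:10, 21:30, 41:50) / 10))
  # interleaved: first/last 30 regardless of label
  expect_equal(window_mean(rts, "interleaved", 1, "first"),
               mean(rt[1:30]))
  expect_equal(window_mean(rts, "interleaved", 1, "last"),
               mean(rt[7:36]))
  # incorrect trials are skipped when filling the window
  correct <- rep(TRUE, 36)
  correct[c(1, 2)] <- FALSE
  rts2 <- make_rts(labels = labs, rt = rt, correct = correct)
  expect_equal(window_mean(rts2, "interleaved", 1, "first", warn = FALSE),
               mean(rt[3:32]))
  # short windows warn and use what is available
  few <- make_rts(labels = rep("A", 40),
                  rt = rep(2, 40), correct = rep(c(TRUE, FALSE), c(5, 35)))
  expect_warning(wm <- window_mean(few, "interleaved", 1, "first"), "only 5")
  expect_equal(wm, 2)
  none <- make_rts(labels = "A", rt = 2, correct = FALSE)
  expect_warning(w0 <- window_mean(none, "interleaved", 1, "first"),
                 "no correct")
  expect_true(is.na(w0))
})

test_that("difference scores follow the sign conventions", {
  # constant 3.0 in day-1 first window, 2.0 in day-1 last, 1.8 in day-2 first
  labs <- rep(c("A", "B", "C"), times = 20)
  rt1 <- c(rep(3, 30), rep(2, 30))
  rt2 <- c(rep(1.8, 30), rep(2, 30))
  rts <- rbind(make_rts(labels = labs, rt = rt1, day = 1),
               make_rts(labels = labs, rt = rt2, day = 2))
  a <- make_assignment("P1", "interleaved", "interleaved")
  d <- difference_scores(rts, list(a), experiment = "retention", warn = FALSE)
  expect_equal(d$value[d$kind == "learning"], -1.0)
  expect_equal(d$value[d$kind == "retention"], -0.2)
  dt <- difference_scores(rts, list(make_assignment("P1", "interleaved",
                                                    "interleaved",
                                                    "transfer")),
                          experiment = "transfer", warn = FALSE)
  expect_equal(dt$value[dt$kind == "transfer"], 1.8 - 3.0)
  # equal day-1-last and day-2-first windows mean perfect retention (zero)
  rts0 <- rbind(make_rts(labels = labs, rt = rt1, day = 1),
                make_rts(labels = labs, rt = c(rep(2, 30), rep(9, 30)),
                         day = 2))
  d0 <- difference_scores(rts0, list(a), experiment = "retention",
                          warn = FALSE)
  expect_equal(d0$value[d0$kind == "retention"], 0)
})

test_that("a day-specific RT shift moves retention but not learning", {
  d <- build_experiment_design("retention", 1, seed = 14, reps = 20)
  p <- d$participants[[1]]
  sim <- simulate_participant(p$assignment, p$schedules, p$sequences,
                              participant_params(), seed = 8)
  srts <- sequence_rts(sim$trials)
  base <- difference_scores(srts, list(p$assignment), warn = FALSE)
  shifted <- srts
  shifted$rt_sum[shifted$day == 2] <- shifted$rt_sum[shifted$day == 2] + 0.5
  sh <- difference_scores(shifted, list(p$assignment), warn = FALSE)
  expect_equal(sh$value[sh$kind == "retention"],
               base$value[base$kind == "retention"] + 0.5)
  expect_equal(sh$value[sh$kind == "learning"],
               base$value[base$kind == "learning"])
})

test_that("accuracy and exclusion flags apply the per-day threshold", {
  log <- make_log(labels = rep("A", 10), rt_sum = rep(2, 10),
                  wrong = rep(c(TRUE, FALSE), c(3, 7)))
  acc <- press_accuracy(log)
  expect_equal(acc$accuracy, 100 * (80 - 3) / 80)
  expect_equal(acc$seq_accuracy, 70)
  ex <- flag_exclusions(data.frame(participant_id = c("P1", "P1", "P2", "P2"),
                                   day = c(1, 2, 1, 2),
                                   accuracy = c(95, 79.9, 92, 93)),
                        threshold = 80)
  expect_identical(ex$excluded, c(TRUE, FALSE))
  expect_match(ex$reason[1], "day 2")
})

test_that("trend tables recover decreasing learning trends per group", {
  co <- simulate_cohort("retention", 2, preset = "paper-like", seed = 404)
  srts <- sequence_rts(co$trials)
  tt <- trend_table(srts, co$design, day = 1, by = "training")
  expect_setequal(tt$group, c("blocked", "interleaved"))
  expect_true(all(tt$tau < 0))
  expect_true(all(tt$p_value < 0.05))
})
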