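# Shared fixtures built in code.

# worked-example recall fixture: typed strings whose positional-similarity
# matrix against the three truths is exactly
#   t1: (0.50, 0, 0);  t2: (0, 0.25, 0);  t3: (0, 0, 0)
# (verified by direct position counting in test-recall.R), so the optimal
# one-to-one assignment recovers recalled fractions (0.5, 0.25, 0).
recall_fixture <- function() {
  list(truths = list(new_sequence(strsplit("UIOPUIOP", "")[[1]], "A"),
                     new_sequence(strsplit("IUPOIUPO", "")[[1]], "B"),
                     new_sequence(strsplit("OUPIUIOP", "")[[1]], "C")),
       typed = c("UIOPOPUI", "IOUUPOPI", "POUUOPII"))
}

# minimal sequence-trial RT table for window tests: one participant, one
# day, alternating labels, all values chosen by hand
make_rts <- function(participant_id = "P1", day = 1,
                     labels, rt, correct = rep(TRUE, length(rt))) {
  data.frame(participant_id = participant_id, day = day,
             trial_index = seq_along(rt) - 1L,
             sequence_label = labels, rt_sum = rt, correct = correct,
             stringsAsFactors = FALSE)
}

# hand-built trial-level log: each row of `trials` gives one sequence trial
# (8 presses); press RTs are rt_sum / 8; `wrong` marks trials with one
# incorrect press
make_log <- function(participant_id = "P1", day = 1, labels, rt_sum,
                     wrong = rep(FALSE, length(rt_sum))) {
  n <- length(rt_sum)
  tgt <- strsplit("UIOPUIOP", "")[[1]]
  do.call(rbind, lapply(seq_len(n), function(i) {
    resp <- tgt
    if (wrong[i]) resp[3] <- if (tgt[3] == "U") "I" else "U"
    data.frame(participant_id = participant_id, day = day,
               trial_index = i - 1L, sequence_label = labels[i],
               press_index = 0:7, target_key = tgt, response_key = resp,
               correct = tgt == resp, press_rt = rt_sum[i] / 8,
               stringsAsFactors = FALSE)
  }))
}

# tiny deterministic group assignment
make_assignment <- function(id = "P1", training = "blocked",
                            testing = "blocked",
                            experiment = "retention") {
  list(participant_id = id, training_condition = training,
       testing_condition = testing,
       cell = paste0(ifelse(training == "blocked", "B", "I"),
                     ifelse(testing == "blocked", "B", "I")),
       experiment = experiment)
}
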