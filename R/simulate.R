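# Synthetic-participant generator: per-press RT model, trial logs, recall.

#' Generative parameters for one synthetic participant
#'
#' The per-press reaction time model is
#' `rt = max(rt_floor, base_press_rt + general_gain * exp(-t / general_tau)
#'  + seq_gain * exp(-e / seq_tau) + switch_cost * is_switch + noise)`,
#' where `t` is the cumulative trial index (continuing across days), `e` the
#' number of prior exposures of the trial's sequence within the current
#' learning phase, and `noise ~ Normal(0, press_noise_sd)`. Day-2 presses
#' additionally receive `consolidation_offset` (the overnight offset implied
#' by the training condition: negative for offline gains, positive for
#' forgetting). Responses equal the target with probability
#' `1 - press_error_prob`, otherwise a uniformly chosen wrong key.
#'
#' @param base_press_rt asymptotic per-press RT, seconds.
#' @param general_gain,general_tau amplitude (s) and time constant (trials)
#'   of the nonspecific speed-up.
#' @param seq_gain,seq_tau amplitude (s) and time constant (exposures) of the
#'   sequence-specific speed-up.
#' @param switch_cost additional seconds per press when the trial's sequence
#'   differs from the previous trial's.
#' @param press_noise_sd Gaussian per-press noise, seconds.
#' @param press_error_prob per-press error probability; length 1, or length 2
#'   for distinct Day-1/Day-2 values.
#' @param consolidation_offset seconds added to every Day-2 press.
#' @param day2_seq_gain_scale multiplier on the Day-2 *rate* of new sequence
#'   learning in the transfer design: the Day-2 sequence term is
#'   `seq_gain * exp(-e * day2_seq_gain_scale / day2_seq_tau)`, so a scale of
#'   0 means novel sequences are not learned at all (RT starts at naive level
#'   and stays there) while 1 is full-rate learning. Ignored in the retention
#'   design, where Day-1 learning simply continues.
#' @param day2_seq_tau Day-2 sequence-learning time constant for the transfer
#'   design; defaults to `seq_tau`.
#' @param post_error_cost seconds added to the press following an error
#'   (0 disables post-error slowing).
#' @param explicit_k integer 0-8: leading items of each relevant sequence the
#'   participant can reproduce at free recall.
#' @param rt_floor lower truncation for press RTs, seconds.
#' @return A validated list of class `srtt_params`.
#' @export
participant_params <- function(base_press_rt = 0.35,
                               general_gain = 0.04, general_tau = 80,
                               seq_gain = 0.10, seq_tau = 30,
                               switch_cost = 0.06,
                               press_noise_sd = 0.05,
                               press_error_prob = 0.05,
                               consolidation_offset = 0,
                               day2_seq_gain_scale = 1,
                               day2_seq_tau = NULL,
                               post_error_cost = 0,
                               explicit_k = 0L,
                               rt_floor = 0.15) {
  p <- list(base_press_rt = base_press_rt,
            general_gain = general_gain, general_tau = general_tau,
            seq_gain = seq_gain, seq_tau = seq_tau,
            switch_cost = switch_cost,
            press_noise_sd = press_noise_sd,
            press_error_prob = press_error_prob,
            consolidation_offset = consolidation_offset,
            day2_seq_gain_scale = day2_seq_gain_scale,
            day2_seq_tau = day2_seq_tau %||% seq_tau,
            post_error_cost = post_error_cost,
            explicit_k = as.integer(explicit_k),
            rt_floor = rt_floor)
  nonneg <- c("base_press_rt", "general_gain", "general_tau", "seq_gain",
              "seq_tau", "switch_cost", "press_noise_sd",
              "day2_seq_gain_scale", "day2_seq_tau", "post_error_cost",
              "rt_floor")
  for (f in nonneg) {
    if (any(p[[f]] < 0)) stop("`", f, "` must be non-negative")
  }
  if (any(p$press_error_prob < 0) || any(p$press_error_prob > 1)) {
    stop("`press_error_prob` must lie in [0, 1]")
  }
  if (!length(p$press_error_prob) %in% 1:2) {
    stop("`press_error_prob` must have length 1 or 2 (per day)")
  }
  if (p$explicit_k < 0L || p$explicit_k > 8L) {
    stop("`explicit_k` must be an integer in 0..8")
  }
  class(p) <- "srtt_params"
  p
}

#' Simulate per-press reaction times
#'
#' Vectorized draw from the generative RT model (see
#' [participant_params()] for the model form). Uses the current RNG stream;
#' results are deterministic given the RNG state.
#'
#' @param params an `srtt_params` object.
#' @param trial_index cumulative 0-based trial index (time input of the
#'   nonspecific learning term).
#' @param exposures_of_sequence 0-based count of prior exposures of the
#'   trial's sequence within the current learning phase.
#' @param is_switch logical: does the trial's sequence differ from the
#'   previous trial's?
#' @param day 1 or 2; Day 2 adds `consolidation_offset`.
#' @return Numeric vector of press RTs in seconds, truncated at `rt_floor`.
#' @export
simulate_press_rt <- function(params, trial_index, exposures_of_sequence,
                              is_switch = FALSE, day = 1L) {
  stopifnot(inherits(params, "srtt_params"),
            all(trial_index >= 0), all(exposures_of_sequence >= 0))
  n <- max(length(trial_index), length(exposures_of_sequence),
           length(is_switch))
  rt <- params$base_press_rt +
    (if (day == 2L) params$consolidation_offset else 0) +
    params$general_gain * exp(-trial_index / params$general_tau) +
    params$seq_gain * exp(-exposures_of_sequence / params$seq_tau) +
    params$switch_cost * as.numeric(is_switch) +
    stats::rnorm(n, 0, params$press_noise_sd)
  pmax(rt, params$rt_floor)
}

# error probability applicable on a given day
day_error_prob <- function(params, day) {
  p <- params$press_error_prob
  if (length(p) == 2L) p[day] else p
}

#' Simulate one participant's two-day session
#'
#' Produces the full trial-level log (240 trials x 8 presses per day) and the
#' free-recall response. Sequence-specific learning continues across days in
#' the retention design (same sequences); in the transfer design the Day-2
#' sequences are novel, so their exposure count restarts and learning
#' proceeds at the Day-2 rate (`day2_seq_gain_scale`, `day2_seq_tau`).
#' Recall reproduces the first `explicit_k` items of each relevant sequence
#' (the Day-1 set for retention; the most recent, Day-2, set for transfer)
#' followed by a random valid completion of the key multiset.
#'
#' @param assignment a group assignment (list with `participant_id`,
#'   `training_condition`, `testing_condition`, `cell`, `experiment`), e.g.
#'   from [build_experiment_design()].
#' @param schedules list with elements `day1` and `day2` (`srtt_schedule`).
#' @param sequences named list of `srtt_sequence` objects covering every
#'   label used by the schedules.
#' @param params an `srtt_params` object.
#' @param seed optional integer seed.
#' @return List with `trials` (data.frame: `participant_id`, `day`,
#'   `trial_index`, `sequence_label`, `press_index`, `target_key`,
#'   `response_key`, `correct`, `press_rt`) and `recall` (list:
#'   `participant_id`, `noticed_pattern`, `reported_count`,
#'   `typed_sequences`).
#' @export
simulate_participant <- function(assignment, schedules, sequences, params,
                                 seed = NULL) {
  stopifnot(inherits(params, "srtt_params"))
  with_seed(seed, {
    cols <- simulate_participant_cols(assignment, schedules, sequences,
                                      params)
    list(trials = do.call(data.frame,
                          c(cols$trials, stringsAsFactors = FALSE)),
         recall = cols$recall)
  })
}

# column-list version shared by simulate_participant and simulate_cohort
# (avoids repeated data.frame/rbind overhead when simulating many
# participants); uses the current RNG stream
simulate_participant_cols <- function(assignment, schedules, sequences,
                                      params) {
  experiment <- assignment$experiment %||% "retention"
  keys <- srtt_keys()
  {
    day_logs <- vector("list", 2L)
    for (day in 1:2) {
      sch <- schedules[[day]]
      labs <- sch$trials
      nt <- length(labs)
      reps <- sch$reps %||% (nt / 3L)
      # exposures within the day's learning phase
      expo <- stats::ave(rep(1, nt), labs, FUN = cumsum) - 1
      p_day <- params
      if (day == 2L) {
        if (experiment == "retention") {
          expo <- expo + reps  # same sequences: learning continues
        } else {
          # novel sequences: fresh phase at the Day-2 learning rate
          p_day$seq_tau <- params$day2_seq_tau /
            max(params$day2_seq_gain_scale, 1e-12)
        }
      }
      is_sw <- c(FALSE, labs[-1L] != labs[-nt])
      tidx <- (day - 1L) * nt + seq_len(nt) - 1L
      npress <- nt * 8L
      rt <- simulate_press_rt(p_day,
                              trial_index = rep(tidx, each = 8L),
                              exposures_of_sequence = rep(expo, each = 8L),
                              is_switch = rep(is_sw, each = 8L),
                              day = day)
      items <- vapply(sequences[unique(labs)], function(s) s$items,
                      character(8L))
      targets <- as.vector(items[, match(labs, colnames(items))])
      err <- stats::runif(npress) < day_error_prob(params, day)
      resp <- targets
      ne <- sum(err)
      if (ne > 0L) {
        ki <- match(targets[err], keys)
        off <- sample.int(3L, ne, replace = TRUE)
        resp[err] <- keys[((ki - 1L + off) %% 4L) + 1L]
      }
      if (params$post_error_cost > 0 && ne > 0L) {
        rt <- rt + params$post_error_cost * c(FALSE, err[-npress])
      }
      day_logs[[day]] <- list(
        participant_id = rep(assignment$participant_id, npress),
        day = rep(day, npress),
        trial_index = rep(seq_len(nt) - 1L, each = 8L),
        sequence_label = rep(labs, each = 8L),
        press_index = rep(0:7, times = nt),
        target_key = targets,
        response_key = resp,
        correct = !err,
        press_rt = rt)
    }
    recall_labels <- if (experiment == "retention") {
      unique(schedules$day1$trials)
    } else {
      unique(schedules$day2$trials)
    }
    k <- params$explicit_k
    typed <- vapply(sequences[recall_labels], function(s) {
      it <- s$items
      if (k >= 8L) return(paste(it, collapse = ""))
      lead <- if (k > 0L) it[seq_len(k)] else character(0)
      rest <- if (k > 0L) sample(it[-seq_len(k)]) else sample(srtt_key_multiset())
      paste(c(lead, rest), collapse = "")
    }, "")
    recall <- list(participant_id = assignment$participant_id,
                   noticed_pattern = k > 0L || stats::runif(1) < 0.5,
                   reported_count = length(typed),
                   typed_sequences = unname(typed))
    trials <- lapply(stats::setNames(nm = names(day_logs[[1]])),
                     function(cn) c(day_logs[[1]][[cn]], day_logs[[2]][[cn]]))
    list(trials = trials, recall = recall)
  }
}

#' Cohort effect presets
#'
#' Returns a function mapping a group assignment to `srtt_params` for one
#' participant (drawing participant-level heterogeneity from the current RNG
#' stream). Three presets ship with the package:
#'
#' * `"null"` - all condition effects zero (no switch cost, equal error
#'   rates, zero-mean consolidation offsets); used for type-I-error
#'   calibration of the downstream tests.
#' * `"paper-like"` - the qualitative retention pattern: blocked practice
#'   acquires faster on Day 1; interleaved-trained participants carry
#'   non-positive retention difference scores while blocked-trained
#'   participants forget, most severely when tested interleaved (BI).
#' * `"transfer-like"` - the qualitative transfer pattern: every cell shows
#'   positive transfer (negative score) except BI, which is near zero and
#'   shows no Day-2 learning trend.
#'
#' @param name preset name.
#' @return A function `f(assignment) -> srtt_params`.
#' @export
cohort_preset <- function(name = c("paper-like", "null", "transfer-like")) {
  name <- match.arg(name)
  tau_for <- function(cond) if (cond == "blocked") 30 else 400
  clamp <- function(x, lo, hi) min(hi, max(lo, x))
  switch(name,
    "paper-like" = function(assignment) {
      tr <- assignment$training_condition
      te <- assignment$testing_condition
      cell <- assignment$cell
      # Day-2 offsets are cell-specific: they bundle overnight consolidation
      # with how well the trained mode of responding carries into the test
      # schedule. Interleaved training transfers to either test schedule
      # (II, IB: mild offline gains, insensitive to testing condition);
      # blocked training barely holds under blocked testing (BB slightly
      # positive) and is strongly impaired under interleaved testing (BI),
      # on top of the switch costs BI's Day-2 window uniquely pays.
      offset_mean <- c(BB = 0.02, BI = 0.10, II = -0.04, IB = 0.00)[cell]
      participant_params(
        base_press_rt = clamp(stats::rnorm(1, 0.35, 0.04), 0.20, 0.60),
        general_gain = max(0, stats::rnorm(1, 0.04, 0.01)), general_tau = 80,
        seq_gain = max(0, stats::rnorm(1, 0.10, 0.02)),
        seq_tau = tau_for(tr), day2_seq_tau = tau_for(te),
        day2_seq_gain_scale = 1,
        switch_cost = max(0, stats::rnorm(1, 0.06, 0.015)),
        press_noise_sd = 0.05,
        press_error_prob = c(if (tr == "blocked") 0.055 else 0.075,
                             if (te == "blocked") 0.055 else 0.075),
        consolidation_offset = stats::rnorm(1, offset_mean, 0.07),
        # recall ability: the random completion plus best-match assignment
        # add ~2-3 items of chance credit on top of explicit_k, so these
        # draws put measured group means near 4.2 items (blocked) vs 3.2
        # (interleaved) with roughly balanced learner classes
        explicit_k = clamp(round(stats::rnorm(
          1, if (tr == "blocked") 2.0 else 0.8,
          if (tr == "blocked") 2.0 else 1.5)), 0, 8),
        rt_floor = 0.15)
    },
    "null" = function(assignment) {
      participant_params(
        base_press_rt = clamp(stats::rnorm(1, 0.35, 0.04), 0.20, 0.60),
        general_gain = max(0, stats::rnorm(1, 0.04, 0.01)), general_tau = 80,
        seq_gain = max(0, stats::rnorm(1, 0.10, 0.02)),
        seq_tau = 60, day2_seq_tau = 60, day2_seq_gain_scale = 1,
        switch_cost = 0, press_noise_sd = 0.05, press_error_prob = 0.05,
        consolidation_offset = stats::rnorm(1, 0, 0.07),
        explicit_k = clamp(round(stats::rnorm(1, 1.5, 1)), 0, 8),
        rt_floor = 0.15)
    },
    "transfer-like" = function(assignment) {
      tr <- assignment$training_condition
      te <- assignment$testing_condition
      cell <- assignment$cell
      # Day-2 carry-over of the trained skill is cell-specific: blocked
      # training generalizes to blocked testing but leaves the learner
      # unprepared for interleaved testing (BI), which also shows no Day-2
      # sequence learning
      offset_mean <- c(BB = -0.055, II = -0.020, IB = 0.000, BI = -0.045)[cell]
      participant_params(
        base_press_rt = clamp(stats::rnorm(1, 0.35, 0.04), 0.20, 0.60),
        general_gain = max(0, stats::rnorm(1, 0.04, 0.01)), general_tau = 80,
        seq_gain = max(0, stats::rnorm(1, 0.10, 0.02)),
        seq_tau = tau_for(tr), day2_seq_tau = tau_for(te),
        day2_seq_gain_scale = if (identical(cell, "BI")) 0 else 1,
        switch_cost = max(0, stats::rnorm(1, 0.06, 0.015)),
        press_noise_sd = 0.05,
        press_error_prob = c(if (tr == "blocked") 0.05 else 0.085,
                             if (te == "blocked") 0.05 else 0.085),
        consolidation_offset = stats::rnorm(1, offset_mean, 0.05),
        explicit_k = sample(0:2, 1, prob = c(0.45, 0.40, 0.15)),
        rt_floor = 0.15)
    })
}

#' Simulate a full cohort
#'
#' Builds a counterbalanced design (`4 * n_per_cell` participants) and
#' simulates every participant under the chosen preset. Everything is
#' reproducible given `seed`.
#'
#' @param experiment `"retention"` or `"transfer"`.
#' @param n_per_cell participants per training/testing cell (>= 1).
#' @param preset preset name (see [cohort_preset()]) or a function
#'   `f(assignment) -> srtt_params`.
#' @param seed optional integer seed.
#' @param run_cap interleaved run-length cap, see [build_schedule()].
#' @param reps presentations per sequence per day.
#' @return An object of class `srtt_cohort`: list with `design`
#'   (`srtt_design`), `trials` (one combined data.frame), `recalls` (list of
#'   recall responses keyed by participant), and `params` (list of
#'   `srtt_params`).
#' @export
simulate_cohort <- function(experiment = c("retention", "transfer"),
                            n_per_cell, preset = "paper-like", seed = NULL,
                            run_cap = 2L, reps = 80L) {
  experiment <- match.arg(experiment)
  stopifnot(n_per_cell >= 1L)
  pf <- if (is.function(preset)) preset else cohort_preset(preset)
  with_seed(seed, {
    design <- build_experiment_design(experiment, 4L * n_per_cell,
                                      run_cap = run_cap, reps = reps)
    params <- list()
    recalls <- list()
    logs <- vector("list", length(design$participants))
    for (i in seq_along(design$participants)) {
      p <- design$participants[[i]]
      pid <- p$assignment$participant_id
      params[[pid]] <- pf(p$assignment)
      sim <- simulate_participant_cols(p$assignment, p$schedules,
                                       p$sequences, params[[pid]])
      logs[[i]] <- sim$trials
      recalls[[pid]] <- sim$recall
    }
    trials <- do.call(data.frame, c(
      lapply(stats::setNames(nm = names(logs[[1]])), function(cn) {
        unlist(lapply(logs, `[[`, cn), use.names = FALSE)
      }),
      stringsAsFactors = FALSE))
    structure(list(design = design, trials = trials,
                   recalls = recalls, params = params,
                   preset = if (is.function(preset)) "custom" else preset,
                   experiment = experiment),
              class = "srtt_cohort")
  })
}

#' @export
print.srtt_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s, %d participants, preset '%s', %d log rows\n",
              x$experiment, length(x$design$participants), x$preset,
              nrow(x$trials)))
  invisible(x)
}

#' Write a trial log to CSV
#'
#' @param trials trial-log data.frame (schema of [simulate_participant()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_triallog <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write recall responses to JSON
#'
#' @param recalls list of recall responses.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recall_json <- function(recalls, path) {
  jsonlite::write_json(recalls, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
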