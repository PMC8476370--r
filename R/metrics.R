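# Trial-log metrics: sequence RTs, accuracy, exclusions, windows,
# difference scores, trend tables.

triallog_required_cols <- function() {
  c("participant_id", "day", "trial_index", "sequence_label", "press_index",
    "target_key", "response_key", "correct", "press_rt")
}

check_triallog <- function(log) {
  miss <- setdiff(triallog_required_cols(), names(log))
  if (length(miss)) {
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(log$press_rt) | log$press_rt < 0)
  if (length(bad)) {
    stop("malformed press_rt at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(log)
}

#' Collapse a trial log to sequence-trial RTs
#'
#' Sums the eight key-press RTs of every sequence trial and marks the trial
#' correct when all eight presses are correct. Downstream analyses use only
#' correct trials, but every trial is retained here so exclusions stay
#' visible.
#'
#' @param log trial-level log (schema of [simulate_participant()]).
#' @return data.frame with one row per sequence trial: `participant_id`,
#'   `day`, `trial_index`, `sequence_label`, `rt_sum` (seconds), `correct`.
#' @export
sequence_rts <- function(log) {
  check_triallog(log)
  pidx <- as.integer(factor(log$participant_id))
  gk <- ((pidx - 1) * 2 + (log$day - 1)) * 100000 + log$trial_index
  o <- order(gk, log$press_index)
  log <- log[o, ]
  gk <- gk[o]
  rt_sum <- rowsum(log$press_rt, gk)
  n_ok <- rowsum(as.integer(log$correct), gk)
  n_press <- rowsum(rep(1L, nrow(log)), gk)
  if (any(n_press != 8L)) {
    first_bad <- which(n_press != 8L)[1]
    keep <- !duplicated(gk)
    meta_bad <- log[keep, ][first_bad, ]
    stop(sprintf(
      "trial with %d presses (expected 8): participant %s day %d trial %d",
      n_press[first_bad], meta_bad$participant_id, meta_bad$day,
      meta_bad$trial_index))
  }
  first <- log[!duplicated(gk), ]
  data.frame(participant_id = first$participant_id,
             day = first$day,
             trial_index = first$trial_index,
             sequence_label = first$sequence_label,
             rt_sum = as.vector(rt_sum),
             correct = as.vector(n_ok) == 8L,
             stringsAsFactors = FALSE)
}

#' Per-press and per-sequence accuracy
#'
#' @param log trial-level log.
#' @param day optionally restrict to one day.
#' @return data.frame with one row per participant-day: `participant_id`,
#'   `day`, `accuracy` (percent correct key presses) and `seq_accuracy`
#'   (percent of trials with all eight presses correct).
#' @export
press_accuracy <- function(log, day = NULL) {
  check_triallog(log)
  if (!is.null(day)) log <- log[log$day %in% day, , drop = FALSE]
  pidx <- as.integer(factor(log$participant_id))
  gk <- (pidx - 1) * 2 + (log$day - 1)
  o <- order(gk)
  log <- log[o, ]
  gk <- gk[o]
  acc <- 100 * as.vector(rowsum(as.integer(log$correct), gk)) /
    as.vector(rowsum(rep(1L, nrow(log)), gk))
  srt <- sequence_rts(log)
  sidx <- as.integer(factor(srt$participant_id))
  sgk <- (sidx - 1) * 2 + (srt$day - 1)
  so <- order(sgk)
  seq_acc <- 100 * as.vector(rowsum(as.integer(srt$correct[so]), sgk[so])) /
    as.vector(rowsum(rep(1L, nrow(srt)), sgk[so]))
  first <- log[!duplicated(gk), c("participant_id", "day")]
  data.frame(first, accuracy = acc, seq_accuracy = seq_acc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag participants below the accuracy threshold
#'
#' Participants with per-press accuracy below the threshold on either day
#' are flagged for exclusion (effort rather than learning drives low
#' accuracy in this simple task).
#'
#' @param accuracy data.frame from [press_accuracy()].
#' @param threshold percent accuracy cutoff (default 80).
#' @return data.frame with one row per participant: `participant_id`,
#'   `excluded`, `reason`.
#' @export
flag_exclusions <- function(accuracy, threshold = 80) {
  stopifnot(threshold > 0, threshold <= 100)
  sp <- split(accuracy, accuracy$participant_id)
  out <- lapply(sp, function(a) {
    low <- a$day[a$accuracy < threshold]
    data.frame(participant_id = a$participant_id[1],
               excluded = length(low) > 0,
               reason = if (length(low)) {
                 sprintf("accuracy below %g%% on day %s", threshold,
                         paste(low, collapse = ","))
               } else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Windowed mean of correct sequence RTs
#'
#' The analysis windows respect the day's schedule: under a blocked schedule
#' the window holds the first or last `n_per_sequence` *correct* trials of
#' each of the three sequences (30 trials in total); under an interleaved
#' schedule it holds the first or last `n_interleaved` correct trials
#' regardless of label. If fewer correct trials are available than the
#' window requests, all available ones are used with a warning; an empty
#' window yields `NA`.
#'
#' @param rts sequence-trial RTs (one participant), see [sequence_rts()].
#' @param condition the day's schedule condition.
#' @param day which day to window.
#' @param end `"first"` or `"last"` window of the day.
#' @param n_per_sequence trials per sequence in the blocked window.
#' @param n_interleaved trials in the interleaved window.
#' @param warn warn when the window is short.
#' @return Mean sequence RT in seconds (`NA` if no correct trials).
#' @export
window_mean <- function(rts, condition = c("blocked", "interleaved"), day,
                        end = c("first", "last"), n_per_sequence = 10L,
                        n_interleaved = 30L, warn = TRUE) {
  condition <- match.arg(condition)
  end <- match.arg(end)
  r <- rts[rts$day == day & rts$correct, , drop = FALSE]
  if (nrow(r) == 0L) {
    if (warn) warning("no correct trials in window (day ", day, ")")
    return(NA_real_)
  }
  r <- r[order(r$trial_index), ]
  take <- function(x, n) if (end == "first") utils::head(x, n) else utils::tail(x, n)
  if (condition == "blocked") {
    vals <- unlist(lapply(split(r$rt_sum, r$sequence_label), take,
                          n = n_per_sequence), use.names = FALSE)
    expected <- 3L * n_per_sequence
  } else {
    vals <- take(r$rt_sum, n_interleaved)
    expected <- n_interleaved
  }
  if (warn && length(vals) < expected) {
    warning(sprintf("window day %d (%s, %s): only %d correct trials of %d",
                    day, condition, end, length(vals), expected))
  }
  mean(vals)
}

#' Windowed difference scores
#'
#' Computes, per participant, the learning score (Day-1 last window minus
#' Day-1 first window) plus the retention score (Day-2 first window minus
#' Day-1 last window) for the retention design, or the transfer score
#' (Day-2 first window minus Day-1 first window) for the transfer design.
#' Negative values mean faster RTs (improvement); zero retention means
#' perfect retention, zero transfer no transfer. Each day's window follows
#' that day's own schedule condition (training on Day 1, testing on Day 2).
#'
#' @param rts sequence-trial RTs for the cohort, see [sequence_rts()].
#' @param design an `srtt_design` (or list of assignments).
#' @param experiment override the design's experiment type.
#' @param n_per_sequence,n_interleaved window sizes, see [window_mean()].
#' @param warn warn on short windows.
#' @return Long data.frame: `participant_id`, `training_condition`,
#'   `testing_condition`, `cell`, `kind` (learning/retention/transfer),
#'   `value` (seconds), `window_n`.
#' @export
difference_scores <- function(rts, design, experiment = NULL,
                              n_per_sequence = 10L, n_interleaved = 30L,
                              warn = TRUE) {
  assigns <- if (inherits(design, "srtt_design")) {
    lapply(design$participants, `[[`, "assignment")
  } else {
    design
  }
  experiment <- experiment %||% assigns[[1]]$experiment %||% "retention"
  sp <- split(rts, rts$participant_id)
  rows <- lapply(assigns, function(a) {
    r <- sp[[a$participant_id]]
    if (is.null(r)) return(NULL)
    wm <- function(day, cond, end) {
      window_mean(r, cond, day, end, n_per_sequence = n_per_sequence,
                  n_interleaved = n_interleaved, warn = warn)
    }
    d1_first <- wm(1L, a$training_condition, "first")
    d1_last <- wm(1L, a$training_condition, "last")
    d2_first <- wm(2L, a$testing_condition, "first")
    kinds <- c("learning",
               if (experiment == "retention") "retention" else "transfer")
    vals <- c(d1_last - d1_first,
              if (experiment == "retention") d2_first - d1_last
              else d2_first - d1_first)
    data.frame(participant_id = a$participant_id,
               training_condition = a$training_condition,
               testing_condition = a$testing_condition,
               cell = a$cell, kind = kinds, value = vals,
               window_n = if (a$training_condition == "blocked") {
                 3L * n_per_sequence
               } else {
                 n_interleaved
               },
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Cell-averaged RT series for trend testing
#'
#' Averages correct sequence-trial RTs over participants within a grouping
#' (training/testing cell or training condition), per trial index, giving
#' the group learning-curve series that the Mann-Kendall trend test is run
#' on.
#'
#' @param rts sequence-trial RTs, see [sequence_rts()].
#' @param design an `srtt_design` (or list of assignments).
#' @param day which day's series to build.
#' @param by group by `"cell"` (BB/II/BI/IB) or `"training"` condition.
#' @return data.frame: `group`, `trial_index`, `mean_rt`, `n`.
#' @export
trend_series <- function(rts, design, day, by = c("cell", "training")) {
  by <- match.arg(by)
  assigns <- if (inherits(design, "srtt_design")) {
    lapply(design$participants, `[[`, "assignment")
  } else {
    design
  }
  grp_of <- vapply(assigns, function(a) {
    if (by == "cell") a$cell else a$training_condition
  }, "")
  names(grp_of) <- vapply(assigns, `[[`, "", "participant_id")
  r <- rts[rts$day == day & rts$correct, , drop = FALSE]
  r$group <- grp_of[r$participant_id]
  r <- r[!is.na(r$group), ]
  agg <- stats::aggregate(rt_sum ~ group + trial_index, data = r, FUN = mean)
  cnt <- stats::aggregate(rt_sum ~ group + trial_index, data = r, FUN = length)
  out <- data.frame(group = agg$group, trial_index = agg$trial_index,
                    mean_rt = agg$rt_sum, n = cnt$rt_sum,
                    stringsAsFactors = FALSE)
  out[order(out$group, out$trial_index), ]
}

#' Mann-Kendall trend table per group
#'
#' Runs [mann_kendall()] on each group's trial-averaged RT series.
#'
#' @inheritParams trend_series
#' @return data.frame: `group`, `n`, `tau`, `S`, `p_value`, `significant`
#'   (p < .05), `direction`.
#' @export
trend_table <- function(rts, design, day, by = c("cell", "training")) {
  ser <- trend_series(rts, design, day, by)
  sp <- split(ser, ser$group)
  out <- lapply(sp, function(s) {
    mk <- mann_kendall(s$mean_rt[order(s$trial_index)])
    data.frame(group = s$group[1], n = nrow(s),
               tau = unname(mk$statistic["tau"]),
               S = unname(mk$statistic["S"]),
               p_value = mk$p_value,
               significant = mk$p_value < 0.05,
               direction = if (mk$statistic["tau"] < 0) "decreasing"
               else if (mk$statistic["tau"] > 0) "increasing" else "flat",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}
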