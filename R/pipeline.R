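# End-to-end orchestration: config, experiment runner, ingest, report.

#' Build a run configuration
#'
#' @param experiment `"retention"` or `"transfer"`.
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (analyze supplied trial logs).
#' @param seed integer seed governing every random stage.
#' @param preset cohort preset name or function, see [cohort_preset()].
#' @param n_per_cell participants per training/testing cell (simulate mode).
#' @param rule recall matching rule, see [similarity()].
#' @param cutoff_items implicit/explicit cutoff, see [classify_learner()].
#' @param accuracy_threshold percent accuracy exclusion threshold.
#' @param run_cap interleaved run-length cap.
#' @param reps presentations per sequence per day.
#' @param calibrate also run the Monte Carlo chance calibration.
#' @param n_comparison,n_reps calibration scale, see [calibrate_chance()].
#' @param trials ingest mode: trial-log data.frame or CSV path.
#' @param design ingest mode: `srtt_design` or list of assignments.
#' @param recalls ingest mode: list of recall responses (optional).
#' @param ms_input ingest mode: trial RTs are in milliseconds.
#' @param out_dir optional directory; when set, all stage artifacts are
#'   written there.
#' @return A validated list of class `srtt_config`.
#' @export
run_config <- function(experiment = c("retention", "transfer"),
                       mode = c("simulate", "ingest"), seed = 1L,
                       preset = "paper-like", n_per_cell = 20L,
                       rule = "positional", cutoff_items = 3,
                       accuracy_threshold = 80, run_cap = 2L, reps = 80L,
                       calibrate = FALSE, n_comparison = 10000L,
                       n_reps = 500L, trials = NULL, design = NULL,
                       recalls = NULL, ms_input = FALSE, out_dir = NULL) {
  experiment <- match.arg(experiment)
  mode <- match.arg(mode)
  stopifnot(accuracy_threshold > 0, accuracy_threshold <= 100)
  if (mode == "simulate" && !is.function(preset)) {
    preset <- match.arg(preset, c("paper-like", "null", "transfer-like"))
  }
  if (mode == "ingest" && (is.null(trials) || is.null(design))) {
    stop("ingest mode requires `trials` and `design`")
  }
  structure(list(experiment = experiment, mode = mode, seed = seed,
                 preset = preset, n_per_cell = n_per_cell, rule = rule,
                 cutoff_items = cutoff_items,
                 accuracy_threshold = accuracy_threshold,
                 run_cap = run_cap, reps = reps, calibrate = calibrate,
                 n_comparison = n_comparison, n_reps = n_reps,
                 trials = trials, design = design, recalls = recalls,
                 ms_input = ms_input, out_dir = out_dir),
            class = "srtt_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys are the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return An `srtt_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Validate and ingest a trial-level log
#'
#' Accepts a CSV path or data.frame in the documented trial-log schema
#' (optionally with renamed columns via `col_map`), checks structural
#' integrity (eight presses per trial, in-range indices, non-negative RTs)
#' and applies unit conversion.
#'
#' @param x CSV path or data.frame.
#' @param ms_to_seconds if `TRUE`, divide `press_rt` by 1000 at ingest.
#' @param col_map optional named character vector mapping schema names to
#'   the file's column names, e.g. `c(press_rt = "RT_ms")`.
#' @return A validated trial-log data.frame.
#' @export
ingest_triallog <- function(x, ms_to_seconds = FALSE, col_map = NULL) {
  log <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      idx <- match(col_map[[schema_name]], names(log))
      if (is.na(idx)) stop("col_map column not found: ", col_map[[schema_name]])
      names(log)[idx] <- schema_name
    }
  }
  if (!"correct" %in% names(log) &&
      all(c("target_key", "response_key") %in% names(log))) {
    log$correct <- log$target_key == log$response_key
  }
  check_triallog(log)
  if (is.numeric(log$correct)) log$correct <- log$correct == 1
  log$correct <- as.logical(log$correct)
  if (ms_to_seconds) log$press_rt <- log$press_rt / 1000
  if (!all(log$day %in% 1:2)) {
    stop("`day` must be 1 or 2; offending row(s): ",
         paste(utils::head(which(!log$day %in% 1:2), 5L), collapse = ", "))
  }
  if (!all(log$press_index %in% 0:7)) {
    stop("`press_index` must be 0..7; offending row(s): ",
         paste(utils::head(which(!log$press_index %in% 0:7), 5L),
               collapse = ", "))
  }
  # structural check: eight presses per trial (errors name the trial)
  invisible(sequence_rts(log))
  log
}

try_stat <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(error = conditionMessage(e)), class = "srtt_stat_error")
  })
}

pick <- function(df, kind, cell = NULL, training = NULL, testing = NULL,
                 learner = NULL) {
  r <- df[df$kind == kind, ]
  if (!is.null(cell)) r <- r[r$cell %in% cell, ]
  if (!is.null(training)) r <- r[r$training_condition %in% training, ]
  if (!is.null(testing)) r <- r[r$testing_condition %in% testing, ]
  if (!is.null(learner)) r <- r[r$learner_class %in% learner, ]
  r$value
}

#' Run a full experiment analysis
#'
#' Executes the complete pipeline: cohort simulation (or ingest), exclusion
#' by accuracy, recall scoring and learner classification, windowed
#' difference scores, trend tests and the experiment's statistical battery.
#' For the retention design the battery comprises the accuracy Mann-Whitney
#' comparisons, recall t test, learning t tests, per-cell one-sample t tests,
#' the 2 x 2 x 2 (training x testing x learner) Type III ANOVA with simple
#' effects, and the 2 x 2 ANCOVA with recall score as covariate. For the
#' transfer design: the same accuracy/recall/learning tests, per-cell
#' one-sample t tests on transfer scores, the 2 x 2 ANOVA with Tukey-Kramer
#' post hoc comparisons and simple effects, the ANCOVA, and per-cell Day-2
#' Mann-Kendall trend tests. The whole run is reproducible given
#' `config$seed`.
#'
#' @param config an `srtt_config`, see [run_config()].
#' @return An object of class `srtt_report`: cohort artifacts, metrics,
#'   report tables (`learner_counts`, `trend_day1`, `trend_day2`,
#'   `diff_table`, `exclusions`), the `stats` battery, and optionally
#'   `calibration`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "srtt_config"))
  with_seed(config$seed, {
    # --- stage 1: cohort -------------------------------------------------
    if (config$mode == "simulate") {
      cohort <- simulate_cohort(config$experiment, config$n_per_cell,
                                preset = config$preset,
                                run_cap = config$run_cap, reps = config$reps)
      trials <- cohort$trials
      design <- cohort$design
      recalls <- cohort$recalls
    } else {
      trials <- ingest_triallog(config$trials, ms_to_seconds = config$ms_input)
      design <- config$design
      recalls <- config$recalls
      cohort <- NULL
    }
    assigns <- design_assignments(
      if (inherits(design, "srtt_design")) design else
        structure(list(participants = lapply(design, function(a)
          list(assignment = a))), class = "srtt_design"))
    # --- stage 2: metrics & exclusions -----------------------------------
    srts <- sequence_rts(trials)
    acc <- press_accuracy(trials)
    excl <- flag_exclusions(acc, config$accuracy_threshold)
    included <- excl$participant_id[!excl$excluded]
    if (length(included) == 0L) {
      return(structure(list(config = config, cohort = cohort,
                            exclusions = excl, accuracy = acc,
                            notice = "all participants excluded by the accuracy threshold",
                            stats = list(), tables = list()),
                       class = "srtt_report"))
    }
    srts_in <- srts[srts$participant_id %in% included, ]
    # --- stage 3: recall scoring -----------------------------------------
    scores <- NULL
    if (!is.null(recalls) && length(recalls) &&
        inherits(design, "srtt_design")) {
      dl <- design$participants
      names(dl) <- vapply(dl, function(p) p$assignment$participant_id, "")
      rows <- lapply(included, function(pid) {
        resp <- recalls[[pid]]
        p <- dl[[pid]]
        if (is.null(resp) || is.null(p)) return(NULL)
        truth_labels <- if (config$experiment == "retention") {
          c("A", "B", "C")
        } else {
          c("A", "B", "C", "D", "E", "F")
        }
        sc <- score_recall(resp, p$sequences[truth_labels],
                           rule = config$rule,
                           cutoff_items = config$cutoff_items)
        data.frame(participant_id = pid,
                   mean_score = sc$mean_score,
                   items_per_sequence = sc$items_per_sequence,
                   learner_class = sc$learner_class,
                   stringsAsFactors = FALSE)
      })
      scores <- do.call(rbind, rows)
    }
    # --- stage 4: difference scores & tables ------------------------------
    diffs <- difference_scores(srts_in, design, experiment = config$experiment,
                               warn = FALSE)
    if (!is.null(scores)) {
      diffs <- merge(diffs, scores, by = "participant_id", all.x = TRUE)
    } else {
      diffs$mean_score <- NA_real_
      diffs$items_per_sequence <- NA_real_
      diffs$learner_class <- NA_character_
    }
    main_kind <- if (config$experiment == "retention") "retention" else "transfer"
    dmain <- diffs[diffs$kind == main_kind, ]
    diff_table <- do.call(rbind, lapply(split(dmain, dmain$cell), function(d) {
      data.frame(cell = d$cell[1], n = nrow(d), mean = mean(d$value),
                 sem = stats::sd(d$value) / sqrt(nrow(d)),
                 stringsAsFactors = FALSE)
    }))
    row.names(diff_table) <- NULL
    learner_counts <- if (!is.null(scores)) {
      lc <- merge(unique(dmain[c("participant_id", "cell")]),
                  scores[c("participant_id", "learner_class")],
                  by = "participant_id")
      as.data.frame.matrix(table(lc$cell, lc$learner_class))
    } else {
      NULL
    }
    trend_day1 <- trend_table(srts_in, design, day = 1L, by = "training")
    trend_day2 <- trend_table(srts_in, design, day = 2L, by = "cell")
    # --- stage 5: statistical battery -------------------------------------
    ain <- merge(acc, assigns, by = "participant_id")
    ain <- ain[ain$participant_id %in% included, ]
    a1 <- ain[ain$day == 1, ]
    a2 <- ain[ain$day == 2, ]
    stats_out <- list(
      accuracy_day1_by_training = try_stat(mann_whitney_u(
        a1$accuracy[a1$training_condition == "interleaved"],
        a1$accuracy[a1$training_condition == "blocked"])),
      accuracy_day2_by_testing = try_stat(mann_whitney_u(
        a2$accuracy[a2$testing_condition == "interleaved"],
        a2$accuracy[a2$testing_condition == "blocked"])),
      accuracy_day2_within_interleaved_test = try_stat(mann_whitney_u(
        a2$accuracy[a2$cell == "II"], a2$accuracy[a2$cell == "BI"])),
      accuracy_day2_within_blocked_test = try_stat(mann_whitney_u(
        a2$accuracy[a2$cell == "BB"], a2$accuracy[a2$cell == "IB"])))
    if (!is.null(scores)) {
      sc2 <- merge(scores, assigns, by = "participant_id")
      stats_out$recall_items_by_training <- try_stat(independent_t(
        sc2$items_per_sequence[sc2$training_condition == "blocked"],
        sc2$items_per_sequence[sc2$training_condition == "interleaved"]))
    }
    stats_out$learning_one_sample <- lapply(
      c(blocked = "blocked", interleaved = "interleaved"),
      function(tr) try_stat(one_sample_t(pick(diffs, "learning",
                                              training = tr))))
    stats_out$learning_by_training <- try_stat(independent_t(
      pick(diffs, "learning", training = "blocked"),
      pick(diffs, "learning", training = "interleaved")))
    cells <- c("BB", "II", "BI", "IB")
    stats_out[[paste0(main_kind, "_one_sample_by_cell")]] <- lapply(
      stats::setNames(cells, cells),
      function(cl) try_stat(one_sample_t(pick(diffs, main_kind, cell = cl))))
    if (config$experiment == "retention") {
      stats_out$anova_2x2x2 <- try_stat(factorial_anova(
        dmain, "value",
        c("training_condition", "testing_condition", "learner_class")))
      stats_out$simple_effects_testing_within_training <-
        try_stat(simple_effects(dmain, "value", "testing_condition",
                                "training_condition"))
      stats_out$simple_effects_learner_within_training <-
        try_stat(simple_effects(dmain, "value", "learner_class",
                                "training_condition"))
    } else {
      stats_out$anova_2x2 <- try_stat(factorial_anova(
        dmain, "value", c("training_condition", "testing_condition")))
      stats_out$tukey <- try_stat(tukey_posthoc(
        dmain, "value", c("training_condition", "testing_condition")))
      stats_out$simple_effects_testing_within_training <-
        try_stat(simple_effects(dmain, "value", "testing_condition",
                                "training_condition"))
    }
    stats_out$ancova <- try_stat(ancova(
      dmain, "value", c("training_condition", "testing_condition"),
      covariate = "items_per_sequence"))
    # --- stage 6: optional chance calibration -----------------------------
    calibration <- if (isTRUE(config$calibrate)) {
      calibrate_chance(config$n_comparison, config$n_reps, rule = config$rule)
    } else {
      NULL
    }
    report <- structure(
      list(config = config, cohort = cohort, design = design,
           sequence_rts = srts, accuracy = acc, exclusions = excl,
           recall_scores = scores, difference_scores = diffs,
           tables = list(learner_counts = learner_counts,
                         trend_day1 = trend_day1, trend_day2 = trend_day2,
                         diff_table = diff_table),
           stats = stats_out, calibration = calibration, notice = NULL),
      class = "srtt_report")
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    report
  })
}

#' @export
print.srtt_report <- function(x, ...) {
  cat(sprintf("<report> %s (%s mode)\n", x$config$experiment, x$config$mode))
  if (!is.null(x$notice)) {
    cat("  NOTICE:", x$notice, "\n")
    return(invisible(x))
  }
  cat(sprintf("  participants: %d analyzed, %d excluded\n",
              sum(!x$exclusions$excluded), sum(x$exclusions$excluded)))
  cat("  difference scores by cell:\n")
  print(x$tables$diff_table, digits = 3)
  cat("  Day-2 trends by cell:\n")
  print(x$tables$trend_day2[c("group", "tau", "p_value", "significant")],
        digits = 3)
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' Materializes every pipeline stage (trial metrics, exclusion log, tables,
#' stats JSON, calibration JSON) so any stage can be inspected or re-run in
#' isolation.
#'
#' @param report an `srtt_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    }
  }
  w(report$accuracy, "accuracy.csv")
  w(report$exclusions, "exclusions.csv")
  w(report$recall_scores, "recall_scores.csv")
  w(report$difference_scores, "difference_scores.csv")
  w(report$tables$diff_table, "diff_table.csv")
  w(report$tables$trend_day1, "trend_day1.csv")
  w(report$tables$trend_day2, "trend_day2.csv")
  if (!is.null(report$tables$learner_counts)) {
    utils::write.csv(report$tables$learner_counts,
                     file.path(dir, "learner_counts.csv"))
  }
  stats_to_json(report$stats, file.path(dir, "stats.json"))
  if (!is.null(report$calibration)) {
    cal <- report$calibration
    jsonlite::write_json(
      list(n_comparison = cal$n_comparison, n_reps = cal$n_reps,
           rule = cal$rule, grand_mean = cal$grand_mean, band = cal$band,
           chance_items = cal$chance_items),
      file.path(dir, "chance_calibration.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(dir)
}

#' Plot group learning curves
#'
#' Bins the cell-averaged RT series and plots mean sequence RT per bin, one
#' panel-free line per group. Uses ggplot2 when available, base graphics
#' otherwise. A convenience for inspection; not part of the analysis
#' contract.
#'
#' @param rts sequence-trial RTs, see [sequence_rts()].
#' @param design an `srtt_design`.
#' @param day day to plot.
#' @param bin trials per bin.
#' @return A ggplot object, or `NULL` (base graphics) invisibly.
#' @export
plot_learning_curves <- function(rts, design, day = 1L, bin = 20L) {
  ser <- trend_series(rts, design, day, by = "cell")
  ser$bin <- (ser$trial_index %/% bin) * bin
  agg <- stats::aggregate(mean_rt ~ group + bin, data = ser, FUN = mean)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(agg, ggplot2::aes(x = .data$bin, y = .data$mean_rt,
                                      colour = .data$group)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = sprintf("Trial (day %d, bins of %d)", day, bin),
                    y = "Mean sequence RT (s)", colour = "Group")
  } else {
    groups <- unique(agg$group)
    ylim <- range(agg$mean_rt)
    graphics::plot(NULL, xlim = range(agg$bin), ylim = ylim,
                   xlab = sprintf("Trial (day %d)", day),
                   ylab = "Mean sequence RT (s)")
    for (i in seq_along(groups)) {
      g <- agg[agg$group == groups[i], ]
      graphics::lines(g$bin, g$mean_rt, col = i)
    }
    graphics::legend("topright", legend = groups, col = seq_along(groups),
                     lty = 1)
    invisible(NULL)
  }
}
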