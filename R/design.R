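# Experimental design: key sequences, practice schedules, group assignment.

#' Response keys used by the task
#'
#' The four response keys of the serial reaction time task, in screen order.
#' Every trial sequence is a permutation of the multiset holding each key
#' exactly twice.
#'
#' @return Character vector of the four key symbols.
#' @export
srtt_keys <- function() c("U", "I", "O", "P")

# the eight-item multiset each sequence permutes
srtt_key_multiset <- function() rep(srtt_keys(), times = 2L)

#' Construct an eight-item key sequence
#'
#' @param items character vector of length 8 over `srtt_keys()`, each key
#'   appearing exactly twice.
#' @param label optional identifier (conventionally one of "A".."F").
#' @return An object of class `srtt_sequence`.
#' @export
new_sequence <- function(items, label = NA_character_) {
  items <- as.character(items)
  if (length(items) != 8L) {
    stop("a sequence must have exactly 8 items, got ", length(items))
  }
  tab <- table(factor(items, levels = srtt_keys()))
  if (any(tab != 2L) || any(!items %in% srtt_keys())) {
    stop("a sequence must contain each of ",
         paste(srtt_keys(), collapse = ", "), " exactly twice")
  }
  structure(list(items = items, label = as.character(label)),
            class = "srtt_sequence")
}

#' @export
print.srtt_sequence <- function(x, ...) {
  cat(sprintf("<sequence %s> %s\n",
              ifelse(is.na(x$label), "?", x$label),
              paste(x$items, collapse = "")))
  invisible(x)
}

#' @export
as.character.srtt_sequence <- function(x, ...) paste(x$items, collapse = "")

# coerce sequence-ish input (srtt_sequence, string, char vector) to items
sequence_items <- function(x) {
  if (inherits(x, "srtt_sequence")) return(x$items)
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    return(strsplit(toupper(x), "")[[1]])
  }
  as.character(x)
}

# recursive multiset permutation enumeration (lexicographic)
multiset_permutations <- function(items) {
  n <- length(items)
  if (n == 1L) return(matrix(items, 1L, 1L))
  u <- sort(unique(items))
  blocks <- lapply(u, function(k) {
    rest <- items[-match(k, items)]
    sub <- multiset_permutations(rest)
    cbind(rep(k, nrow(sub)), sub, deparse.level = 0)
  })
  do.call(rbind, blocks)
}

#' Enumerate the full sequence space
#'
#' All distinct eight-item sequences over the four keys with each key used
#' exactly twice; there are 8!/2^4 = 2520 of them. The enumeration is cached
#' for the session.
#'
#' @param as return a character matrix of items (`"matrix"`) or a character
#'   vector of collapsed eight-character strings (`"character"`).
#' @return A 2520 x 8 character matrix or a length-2520 character vector.
#' @export
all_sequences <- function(as = c("matrix", "character")) {
  as <- match.arg(as)
  if (is.null(.srttci_cache$all_seq)) {
    m <- multiset_permutations(sort(srtt_key_multiset()))
    .srttci_cache$all_seq <- m
    .srttci_cache$all_seq_str <- apply(m, 1L, paste, collapse = "")
  }
  if (as == "matrix") .srttci_cache$all_seq else .srttci_cache$all_seq_str
}

normalize_forbidden <- function(forbidden) {
  if (is.null(forbidden) || length(forbidden) == 0L) return(character(0))
  if (inherits(forbidden, "srtt_sequence")) forbidden <- list(forbidden)
  vapply(forbidden, function(f) paste(sequence_items(f), collapse = ""), "")
}

#' Sample a random sequence
#'
#' Draws uniformly from the 2520 valid sequences (each key exactly twice),
#' excluding any in `forbidden`. Sequences are randomized across participants
#' so that no two share the same set.
#'
#' @param seed optional integer seed; the draw is deterministic given the
#'   seed and the forbidden set.
#' @param forbidden sequences to exclude: a list of `srtt_sequence` objects
#'   or a character vector of collapsed strings.
#' @param forbid_adjacent_repeats if `TRUE`, additionally reject sequences in
#'   which the same key occurs on consecutive positions.
#' @param label label to attach to the result.
#' @return An `srtt_sequence`.
#' @export
generate_sequence <- function(seed = NULL, forbidden = NULL,
                              forbid_adjacent_repeats = FALSE,
                              label = NA_character_) {
  forb <- normalize_forbidden(forbidden)
  with_seed(seed, {
    items <- NULL
    for (i in seq_len(200L)) {
      cand <- sample(srtt_key_multiset())
      if (forbid_adjacent_repeats && any(cand[-1L] == cand[-8L])) next
      if (!(paste(cand, collapse = "") %in% forb)) {
        items <- cand
        break
      }
    }
    if (is.null(items)) {
      # forbidden set is dense: enumerate what is left and sample from it
      strs <- all_sequences("character")
      if (forbid_adjacent_repeats) {
        m <- all_sequences("matrix")
        strs <- strs[rowSums(m[, -1L, drop = FALSE] ==
                               m[, -8L, drop = FALSE]) == 0L]
      }
      avail <- setdiff(strs, forb)
      if (length(avail) == 0L) {
        stop("sequence space exhausted: every valid sequence is forbidden")
      }
      items <- strsplit(avail[sample.int(length(avail), 1L)], "")[[1]]
    }
    new_sequence(items, label)
  })
}

# sequential constrained sampler for the interleaved order: weighted by
# remaining counts, never extending a run beyond `cap`; restarts on dead ends
sample_interleaved <- function(labels, reps, cap) {
  k <- length(labels)
  total <- k * reps
  repeat {
    counts <- rep(reps, k)
    out <- integer(total)
    prev <- 0L
    run <- 0L
    ok <- TRUE
    for (i in seq_len(total)) {
      w <- counts
      if (run >= cap && prev > 0L) w[prev] <- 0
      if (sum(w) == 0) {
        ok <- FALSE
        break
      }
      pick <- if (sum(w > 0) == 1L) which(w > 0) else sample.int(k, 1L, prob = w)
      out[i] <- pick
      counts[pick] <- counts[pick] - 1L
      if (pick == prev) run <- run + 1L else {
        prev <- pick
        run <- 1L
      }
    }
    if (ok) return(labels[out])
  }
}

#' Build a one-day practice schedule
#'
#' A schedule is the ordered list of sequence labels governing the day's
#' trials: 80 presentations of each of three sequences (240 trials). Blocked
#' schedules present each sequence as one contiguous run (run order
#' randomized); interleaved schedules intermix the three sequences under a
#' maximum-run-length constraint.
#'
#' @param condition `"blocked"` or `"interleaved"`.
#' @param labels three distinct sequence labels.
#' @param seed optional integer seed.
#' @param run_cap maximum run of identical adjacent labels in the interleaved
#'   condition (default 2, keeping interference high).
#' @param day day number (1 training, 2 testing), metadata only.
#' @param experiment `"retention"` or `"transfer"`, metadata only.
#' @param reps presentations per sequence (80 in the standard design).
#' @return An object of class `srtt_schedule` with a `trials` vector of
#'   length `3 * reps`.
#' @export
build_schedule <- function(condition = c("blocked", "interleaved"), labels,
                           seed = NULL, run_cap = 2L, day = 1L,
                           experiment = c("retention", "transfer"),
                           reps = 80L) {
  condition <- match.arg(condition)
  experiment <- match.arg(experiment)
  labels <- as.character(labels)
  if (length(labels) != 3L || anyDuplicated(labels)) {
    stop("`labels` must be three distinct sequence labels")
  }
  stopifnot(reps >= 1L, run_cap >= 1L)
  trials <- with_seed(seed, {
    if (condition == "blocked") {
      rep(sample(labels), each = reps)
    } else {
      sample_interleaved(labels, reps = reps, cap = run_cap)
    }
  })
  structure(list(condition = condition, day = as.integer(day),
                 experiment = experiment, trials = trials,
                 reps = as.integer(reps)),
            class = "srtt_schedule")
}

#' @export
print.srtt_schedule <- function(x, ...) {
  cat(sprintf("<schedule> %s day %d (%s), %d trials: %s...\n",
              x$condition, x$day, x$experiment, length(x$trials),
              paste(utils::head(x$trials, 12L), collapse = "")))
  invisible(x)
}

srtt_cells <- function() {
  data.frame(cell = c("BB", "II", "BI", "IB"),
             training_condition = c("blocked", "interleaved",
                                    "blocked", "interleaved"),
             testing_condition = c("blocked", "interleaved",
                                   "interleaved", "blocked"),
             stringsAsFactors = FALSE)
}

#' Build a full two-day experiment design
#'
#' Generates per-participant sequences, schedules and counterbalanced group
#' assignments for the retention or transfer design. Participants are
#' assigned to the four training/testing cells (BB, II, BI, IB) in shuffled
#' blocks of four, keeping cell sizes within one of each other. Retention
#' participants see the same three sequences (A, B, C) on both days; transfer
#' participants receive three novel sequences (D, E, F) on Day 2, six unique
#' sequences in total. No two participants share an identical ordered set of
#' sequences.
#'
#' @param experiment `"retention"` or `"transfer"`.
#' @param n_participants number of participants (>= 1).
#' @param seed optional integer seed; the whole design is reproducible given
#'   the seed.
#' @param run_cap interleaved maximum run length, see [build_schedule()].
#' @param forbid_adjacent_repeats passed to [generate_sequence()].
#' @param reps presentations per sequence per day (default 80).
#' @return An object of class `srtt_design`: a list with one entry per
#'   participant, each holding `assignment`, `sequences` (named list over
#'   labels) and `schedules` (`day1`, `day2`).
#' @export
build_experiment_design <- function(experiment = c("retention", "transfer"),
                                    n_participants, seed = NULL,
                                    run_cap = 2L,
                                    forbid_adjacent_repeats = FALSE,
                                    reps = 80L) {
  experiment <- match.arg(experiment)
  stopifnot(n_participants >= 1L)
  cells <- srtt_cells()
  with_seed(seed, {
    n_blocks <- ceiling(n_participants / 4)
    cell_order <- unlist(lapply(seq_len(n_blocks),
                                function(b) sample(cells$cell)))
    cell_order <- cell_order[seq_len(n_participants)]
    used_sets <- character(0)
    participants <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      cell <- cell_order[i]
      row <- cells[cells$cell == cell, ]
      repeat {
        day1_labels <- c("A", "B", "C")
        seqs <- list()
        for (lab in day1_labels) {
          seqs[[lab]] <- generate_sequence(
            forbidden = seqs, forbid_adjacent_repeats = forbid_adjacent_repeats,
            label = lab)
        }
        day2_labels <- day1_labels
        if (experiment == "transfer") {
          day2_labels <- c("D", "E", "F")
          for (lab in day2_labels) {
            seqs[[lab]] <- generate_sequence(
              forbidden = seqs,
              forbid_adjacent_repeats = forbid_adjacent_repeats, label = lab)
          }
        }
        key <- paste(vapply(seqs, as.character, ""), collapse = "|")
        if (!key %in% used_sets) break
      }
      used_sets <- c(used_sets, key)
      assignment <- list(participant_id = sprintf("P%03d", i),
                         training_condition = row$training_condition,
                         testing_condition = row$testing_condition,
                         cell = cell, experiment = experiment)
      schedules <- list(
        day1 = build_schedule(row$training_condition, day1_labels,
                              run_cap = run_cap, day = 1L,
                              experiment = experiment, reps = reps),
        day2 = build_schedule(row$testing_condition, day2_labels,
                              run_cap = run_cap, day = 2L,
                              experiment = experiment, reps = reps))
      participants[[i]] <- list(assignment = assignment, sequences = seqs,
                                schedules = schedules)
    }
    structure(list(participants = participants),
              class = "srtt_design", experiment = experiment,
              reps = as.integer(reps))
  })
}

#' @export
print.srtt_design <- function(x, ...) {
  cells <- vapply(x$participants, function(p) p$assignment$cell, "")
  cat(sprintf("<design> %s, %d participants (%s)\n",
              attr(x, "experiment"), length(x$participants),
              paste(sprintf("%s:%d", names(table(cells)), table(cells)),
                    collapse = " ")))
  invisible(x)
}

# data.frame of assignments, one row per participant
design_assignments <- function(design) {
  do.call(rbind, lapply(design$participants, function(p) {
    as.data.frame(p$assignment, stringsAsFactors = FALSE)
  }))
}

#' Flatten a design to a per-press table
#'
#' One row per key press slot: participant, day, trial and item position with
#' the cued target key. This is the export schema used to drive stimulus
#' presentation or to join with recorded responses.
#'
#' @param design an `srtt_design`.
#' @return data.frame with columns `participant_id`, `experiment`,
#'   `training_condition`, `testing_condition`, `day`, `trial_index`
#'   (0-based), `sequence_label`, `item_position` (0-7), `target_key`.
#' @export
design_table <- function(design) {
  out <- lapply(design$participants, function(p) {
    per_day <- lapply(1:2, function(day) {
      sch <- p$schedules[[day]]
      labs <- sch$trials
      nt <- length(labs)
      items <- vapply(p$sequences[unique(labs)], function(s) s$items,
                      character(8L))
      data.frame(participant_id = p$assignment$participant_id,
                 experiment = p$assignment$experiment,
                 training_condition = p$assignment$training_condition,
                 testing_condition = p$assignment$testing_condition,
                 day = day,
                 trial_index = rep(seq_len(nt) - 1L, each = 8L),
                 sequence_label = rep(labs, each = 8L),
                 item_position = rep(0:7, times = nt),
                 target_key = as.vector(items[, match(labs, colnames(items))]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_day)
  })
  do.call(rbind, out)
}

#' Write a design to CSV
#'
#' @param design an `srtt_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design_table(design), path, row.names = FALSE)
  invisible(path)
}
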