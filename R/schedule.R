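#' Build a pseudo-random recall schedule without immediate repeats
#'
#' Generates the trial order for an event-related recall experiment: each of
#' \code{n_classes} memories is cued \code{n_per_class} times in a
#' pseudo-random order constrained so that the same memory never occurs on
#' two consecutive trials.  Onsets are spaced regularly; each trial consists
#' of a cue, a fixed-length recall window and an inter-trial gap covering the
#' button press tail, rating screens and rest.
#'
#' Onset times are relative to the first retained (post-dummy) volume of the
#' accompanying BOLD run.
#'
#' The label sequence is drawn by constrained sequential sampling: at each
#' position a label is chosen uniformly among those that (a) differ from the
#' previous label and (b) leave a completable suffix (no remaining label count
#' may exceed half the remaining slots, rounded up).  This is exact, never
#' backtracks, and is deterministic given \code{seed}.
#'
#' @param n_classes number of distinct memories (>= 2).
#' @param n_per_class repetitions of each memory (>= 1).
#' @param seed integer RNG seed.
#' @param recall_duration_s length of the recall window (s).
#' @param inter_trial_gap_s time between the end of one recall window and the
#'   next cue onset (s); collapses press tail, fixation, ratings and rest.
#' @param cue_duration_s cue presentation time before recall begins (s).
#' @param start_s onset of the first cue (s).
#' @return a data frame (trial table) with columns \code{trial_index},
#'   \code{class_label}, \code{cue_onset_s}, \code{recall_onset_s}.
#' @examples
#' sched <- make_schedule(3, 20, seed = 1)
#' table(sched$class_label)
#' @export
make_schedule <- function(n_classes, n_per_class, seed,
                          recall_duration_s = 7, inter_trial_gap_s = 12,
                          cue_duration_s = 2, start_s = 0) {
  stopifnot(n_per_class >= 1, recall_duration_s > 0, inter_trial_gap_s >= 0)
  if (n_classes < 2) {
    stop("n_classes must be >= 2: the no-immediate-repeat constraint is ",
         "unsatisfiable with a single memory")
  }
  n <- n_classes * n_per_class
  labels <- integer(n)
  counts <- rep(n_per_class, n_classes)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  prev <- 0L
  for (i in seq_len(n)) {
    remaining <- n - i + 1L
    feasible <- vapply(seq_len(n_classes), function(l) {
      if (l == prev || counts[l] == 0L) return(FALSE)
      cnt <- counts
      cnt[l] <- cnt[l] - 1L
      r <- remaining - 1L
      if (r == 0L) return(TRUE)
      m <- max(cnt)
      if (m > ceiling(r / 2)) return(FALSE)
      # if one label must fill every other slot it must also start the
      # suffix, which the no-repeat rule forbids when that label is l
      if (2L * m == r + 1L && which.max(cnt) == l && sum(cnt == m) == 1L)
        return(FALSE)
      TRUE
    }, logical(1))
    choice <- which(feasible)
    labels[i] <- if (length(choice) == 1L) choice else sample(choice, 1L)
    counts[labels[i]] <- counts[labels[i]] - 1L
    prev <- labels[i]
  }
  period <- cue_duration_s + recall_duration_s + inter_trial_gap_s
  cue_onset <- start_s + (seq_len(n) - 1) * period
  data.frame(
    trial_index = seq_len(n),
    class_label = labels,
    cue_onset_s = cue_onset,
    recall_onset_s = cue_onset + cue_duration_s
  )
}

#' Simulate button-press and rating behaviour for a schedule
#'
#' Adds a press latency (seconds from recall onset) and two 1-5 ratings
#' (vividness and accuracy) to each trial.  A fraction \code{exclusion_rate}
#' of trials is made excludable by one of the three mechanisms used at
#' trial screening, chosen uniformly at random: a premature press
#' (latency < 5.5 s), a late or missing press (> 10 s), or a rating below 3.
#' All remaining trials have latency in [5.5, 10] s and both ratings >= 3.
#'
#' @param schedule trial table from [make_schedule()].
#' @param exclusion_rate probability in [0, 1) that a trial is excludable.
#' @param seed integer RNG seed.
#' @return the schedule with columns \code{press_latency_s} (NA = no press),
#'   \code{vividness}, \code{accuracy} appended.
#' @export
simulate_behaviour <- function(schedule, exclusion_rate, seed) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1)
  if (exclusion_rate < 0 || exclusion_rate >= 1)
    stop("exclusion_rate must be in [0, 1)")
  n <- nrow(schedule)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  excl <- runif(n) < exclusion_rate
  mech <- sample(c("too_fast", "too_slow", "low_rating"), n, replace = TRUE)
  lat <- runif(n, 5.5, 10)
  viv <- sample(3:5, n, replace = TRUE, prob = c(0.25, 0.4, 0.35))
  acc <- sample(3:5, n, replace = TRUE, prob = c(0.25, 0.4, 0.35))
  for (i in which(excl)) {
    if (mech[i] == "too_fast") {
      lat[i] <- runif(1, 3, 5.4)
    } else if (mech[i] == "too_slow") {
      # half late presses, half no press at all
      lat[i] <- if (runif(1) < 0.5) runif(1, 10.1, 12) else NA_real_
    } else {
      if (runif(1) < 0.5) viv[i] <- sample(1:2, 1) else acc[i] <- sample(1:2, 1)
    }
  }
  schedule$press_latency_s <- lat
  schedule$vividness <- viv
  schedule$accuracy <- acc
  schedule
}

# Preserve the caller's RNG state around seeded sections.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
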