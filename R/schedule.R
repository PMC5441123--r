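#' Build a motor-imagery training trial schedule
#'
#' Reproduces the cue protocol of a standard four-class MI training session:
#' each run presents every class cue `reps_per_class` times in a seeded random
#' order; each trial is a blank interval followed by an imagery interval.
#' With the default configuration of 2 sessions x 2 runs x 15 repetitions the
#' schedule holds 240 trials, 60 per class.
#'
#' @param n_sessions Number of recording sessions (>= 1).
#' @param runs_per_session Runs per session (>= 1).
#' @param reps_per_class Cue repetitions per class within one run (>= 1).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param blank_s Blank interval before each cue, seconds (default 2).
#' @param mi_s Imagery interval per trial, seconds (default 4).
#'
#' @return An object of class `"trial_schedule"`: a list with `entries`
#'   (data frame with columns `session`, `run`, `trial_index`, `mi_class`,
#'   `onset_s` -- onset of the imagery interval on a continuous timeline),
#'   `blank_s`, `mi_s` and `classes`.
#' @export
#' @examples
#' sch <- build_schedule(2, 2, 15, seed = 1)
#' nrow(sch$entries)          # 240
#' table(sch$entries$mi_class)  # 60 each
build_schedule <- function(n_sessions, runs_per_session, reps_per_class, seed,
                           blank_s = 2, mi_s = 4) {
  n_sessions <- check_count(n_sessions, "n_sessions")
  runs_per_session <- check_count(runs_per_session, "runs_per_session")
  reps_per_class <- check_count(reps_per_class, "reps_per_class")
  blank_s <- check_number(blank_s, "blank_s", lower = 0)
  mi_s <- check_number(mi_s, "mi_s", lower = .Machine$double.eps)
  classes <- mi_classes()
  trial_len <- blank_s + mi_s
  entries <- with_seed(seed, {
    rows <- list()
    t0 <- 0
    for (s in seq_len(n_sessions)) {
      for (r in seq_len(runs_per_session)) {
        order <- sample(rep(classes, reps_per_class))
        rows[[length(rows) + 1L]] <- data.frame(
          session = s, run = r, trial_index = seq_along(order),
          mi_class = order,
          onset_s = t0 + (seq_along(order) - 1) * trial_len + blank_s,
          stringsAsFactors = FALSE)
        t0 <- t0 + length(order) * trial_len
      }
    }
    do.call(rbind, rows)
  })
  structure(list(entries = entries, blank_s = blank_s, mi_s = mi_s,
                 classes = classes),
            class = "trial_schedule")
}

## total recorded duration implied by a schedule (seconds)
schedule_duration <- function(schedule) {
  max(schedule$entries$onset_s) + schedule$mi_s
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d trials (%s), blank %gs + MI %gs\n",
              nrow(x$entries),
              paste(sprintf("%s: %d", names(table(x$entries$mi_class)),
                            table(x$entries$mi_class)), collapse = ", "),
              x$blank_s, x$mi_s))
  invisible(x)
}
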