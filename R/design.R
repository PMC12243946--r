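# Experiment design: the 16-condition delayed match-to-sample task with
# distractor streams during the memory delay, and its per-run event schedule.

# fixed trial timing (seconds from trial onset)
.TRIAL <- list(
  fixation_on  = 0.0,  fixation_dur  = 0.5,
  target_on    = 0.5,  target_dur    = 0.5,
  early_delay  = 1.0,  early_dur     = 1.5,
  delay_on     = 2.5,  delay_dur     = 10.0,
  probe_on     = 12.5, probe_dur     = 2.5,
  total        = 15.0,
  n_distractor_images = 20L,
  image_dur    = 0.3,  image_gap     = 0.2,
  n_exemplars  = 10L
)

.TR <- 0.8
.RUN_EDGE_BLANK <- 8
.N_LONG_BLANKS <- 3L
.N_SHORT_BLANKS <- 12L
.LONG_BLANK <- 8
.SHORT_BLANK <- 2

#' The four object categories
#'
#' Returns the object categories used as memory targets and delay-period
#' distractors, in their stable enumeration order (used everywhere pairs of
#' objects are enumerated).
#'
#' @return Character vector of length 4.
#' @export
vwm_objects <- function() c("bike", "couch", "hanger", "shoe")

#' Enumerate the 16 trial conditions
#'
#' The condition roster crosses 4 target objects with the 3 possible
#' distractor objects (target and distractor always differ), giving 12
#' with-distractor conditions, followed by the 4 no-distractor conditions.
#'
#' @return A data frame with columns `condition` (integer 1..16), `target`,
#'   and `distractor` (`NA` for the no-distractor conditions).
#' @export
#' @examples
#' vwm_conditions()
vwm_conditions <- function() {
  obj <- vwm_objects()
  tgt <- rep(obj, each = 3L)
  dst <- unlist(lapply(obj, function(o) setdiff(obj, o)))
  data.frame(
    condition  = seq_len(16L),
    target     = c(tgt, obj),
    distractor = c(dst, rep(NA_character_, 4L)),
    stringsAsFactors = FALSE
  )
}

condition_index <- function(target, distractor = NA_character_) {
  cond <- vwm_conditions()
  hit <- cond$target == target &
    (is.na(cond$distractor) & is.na(distractor) |
       !is.na(cond$distractor) & !is.na(distractor) & cond$distractor == distractor)
  idx <- cond$condition[which(hit)]
  if (length(idx) != 1L) stopf("no such condition: target=%s distractor=%s", target, distractor)
  idx
}

# distractor exemplar order: 10 unique exemplars, each shown twice, no
# back-to-back repeat; rejection sampling with a bounded number of attempts
sample_exemplar_order <- function(max_attempts = 1000L) {
  pool <- rep(seq_len(.TRIAL$n_exemplars), 2L)
  for (i in seq_len(max_attempts)) {
    s <- sample(pool)
    if (all(diff(s) != 0L)) return(s)
  }
  stopf("failed to draw a no-repeat exemplar order in %d attempts", max_attempts)
}

#' Build a fully timed run schedule
#'
#' Lays out one run of the task: an 8 s blank, 16 trials of 15 s (one per
#' condition), 15 intertrial blanks (3 of 8 s and 12 of 2 s), and a closing
#' 8 s blank, for a total of 304 s.  Each trial contains a 0.5 s fixation cue,
#' a 0.5 s target, a 1.5 s early delay, a 10 s delay that is either blank or
#' filled with 20 distractor images (0.3 s image + 0.2 s gap; 10 exemplars
#' shown twice each, never back-to-back), and a 2.5 s probe.
#'
#' @param condition_order Integer permutation of 1..16 giving the trial order.
#' @param blank_durations Numeric vector of the 15 intertrial blank durations
#'   (three 8 s and twelve 2 s entries in any order), or `NULL` to place the
#'   long blanks at random.
#' @param seed Integer seed driving the distractor exemplar orders, the probe
#'   match/non-match assignment and, when unspecified, `condition_order` and
#'   `blank_durations`.  Equal seeds give identical schedules.
#' @return A `vwm_schedule`: a data frame of events with columns `onset`,
#'   `duration`, `trial_type`, `trial`, `condition`, `target`, `distractor`,
#'   `exemplar`, `probe_match`, and attribute `tr_seconds = 0.8`.
#' @seealso [random_run_schedule()], [round_onsets_to_tr()]
#' @export
build_run_schedule <- function(condition_order = seq_len(16L),
                               blank_durations = NULL,
                               seed = NULL) {
  if (length(condition_order) == 0L) stopf("condition_order is empty")
  if (!setequal(condition_order, seq_len(16L)) || length(condition_order) != 16L) {
    stopf("condition_order must be a permutation of 1..16")
  }
  with_seed(seed, {
    if (is.null(blank_durations)) {
      blank_durations <- rep(.SHORT_BLANK, .N_LONG_BLANKS + .N_SHORT_BLANKS)
      blank_durations[sample(length(blank_durations), .N_LONG_BLANKS)] <- .LONG_BLANK
    }
    if (length(blank_durations) != 15L ||
        sum(blank_durations == .LONG_BLANK) != .N_LONG_BLANKS ||
        sum(blank_durations == .SHORT_BLANK) != .N_SHORT_BLANKS) {
      stopf("blank_durations must hold three 8 s and twelve 2 s blanks")
    }
    cond <- vwm_conditions()
    acc <- new.env(parent = emptyenv())
    acc$onset <- numeric(0); acc$duration <- numeric(0); acc$trial_type <- character(0)
    acc$trial <- integer(0); acc$condition <- integer(0); acc$target <- character(0)
    acc$distractor <- character(0); acc$exemplar <- integer(0); acc$probe_match <- logical(0)
    add <- function(onset, duration, type, trial = NA_integer_, condition = NA_integer_,
                    target = NA_character_, distractor = NA_character_,
                    exemplar = NA_integer_, probe_match = NA) {
      n <- length(onset)
      acc$onset <- c(acc$onset, onset)
      acc$duration <- c(acc$duration, rep_len(duration, n))
      acc$trial_type <- c(acc$trial_type, rep_len(type, n))
      acc$trial <- c(acc$trial, rep_len(trial, n))
      acc$condition <- c(acc$condition, rep_len(condition, n))
      acc$target <- c(acc$target, rep_len(target, n))
      acc$distractor <- c(acc$distractor, rep_len(distractor, n))
      acc$exemplar <- c(acc$exemplar, rep_len(exemplar, n))
      acc$probe_match <- c(acc$probe_match, rep_len(probe_match, n))
    }
    t <- 0
    add(t, .RUN_EDGE_BLANK, "run_blank"); t <- t + .RUN_EDGE_BLANK
    for (i in seq_len(16L)) {
      ci <- condition_order[i]
      tg <- cond$target[ci]; ds <- cond$distractor[ci]
      t0 <- t
      add(t0 + .TRIAL$fixation_on, .TRIAL$fixation_dur, "fixation", i, ci, tg, ds)
      add(t0 + .TRIAL$target_on, .TRIAL$target_dur, "target", i, ci, tg, ds)
      add(t0 + .TRIAL$early_delay, .TRIAL$early_dur, "blank_delay", i, ci, tg, ds)
      if (is.na(ds)) {
        add(t0 + .TRIAL$delay_on, .TRIAL$delay_dur, "blank_delay", i, ci, tg, ds)
      } else {
        ex <- sample_exemplar_order()
        step <- .TRIAL$image_dur + .TRIAL$image_gap
        k <- seq_len(.TRIAL$n_distractor_images)
        add(t0 + .TRIAL$delay_on + (k - 1L) * step, .TRIAL$image_dur,
            "distractor_image", i, ci, tg, ds, exemplar = ex)
      }
      add(t0 + .TRIAL$probe_on, .TRIAL$probe_dur, "probe", i, ci, tg, ds,
          probe_match = runif(1) < 0.5)
      t <- t0 + .TRIAL$total
      if (i < 16L) {
        add(t, blank_durations[i], "intertrial_blank"); t <- t + blank_durations[i]
      }
    }
    add(t, .RUN_EDGE_BLANK, "run_blank")
    ev <- data.frame(
      onset = acc$onset, duration = acc$duration, trial_type = acc$trial_type,
      trial = acc$trial, condition = acc$condition, target = acc$target,
      distractor = acc$distractor, exemplar = acc$exemplar,
      probe_match = acc$probe_match, stringsAsFactors = FALSE)
    structure(ev, tr_seconds = .TR, class = c("vwm_schedule", "data.frame"))
  })
}

#' Draw a random run schedule
#'
#' Convenience wrapper around [build_run_schedule()] with a seeded uniform
#' random condition order and random placement of the three long intertrial
#' blanks.
#'
#' @param seed Integer seed; equal seeds give identical schedules.
#' @return A `vwm_schedule`.
#' @export
random_run_schedule <- function(seed) {
  ord <- with_seed(seed, sample(16L))
  build_run_schedule(ord, blank_durations = NULL, seed = child_seed(seed, 1L))
}

#' Total run duration in seconds
#' @param schedule A `vwm_schedule`.
#' @return Scalar seconds (304 for the canonical design).
#' @export
run_duration <- function(schedule) max(schedule$onset + schedule$duration)

#' Round trial onsets to the TR grid
#'
#' Trial onsets are jittered with respect to the 0.8 s TR because the
#' intertrial blanks are not TR multiples; before FIR modelling each trial is
#' shifted so its onset lies on the nearest TR (exact half-TR ties round up).
#' All events within a trial move together, so event order and within-trial
#' timing are preserved.  Idempotent.
#'
#' @param schedule A `vwm_schedule`.
#' @return A `vwm_schedule` with every trial onset an integer multiple of
#'   `tr_seconds`.
#' @export
round_onsets_to_tr <- function(schedule) {
  tr <- attr(schedule, "tr_seconds") %||% .TR
  if (tr <= 0) stopf("tr_seconds must be positive")
  for (i in unique(schedule$trial[!is.na(schedule$trial)])) {
    sel <- !is.na(schedule$trial) & schedule$trial == i
    onset <- min(schedule$onset[sel])
    # round half up, with a small tolerance against binary representation of
    # decimal onsets
    k <- floor(onset / tr + 0.5 + 1e-9)
    schedule$onset[sel] <- schedule$onset[sel] + (k * tr - onset)
  }
  schedule
}

trial_onsets <- function(schedule) {
  ev <- schedule[!is.na(schedule$trial), , drop = FALSE]
  on <- tapply(ev$onset, ev$trial, min)
  cd <- tapply(ev$condition, ev$trial, function(x) x[1L])
  data.frame(trial = as.integer(names(on)), onset = as.numeric(on),
             condition = as.integer(cd))
}

#' @export
print.vwm_schedule <- function(x, ...) {
  cat(sprintf("<vwm_schedule> %d events, %d trials, %.0f s (TR = %.1f s)\n",
              nrow(x), length(unique(x$trial[!is.na(x$trial)])),
              run_duration(x), attr(x, "tr_seconds")))
  invisible(x)
}

#' A two-session scan plan
#'
#' @param runs_per_session Integer vector of length 2, e.g. `c(13, 14)` (the
#'   canonical plan) or `c(14, 14)`.  Sessions with fewer than 10 runs make the
#'   odd/even split-combination plan ill-posed and trigger a warning.
#' @param seed Integer seed attached to the plan.
#' @return A `vwm_session_plan`.
#' @export
vwm_session_plan <- function(runs_per_session = c(13L, 14L), seed = 1L) {
  if (length(runs_per_session) != 2L || !all(vapply(runs_per_session, is_count, TRUE))) {
    stopf("runs_per_session must be two positive integers")
  }
  if (any(runs_per_session < 10L)) {
    warnf("sessions with fewer than 10 runs make the odd/even split plan ill-posed")
  }
  structure(list(runs_per_session = as.integer(runs_per_session), seed = as.integer(seed)),
            class = "vwm_session_plan")
}

#' @export
print.vwm_session_plan <- function(x, ...) {
  cat(sprintf("<vwm_session_plan> sessions of %s runs (seed %d)\n",
              paste(x$runs_per_session, collapse = " + "), x$seed))
  invisible(x)
}
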