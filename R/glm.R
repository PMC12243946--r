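# FIR beta-series estimation.
#
# Because every condition appears exactly once per run and intertrial gaps are
# short relative to the hemodynamic lag, FIR amplitudes cannot be estimated
# from a single run.  Runs are therefore split into odd and even halves within
# each scan session, and within each half a GLM is fit jointly to each
# leave-one-run-out combination of runs (plus the all-runs combination when the
# half has six runs or fewer), giving 7 dependent patterns per split and 28
# patterns per condition and lag in total for the canonical 13 + 14 run plan.
# Patterns from different splits come from disjoint runs and are independent.

# 1-based TR row hit by each (condition, lag) column of the FIR design for one
# run; NA where the lag falls beyond the end of the run.  Columns are ordered
# lag-within-condition.
fir_rows <- function(schedule, n_lags = n_lags_default(), n_tr = NULL) {
  tr <- attr(schedule, "tr_seconds") %||% .TR
  if (is.null(n_tr)) n_tr <- as.integer(round(run_duration(schedule) / tr))
  ons <- trial_onsets(schedule)
  o <- round(ons$onset / tr)
  if (any(abs(ons$onset / tr - o) > 1e-6)) {
    stopf("trial onsets are not on the TR grid; call round_onsets_to_tr() first")
  }
  rows <- rep(NA_integer_, 16L * n_lags)
  for (i in seq_len(nrow(ons))) {
    ci <- ons$condition[i]
    idx <- (ci - 1L) * n_lags + seq_len(n_lags)
    rr <- as.integer(o[i]) + seq_len(n_lags)  # onset TR is row o + 1
    rr[rr > n_tr] <- NA_integer_
    rows[idx] <- rr
  }
  rows
}

# Dense FIR design matrix (TRs x 16 * n_lags); used for diagnostics and as the
# reference in tests.
fir_design_matrix <- function(schedule, n_lags = n_lags_default(), n_tr = NULL) {
  rows <- fir_rows(schedule, n_lags, n_tr)
  tr <- attr(schedule, "tr_seconds") %||% .TR
  if (is.null(n_tr)) n_tr <- as.integer(round(run_duration(schedule) / tr))
  X <- matrix(0, n_tr, length(rows))
  ok <- !is.na(rows)
  X[cbind(rows[ok], which(ok))] <- 1
  colnames(X) <- fir_column_names(n_lags)
  X
}

fir_column_names <- function(n_lags = n_lags_default()) {
  sprintf("c%02d_l%02d", rep(seq_len(16L), each = n_lags),
          rep(seq_len(n_lags) - 1L, times = 16L))
}

#' Remove linear and quadratic trends from a run
#'
#' Per vertex, the best-fitting mean + linear + quadratic polynomial of TR
#' index is subtracted, leaving each vertex's series with zero mean and no
#' low-order trend.
#'
#' @param x A `vwm_run` or plain matrix, vertices x TRs (>= 4 TRs).
#' @return The detrended matrix, with attributes preserved.
#' @export
detrend <- function(x) {
  n <- ncol(x)
  if (n < 4L) stopf("detrending needs at least 4 TRs (got %d)", n)
  t <- seq_len(n)
  Q <- qr.Q(qr(cbind(1, t, t^2)))
  out <- x - (x %*% Q) %*% t(Q)
  for (nm in c("tr_seconds", "schedule")) {
    if (!is.null(attr(x, nm))) attr(out, nm) <- attr(x, nm)
  }
  class(out) <- class(x)
  out
}

#' Build the odd/even split and run-combination plan
#'
#' Runs are split into odd and even halves by run index within each session
#' (the odd half takes the extra run when the count is odd).  A half with
#' seven runs contributes its seven 6-run combinations; a half with six runs
#' contributes its six 5-run combinations plus the all-6 combination — seven
#' combinations per split either way, and 28 in total for 13 + 14 or
#' 14 + 14 run plans.  The same leave-one-out rule generalizes to other run
#' counts (with a warning); halves with fewer than two runs are an error.
#'
#' @param runs_per_session Integer vector of length 2.
#' @return A `vwm_split_plan`: a list of 4 splits, each with `session`,
#'   `half`, `runs` (run ids) and `combinations` (list of run-id vectors).
#' @export
#' @examples
#' plan <- build_split_plan(c(13, 14))
#' sum(lengths(lapply(plan$splits, `[[`, "combinations")))  # 28
build_split_plan <- function(runs_per_session) {
  if (length(runs_per_session) != 2L) stopf("expected run counts for exactly two sessions")
  if (!all(runs_per_session %in% c(13L, 14L))) {
    warnf("split plan is calibrated for 13- or 14-run sessions; generalizing the leave-one-out rule to %s",
          paste(runs_per_session, collapse = " + "))
  }
  splits <- list()
  for (s in seq_len(2L)) {
    ids <- sprintf("s%d_r%02d", s, seq_len(runs_per_session[s]))
    for (half in c("odd", "even")) {
      sel <- if (half == "odd") seq(1L, length(ids), by = 2L) else seq(2L, length(ids), by = 2L)
      runs <- ids[sel]
      n <- length(runs)
      if (n < 2L) stopf("session %d %s half has %d run(s); need at least 2", s, half, n)
      combos <- lapply(seq_len(n), function(i) runs[-i])
      if (n <= 6L) combos <- c(combos, list(runs))
      splits[[length(splits) + 1L]] <- list(
        session = s, half = half, runs = runs, combinations = combos)
    }
  }
  structure(list(splits = splits, runs_per_session = as.integer(runs_per_session)),
            class = "vwm_split_plan")
}

#' @export
print.vwm_split_plan <- function(x, ...) {
  n <- vapply(x$splits, function(s) length(s$combinations), integer(1))
  cat(sprintf("<vwm_split_plan> %s runs; 4 splits with %s combinations (%d patterns)\n",
              paste(x$runs_per_session, collapse = " + "),
              paste(n, collapse = "/"), sum(n)))
  invisible(x)
}

n_split_patterns <- function(plan) {
  sum(vapply(plan$splits, function(s) length(s$combinations), integer(1)))
}

#' Fit the FIR GLM to a combination of runs
#'
#' Ordinary least squares, per vertex, on the runs fit jointly: the stacked
#' design holds the 480 condition-lag indicator regressors (30 lags x 16
#' conditions, shared across runs) plus one intercept per run as nuisance.
#' Runs should be detrended first; no prewhitening is applied.
#'
#' @param runs List of detrended matrices (vertices x TRs), one per run.
#' @param schedules List of the matching TR-grid `vwm_schedule`s.
#' @param n_lags Number of FIR lags per condition (default 30, i.e. 24 s).
#' @return Matrix vertices x `16 * n_lags` of beta estimates, columns ordered
#'   lag-within-condition and named `c<condition>_l<lag>`.
#' @export
fit_fir_glm <- function(runs, schedules, n_lags = n_lags_default()) {
  if (length(runs) != length(schedules)) stopf("runs and schedules differ in length")
  if (length(runs) < 1L) stopf("no runs supplied")
  if (length(runs) == 1L) {
    warnf("FIR amplitudes cannot be reliably estimated from a single run; combine several runs")
  }
  V <- nrow(runs[[1L]])
  p <- 16L * n_lags
  R <- length(runs)
  A <- matrix(0, p + R, p + R)
  b <- matrix(0, p + R, V)
  for (k in seq_len(R)) {
    y <- runs[[k]]
    if (nrow(y) != V) stopf("run %d has %d vertices; expected %d", k, nrow(y), V)
    n_tr <- ncol(y)
    r <- fir_rows(schedules[[k]], n_lags, n_tr)
    ok <- which(!is.na(r))
    rv <- r[ok]
    # each column carries at most one event per run, so the stimulus block of
    # X'X for this run is the row-coincidence indicator
    A[ok, ok] <- A[ok, ok] + outer(rv, rv, "==")
    A[ok, p + k] <- A[ok, p + k] + 1
    A[p + k, ok] <- A[p + k, ok] + 1
    A[p + k, p + k] <- n_tr
    yt <- t(y)
    b[ok, ] <- b[ok, ] + yt[rv, , drop = FALSE]
    b[p + k, ] <- b[p + k, ] + rowSums(y)
  }
  betas <- solve_fir_system(A, b, p, R, n_lags)
  colnames(betas) <- fir_column_names(n_lags)
  betas
}

# Solve the normal equations A coef = b, dropping stimulus columns that were
# never observed (a late lag can fall beyond the end of every run of a
# combination when the same condition ends them all); their betas are NA.
# Rank deficiency among observed columns is an error naming the columns.
solve_fir_system <- function(A, b, p, R, n_lags) {
  observed <- diag(A)[seq_len(p)] > 0
  keep <- c(which(observed), p + seq_len(R))
  if (!all(observed)) {
    warnf("%d condition-lag regressor(s) fall beyond the end of every run in this combination; their betas are NA",
          sum(!observed))
  }
  ch <- tryCatch(chol(A[keep, keep, drop = FALSE]), error = function(e) NULL)
  if (is.null(ch)) {
    labels <- c(fir_column_names(n_lags), sprintf("run%d_intercept", seq_len(R)))[keep]
    qa <- qr(A[keep, keep, drop = FALSE])
    bad <- if (qa$rank < length(keep)) {
      labels[qa$pivot[seq(qa$rank + 1L, length(keep))]]
    } else {
      "(numerically singular)"
    }
    stopf("FIR design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  coef <- backsolve(ch, forwardsolve(t(ch), b[keep, , drop = FALSE]))
  full <- matrix(NA_real_, p, ncol(b))
  full[observed, ] <- coef[seq_len(sum(observed)), , drop = FALSE]
  t(full)
}

new_vwm_patterns <- function(arr, split, combination, roi) {
  stopifnot(length(dim(arr)) == 4L, dim(arr)[4L] == length(split))
  structure(arr, split = as.integer(split), combination = combination,
            roi = roi, class = "vwm_patterns")
}

#' @export
print.vwm_patterns <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vwm_patterns> ROI %s: %d vertices x %d conditions x %d lags x %d patterns (splits of %s)\n",
              attr(x, "roi"), d[1L], d[2L], d[3L], d[4L],
              paste(tabulate(attr(x, "split")), collapse = "/")))
  invisible(x)
}

#' Assemble ROI beta patterns across all run combinations
#'
#' Restricts per-combination beta estimates to an ROI and stacks them into the
#' pattern set used for decoding: for the canonical plan, 28 patterns (7 per
#' split) per condition and lag.
#'
#' @param fits Named list of beta matrices from [fit_fir_glm()], one per
#'   combination, named `split<k>_comb<j>`; the helper
#'   [participant_patterns()] builds this for you.
#' @param plan The `vwm_split_plan` the fits follow.
#' @param roi Integer vector of vertex indices (1-based) forming the ROI.
#' @param roi_name Label stored with the patterns.
#' @return A `vwm_patterns` array, vertices x 16 x lags x patterns, with the
#'   originating split of each pattern in `attr(, "split")`.
#' @export
assemble_patterns <- function(fits, plan, roi, roi_name = "ROI") {
  if (length(roi) < 1L) stopf("empty ROI")
  ids <- combo_ids(plan)
  missing <- setdiff(ids$id, names(fits))
  if (length(missing) > 0L) stopf("missing fitted combinations: %s", paste(missing, collapse = ", "))
  n_lags <- ncol(fits[[ids$id[1L]]]) / 16L
  if (any(roi > nrow(fits[[ids$id[1L]]]) | roi < 1L)) stopf("ROI vertex index out of range")
  arr <- array(0, dim = c(length(roi), 16L, n_lags, nrow(ids)))
  for (j in seq_len(nrow(ids))) {
    B <- fits[[ids$id[j]]][roi, , drop = FALSE]
    arr[, , , j] <- aperm(array(B, dim = c(length(roi), n_lags, 16L)), c(1L, 3L, 2L))
  }
  new_vwm_patterns(arr, split = ids$split, combination = ids$id, roi = roi_name)
}

combo_ids <- function(plan) {
  out <- list()
  for (s in seq_along(plan$splits)) {
    combos <- plan$splits[[s]]$combinations
    for (j in seq_along(combos)) {
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("split%d_comb%d", s, j), split = s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Estimate all combination GLMs for one participant
#'
#' Detrends every run, fits the FIR GLM for each run combination of the split
#' plan (jointly over each combination's runs), and assembles the ROI pattern
#' sets.
#'
#' @param participant A `vwm_participant`.
#' @param rois Named list of integer vertex-index vectors.
#' @param n_lags Number of FIR lags (default 30).
#' @return Named list of `vwm_patterns`, one per ROI.
#' @export
participant_patterns <- function(participant, rois, n_lags = n_lags_default()) {
  plan <- suppressWarnings(build_split_plan(participant$plan$runs_per_session))
  det <- lapply(participant$runs, detrend)
  fits <- fit_fir_glm_multi(det, participant$schedules, plan, n_lags)
  lapply_named(rois, function(roi, nm) assemble_patterns(fits, plan, roi, roi_name = nm))
}

# Fit every combination of the split plan, sharing the per-run design
# cross-products across the leave-one-run-out combinations; algebraically
# identical to calling fit_fir_glm() per combination.
fit_fir_glm_multi <- function(runs, schedules, plan, n_lags = n_lags_default()) {
  p <- 16L * n_lags
  V <- nrow(runs[[1L]])
  pre <- lapply(names(runs), function(id) {
    y <- runs[[id]]
    n_tr <- ncol(y)
    r <- fir_rows(schedules[[id]], n_lags, n_tr)
    ok <- which(!is.na(r)); rv <- r[ok]
    E <- matrix(0, p, p)
    E[ok, ok] <- outer(rv, rv, "==")
    bs <- matrix(0, p, V)
    bs[ok, ] <- t(y)[rv, , drop = FALSE]
    list(ok = ok, E = E, bs = bs, rs = rowSums(y), n_tr = n_tr)
  })
  names(pre) <- names(runs)
  fits <- list()
  for (s in seq_along(plan$splits)) {
    combos <- plan$splits[[s]]$combinations
    for (j in seq_along(combos)) {
      cids <- combos[[j]]
      R <- length(cids)
      A <- matrix(0, p + R, p + R)
      b <- matrix(0, p + R, V)
      for (k in seq_len(R)) {
        pk <- pre[[cids[k]]]
        A[1:p, 1:p] <- A[1:p, 1:p] + pk$E
        A[pk$ok, p + k] <- 1
        A[p + k, pk$ok] <- 1
        A[p + k, p + k] <- pk$n_tr
        b[1:p, ] <- b[1:p, ] + pk$bs
        b[p + k, ] <- pk$rs
      }
      betas <- solve_fir_system(A, b, p, R, n_lags)
      colnames(betas) <- fir_column_names(n_lags)
      fits[[sprintf("split%d_comb%d", s, j)]] <- betas
    }
  }
  fits
}

lapply_named <- function(x, f) {
  out <- lapply(seq_along(x), function(i) f(x[[i]], names(x)[i] %||% as.character(i)))
  names(out) <- names(x)
  out
}

period_windows <- function() {
  list(encoding = c(4.0, 6.4), delay = c(9.6, 12.0))
}

period_lags <- function(period = c("encoding", "delay"), tr = 0.8,
                        n_lags = n_lags_default()) {
  period <- match.arg(period)
  w <- period_windows()[[period]]
  lag_t <- (seq_len(n_lags) - 1L) * tr
  which(lag_t >= w[1L] - 1e-9 & lag_t <= w[2L] + 1e-9)
}

#' Average beta patterns within a trial period
#'
#' The encoding period covers post-onset times 4–6.4 s and the delay period
#' 9.6–12 s (both inclusive); at TR 0.8 s each selects exactly four FIR lags,
#' which are averaged arithmetically.
#'
#' @param patterns A `vwm_patterns` array.
#' @param period `"encoding"` or `"delay"`.
#' @return A 3-d array, vertices x conditions x patterns, with attributes
#'   `period`, `lags` (the 0-based lags averaged) and `split`.
#' @export
average_period <- function(patterns, period = c("encoding", "delay")) {
  period <- match.arg(period)
  lags <- period_lags(period, n_lags = dim(patterns)[3L])
  if (length(lags) == 0L) stopf("no lags fall inside the %s window", period)
  d <- dim(patterns)
  acc <- array(0, dim = d[c(1L, 2L, 4L)])
  for (l in lags) acc <- acc + array(patterns[, , l, ], dim = d[c(1L, 2L, 4L)])
  out <- acc / length(lags)
  structure(out, period = period, lags = lags - 1L, split = attr(patterns, "split"),
            roi = attr(patterns, "roi"))
}

#' ROI-mean response time course per condition
#'
#' Averages beta weights over all vertices and all patterns, yielding one
#' amplitude-by-lag curve per condition — the diagnostic used to place the
#' encoding and delay windows.
#'
#' @param patterns A `vwm_patterns` array.
#' @return Data frame with columns `condition`, `target`, `distractor`, `lag`,
#'   `time_s`, `amplitude`.
#' @export
roi_mean_timecourse <- function(patterns) {
  tc <- apply(patterns, c(2L, 3L), mean, na.rm = TRUE)
  cond <- vwm_conditions()
  n_lags <- ncol(tc)
  data.frame(
    condition = rep(cond$condition, times = n_lags),
    target = rep(cond$target, times = n_lags),
    distractor = rep(cond$distractor, times = n_lags),
    lag = rep(seq_len(n_lags) - 1L, each = 16L),
    time_s = rep((seq_len(n_lags) - 1L) * .TR, each = 16L),
    amplitude = as.vector(tc),
    stringsAsFactors = FALSE
  )
}
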