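# Synthetic vertex time series with a controllable representational geometry.
#
# The generator realizes the hypothesis space the cross-decoding analysis is
# built to probe: every object category has a perceptual population code
# (driving responses whenever the object is on screen, whether as target or
# distractor) and a memory population code (sustained through the delay while
# the object is held in working memory).  The two codes are related by a
# rotation angle theta: theta = 0 means perception and memory share one code,
# theta = pi/2 means the codes are orthogonal.

#' Ground-truth representational geometry
#'
#' Draws, per object category, a perceptual pattern (a random unit vector over
#' vertices) and a memory pattern constructed as
#' `cos(theta) * perceptual + sin(theta) * q`, where `q` is a random unit
#' vector orthogonal to the perceptual pattern.  The inner product between the
#' memory and perceptual pattern of an object is therefore exactly
#' `cos(theta)`.
#'
#' Gains set the amplitude (arbitrary BOLD-like units) of the neural signal
#' attached to each code: `gain_encoding` scales the perceptual pattern of the
#' target while it is on screen, `gain_delay` scales the memory pattern of the
#' target sustained from target offset to probe onset, and `gain_distractor`
#' scales the perceptual pattern of the distractor object during each
#' distractor image.  The defaults put the generator in the regime the task
#' produces in visual cortex: a delay-period distractor signal far stronger
#' than the sustained memory signal (distractor decoding saturates near 1),
#' with memory decoding well above chance but visibly weaker.
#'
#' @param n_vertices Number of surface vertices (>= 8 so that the orthogonal
#'   directions can be drawn; default 200).
#' @param theta Rotation angle between perceptual and memory codes, in
#'   `[0, pi/2]`.
#' @param gain_encoding,gain_delay,gain_distractor Non-negative signal
#'   amplitudes (see above).
#' @param noise_sd Standard deviation of the additive white Gaussian noise per
#'   vertex and TR.
#' @param pattern_mean Strength of the positive baseline component shared by
#'   all patterns (object-evoked BOLD responses are positive on average across
#'   a visually responsive ROI).  The baseline is common to all objects, so
#'   pairwise decoding — which sees only pattern differences after
#'   z-normalization — is unaffected; it makes ROI-mean response time courses
#'   positive and realistic.
#' @param seed Integer seed; equal seeds give identical geometries.
#' @return A `vwm_truth` object: matrices `perceptual` and `memory`
#'   (vertices x 4 objects) plus the parameters.
#' @export
#' @examples
#' tr <- make_ground_truth(50, theta = pi / 2, seed = 1)
#' round(colSums(tr$perceptual * tr$memory), 10)  # cos(theta) per object
make_ground_truth <- function(n_vertices = 200L, theta = 0,
                              gain_encoding = 0.5, gain_delay = 0.5,
                              gain_distractor = 1, noise_sd = 2,
                              pattern_mean = 1, seed = NULL) {
  if (!is_count(n_vertices) || n_vertices < 8) {
    stopf("n_vertices must be an integer >= 8 (got %s)", format(n_vertices))
  }
  if (theta < 0 || theta > pi / 2) stopf("theta must lie in [0, pi/2]")
  gains <- c(gain_encoding, gain_delay, gain_distractor)
  if (any(gains < 0) || noise_sd < 0) stopf("gains and noise_sd must be non-negative")
  obj <- vwm_objects()
  with_seed(seed, {
    unit <- function(v) v / sqrt(sum(v^2))
    P <- matrix(0, n_vertices, 4L, dimnames = list(NULL, obj))
    M <- P
    for (o in seq_len(4L)) {
      p <- unit(rnorm(n_vertices) + pattern_mean)
      # the rotation target q is drawn zero-mean: the positive baseline is a
      # property of the perceptual code, and a biased q would couple the
      # memory code of one object to the perceptual codes of the others
      q <- rnorm(n_vertices)
      q <- unit(q - sum(q * p) * p)
      P[, o] <- p
      M[, o] <- cos(theta) * p + sin(theta) * q
    }
    structure(list(
      n_vertices = as.integer(n_vertices), theta = theta,
      perceptual = P, memory = M,
      gain_encoding = gain_encoding, gain_delay = gain_delay,
      gain_distractor = gain_distractor, noise_sd = noise_sd,
      pattern_mean = pattern_mean
    ), class = "vwm_truth")
  })
}

#' @export
print.vwm_truth <- function(x, ...) {
  cat(sprintf(
    "<vwm_truth> %d vertices, theta = %.3f rad (cos = %.3f)\n  gains: encoding %.3g, delay %.3g, distractor %.3g; noise_sd %.3g\n",
    x$n_vertices, x$theta, cos(x$theta), x$gain_encoding, x$gain_delay,
    x$gain_distractor, x$noise_sd))
  invisible(x)
}

#' Hemodynamic forward model
#'
#' The simulator maps neural amplitude at each TR to BOLD-like signal by
#' discrete convolution with a kernel.  `"double_gamma"` is the standard
#' two-gamma impulse response (positive lobe peaking at `peak_time`, undershoot
#' peaking at `undershoot_time`, peak-to-undershoot amplitude ratio
#' `undershoot_ratio`), sampled at the TR over 24 s and scaled to unit peak.
#' `"fir_identity"` is a single unit tap, so the simulated signal equals the
#' neural amplitude exactly; it exists so that FIR GLM recovery can be tested
#' against ground truth to machine precision.
#'
#' @param kind `"double_gamma"` or `"fir_identity"`.
#' @param tr_seconds Sampling interval (default 0.8).
#' @param peak_time,undershoot_time,undershoot_ratio Double-gamma parameters
#'   in seconds / ratio units.
#' @param length_s Kernel support in seconds (<= 24).
#' @return A `vwm_hemo` object with the sampled `kernel`.
#' @export
hemodynamic_model <- function(kind = c("double_gamma", "fir_identity"),
                              tr_seconds = 0.8, peak_time = 5,
                              undershoot_time = 15, undershoot_ratio = 6,
                              length_s = 24) {
  kind <- match.arg(kind)
  if (length_s > 24) stopf("kernel length must be <= 24 s")
  if (kind == "fir_identity") {
    kernel <- 1
  } else {
    t <- seq(0, length_s - tr_seconds, by = tr_seconds)
    # gamma densities with rate 1 peak at shape - 1
    kernel <- stats::dgamma(t, shape = peak_time + 1, rate = 1) -
      stats::dgamma(t, shape = undershoot_time + 1, rate = 1) / undershoot_ratio
    kernel <- kernel / max(kernel)
  }
  if (!all(is.finite(kernel)) || sum(kernel) <= 0) stopf("kernel must integrate to a positive value")
  structure(list(kind = kind, tr_seconds = tr_seconds, kernel = kernel),
            class = "vwm_hemo")
}

#' @export
print.vwm_hemo <- function(x, ...) {
  cat(sprintf("<vwm_hemo> %s kernel, %d taps at TR %.1f s\n",
              x$kind, length(x$kernel), x$tr_seconds))
  invisible(x)
}

n_lags_default <- function() 30L

# Scalar neural amplitude profiles at lag times l * TR after trial onset, for
# each of the three signal sources; sampled with [start, end) stage intervals.
neural_lag_profiles <- function(n_lags = n_lags_default(), tr = 0.8) {
  t <- (seq_len(n_lags) - 1L) * tr
  enc <- as.numeric(t >= .TRIAL$target_on & t < .TRIAL$target_on + .TRIAL$target_dur)
  mem <- as.numeric(t >= .TRIAL$early_delay & t < .TRIAL$probe_on)
  img_start <- .TRIAL$delay_on + (seq_len(.TRIAL$n_distractor_images) - 1L) *
    (.TRIAL$image_dur + .TRIAL$image_gap)
  img <- vapply(t, function(tt) {
    as.numeric(any(tt >= img_start & tt < img_start + .TRIAL$image_dur))
  }, numeric(1))
  list(encoding = enc, memory = mem, distractor = img)
}

# Convolve a scalar lag profile with the hemodynamic kernel, truncated to the
# n_lags FIR window (trial responses are modelled within the 24 s window).
convolve_profile <- function(profile, kernel, n_lags = length(profile)) {
  out <- numeric(n_lags)
  for (j in seq_along(kernel)) {
    idx <- seq_len(n_lags - j + 1L)
    out[idx + j - 1L] <- out[idx + j - 1L] + kernel[j] * profile[idx]
  }
  out
}

#' Ground-truth FIR lag patterns per condition
#'
#' The expected response of every vertex at each of the 30 FIR lags of each
#' condition, i.e. the condition-lag beta matrix a noiseless GLM should
#' recover.  Columns are ordered lag-within-condition to match
#' [fit_fir_glm()].
#'
#' @param truth A `vwm_truth`.
#' @param hemo A `vwm_hemo`.
#' @param n_lags Number of FIR lags (default 30).
#' @return Matrix `n_vertices x (16 * n_lags)` with attributes `condition` and
#'   `lag` (0-based) per column, and `profiles` holding the convolved scalar
#'   stage profiles.
#' @export
true_lag_betas <- function(truth, hemo, n_lags = n_lags_default()) {
  prof <- neural_lag_profiles(n_lags, hemo$tr_seconds)
  cp <- lapply(prof, convolve_profile, kernel = hemo$kernel, n_lags = n_lags)
  cond <- vwm_conditions()
  B <- matrix(0, truth$n_vertices, 16L * n_lags)
  for (ci in seq_len(16L)) {
    cols <- (ci - 1L) * n_lags + seq_len(n_lags)
    contrib <- truth$perceptual[, cond$target[ci]] %o% (truth$gain_encoding * cp$encoding) +
      truth$memory[, cond$target[ci]] %o% (truth$gain_delay * cp$memory)
    if (!is.na(cond$distractor[ci])) {
      contrib <- contrib +
        truth$perceptual[, cond$distractor[ci]] %o% (truth$gain_distractor * cp$distractor)
    }
    B[, cols] <- contrib
  }
  structure(B,
            condition = rep(seq_len(16L), each = n_lags),
            lag = rep(seq_len(n_lags) - 1L, times = 16L),
            profiles = cp)
}

#' Simulate one run of vertex time series
#'
#' Builds the run's neural signal from the schedule and ground truth (target
#' perceptual response during target presentation, sustained memory response
#' through the delay, distractor perceptual response during each distractor
#' image), convolves it with the hemodynamic kernel, and adds white Gaussian
#' noise and an optional per-vertex linear drift.
#'
#' @param schedule A `vwm_schedule` already on the TR grid
#'   (see [round_onsets_to_tr()]); off-grid trial onsets are an error.
#' @param truth A `vwm_truth`.
#' @param hemo A `vwm_hemo`; its TR must match the schedule's.
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @param drift Half-range of the per-vertex linear drift over the run
#'   (0 disables; drift slopes are uniform on `[-drift, drift]`).
#' @param ar1 AR(1) coefficient for temporally autocorrelated noise
#'   (default 0 = white noise).
#' @return A `vwm_run`: matrix `n_vertices x n_TRs` with attributes
#'   `tr_seconds` and `schedule`.
#' @export
simulate_run <- function(schedule, truth, hemo = hemodynamic_model(),
                         seed = NULL, drift = 0, ar1 = 0, .betas = NULL) {
  tr <- attr(schedule, "tr_seconds") %||% .TR
  if (abs(tr - hemo$tr_seconds) > 1e-9) stopf("schedule TR (%g) and hemodynamic model TR (%g) differ", tr, hemo$tr_seconds)
  ons <- trial_onsets(schedule)
  off <- ons$onset / tr
  if (any(abs(off - round(off)) > 1e-6)) {
    stopf("trial onsets are not on the TR grid; call round_onsets_to_tr() first")
  }
  n_tr <- as.integer(round(run_duration(schedule) / tr))
  n_lags <- n_lags_default()
  B <- .betas %||% true_lag_betas(truth, hemo, n_lags)
  rowsv <- fir_rows(schedule, n_lags = n_lags, n_tr = n_tr)
  sig <- matrix(0, truth$n_vertices, n_tr)
  keep <- !is.na(rowsv)
  if (any(keep)) {
    agg <- rowsum(t(B[, keep, drop = FALSE]), group = rowsv[keep])
    sig[, as.integer(rownames(agg))] <- sig[, as.integer(rownames(agg))] + t(agg)
  }
  with_seed(seed, {
    if (truth$noise_sd > 0) {
      eps <- matrix(stats::rnorm(truth$n_vertices * n_tr, sd = truth$noise_sd),
                    truth$n_vertices, n_tr)
      if (ar1 != 0) {
        eps <- t(apply(eps, 1L, function(e) as.numeric(stats::filter(e, ar1, method = "recursive"))))
      }
      sig <- sig + eps
    }
    if (drift > 0) {
      slope <- stats::runif(truth$n_vertices, -drift, drift)
      sig <- sig + slope %o% seq(0, 1, length.out = n_tr)
    }
    structure(sig, tr_seconds = tr, schedule = schedule, class = "vwm_run")
  })
}

#' @export
print.vwm_run <- function(x, ...) {
  cat(sprintf("<vwm_run> %d vertices x %d TRs (TR = %.1f s)\n",
              nrow(x), ncol(x), attr(x, "tr_seconds")))
  invisible(x)
}

#' Simulate a whole participant
#'
#' Generates one randomized run schedule and one simulated time series per run
#' of the session plan, all driven by a single seed.
#'
#' @param plan A `vwm_session_plan`.
#' @param truth A `vwm_truth` (this participant's geometry).
#' @param hemo A `vwm_hemo`.
#' @param seed Integer seed; equal seeds give identical participants.
#' @param participant_id Identifier stored with the data.
#' @param drift,ar1 Passed to [simulate_run()].
#' @return A `vwm_participant`: lists `runs` and `schedules` named by run id
#'   (`s<session>_r<run>`), plus `plan`, `truth`, and `participant_id`.
#' @export
simulate_participant <- function(plan, truth, hemo = hemodynamic_model(),
                                 seed = 1L, participant_id = "sub-01",
                                 drift = 0, ar1 = 0) {
  stopifnot(inherits(plan, "vwm_session_plan"))
  runs <- list()
  schedules <- list()
  B <- true_lag_betas(truth, hemo)
  k <- 0L
  for (s in seq_along(plan$runs_per_session)) {
    for (r in seq_len(plan$runs_per_session[s])) {
      k <- k + 1L
      id <- sprintf("s%d_r%02d", s, r)
      sch <- round_onsets_to_tr(random_run_schedule(child_seed(seed, 2L * k)))
      schedules[[id]] <- sch
      runs[[id]] <- simulate_run(sch, truth, hemo, seed = child_seed(seed, 2L * k + 1L),
                                 drift = drift, ar1 = ar1, .betas = B)
    }
  }
  structure(list(participant_id = participant_id, plan = plan, truth = truth,
                 hemo = hemo, runs = runs, schedules = schedules),
            class = "vwm_participant")
}

#' @export
print.vwm_participant <- function(x, ...) {
  cat(sprintf("<vwm_participant> %s: %d runs (%s), %d vertices\n",
              x$participant_id, length(x$runs),
              paste(x$plan$runs_per_session, collapse = " + "),
              x$truth$n_vertices))
  invisible(x)
}

#' Zero-signal beta patterns
#'
#' Draws a pattern set identical in shape to [assemble_patterns()] output but
#' containing pure Gaussian noise.  Used to calibrate chance levels and type-I
#' error of the downstream decoding and statistics: any systematic departure
#' from chance on these patterns would mean the pipeline manufactures
#' information.
#'
#' @param n_vertices Number of vertices.
#' @param n_patterns Number of patterns per condition and lag (default 28,
#'   7 per split).
#' @param n_lags Number of FIR lags (default 30).
#' @param sd Noise standard deviation.
#' @param seed Integer seed.
#' @return A `vwm_patterns` object.
#' @export
simulate_null_patterns <- function(n_vertices = 50L, n_patterns = 28L,
                                   n_lags = n_lags_default(), sd = 1, seed = 1L) {
  stopifnot(n_patterns %% 4L == 0L)
  arr <- with_seed(seed, array(stats::rnorm(n_vertices * 16L * n_lags * n_patterns, sd = sd),
                               dim = c(n_vertices, 16L, n_lags, n_patterns)))
  new_vwm_patterns(arr, split = rep(seq_len(4L), each = n_patterns / 4L),
                   combination = sprintf("null%02d", seq_len(n_patterns)),
                   roi = "null")
}
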