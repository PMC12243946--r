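# Lazily built, cached fixtures shared across test files.  Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# independent brute-force step-up definition of the BH adjustment:
# p_adj(i) = min over the step-up set of min(1, m * p(j) / rank(j))
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) m * p[o[j]] / j, numeric(1))
    min(1, min(cand[seq(which(o == i), m)]))
  }, numeric(1))
}

# A small noiseless participant under the identity forward kernel: FIR
# estimates must reproduce the ground-truth lag patterns exactly.
fx_noiseless <- function() {
  fx("noiseless", {
    truth <- make_ground_truth(24, theta = pi / 4, gain_encoding = 0.7,
                               gain_delay = 0.4, gain_distractor = 1.2,
                               noise_sd = 0, seed = 101)
    hemo <- hemodynamic_model("fir_identity")
    plan <- suppressWarnings(vwm_session_plan(c(13L, 14L), seed = 1L))
    part <- simulate_participant(plan, truth, hemo, seed = 102)
    list(truth = truth, hemo = hemo, part = part,
         patterns = participant_patterns(part, list(ALL = 1:24))$ALL)
  })
}

# ground-truth lag patterns reshaped to match the vwm_patterns layout
true_pattern_array <- function(truth, hemo, n_lags = 30L) {
  B <- true_lag_betas(truth, hemo, n_lags)
  aperm(array(B, dim = c(truth$n_vertices, n_lags, 16L)), c(1L, 3L, 2L))
}

# six noiseless identity-kernel runs sharing one small truth, for GLM unit
# tests (tests add their own noise where needed)
fx_small_runs <- function() {
  fx("small_runs", {
    truth <- make_ground_truth(10, theta = 0, noise_sd = 0, seed = 7)
    hemo <- hemodynamic_model("fir_identity")
    scheds <- lapply(1:6, function(k) round_onsets_to_tr(random_run_schedule(200 + k)))
    runs <- lapply(seq_along(scheds), function(k) {
      simulate_run(scheds[[k]], truth, hemo, seed = 300 + k)
    })
    list(truth = truth, hemo = hemo, scheds = scheds, runs = runs)
  })
}

# a deterministic synthetic cohort decoding table (no simulation): accuracies
# with a known drop structure for battery shape tests
fx_fake_decoding <- function() {
  fx("fake_decoding", {
    set.seed(42)
    rois <- c(V1 = "posterior", LOT = "ventral", IPS2 = "dorsal")
    schemes <- data.frame(
      scheme = c("within_target_delay", "cross_distractor_to_target_delay",
                 "within_target_delay", "cross_to_no_distractor_targets"),
      trial_set = c("with_distractors", "with_distractors",
                    "without_distractors", "with_distractors"),
      base = c(0.80, 0.62, 0.78, 0.64), stringsAsFactors = FALSE)
    rows <- list()
    for (p in sprintf("sub-%02d", 1:6)) {
      for (r in names(rois)) {
        for (i in seq_len(nrow(schemes))) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant = p, roi = r, sector = rois[[r]],
            scheme = schemes$scheme[i], trial_set = schemes$trial_set[i],
            irrelevant_match = "same",
            accuracy = schemes$base[i] + rnorm(1, 0, 0.03),
            chance = 0.5, n_instances = 12L, n_train = 21L, n_test = 7L,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("vwm_decoding", "data.frame")
    out
  })
}
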