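# End-to-end driver: simulate -> estimate -> decode -> group statistics.

#' Pipeline configuration
#'
#' Collects every knob of the synthetic cross-decoding study.  All seeds are
#' explicit: the same configuration reproduces the same results bit for bit.
#'
#' @param n_participants Cohort size (>= 3 for the ANOVA battery).
#' @param runs_per_session Runs in each of the two scan sessions (default the
#'   canonical `c(13, 14)`).
#' @param rois Data frame with columns `name`, `sector` (`NA` for none) and
#'   `n_vertices`; each ROI gets its own ground-truth geometry per
#'   participant.
#' @param theta Rotation angle between perceptual and memory codes
#'   (default `pi / 2`, the fully transformed regime).
#' @param gain_encoding,gain_delay,gain_distractor,noise_sd Generator
#'   amplitudes and noise; see [make_ground_truth()].
#' @param hemodynamics `"double_gamma"` (default) or `"fir_identity"`.
#' @param schemes List of `vwm_scheme`s to decode (default
#'   [default_schemes()]).
#' @param alpha Significance level for the battery.
#' @param seed Master integer seed.
#' @return A `vwm_config`.
#' @export
vwm_config <- function(n_participants = 3L,
                       runs_per_session = c(13L, 14L),
                       rois = data.frame(name = c("V1", "LOT", "IPS2"),
                                         sector = c("posterior", "ventral", "dorsal"),
                                         n_vertices = 200L,
                                         stringsAsFactors = FALSE),
                       theta = pi / 2,
                       gain_encoding = 0.5, gain_delay = 0.5,
                       gain_distractor = 1, noise_sd = 2,
                       hemodynamics = "double_gamma",
                       schemes = default_schemes(),
                       alpha = 0.05,
                       seed = NULL) {
  if (is.null(seed)) stopf("a seed is required; all randomness must be reproducible")
  if (!is_count(n_participants)) stopf("n_participants must be a positive integer")
  if (!all(c("name", "sector", "n_vertices") %in% names(rois))) {
    stopf("rois needs columns name, sector, n_vertices")
  }
  cfg <- list(n_participants = as.integer(n_participants),
              runs_per_session = as.integer(runs_per_session),
              rois = rois, theta = theta, gain_encoding = gain_encoding,
              gain_delay = gain_delay, gain_distractor = gain_distractor,
              noise_sd = noise_sd, hemodynamics = hemodynamics,
              schemes = schemes, alpha = alpha, seed = as.integer(seed))
  structure(cfg, class = "vwm_config")
}

#' @export
print.vwm_config <- function(x, ...) {
  cat(sprintf(
    "<vwm_config> %d participants, %s runs, %d ROI(s), theta = %.3f, seed %d\n",
    x$n_participants, paste(x$runs_per_session, collapse = "+"),
    nrow(x$rois), x$theta, x$seed))
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' Schemes are stored by name/trial-set/irrelevant-match so the file
#' round-trips losslessly.
#'
#' @param config A `vwm_config`.
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a `vwm_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$rois <- as.list(as.data.frame(x$rois))
  x$schemes <- lapply(config$schemes, function(s) {
    list(name = s$name, trial_set = s$trial_set, irrelevant_match = s$irrelevant_match)
  })
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  schemes <- lapply(x$schemes, function(s) {
    decoding_scheme(s$name, s$trial_set, s$irrelevant_match)
  })
  vwm_config(
    n_participants = x$n_participants, runs_per_session = x$runs_per_session,
    rois = data.frame(name = x$rois$name, sector = x$rois$sector,
                      n_vertices = x$rois$n_vertices, stringsAsFactors = FALSE),
    theta = x$theta, gain_encoding = x$gain_encoding, gain_delay = x$gain_delay,
    gain_distractor = x$gain_distractor, noise_sd = x$noise_sd,
    hemodynamics = x$hemodynamics, schemes = schemes, alpha = x$alpha,
    seed = x$seed)
}

#' Simulate and analyse one participant
#'
#' Generates the participant's run schedules once (shared by all ROIs), then
#' per ROI draws a ground-truth geometry, simulates every run, estimates the
#' FIR beta patterns under the split plan, and decodes the configured schemes.
#'
#' @param config A `vwm_config`.
#' @param p Participant number (drives the participant's seeds).
#' @param return_patterns Also return the ROI pattern sets (memory-heavy).
#' @return List with `decoding` (a `vwm_decoding` table) and optionally
#'   `patterns`.
#' @export
run_participant <- function(config, p, return_patterns = FALSE) {
  pid <- sprintf("sub-%02d", p)
  pseed <- child_seed(config$seed, 104729L * p)
  plan <- suppressWarnings(vwm_session_plan(config$runs_per_session, seed = pseed))
  hemo <- hemodynamic_model(config$hemodynamics)
  schedules <- list()
  k <- 0L
  for (s in seq_along(plan$runs_per_session)) {
    for (r in seq_len(plan$runs_per_session[s])) {
      k <- k + 1L
      schedules[[sprintf("s%d_r%02d", s, r)]] <-
        round_onsets_to_tr(random_run_schedule(child_seed(pseed, k)))
    }
  }
  sectors <- stats::setNames(config$rois$sector, config$rois$name)
  pats <- list()
  for (i in seq_len(nrow(config$rois))) {
    nv <- config$rois$n_vertices[i]
    truth <- make_ground_truth(nv, config$theta, config$gain_encoding,
                               config$gain_delay, config$gain_distractor,
                               config$noise_sd,
                               seed = child_seed(pseed, 1000L + i))
    B <- true_lag_betas(truth, hemo)
    runs <- list()
    for (j in seq_along(schedules)) {
      runs[[names(schedules)[j]]] <- simulate_run(
        schedules[[j]], truth, hemo,
        seed = child_seed(pseed, 10000L + 100L * i + j), .betas = B)
    }
    part <- structure(list(participant_id = pid, plan = plan, truth = truth,
                           hemo = hemo, runs = runs, schedules = schedules),
                      class = "vwm_participant")
    roi_name <- config$rois$name[i]
    pats[[roi_name]] <- participant_patterns(
      part, stats::setNames(list(seq_len(nv)), roi_name))[[roi_name]]
  }
  dec <- decode_participant(pats, config$schemes, sectors, pid)
  out <- list(decoding = dec)
  if (return_patterns) out$patterns <- pats
  out
}

#' Run the full synthetic cross-decoding study
#'
#' Simulates the cohort, estimates FIR beta patterns, decodes every configured
#' scheme in every ROI, computes cross-decoding ratios, and runs the
#' group-level statistical battery.  When `out_dir` is given, tidy TSV tables,
#' the configuration, and a manifest with MD5 checksums of every output are
#' written there.
#'
#' @param config A `vwm_config`.
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress.
#' @return A `vwm_pipeline` object: `config`, `decoding`, `sector_decoding`,
#'   `stats`, and (when written) `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  dec <- list()
  for (p in seq_len(config$n_participants)) {
    say("[simulate+estimate+decode] participant %d/%d (seed %d)", p,
        config$n_participants, child_seed(config$seed, 104729L * p))
    dec[[p]] <- run_participant(config, p)$decoding
  }
  decoding <- do.call(rbind, dec)
  class(decoding) <- c("vwm_decoding", "data.frame")
  say("[stats] battery over %d participants", config$n_participants)
  stats_report <- run_battery(decoding, alpha = config$alpha)
  sector_dec <- sector_average(decoding)
  out <- structure(list(config = config, decoding = decoding,
                        sector_decoding = sector_dec, stats = stats_report,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   class = "vwm_pipeline")
  if (!is.null(out_dir)) {
    out$manifest <- write_pipeline_outputs(out, out_dir)
  }
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)
  write_config(result$config, p("config.yaml")); paths <- c(paths, p("config.yaml"))
  write_tidy_tsv(as.data.frame(result$decoding), p("decoding.tsv"))
  write_tidy_tsv(result$sector_decoding, p("decoding_sectors.tsv"))
  paths <- c(paths, p("decoding.tsv"), p("decoding_sectors.tsv"))
  st <- result$stats
  for (nm in c("vs_chance_roi", "vs_chance_sector", "drops_roi", "drops_sector",
               "anova_roi", "anova_sector", "sector_pairs")) {
    if (!is.null(st[[nm]])) {
      write_tidy_tsv(st[[nm]], p(paste0(nm, ".tsv"))); paths <- c(paths, p(paste0(nm, ".tsv")))
    }
  }
  if (!is.null(st$ratios$per_participant)) {
    write_tidy_tsv(st$ratios$per_participant, p("ratios_participant.tsv"))
    paths <- c(paths, p("ratios_participant.tsv"))
  }
  if (!is.null(st$ratios$group)) {
    write_tidy_tsv(st$ratios$group, p("ratios_group.tsv"))
    paths <- c(paths, p("ratios_group.tsv"))
  }
  manifest <- list(
    package = "vwmdecode",
    version = as.character(utils::packageVersion("vwmdecode")),
    seed = result$config$seed,
    parameter_hash = unname(tools::md5sum(p("config.yaml"))),
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.vwm_pipeline <- function(x, ...) {
  cat(sprintf("<vwm_pipeline> %d participants, %d ROI(s), theta = %.3f (%.1f s)\n",
              x$config$n_participants, nrow(x$config$rois), x$config$theta,
              x$elapsed_s))
  agg <- stats::aggregate(accuracy ~ scheme + trial_set, data = as.data.frame(x$decoding),
                          FUN = mean)
  cat("\nMean decoding accuracy across participants and ROIs:\n")
  print.data.frame(agg, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.vwm_pipeline <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$stats)
  invisible(object)
}

#' @export
plot.vwm_pipeline <- function(x, ...) plot(x$decoding, ...)
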