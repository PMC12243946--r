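# Within- and cross-decoding of object pairs from period-averaged beta
# patterns, and the cross-decoding ratio.
#
# All decoding is pairwise.  A four-way decoder is deliberately rejected: the
# four distractor objects do not appear equally often with each target object
# (an object never distracts itself), so a four-way target decoder would pick
# up distractor differences — which dominate the delay-period signal — rather
# than target differences.  Pairwise decoding holds the irrelevant object
# constant and avoids the confound.

#' z-normalize a response pattern
#'
#' Centers and scales a pattern to mean 0 and standard deviation 1 across
#' vertices (population convention, i.e. dividing by `sqrt(mean((x - m)^2))`),
#' removing amplitude differences between conditions, ROIs, and trial periods
#' before decoding.
#'
#' @param x Numeric vector of length >= 2 with nonzero variance.
#' @return The normalized vector.
#' @export
#' @examples
#' znorm(c(1, 2, 3))
znorm <- function(x) {
  if (length(x) < 2L) stopf("znorm needs at least 2 vertices")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stopf("cannot z-normalize a zero-variance pattern")
  (x - m) / s
}

scheme_names <- function() {
  c("within_target_delay", "cross_distractor_to_target_delay",
    "within_target_encoding", "cross_distractor_to_target_encoding",
    "within_encoding", "within_delay", "cross_encoding_delay",
    "cross_to_no_distractor_targets")
}

#' Define a decoding scheme
#'
#' A scheme fixes what the classifier is trained and tested on: the role of
#' the decoded objects (memory target vs delay-period distractor), the trial
#' period of the patterns (encoding vs delay), and the trial set (trials with
#' or without distractors).  Two families are supported: (1)
#' distractor-to-target cross-decoding, trained on delay-period distractor
#' patterns and tested — in that direction only, because distractor decoding
#' saturates — on target patterns during the delay or encoding period, in
#' with-distractor or no-distractor trials; and (2) encoding/delay
#' cross-decoding of targets, averaged over both training directions.
#' `"four_way"` is rejected with an explanation.
#'
#' @param name One of `r paste0('"', paste(scheme_names(), collapse = '", "'), '"')`.
#' @param trial_set `"with_distractors"` or `"without_distractors"` — the
#'   trials the decoded target patterns come from (distractor training always
#'   uses with-distractor trials).
#' @param irrelevant_match `"same"` (default: the irrelevant object is
#'   identical in training and test) or `"different"`.
#' @return A `vwm_scheme` object.
#' @export
decoding_scheme <- function(name,
                            trial_set = c("with_distractors", "without_distractors"),
                            irrelevant_match = c("same", "different")) {
  trial_set <- match.arg(trial_set)
  irrelevant_match <- match.arg(irrelevant_match)
  if (identical(name, "four_way")) {
    stopf(paste("four-way decoding is not supported: because an object never serves",
                "as its own distractor, the distractor objects are unbalanced across",
                "target classes and a four-way decoder would read out distractor",
                "rather than target information; use pairwise schemes instead"))
  }
  name <- match.arg(name, scheme_names())
  side <- function(role, period, dist) list(role = role, period = period, dist = dist)
  tgt_dist <- trial_set == "with_distractors"
  def <- switch(name,
    within_target_delay = ,
    within_delay = list(train = side("target", "delay", tgt_dist),
                        test = side("target", "delay", tgt_dist), directions = 1L),
    within_target_encoding = ,
    within_encoding = list(train = side("target", "encoding", tgt_dist),
                           test = side("target", "encoding", tgt_dist), directions = 1L),
    cross_distractor_to_target_delay = list(
      train = side("distractor", "delay", TRUE),
      test = side("target", "delay", TRUE), directions = 1L),
    cross_distractor_to_target_encoding = list(
      train = side("distractor", "delay", TRUE),
      test = side("target", "encoding", TRUE), directions = 1L),
    cross_to_no_distractor_targets = list(
      train = side("distractor", "delay", TRUE),
      test = side("target", "delay", FALSE), directions = 1L),
    cross_encoding_delay = list(
      train = side("target", "encoding", tgt_dist),
      test = side("target", "delay", tgt_dist), directions = 2L)
  )
  if (name %in% c("cross_distractor_to_target_delay",
                  "cross_distractor_to_target_encoding") &&
      trial_set == "without_distractors") {
    stopf("distractor-trained schemes test with-distractor trials; use cross_to_no_distractor_targets for no-distractor test trials")
  }
  structure(c(list(name = name, trial_set = trial_set,
                   irrelevant_match = irrelevant_match), def),
            class = "vwm_scheme")
}

#' @export
print.vwm_scheme <- function(x, ...) {
  cat(sprintf("<vwm_scheme> %s [%s]: train %s/%s -> test %s/%s (%d direction%s, irrelevant %s)\n",
              x$name, x$trial_set, x$train$role, x$train$period, x$test$role,
              x$test$period, x$directions, if (x$directions > 1L) "s" else "",
              x$irrelevant_match))
  invisible(x)
}

scheme_id <- function(scheme) paste(scheme$name, scheme$trial_set, sep = "|")

#' Enumerate the pair instances of a scheme
#'
#' For the four objects there are six unordered pairs.  A side whose patterns
#' come from with-distractor trials carries an irrelevant object (the target
#' when decoding distractors, the distractor when decoding targets); each pair
#' admits the two objects outside the pair as irrelevant.  Under
#' `irrelevant_match = "same"` the irrelevant object is identical on both
#' sides; under `"different"` it differs.  Sides without an irrelevant object
#' (no-distractor trials) contribute `NA`.
#'
#' @param scheme A `vwm_scheme`.
#' @return Data frame with columns `a`, `b`, `irr_train`, `irr_test`.
#' @export
enumerate_pair_instances <- function(scheme) {
  obj <- vwm_objects()
  prs <- utils::combn(obj, 2L)
  out <- list()
  for (i in seq_len(ncol(prs))) {
    a <- prs[1L, i]; b <- prs[2L, i]
    others <- setdiff(obj, c(a, b))
    tr_irr <- scheme$train$dist
    te_irr <- scheme$test$dist
    inst <- if (tr_irr && te_irr) {
      if (scheme$irrelevant_match == "same") {
        data.frame(irr_train = others, irr_test = others, stringsAsFactors = FALSE)
      } else {
        data.frame(irr_train = others, irr_test = rev(others), stringsAsFactors = FALSE)
      }
    } else if (tr_irr) {
      data.frame(irr_train = others, irr_test = NA_character_, stringsAsFactors = FALSE)
    } else if (te_irr) {
      data.frame(irr_train = NA_character_, irr_test = others, stringsAsFactors = FALSE)
    } else {
      data.frame(irr_train = NA_character_, irr_test = NA_character_,
                 stringsAsFactors = FALSE)
    }
    out[[i]] <- cbind(data.frame(a = a, b = b, stringsAsFactors = FALSE), inst)
  }
  do.call(rbind, out)
}

# conditions (2) supplying the patterns of one side of a pair instance
side_conditions <- function(side, a, b, irr) {
  if (side$role == "target") {
    if (side$dist) {
      c(condition_index(a, irr), condition_index(b, irr))
    } else {
      c(condition_index(a, NA_character_), condition_index(b, NA_character_))
    }
  } else {
    c(condition_index(irr, a), condition_index(irr, b))
  }
}

#' Train and test a linear SVM once
#'
#' Fits a linear maximum-margin classifier (LIBSVM via \pkg{e1071}, cost 1, no
#' internal rescaling — patterns are already z-normalized) and returns the
#' fraction of correct test predictions.  A test point exactly on the decision
#' boundary is assigned to the first factor level, for determinism.
#'
#' @param train_x,test_x Numeric matrices, patterns in rows.
#' @param train_y,test_y Labels (coerced to factor).
#' @return Accuracy in `[0, 1]`.
#' @export
decode_once <- function(train_x, train_y, test_x, test_y) {
  train_y <- factor(train_y)
  if (nlevels(train_y) != 2L) stopf("training set must contain exactly two classes")
  fit <- e1071::svm(train_x, train_y, kernel = "linear", cost = 1, scale = FALSE)
  dv <- attr(stats::predict(fit, test_x, decision.values = TRUE), "decision.values")
  pos <- strsplit(colnames(dv), "/", fixed = TRUE)[[1L]]
  pred <- ifelse(as.numeric(dv) >= 0, pos[1L], pos[2L])
  mean(pred == as.character(test_y))
}

# z-normalize every pattern (vertex vector) of a period array in place
znorm_periods <- function(arr) {
  d <- dim(arr)
  if (d[1L] < 2L) {
    warnf("ROI has a single vertex; skipping z-normalization (decoding is degenerate)")
    return(arr)
  }
  m <- colMeans(arr)
  centered <- arr - rep(m, each = d[1L])
  s <- sqrt(colMeans(centered^2))
  if (any(s == 0)) stopf("cannot z-normalize a zero-variance pattern")
  centered / rep(s, each = d[1L])
}

# stack patterns of two conditions from the given splits into an X, y pair
stack_patterns <- function(zarr, split, conds, splits, labels) {
  sel <- which(split %in% splits)
  x <- rbind(t(zarr[, conds[1L], sel, drop = TRUE]),
             t(zarr[, conds[2L], sel, drop = TRUE]))
  if (dim(zarr)[1L] == 1L) x <- cbind(c(zarr[, conds[1L], sel], zarr[, conds[2L], sel]))
  list(x = x, y = factor(rep(labels, each = length(sel)), levels = sort(labels)))
}

# accuracy for one pair instance, averaged over the 4 train/test rotations
# (and both directions for two-direction schemes)
rotate_instance <- function(periods, split, scheme, inst) {
  dirs <- seq_len(scheme$directions)
  accs <- numeric(0)
  for (d in dirs) {
    tr_side <- if (d == 1L) scheme$train else scheme$test
    te_side <- if (d == 1L) scheme$test else scheme$train
    tr_conds <- side_conditions(tr_side, inst$a, inst$b, inst$irr_train)
    te_conds <- side_conditions(te_side, inst$a, inst$b, inst$irr_test)
    tr_arr <- periods[[tr_side$period]]
    te_arr <- periods[[te_side$period]]
    for (rot in seq_len(4L)) {
      train <- stack_patterns(tr_arr, split, tr_conds, setdiff(1:4, rot), c(inst$a, inst$b))
      test <- stack_patterns(te_arr, split, te_conds, rot, c(inst$a, inst$b))
      accs <- c(accs, decode_once(train$x, train$y, test$x, test$y))
    }
  }
  mean(accs)
}

#' Run one decoding scheme on an ROI's pattern set
#'
#' Averages the beta patterns into the encoding and delay periods,
#' z-normalizes every pattern, and for every pair instance trains on all
#' patterns from three data splits (21 per condition for the canonical plan)
#' and tests on the left-out split (7 per condition), rotating the left-out
#' split through all four positions.  The scheme accuracy is the mean over
#' rotations (both training directions for encoding/delay cross-decoding) and
#' pair instances.
#'
#' @param patterns A `vwm_patterns` array for one ROI.
#' @param scheme A `vwm_scheme` or a scheme name accepted by
#'   [decoding_scheme()].
#' @param trial_set,irrelevant_match Used when `scheme` is given by name.
#' @return A one-row data frame: `scheme`, `trial_set`, `irrelevant_match`,
#'   `accuracy`, `chance`, `n_instances`, `n_train`, `n_test`.
#' @export
run_scheme <- function(patterns, scheme,
                       trial_set = "with_distractors",
                       irrelevant_match = "same") {
  if (!inherits(scheme, "vwm_scheme")) {
    scheme <- decoding_scheme(scheme, trial_set, irrelevant_match)
  }
  periods <- list(
    encoding = znorm_periods(average_period(patterns, "encoding")),
    delay = znorm_periods(average_period(patterns, "delay"))
  )
  scheme_accuracy(periods, attr(patterns, "split"), scheme)
}

scheme_accuracy <- function(periods, split, scheme) {
  if (length(unique(split)) != 4L) stopf("decoding requires all 4 data splits; found %d", length(unique(split)))
  inst <- enumerate_pair_instances(scheme)
  accs <- vapply(seq_len(nrow(inst)), function(i) {
    rotate_instance(periods, split, scheme, inst[i, ])
  }, numeric(1))
  n_per_split <- sum(split == split[1L])
  data.frame(
    scheme = scheme$name, trial_set = scheme$trial_set,
    irrelevant_match = scheme$irrelevant_match,
    accuracy = mean(accs), chance = 0.5, n_instances = nrow(inst),
    n_train = 3L * n_per_split, n_test = n_per_split,
    stringsAsFactors = FALSE
  )
}

#' Decode all schemes for one participant
#'
#' @param roi_patterns Named list of `vwm_patterns` (one per ROI) from
#'   [participant_patterns()].
#' @param schemes List of `vwm_scheme` objects (default: the full battery from
#'   [default_schemes()]).
#' @param sectors Named character vector mapping ROI names to sectors
#'   (`NA` for ROIs outside any sector); default [vwm_sectors()].
#' @param participant_id Identifier for the output rows.
#' @return A `vwm_decoding` data frame: one row per ROI x scheme.
#' @export
decode_participant <- function(roi_patterns, schemes = default_schemes(),
                               sectors = vwm_sectors(),
                               participant_id = "sub-01") {
  out <- list()
  for (roi in names(roi_patterns)) {
    pat <- roi_patterns[[roi]]
    periods <- list(
      encoding = znorm_periods(average_period(pat, "encoding")),
      delay = znorm_periods(average_period(pat, "delay"))
    )
    split <- attr(pat, "split")
    for (sc in schemes) {
      row <- scheme_accuracy(periods, split, sc)
      row$participant <- participant_id
      row$roi <- roi
      row$sector <- unname(sectors[roi] %||% NA_character_)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("participant", "roi", "sector", "scheme", "trial_set",
                 "irrelevant_match", "accuracy", "chance", "n_instances",
                 "n_train", "n_test")]
  class(res) <- c("vwm_decoding", "data.frame")
  res
}

#' The default scheme battery
#'
#' The eight scheme/trial-set combinations reported by the analysis:
#' within-target and distractor-to-target decoding during delay and encoding,
#' the no-distractor variants, and encoding/delay cross-decoding for both
#' trial sets.
#'
#' @return List of `vwm_scheme` objects.
#' @export
default_schemes <- function() {
  list(
    decoding_scheme("within_target_delay"),
    decoding_scheme("cross_distractor_to_target_delay"),
    decoding_scheme("within_target_encoding"),
    decoding_scheme("cross_distractor_to_target_encoding"),
    decoding_scheme("within_target_delay", trial_set = "without_distractors"),
    decoding_scheme("cross_to_no_distractor_targets"),
    decoding_scheme("cross_encoding_delay"),
    decoding_scheme("cross_encoding_delay", trial_set = "without_distractors")
  )
}

#' ROI sector membership
#'
#' Sectors group ROIs at the three ends of the visual hierarchy: posterior
#' (V1–V4, early visual cortex), ventral (LOT and VOT, object-selective
#' occipitotemporal cortex), and dorsal (IPS2–IPS4, posterior parietal
#' cortex).  V3a, V3b, IPS0 and IPS1 belong to no sector.
#'
#' @return Named character vector mapping ROI name to sector (`NA` = none).
#' @export
vwm_sectors <- function() {
  c(V1 = "posterior", V2 = "posterior", V3 = "posterior", V4 = "posterior",
    LOT = "ventral", VOT = "ventral",
    IPS2 = "dorsal", IPS3 = "dorsal", IPS4 = "dorsal",
    V3a = NA, V3b = NA, IPS0 = NA, IPS1 = NA)
}

#' Cross-decoding ratio
#'
#' `(cross - 0.5) / (within - 0.5)`: 1 means cross-decoding generalizes fully
#' (equally good decoding within and across), 0 means no generalization at
#' all.  The ratio is undefined when within-decoding is at chance; entries
#' with `within - 0.5 <= eps` are flagged invalid rather than dropped.
#'
#' @param within,cross Within- and cross-decoding accuracies (vectors
#'   recycled to a common length).
#' @param eps Guard on the denominator (default 0.01).
#' @return Data frame with columns `within`, `cross`, `ratio`, `valid`.
#' @export
#' @examples
#' cross_ratio(within = 0.70, cross = 0.60)  # ratio 0.5
cross_ratio <- function(within, cross, eps = 0.01) {
  n <- max(length(within), length(cross))
  within <- rep_len(within, n); cross <- rep_len(cross, n)
  valid <- (within - 0.5) > eps
  ratio <- ifelse(valid, (cross - 0.5) / (within - 0.5), NA_real_)
  data.frame(within = within, cross = cross, ratio = ratio, valid = valid)
}

#' Average ROI-level results within sectors
#'
#' Each ROI is decoded separately and the resulting accuracies (or ratios) are
#' averaged, unweighted, within each sector — rather than decoding one merged
#' ROI, which would overweight larger ROIs.
#'
#' @param df A `vwm_decoding` data frame (or any data frame with
#'   `participant`, `sector`, `scheme`, `trial_set` and a value column).
#' @param value Name of the value column (default `"accuracy"`).
#' @return Data frame aggregated to participant x sector x scheme.
#' @export
sector_average <- function(df, value = "accuracy") {
  keep <- !is.na(df$sector)
  if (!any(keep)) stopf("no ROI in the table belongs to a sector")
  d <- df[keep, , drop = FALSE]
  out <- stats::aggregate(d[[value]],
                          by = list(participant = d$participant, sector = d$sector,
                                    scheme = d$scheme, trial_set = d$trial_set),
                          FUN = mean)
  names(out)[names(out) == "x"] <- value
  out
}

#' @export
print.vwm_decoding <- function(x, ...) {
  cat(sprintf("<vwm_decoding> %d rows: %d participant(s), %d ROI(s), %d scheme(s)\n",
              nrow(x), length(unique(x$participant)), length(unique(x$roi)),
              length(unique(paste(x$scheme, x$trial_set)))))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
plot.vwm_decoding <- function(x, value = "accuracy", ...) {
  sec <- sector_average(as.data.frame(x), value)
  agg <- stats::aggregate(sec[[value]],
                          by = list(sector = sec$sector,
                                    scheme = paste(sec$scheme, sec$trial_set, sep = "\n")),
                          FUN = mean)
  tab <- stats::xtabs(x ~ sector + scheme, data = agg)
  graphics::barplot(tab, beside = TRUE, legend.text = rownames(tab),
                    ylab = value, las = 2, cex.names = 0.6, ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}
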