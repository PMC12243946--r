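# Group-level statistics: t tests against chance and between conditions,
# Benjamini-Hochberg correction within explicit families, and two-way
# repeated-measures ANOVA.

#' One-sample t test against chance
#'
#' One-tailed by default, since only above-chance decoding is meaningful.
#' A zero-variance sample exactly at chance yields `t = 0`, `p = 0.5` (the
#' limiting value); a zero-variance sample away from chance has an undefined
#' p, reported as `NA`.
#'
#' @param x Per-participant values (n >= 2).
#' @param chance Null value (default 0.5).
#' @param tail `"one"` (greater than chance) or `"two"`.
#' @return One-row data frame: `mean`, `t`, `df`, `p`, `tail`, `n`.
#' @export
t_test_vs_chance <- function(x, chance = 0.5, tail = c("one", "two")) {
  tail <- match.arg(tail)
  n <- length(x)
  if (n < 2L) stopf("need at least 2 participants")
  if (stats::sd(x) == 0) {
    tt <- if (mean(x) == chance) 0 else NA_real_
    p <- if (is.na(tt)) NA_real_ else if (tail == "one") 0.5 else 1
    return(data.frame(mean = mean(x), t = tt, df = n - 1L, p = p, tail = tail, n = n))
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  ht <- stats::t.test(x, mu = chance, alternative = alt)
  data.frame(mean = mean(x), t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, tail = tail, n = n)
}

#' Paired t test for a cross-decoding drop
#'
#' Tests `within > cross` (one-tailed: the drop is expected to be null or
#' positive), or a two-tailed paired difference.
#'
#' @param within,cross Matched per-participant vectors.
#' @param tail `"one"` or `"two"`.
#' @return One-row data frame: `mean_diff`, `t`, `df`, `p`, `tail`, `n`.
#' @export
paired_drop_test <- function(within, cross, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (length(within) != length(cross)) stopf("paired vectors differ in length")
  d <- within - cross
  n <- length(d)
  if (n < 2L) stopf("need at least 2 participants")
  if (stats::sd(d) == 0) {
    tt <- if (mean(d) == 0) 0 else NA_real_
    p <- if (is.na(tt)) NA_real_ else if (tail == "one") 0.5 else 1
    return(data.frame(mean_diff = mean(d), t = tt, df = n - 1L, p = p, tail = tail, n = n))
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  ht <- stats::t.test(d, mu = 0, alternative = alt)
  data.frame(mean_diff = mean(d), t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, tail = tail, n = n)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment within one test family; adjusted
#' values are monotone in the raw p values and clipped at 1.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NAs passed through).
#' @return Adjusted p values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor design with subject as the random blocking
#' factor: each effect is tested against its own subject-by-effect error
#' stratum (no sphericity correction is applied; noted in the output).  When
#' one factor has a single level the model reduces to a one-way
#' repeated-measures ANOVA on the other factor, whose F equals the squared
#' paired t statistic in the two-level case.
#'
#' @param data Data frame in long format.
#' @param subject,factor_a,factor_b,value Column names.
#' @return A `vwm_anova`: data frame with rows per effect (`A`, `B`, `A:B`),
#'   columns `effect`, `df1`, `df2`, `F`, `p`; attribute
#'   `sphericity_correction = "none"`.
#' @export
rm_anova_2way <- function(data, subject = "participant", factor_a = "A",
                          factor_b = "B", value = "value") {
  d <- data.frame(
    s = factor(data[[subject]]), A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]]), y = data[[value]]
  )
  if (anyNA(d)) stopf("missing values in the ANOVA table")
  full <- table(d$s, d$A, d$B)
  if (any(full == 0L)) stopf("design has empty cells; a fully crossed within-subject design is required")
  if (any(full != full[1L])) stopf("design is unbalanced")
  if (nlevels(d$s) < 3L) stopf("need at least 3 participants")
  la <- nlevels(d$A); lb <- nlevels(d$B)
  if (la < 2L && lb < 2L) stopf("at least one factor needs two levels")
  pull <- function(smry, label, df1_name) {
    for (stratum in smry) {
      tab <- stratum[[1L]]
      rn <- trimws(rownames(tab))
      hit <- match(label, rn)
      if (!is.na(hit)) {
        return(data.frame(effect = df1_name, df1 = tab$Df[hit],
                          df2 = tab$Df[rn == "Residuals"],
                          F = tab$`F value`[hit], p = tab$`Pr(>F)`[hit]))
      }
    }
    NULL
  }
  if (la >= 2L && lb >= 2L) {
    fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = d)
    smry <- summary(fit)
    out <- rbind(pull(smry, "A", "A"), pull(smry, "B", "B"), pull(smry, "A:B", "A:B"))
  } else {
    f <- if (la >= 2L) "A" else "B"
    d$G <- d[[f]]
    fit <- stats::aov(y ~ G + Error(s / G), data = d)
    smry <- summary(fit)
    out <- pull(smry, "G", f)
  }
  structure(out, sphericity_correction = "none", class = c("vwm_anova", "data.frame"))
}

#' @export
print.vwm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (no sphericity correction)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

# one vs-chance t test per unit (ROI or sector) and scheme, BH-corrected
# within unit
vs_chance_table <- function(values, unit_col, alpha) {
  out <- list()
  for (u in unique(values[[unit_col]])) {
    du <- values[values[[unit_col]] == u, , drop = FALSE]
    for (sc in unique(du$scheme_id)) {
      v <- du$accuracy[du$scheme_id == sc]
      tt <- t_test_vs_chance(v, tail = "one")
      tt$unit <- u; tt$scheme_id <- sc
      tt$family <- paste0(u, ":vs_chance")
      out[[length(out) + 1L]] <- tt
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- stats::ave(res$p, res$family, FUN = bh_adjust)
  res$significant <- ifelse(is.na(res$p_adj), NA, res$p_adj < alpha)
  res[, c("unit", "scheme_id", "family", "mean", "t", "df", "p", "p_adj",
          "significant", "n")]
}

# the within/cross comparisons the battery reports
battery_comparisons <- function() {
  data.frame(
    comparison = c("delay_with", "encoding_with", "delay_without",
                   "enc_delay_with", "enc_delay_without"),
    within = c("within_target_delay|with_distractors",
               "within_target_encoding|with_distractors",
               "within_target_delay|without_distractors",
               "within_mean_enc_delay|with_distractors",
               "within_mean_enc_delay|without_distractors"),
    cross = c("cross_distractor_to_target_delay|with_distractors",
              "cross_distractor_to_target_encoding|with_distractors",
              "cross_to_no_distractor_targets|with_distractors",
              "cross_encoding_delay|with_distractors",
              "cross_encoding_delay|without_distractors"),
    stringsAsFactors = FALSE
  )
}

#' Run the group-level statistical battery
#'
#' From a cohort's decoding table, computes (per ROI and per sector): (1)
#' one-tailed t tests of every scheme's accuracy against chance,
#' Benjamini-Hochberg corrected within the unit; (2) one-tailed paired tests
#' of the cross-decoding drop for every within/cross comparison present; (3)
#' two-way repeated-measures ANOVA with trial type (with vs without
#' distractors) and decoding (within vs cross) as within-subject factors,
#' matching the published table layout; (4) two-tailed pairwise comparisons
#' of the drop across the three sectors, BH-corrected over the three pairs;
#' and (5) cross-decoding ratios per participant and from group-mean
#' accuracies.
#'
#' @param decoding A `vwm_decoding` table covering at least the
#'   within/cross delay schemes for both trial sets.
#' @param alpha Significance level (default 0.05).
#' @return A `vwm_stat_report` list with elements `vs_chance_roi`,
#'   `vs_chance_sector`, `drops_roi`, `drops_sector`, `anova_roi`,
#'   `anova_sector`, `sector_pairs`, `ratios`, `alpha`.
#' @export
run_battery <- function(decoding, alpha = 0.05) {
  df <- as.data.frame(decoding)
  df$scheme_id <- paste(df$scheme, df$trial_set, sep = "|")
  # synthesize the direction-averaged within measure for encoding/delay
  # comparisons: the mean of within-encoding and within-delay accuracies
  for (ts in unique(df$trial_set)) {
    wd <- df[df$scheme_id == paste0("within_target_delay|", ts), , drop = FALSE]
    we <- df[df$scheme_id == paste0("within_target_encoding|", ts), , drop = FALSE]
    if (ts == "without_distractors" && nrow(we) == 0L) {
      we <- df[df$scheme_id == "within_target_encoding|with_distractors", , drop = FALSE]
    }
    if (nrow(wd) > 0L && nrow(we) > 0L) {
      key <- c("participant", "roi")
      m <- merge(wd[, c(key, "sector", "accuracy")], we[, c(key, "accuracy")], by = key)
      if (nrow(m) > 0L) {
        add <- data.frame(participant = m$participant, roi = m$roi, sector = m$sector,
                          scheme = "within_mean_enc_delay", trial_set = ts,
                          irrelevant_match = "same",
                          accuracy = (m$accuracy.x + m$accuracy.y) / 2,
                          chance = 0.5, n_instances = NA_integer_,
                          n_train = NA_integer_, n_test = NA_integer_,
                          scheme_id = paste0("within_mean_enc_delay|", ts))
        df <- rbind(df, add)
      }
    }
  }
  cohort_n <- length(unique(df$participant))
  if (cohort_n < 2L) stopf("the battery needs at least 2 participants")
  sec <- sector_average(df, "accuracy")
  sec$scheme_id <- paste(sec$scheme, sec$trial_set, sep = "|")
  sec$unit <- sec$sector
  roi_tab <- df; roi_tab$unit <- roi_tab$roi
  report <- list(alpha = alpha)
  report$vs_chance_roi <- vs_chance_table(roi_tab, "unit", alpha)
  report$vs_chance_sector <- vs_chance_table(sec, "unit", alpha)
  report$drops_roi <- drop_table(roi_tab, "roi", alpha)
  report$drops_sector <- drop_table(sec, "sector", alpha)
  report$anova_roi <- anova_table(roi_tab, "roi")
  report$anova_sector <- anova_table(sec, "sector")
  report$sector_pairs <- sector_pair_table(sec, alpha)
  report$ratios <- ratio_tables(df, sec)
  class(report) <- "vwm_stat_report"
  report
}

value_matrix <- function(d, unit_col, unit, scheme_id) {
  v <- d[d[[unit_col]] == unit & d$scheme_id == scheme_id, , drop = FALSE]
  v <- v[order(v$participant), , drop = FALSE]
  stats::setNames(v$accuracy, v$participant)
}

drop_table <- function(d, unit_col, alpha) {
  cmp <- battery_comparisons()
  out <- list()
  for (u in unique(d[[unit_col]])) {
    for (i in seq_len(nrow(cmp))) {
      w <- value_matrix(d, unit_col, u, cmp$within[i])
      x <- value_matrix(d, unit_col, u, cmp$cross[i])
      common <- intersect(names(w), names(x))
      if (length(common) < 2L) next
      tt <- paired_drop_test(w[common], x[common], tail = "one")
      tt$unit <- u; tt$comparison <- cmp$comparison[i]
      tt$family <- paste0(u, ":drop")
      out[[length(out) + 1L]] <- tt
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res$p_adj <- stats::ave(res$p, res$family, FUN = bh_adjust)
  res$significant <- ifelse(is.na(res$p_adj), NA, res$p_adj < alpha)
  res[, c("unit", "comparison", "family", "mean_diff", "t", "df", "p", "p_adj",
          "significant", "n")]
}

# trial type (with/without) x decoding (within/cross) RM-ANOVA per unit,
# using delay-period decoding — the published per-ROI table layout
anova_table <- function(d, unit_col) {
  need <- c("within_target_delay|with_distractors",
            "cross_distractor_to_target_delay|with_distractors",
            "within_target_delay|without_distractors",
            "cross_to_no_distractor_targets|with_distractors")
  if (!all(need %in% d$scheme_id)) return(NULL)
  out <- list()
  for (u in unique(d[[unit_col]])) {
    du <- d[d[[unit_col]] == u & d$scheme_id %in% need, , drop = FALSE]
    du$trial_type <- ifelse(du$scheme_id %in% need[1:2], "with", "without")
    du$decoding <- ifelse(grepl("^within", du$scheme_id), "within", "cross")
    keep <- stats::aggregate(seq_len(nrow(du)),
                             by = list(du$participant), FUN = length)
    full <- keep$x == 4L
    du <- du[du$participant %in% keep$Group.1[full], , drop = FALSE]
    if (length(unique(du$participant)) < 3L) next
    an <- rm_anova_2way(du, subject = "participant", factor_a = "trial_type",
                        factor_b = "decoding", value = "accuracy")
    an <- as.data.frame(an)
    an$effect <- c("trial_type", "decoding", "trial_type:decoding")[match(an$effect, c("A", "B", "A:B"))]
    an$unit <- u
    out[[length(out) + 1L]] <- an
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)[, c("unit", "effect", "df1", "df2", "F", "p")]
}

sector_pair_table <- function(sec, alpha) {
  cmp <- battery_comparisons()[1L, ]  # delay drop, with distractors
  w <- sec[sec$scheme_id == cmp$within, , drop = FALSE]
  x <- sec[sec$scheme_id == cmp$cross, , drop = FALSE]
  if (nrow(w) == 0L || nrow(x) == 0L) return(NULL)
  m <- merge(w[, c("participant", "sector", "accuracy")],
             x[, c("participant", "sector", "accuracy")],
             by = c("participant", "sector"), suffixes = c("_within", "_cross"))
  m$drop <- m$accuracy_within - m$accuracy_cross
  sectors <- sort(unique(m$sector))
  if (length(sectors) < 2L) return(NULL)
  prs <- utils::combn(sectors, 2L)
  out <- list()
  for (i in seq_len(ncol(prs))) {
    a <- m[m$sector == prs[1L, i], ]; b <- m[m$sector == prs[2L, i], ]
    common <- intersect(a$participant, b$participant)
    if (length(common) < 2L) next
    av <- stats::setNames(a$drop, a$participant)[common]
    bv <- stats::setNames(b$drop, b$participant)[common]
    tt <- paired_drop_test(av, bv, tail = "two")
    tt$pair <- paste(prs[, i], collapse = "-")
    out[[length(out) + 1L]] <- tt
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res$family <- "sector_pairs"
  res$p_adj <- bh_adjust(res$p)
  res$significant <- ifelse(is.na(res$p_adj), NA, res$p_adj < alpha)
  res[, c("pair", "family", "mean_diff", "t", "df", "p", "p_adj", "significant", "n")]
}

# per-participant ratios plus the group-level ratio from mean accuracies
ratio_tables <- function(df, sec) {
  cmp <- battery_comparisons()
  out_p <- list(); out_g <- list()
  for (i in seq_len(nrow(cmp))) {
    for (unit_col in c("roi", "sector")) {
      d <- if (unit_col == "roi") df else { sec$roi <- NULL; sec }
      ucol <- if (unit_col == "roi") "roi" else "sector"
      w <- d[d$scheme_id == cmp$within[i], , drop = FALSE]
      x <- d[d$scheme_id == cmp$cross[i], , drop = FALSE]
      if (nrow(w) == 0L || nrow(x) == 0L) next
      m <- merge(w[, c("participant", ucol, "accuracy")],
                 x[, c("participant", ucol, "accuracy")],
                 by = c("participant", ucol), suffixes = c("_w", "_x"))
      if (nrow(m) == 0L) next
      r <- cross_ratio(m$accuracy_w, m$accuracy_x)
      out_p[[length(out_p) + 1L]] <- data.frame(
        level = unit_col, unit = m[[ucol]], participant = m$participant,
        comparison = cmp$comparison[i], within = r$within, cross = r$cross,
        ratio = r$ratio, valid = r$valid, stringsAsFactors = FALSE)
      m$unit <- m[[ucol]]
      gm <- stats::aggregate(cbind(accuracy_w, accuracy_x) ~ unit, data = m, FUN = mean)
      gr <- cross_ratio(gm$accuracy_w, gm$accuracy_x)
      out_g[[length(out_g) + 1L]] <- data.frame(
        level = unit_col, unit = gm$unit, comparison = cmp$comparison[i],
        within = gr$within, cross = gr$cross, ratio = gr$ratio, valid = gr$valid,
        stringsAsFactors = FALSE)
    }
  }
  list(per_participant = if (length(out_p)) do.call(rbind, out_p) else NULL,
       group = if (length(out_g)) do.call(rbind, out_g) else NULL)
}

#' @export
print.vwm_stat_report <- function(x, ...) {
  cat(sprintf("<vwm_stat_report> alpha = %g\n", x$alpha))
  if (!is.null(x$vs_chance_sector)) {
    cat("\nSector decoding vs chance (one-tailed, BH-corrected per sector):\n")
    print.data.frame(x$vs_chance_sector, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$drops_sector)) {
    cat("\nCross-decoding drop (paired one-tailed, BH-corrected per sector):\n")
    print.data.frame(x$drops_sector, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$anova_sector)) {
    cat("\nTrial type x decoding repeated-measures ANOVA per sector:\n")
    print.data.frame(x$anova_sector, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$ratios$group)) {
    g <- x$ratios$group
    g <- g[g$level == "sector", , drop = FALSE]
    if (nrow(g)) {
      cat("\nGroup-level cross-decoding ratios per sector:\n")
      print.data.frame(g, digits = 3, row.names = FALSE)
    }
  }
  invisible(x)
}
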