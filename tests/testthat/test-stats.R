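test_that("one-sample t against chance matches hand-computed values", {
  tt <- t_test_vs_chance(c(0.6, 0.7, 0.8))
  expect_equal(tt$t, 3.4641016, tolerance = 1e-6)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, stats::pt(3.4641016, 2, lower.tail = FALSE), tolerance = 1e-6)
  # all values exactly at chance: t = 0, one-tailed p = 0.5
  flat <- t_test_vs_chance(rep(0.5, 4))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 0.5)
  # zero variance away from chance: undefined p
  sat <- t_test_vs_chance(rep(1, 4))
  expect_true(is.na(sat$p))
  expect_error(t_test_vs_chance(0.7), "2 participants")
})

test_that("the paired drop test is one-tailed in the within > cross direction", {
  d <- paired_drop_test(c(0.8, 0.75, 0.82), c(0.6, 0.62, 0.64))
  expect_gt(d$t, 0)
  expect_lt(d$p, 0.05)
  expect_equal(paired_drop_test(c(0.7, 0.8), c(0.7, 0.8))$t, 0)
  # a drop in the unexpected direction gives p > 0.5
  neg <- paired_drop_test(c(0.6, 0.62, 0.61), c(0.8, 0.79, 0.81))
  expect_gt(neg$p, 0.5)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))
  set.seed(31)
  for (m in c(1L, 2L, 5L, 12L)) {
    p <- round(runif(m), 3)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  p <- c(0.04, 0.04, 0.9, 0.001)  # ties
  expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  # monotone in the raw p values, and adjusted >= raw
  set.seed(5)
  p <- runif(10)
  a <- bh_adjust(p)
  expect_true(all(a >= p - 1e-12))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the repeated-measures ANOVA matches a hand-worked sums-of-squares partition", {
  # 3 subjects x 2 x 2, fixed values
  d <- expand.grid(s = paste0("s", 1:3), A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$y <- c(0.60, 0.55, 0.70,   # a1 b1
           0.80, 0.72, 0.86,   # a2 b1
           0.58, 0.50, 0.66,   # a1 b2
           0.71, 0.60, 0.79)   # a2 b2
  an <- rm_anova_2way(d, subject = "s", factor_a = "A", factor_b = "B", value = "y")
  # independent oracle: explicit SS partition
  gm <- mean(d$y)
  ma <- tapply(d$y, d$A, mean); mb <- tapply(d$y, d$B, mean)
  ms <- tapply(d$y, d$s, mean)
  mab <- tapply(d$y, list(d$A, d$B), mean)
  mas <- tapply(d$y, list(d$A, d$s), mean)
  mbs <- tapply(d$y, list(d$B, d$s), mean)
  ss_a <- 2 * 3 * sum((ma - gm)^2)
  ss_b <- 2 * 3 * sum((mb - gm)^2)
  ss_ab <- 3 * sum((mab - outer(ma, rep(1, 2)) - outer(rep(1, 2), mb) + gm)^2)
  ss_as <- 2 * sum((mas - outer(ma, rep(1, 3)) - outer(rep(1, 2), ms) + gm)^2)
  ss_bs <- 2 * sum((mbs - outer(mb, rep(1, 3)) - outer(rep(1, 2), ms) + gm)^2)
  cell <- tapply(d$y, list(d$A, d$B, d$s), mean)
  ss_abs <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:3) {
    ss_abs <- ss_abs + (cell[i, j, k] - mab[i, j] - mas[i, k] - mbs[j, k] +
                          ma[i] + mb[j] + ms[k] - gm)^2
  }
  f_a <- as.numeric((ss_a / 1) / (ss_as / 2))
  f_b <- as.numeric((ss_b / 1) / (ss_bs / 2))
  f_ab <- as.numeric((ss_ab / 1) / (ss_abs / 2))
  expect_equal(an$F[an$effect == "A"], f_a, tolerance = 1e-8)
  expect_equal(an$F[an$effect == "B"], f_b, tolerance = 1e-8)
  expect_equal(an$F[an$effect == "A:B"], f_ab, tolerance = 1e-8)
  expect_equal(an$df1, c(1, 1, 1))
  expect_equal(an$df2, c(2, 2, 2))
  expect_equal(an$p[1], stats::pf(f_a, 1, 2, lower.tail = FALSE), tolerance = 1e-8)
  expect_equal(attr(an, "sphericity_correction"), "none")
})

test_that("the ANOVA reduces to the squared paired t when one factor is degenerate", {
  set.seed(12)
  d <- expand.grid(s = paste0("s", 1:6), A = c("x", "y"), B = "only",
                   stringsAsFactors = FALSE)
  d$y <- rnorm(12, mean = ifelse(d$A == "x", 0.6, 0.7), sd = 0.05)
  an <- rm_anova_2way(d, subject = "s", factor_a = "A", factor_b = "B", value = "y")
  expect_equal(nrow(an), 1L)
  tt <- stats::t.test(d$y[d$A == "x"], d$y[d$A == "y"], paired = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(an$p, tt$p.value, tolerance = 1e-8)
})

test_that("ANOVA symmetry, null interaction, and input validation", {
  d <- expand.grid(s = paste0("s", 1:4), A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  # cell means are exactly additive (interaction SS = 0); a zero-sum-per-cell
  # jitter across subjects keeps the means intact but gives the interaction
  # error stratum a nonzero SS, so its F is well defined and ~0
  eff_a <- ifelse(d$A == "a1", 0, 0.1)
  eff_b <- ifelse(d$B == "b1", 0, 0.05)
  eff_s <- as.numeric(factor(d$s)) * 0.02
  jitter <- 0.01 * c(-1, 2, -1, 0,  2, -1, 0, -1,  0, -1, 2, -1,  -1, 0, -1, 2)
  d$y <- 0.5 + eff_a + eff_b + eff_s + jitter
  an <- rm_anova_2way(d, subject = "s", factor_a = "A", factor_b = "B", value = "y")
  expect_lt(an$F[an$effect == "A:B"], 1e-10)
  # swapping the factors swaps the effect labels but not the F values
  an2 <- rm_anova_2way(d, subject = "s", factor_a = "B", factor_b = "A", value = "y")
  expect_equal(an2$F[an2$effect == "A"], an$F[an$effect == "B"], tolerance = 1e-10)
  expect_equal(an2$F[an2$effect == "B"], an$F[an$effect == "A"], tolerance = 1e-10)
  expect_error(rm_anova_2way(d[-1, ], subject = "s", factor_a = "A",
                             factor_b = "B", value = "y"), "empty cells|unbalanced")
  d2 <- d[d$s %in% c("s1", "s2"), ]
  expect_error(rm_anova_2way(d2, subject = "s", factor_a = "A", factor_b = "B",
                             value = "y"), "3 participants")
})

test_that("the battery reports the published table shapes on a synthetic cohort", {
  dec <- fx_fake_decoding()
  rep_ <- run_battery(dec, alpha = 0.05)
  expect_s3_class(rep_, "vwm_stat_report")
  # vs-chance: one row per unit x scheme, BH within unit families
  vs <- rep_$vs_chance_sector
  expect_setequal(unique(vs$unit), c("posterior", "ventral", "dorsal"))
  expect_true(all(vs$p_adj >= vs$p - 1e-12, na.rm = TRUE))
  # drops: the constructed cohort has a clear drop everywhere
  dr <- rep_$drops_sector
  expect_true(all(dr$mean_diff > 0))
  expect_true(all(dr$significant))
  # ANOVA table: trial type, decoding, interaction per unit (ROI and sector)
  expect_setequal(unique(rep_$anova_roi$effect),
                  c("trial_type", "decoding", "trial_type:decoding"))
  expect_equal(nrow(rep_$anova_sector), 3L * 3L)
  # sector pairwise family has exactly 3 members
  expect_equal(nrow(rep_$sector_pairs), 3L)
  expect_equal(unique(rep_$sector_pairs$family), "sector_pairs")
  # ratios emitted at both the participant and the group level
  expect_true(all(c("per_participant", "group") %in% names(rep_$ratios)))
  g <- rep_$ratios$group
  expect_true(all(g$ratio[g$valid] <= 1.5))
})

test_that("the one-tailed vs-chance test attains its nominal type-I error on null cohorts", {
  # scaled-down null calibration on pattern-level zero-signal cohorts
  set.seed(77)
  n_cohorts <- 600L
  alpha <- 0.05
  # per-cohort accuracies drawn by decoding pure-noise patterns is exercised
  # in the acceptance suite; here the t test itself is audited on matched
  # null accuracy draws (symmetric around chance)
  rejections <- vapply(seq_len(n_cohorts), function(i) {
    acc <- 0.5 + stats::rnorm(6, 0, 0.05)
    t_test_vs_chance(acc)$p < alpha
  }, logical(1))
  rate <- mean(rejections)
  ci_half <- 2 * sqrt(alpha * (1 - alpha) / n_cohorts)
  expect_lt(abs(rate - alpha), ci_half + 0.01)
})
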