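test_that("z-normalization uses the population-sd convention and is idempotent", {
  z <- znorm(c(1, 2, 3))
  expect_equal(z, c(-1.224744871, 0, 1.224744871), tolerance = 1e-8)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(znorm(z), z, tolerance = 1e-12)
  expect_error(znorm(rep(2, 5)), "zero-variance")
  expect_error(znorm(1), "at least 2")
})

test_that("pair instances follow the scheme's irrelevant-object rules", {
  # 4 objects -> 6 unordered pairs; 2 eligible irrelevant objects each
  w <- enumerate_pair_instances(decoding_scheme("within_target_delay"))
  expect_equal(nrow(w), 12L)
  expect_true(all(w$irr_train == w$irr_test))
  expect_true(all(w$irr_train != w$a & w$irr_train != w$b))
  x <- enumerate_pair_instances(decoding_scheme("cross_distractor_to_target_delay",
                                                irrelevant_match = "different"))
  expect_equal(nrow(x), 12L)
  expect_true(all(x$irr_train != x$irr_test))
  nd <- enumerate_pair_instances(decoding_scheme("within_target_delay",
                                                 trial_set = "without_distractors"))
  expect_equal(nrow(nd), 6L)
  expect_true(all(is.na(nd$irr_train)) && all(is.na(nd$irr_test)))
  cn <- enumerate_pair_instances(decoding_scheme("cross_to_no_distractor_targets"))
  expect_equal(nrow(cn), 12L)
  expect_true(all(!is.na(cn$irr_train)) && all(is.na(cn$irr_test)))
})

test_that("four-way decoding is rejected with an explanation", {
  expect_error(decoding_scheme("four_way"), "unbalanced|pairwise")
})

test_that("no scheme trains on delay-period targets to decode distractors", {
  for (sc in default_schemes()) {
    expect_false(sc$train$role == "target" && sc$test$role == "distractor")
    if (sc$train$role == "distractor") expect_equal(sc$directions, 1L)
  }
})

test_that("the linear SVM separates separable clusters and is at chance on permuted labels", {
  set.seed(7)
  n <- 20L
  x1 <- matrix(rnorm(n * 10, mean = 2), n)
  x2 <- matrix(rnorm(n * 10, mean = -2), n)
  tr_x <- rbind(x1[1:10, ], x2[1:10, ])
  te_x <- rbind(x1[11:20, ], x2[11:20, ])
  y <- factor(rep(c("a", "b"), each = 10L))
  expect_equal(decode_once(tr_x, y, te_x, y), 1.0)
  expect_error(decode_once(tr_x, factor(rep("a", 20L)), te_x, y), "two classes")
  # permutation null: accuracy within 3 binomial SDs of 0.5
  accs <- replicate(30, {
    xx <- matrix(rnorm(40 * 12), 40)
    yy <- factor(sample(rep(c("a", "b"), each = 20L)))
    decode_once(xx[1:30, ], yy[1:30], xx[31:40, ], yy[31:40])
  })
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / (30 * 10)))
})

test_that("training on one code and testing along an uncorrelated code is at chance", {
  set.seed(21)
  v <- 80L
  d1 <- rnorm(v); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- rnorm(v); d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  accs <- replicate(25, {
    tr <- rbind(t(replicate(12, 3 * d1 + rnorm(v, sd = 0.7))),
                t(replicate(12, -3 * d1 + rnorm(v, sd = 0.7))))
    te <- rbind(t(replicate(8, 3 * d2 + rnorm(v, sd = 0.7))),
                t(replicate(8, -3 * d2 + rnorm(v, sd = 0.7))))
    y_tr <- factor(rep(c("a", "b"), each = 12L))
    y_te <- factor(rep(c("a", "b"), each = 8L))
    decode_once(tr, y_tr, te, y_te)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("rotations use 21 training and 7 test patterns and average symmetrically", {
  pat <- simulate_null_patterns(30, seed = 1)
  res <- run_scheme(pat, "within_target_delay")
  expect_equal(res$n_train, 21L)
  expect_equal(res$n_test, 7L)
  expect_equal(res$n_instances, 12L)
  expect_true(res$accuracy >= 0 && res$accuracy <= 1)
  # permuting the split labels leaves the rotation-averaged result unchanged
  pat2 <- pat
  relab <- c(3L, 1L, 4L, 2L)[attr(pat, "split")]
  attr(pat2, "split") <- relab
  res2 <- run_scheme(pat2, "within_target_delay")
  expect_equal(res2$accuracy, res$accuracy, tolerance = 1e-12)
})

test_that("zero-signal patterns decode at chance (the pipeline manufactures no information)", {
  accs <- vapply(1:50, function(s) {
    pat <- simulate_null_patterns(24, seed = 1000 + s)
    run_scheme(pat, "within_target_delay")$accuracy
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2 * se + 1e-12)
})

test_that("the cross-decoding ratio matches its definition and flags chance denominators", {
  expect_equal(cross_ratio(0.75, 0.75)$ratio, 1)
  expect_equal(cross_ratio(0.75, 0.50)$ratio, 0)
  expect_equal(cross_ratio(0.70, 0.60)$ratio, 0.5)
  r <- cross_ratio(c(0.75, 0.505), c(0.6, 0.6))
  expect_true(r$valid[1L])
  expect_false(r$valid[2L])
  expect_true(is.na(r$ratio[2L]))
})

test_that("sector averaging is an unweighted mean, invariant to ROI order", {
  df <- data.frame(
    participant = "sub-01",
    roi = c("V1", "V2", "LOT", "V3b"),
    sector = c("posterior", "posterior", "ventral", NA),
    scheme = "within_target_delay", trial_set = "with_distractors",
    accuracy = c(0.6, 0.8, 0.7, 0.9), stringsAsFactors = FALSE)
  s <- sector_average(df)
  expect_equal(s$accuracy[s$sector == "posterior"], 0.7)
  expect_equal(s$accuracy[s$sector == "ventral"], 0.7)
  expect_false("V3b" %in% s$sector)  # out-of-sector ROIs are dropped
  s2 <- sector_average(df[c(4, 3, 2, 1), ])
  expect_equal(s2[order(s2$sector), ], s[order(s$sector), ], ignore_attr = TRUE)
  expect_error(sector_average(transform(df, sector = NA)), "no ROI")
})

test_that("train and test splits never overlap within a rotation", {
  pat <- simulate_null_patterns(16, seed = 3)
  split <- attr(pat, "split")
  for (rot in 1:4) {
    train_idx <- which(split %in% setdiff(1:4, rot))
    test_idx <- which(split == rot)
    expect_length(intersect(train_idx, test_idx), 0L)
    expect_length(train_idx, 21L)
    expect_length(test_idx, 7L)
  }
})
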