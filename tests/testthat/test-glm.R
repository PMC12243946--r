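test_that("detrending annihilates quadratic trends and is an orthogonal projection", {
  t <- 1:50
  x <- rbind(3 + 0.2 * t - 0.01 * t^2, rep(1, 50))
  expect_lt(max(abs(detrend(x))), 1e-10)
  set.seed(1)
  y <- matrix(rnorm(200), 4L)
  r <- detrend(y)
  basis <- cbind(1, 1:50, (1:50)^2)
  expect_lt(max(abs(r %*% basis)), 1e-8)
  expect_error(detrend(y[, 1:2, drop = FALSE]), "4 TRs")
})

test_that("the split plan yields 28 combinations for 13+14 and 14+14 runs, odd halves first", {
  p1 <- build_split_plan(c(13L, 14L))
  expect_equal(vwmdecode:::n_split_patterns(p1), 28L)
  expect_equal(vapply(p1$splits, function(s) length(s$runs), integer(1)),
               c(7L, 6L, 7L, 7L))
  expect_equal(vapply(p1$splits, function(s) length(s$combinations), integer(1)),
               rep(7L, 4L))
  # 7-run halves: all 6-run subsets; 6-run half: all 5-run subsets + all 6
  expect_equal(sort(unique(lengths(p1$splits[[1L]]$combinations))), 6L)
  expect_equal(sort(unique(lengths(p1$splits[[2L]]$combinations))), c(5L, 6L))
  # odd run indices go to the odd half
  expect_equal(p1$splits[[1L]]$runs, sprintf("s1_r%02d", seq(1, 13, 2)))
  p2 <- build_split_plan(c(14L, 14L))
  expect_equal(vwmdecode:::n_split_patterns(p2), 28L)
  expect_true(all(vapply(p2$splits, function(s) length(s$runs), integer(1)) == 7L))
  # runs never shared across splits
  all_runs <- unlist(lapply(p1$splits, `[[`, "runs"))
  expect_false(any(duplicated(all_runs)))
  for (s in p1$splits) expect_true(all(unlist(s$combinations) %in% s$runs))
  expect_warning(build_split_plan(c(10L, 10L)), "calibrated")
  expect_error(suppressWarnings(build_split_plan(c(2L, 13L))), "at least 2")
})

test_that("the FIR design has 480 stimulus columns, each trial filling 30 consecutive rows", {
  sch <- round_onsets_to_tr(random_run_schedule(31))
  X <- vwmdecode:::fir_design_matrix(sch)
  expect_equal(ncol(X), 480L)
  expect_equal(nrow(X), 380L)
  # each column holds at most one event per run
  expect_true(all(colSums(X) <= 1))
  ons <- vwmdecode:::trial_onsets(sch)
  for (tr in c(1L, 16L)) {
    ci <- ons$condition[tr]
    o <- round(ons$onset[tr] / 0.8)
    rows <- which(rowSums(X[, (ci - 1L) * 30L + 1:30, drop = FALSE]) > 0)
    expect_equal(rows, seq(o + 1L, min(o + 30L, 380L)))
  }
})

test_that("noiseless FIR estimation recovers the simulated truth to machine precision", {
  sm <- fx_small_runs()
  betas <- fit_fir_glm(sm$runs, sm$scheds)
  B <- true_lag_betas(sm$truth, sm$hemo)
  expect_lt(max(abs(betas - B)) / max(abs(B)), 1e-10)
  # all-zero data give all-zero betas
  zero_runs <- lapply(sm$runs, function(r) r * 0)
  expect_true(all(fit_fir_glm(zero_runs, sm$scheds) == 0))
})

test_that("estimation is equivariant to vertex permutation", {
  sm <- fx_small_runs()
  set.seed(99)
  noisy <- lapply(sm$runs, function(r) unclass(r) + matrix(rnorm(length(r)), nrow(r)))
  perm <- c(3L, 1L, 2L, 10L, 9L, 4L, 5L, 8L, 6L, 7L)
  b1 <- fit_fir_glm(noisy, sm$scheds)
  b2 <- fit_fir_glm(lapply(noisy, function(r) r[perm, ]), sm$scheds)
  expect_equal(b2, b1[perm, ], tolerance = 1e-10)
})

test_that("single-run fits warn and are rank deficient", {
  sm <- fx_small_runs()
  expect_warning(
    expect_error(fit_fir_glm(sm$runs[1], sm$scheds[1]), "rank deficient"),
    "single run")
})

test_that("the multi-combination fit matches per-combination fits exactly", {
  sm <- fx_small_runs()
  plan <- suppressWarnings(build_split_plan(c(13L, 14L)))
  # rename the six runs as split 1's even half (6 runs -> 7 combinations)
  runs <- stats::setNames(sm$runs, plan$splits[[2L]]$runs)
  scheds <- stats::setNames(sm$scheds, plan$splits[[2L]]$runs)
  mini_plan <- plan
  mini_plan$splits <- plan$splits[2L]
  fits <- vwmdecode:::fit_fir_glm_multi(runs, scheds, mini_plan)
  expect_equal(length(fits), 7L)
  for (j in c(1L, 7L)) {
    ids <- mini_plan$splits[[1L]]$combinations[[j]]
    direct <- fit_fir_glm(runs[ids], scheds[ids])
    expect_equal(fits[[sprintf("split1_comb%d", j)]], direct, tolerance = 1e-10)
  }
})

test_that("assembled patterns number 28 per condition and lag, and ROI bounds are checked", {
  nl <- fx_noiseless()
  pat <- nl$patterns
  expect_equal(dim(pat), c(24L, 16L, 30L, 28L))
  expect_equal(tabulate(attr(pat, "split")), rep(7L, 4L))
  plan <- suppressWarnings(build_split_plan(c(13L, 14L)))
  fits <- list(split1_comb1 = matrix(0, 5, 480))
  expect_error(assemble_patterns(fits, plan, integer(0)), "empty ROI")
  expect_error(assemble_patterns(fits, plan, 1:2), "missing fitted")
})

test_that("period averaging selects exactly the four lags of each window", {
  expect_equal(vwmdecode:::period_lags("encoding") - 1L, 5:8)
  expect_equal(vwmdecode:::period_lags("delay") - 1L, 12:15)
  nl <- fx_noiseless()
  enc <- average_period(nl$patterns, "encoding")
  expect_equal(attr(enc, "lags"), 5:8)
  expect_equal(dim(enc), c(24L, 16L, 28L))
  # identical patterns at every lag average to themselves
  flat <- nl$patterns
  for (l in 2:30) flat[, , l, ] <- flat[, , 1L, ]
  expect_equal(average_period(flat, "delay")[, , 1L], flat[, , 1L, 1L],
               ignore_attr = TRUE)
})

test_that("detrend-free noiseless patterns equal ground truth; detrended pipeline stays close", {
  nl <- fx_noiseless()
  tru <- true_pattern_array(nl$truth, nl$hemo)
  # the full pipeline (with detrending) absorbs a little signal into the
  # trend regressors but stays within a few percent of truth
  relerr <- max(abs(nl$patterns[, , , 1L] - tru)) / max(abs(tru))
  expect_lt(relerr, 0.1)
})

test_that("ROI-mean time courses follow the convolved forward model", {
  nl <- fx_noiseless()
  # bypass detrending: fit raw runs for one combination
  plan <- suppressWarnings(build_split_plan(c(13L, 14L)))
  ids <- plan$splits[[1L]]$combinations[[1L]]
  betas <- fit_fir_glm(nl$part$runs[ids], nl$part$schedules[ids])
  fits <- stats::setNames(
    rep(list(betas), 28L),
    vwmdecode:::combo_ids(plan)$id)
  pat <- assemble_patterns(fits, plan, 1:24, "ALL")
  tc <- roi_mean_timecourse(pat)
  cp <- attr(true_lag_betas(nl$truth, nl$hemo), "profiles")
  cond <- vwm_conditions()
  for (ci in c(1L, 13L)) {  # one with-distractor, one without
    pm <- mean(nl$truth$perceptual[, cond$target[ci]])
    mm <- mean(nl$truth$memory[, cond$target[ci]])
    expected <- nl$truth$gain_encoding * cp$encoding * pm +
      nl$truth$gain_delay * cp$memory * mm
    if (!is.na(cond$distractor[ci])) {
      expected <- expected +
        nl$truth$gain_distractor * cp$distractor * mean(nl$truth$perceptual[, cond$distractor[ci]])
    }
    got <- tc$amplitude[tc$condition == ci][order(tc$lag[tc$condition == ci])]
    expect_equal(got, expected, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # with a stronger distractor than memory gain, the with-distractor delay
  # response exceeds the no-distractor one (positive-mean patterns)
  delay_amp <- function(ci) mean(tc$amplitude[tc$condition == ci & tc$lag %in% 12:15])
  expect_gt(delay_amp(1L), delay_amp(13L))
})
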