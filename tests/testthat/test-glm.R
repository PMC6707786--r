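test_that("build_design constructs stick and convolved stimulus columns", {
  d <- structure(list(n_volumes = 30L,
                      onsets = data.frame(onset = c(0L, 10L, 13L),
                                          condition = "sound",
                                          is_catch = FALSE),
                      isi_volumes = c(3L, 4L, 5L)), class = "event_design")
  ## stick mode with a single onset at 0: 9 shifted unit impulses
  d1 <- d; d1$onsets <- d$onsets[1, , drop = FALSE]
  X <- build_design(d1, hrf = NULL)$X
  for (lag in 0:8) {
    col <- numeric(30); col[1 + lag] <- 1   # response begins at the onset volume
    expect_equal(unname(X[, lag + 1]), col)
  }
  ## unit-impulse HRF reproduces the onset indicator
  Xi <- build_design(d, hrf = c(1, rep(0, 8)))$X
  ind <- numeric(30); ind[d$onsets$onset + 1] <- 1
  expect_equal(unname(Xi[, "stimulus"]), ind)
  ## overlapping HRFs add: direct convolution oracle
  h <- hrf_taps()
  Xc <- build_design(d, hrf = h)$X
  oracle <- numeric(30)
  for (o in d$onsets$onset) {
    idx <- o + seq_along(h); ok <- idx <= 30
    oracle[idx[ok]] <- oracle[idx[ok]] + h[ok]
  }
  expect_equal(unname(Xc[, "stimulus"]), oracle)
  ## catch trials get their own column, never the stimulus one
  d2 <- d; d2$onsets$is_catch <- c(FALSE, FALSE, TRUE)
  dm <- build_design(d2, hrf = h)
  expect_false(is.na(dm$catch_col))
  expect_equal(sum(dm$X[, dm$catch_col] != 0), sum(h != 0))
})

test_that("fit_glm equals the normal-equations oracle", {
  set.seed(21)
  X <- cbind(rnorm(5), rnorm(5), 1)
  Y <- matrix(rnorm(5 * 7), 5, 7)
  fit <- fit_glm(Y, X, contrast_col = 1)
  beta_orc <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_lt(max(abs(fit$coef - beta_orc)), 1e-10)
  ## residuals orthogonal to all design columns
  expect_lt(max(abs(t(X) %*% fit$resid)), 1e-8)
  ## noiseless orthogonal design recovers betas exactly
  Xo <- cbind(rep(c(1, -1), 4), rep(c(1, 1, -1, -1), 2)) / sqrt(8)
  Yo <- Xo %*% c(2, -1)
  fo <- fit_glm(cbind(Yo), cbind(Xo, 1))
  expect_equal(unname(fo$coef[1:2, 1]), c(2, -1), tolerance = 1e-10)
})

test_that("noiseless FIR deconvolution recovers the true taps", {
  sc <- small_cohort()
  des <- lapply(1:2, function(i) make_event_design(80, 12, seed = i))
  sp0 <- sc$spec; sp0$noise_sd <- 1e-9; sp0$n_noise_components <- 0L
  h_true <- hrf_taps()
  ss <- simulate_subject_runs(sp0, sc$rois$labels[[1]], des, hrf = h_true,
                              seed = 3)
  h <- deconvolve_hrf(ss$runs, des, mask = as_mask(sc$rois$labels[[1]]))
  expect_length(h$taps, 9)
  expect_lt(max(abs(h$taps - h_true)), 1e-6)
  ## pure-noise voxels refuse aggregation
  spN <- sc$spec; spN$effect_size <- 0; spN$n_noise_components <- 0L
  ssN <- simulate_subject_runs(spN, sc$rois$labels[[1]], des, seed = 4)
  expect_error(deconvolve_hrf(ssN$runs, des, mask = as_mask(sc$rois$labels[[1]])),
               class = "subcortaud_no_responsive_voxels")
})

test_that("noise pool selection recovers the planted pool", {
  sc <- small_cohort()
  des <- lapply(1:2, function(i) make_event_design(80, 12, seed = i))
  ss <- simulate_subject_runs(sc$spec, sc$rois$labels[[1]], des, seed = 8)
  pool <- select_noise_pool(ss$runs, des, sc$brain, f_alpha = 0.05)
  truth_pool <- sc$rois$labels[[1]]$data == 0
  sel <- pool$data != 0
  expect_gt(sum(sel & truth_pool) / sum(truth_pool), 0.95)
  expect_lt(sum(sel & !truth_pool) / sum(!truth_pool), 0.10)
  ## all-null data: pool fraction ~ 1 - f_alpha
  spN <- sc$spec; spN$effect_size <- 0; spN$n_noise_components <- 0L
  ssN <- simulate_subject_runs(spN, sc$rois$labels[[1]], des, seed = 9)
  poolN <- select_noise_pool(ssN$runs, des, sc$brain, f_alpha = 0.05)
  frac <- mask_size(poolN) / prod(dim(sc$brain$data))
  expect_lt(abs(frac - 0.95), 3 * sqrt(0.05 * 0.95 / prod(dim(sc$brain$data))) + 0.01)
  ## degenerate threshold empties the pool
  expect_error(select_noise_pool(ss$runs, des, sc$brain, f_alpha = 1 - 1e-12),
               class = "subcortaud_empty_pool")
})

test_that("noise regressors are orthonormal and capture planted rank", {
  sc <- small_cohort()
  des <- list(make_event_design(80, 12, seed = 1))
  spK <- sc$spec; spK$n_noise_components <- 1L; spK$noise_component_sd <- 10
  ss <- simulate_subject_runs(spK, sc$rois$labels[[1]], des, seed = 10)
  pool <- as_mask(volume(array(as.integer(sc$rois$labels[[1]]$data == 0),
                               dim(sc$brain$data)), sc$brain$affine))
  N <- compute_noise_regressors(ss$runs[[1]], pool, 4)
  expect_equal(dim(N), c(80L, 4L))
  expect_lt(max(abs(crossprod(N) - diag(4))), 1e-8)
  ## rank-1 planted structure: first PC dominates the pool variance
  P <- subcortaud:::scale_pool(
    subcortaud:::as_timeseries(ss$runs[[1]])[, pool$data != 0])
  d2 <- svd(P, nu = 0, nv = 0)$d^2
  expect_gt(d2[1] / sum(d2), 0.5)
  expect_gt(sum((t(N[, 1]) %*% P)^2) / sum(d2), 0.5)
  ## k = 0 gives an empty matrix; k beyond rank errors
  expect_equal(ncol(compute_noise_regressors(ss$runs[[1]], pool, 0)), 0)
  expect_error(compute_noise_regressors(ss$runs[[1]], pool, 80),
               class = "subcortaud_k_too_large")
})

test_that("optimize_k recovers the planted component count within 1", {
  ## background-dominated grid so the score median sits in structured voxels
  tm <- cohort_template(c(28L, 28L, 28L))
  sp <- cohort_spec(n_subjects = 1, roi_radius_mm = 1.5, jitter_sd_mm = 0)
  sp$roi_centers_mm <- sp$roi_centers_mm[1:2, , drop = FALSE] * 0.5
  rois <- make_cohort_rois(sp, tm)
  brain <- as_mask(volume(array(1L, dim(tm$data)), tm$affine))
  des <- lapply(1:4, function(i) make_event_design(100, 18, seed = 10 + i))
  ks <- kn <- integer(0)
  for (seed in 1:5) {
    spK <- sp; spK$n_noise_components <- 3L
    ss <- simulate_subject_runs(spK, rois$labels[[1]], des, seed = seed)
    pool <- select_noise_pool(ss$runs, des, brain)
    ks <- c(ks, optimize_k(ss$runs, des, pool, brain, k_max = 5)$k)
    spN <- sp; spN$n_noise_components <- 0L
    ssN <- simulate_subject_runs(spN, rois$labels[[1]], des, seed = 200 + seed)
    poolN <- select_noise_pool(ssN$runs, des, brain)
    kn <- c(kn, optimize_k(ssN$runs, des, poolN, brain, k_max = 5)$k)
  }
  expect_gte(mean(ks %in% 2:4), 0.9)
  expect_gt(mean(kn <= 1), 0.5)
  expect_true(all(ks <= 5))
  expect_error(optimize_k(list(matrix(rnorm(40), 10)), des[1],
                          rand_mask(), rand_mask()),
               class = "subcortaud_too_few_runs")
})

test_that("fixed-effects combination follows the inverse-variance formulas", {
  ## hand-computed two-fold case
  f1 <- list(beta = 2, se = 1, dof = 10)
  f2 <- list(beta = 4, se = 2, dof = 12)
  cmb <- fixed_effects_combine(list(f1, f2))
  expect_equal(unname(cmb$beta), (2 * 1 + 4 * 0.25) / 1.25)
  expect_equal(unname(cmb$se), sqrt(1 / 1.25))
  expect_equal(cmb$dof, 22)
  expect_equal(unname(cmb$t), 2.4 / sqrt(0.8))
  ## n identical folds shrink the variance by n
  fs <- replicate(4, list(list(beta = c(1, 2), se = c(0.5, 0.5), dof = 5))[[1]],
                  simplify = FALSE)
  c4 <- fixed_effects_combine(fs)
  expect_equal(unname(c4$se^2), rep(0.25 / 4, 2))
  expect_equal(unname(c4$beta), c(1, 2))
  ## a single fold passes through
  c1 <- fixed_effects_combine(list(f1))
  expect_equal(unname(c1$beta), 2)
  expect_equal(unname(c1$se), 1)
  ## zero se with disagreeing betas is rejected
  expect_error(fixed_effects_combine(list(list(beta = 1, se = 0, dof = 2),
                                          list(beta = 2, se = 0, dof = 2))),
               class = "subcortaud_inconsistent_folds")
})

test_that("cross-validation layout reproduces the published fold arithmetic", {
  ## 12 runs/session, 4 stimulus sets: 9 training + 3 testing runs,
  ## 126 training + 42 testing sounds per fold
  p1 <- cv_fold_plan(168, n_sets = 4, runs_per_session = 12, n_sessions = 2)
  expect_equal(p1$train_runs, 9)
  expect_equal(p1$test_runs, 3)
  expect_equal(p1$train_sounds, 126)
  expect_equal(p1$test_sounds, 42)
  expect_equal(p1$n_folds, 4)
  ## non-overlapping test runs across folds: 4 folds x 3 runs = 12 runs
  expect_equal(p1$n_folds * p1$test_runs, 12)
  p2 <- cv_fold_plan(96, n_sets = 4, runs_per_session = 8, n_sessions = 2)
  expect_equal(p2$train_sounds, 72)
  expect_equal(p2$test_sounds, 24)
  expect_equal(p2$train_runs, 6)
})

test_that("end-to-end subject analysis separates planted activity", {
  sc <- small_cohort(shape = c(16L, 16L, 16L), radius = 1.5)
  des <- lapply(1:3, function(i) make_event_design(70, 10, seed = 30 + i))
  ss <- simulate_subject_runs(sc$spec, sc$rois$labels[[1]], des, seed = 12)
  res <- analyze_subject(ss$runs, des, sc$brain, k_max = 2)
  act <- sc$rois$labels[[1]]$data > 0
  expect_gt(median(res$t$data[act]), quantile(res$t$data[!act], 0.99))
  expect_true(all(res$p$data >= 0 & res$p$data <= 1))
  ## determinism given the fixture seed
  res2 <- analyze_subject(ss$runs, des, sc$brain, k_max = 2)
  expect_identical(res$t$data, res2$t$data)
})
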