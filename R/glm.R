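#' Build a single-run design matrix
#'
#' The stimulus regressor is the onset indicator convolved with the supplied
#' HRF taps; in deconvolution mode (`hrf = NULL`) it is replaced by
#' `n_sticks` shifted unit-impulse (FIR "stick") columns. Catch trials
#' (stimulus repetitions) are modelled by a separate regressor of no interest
#' and never enter the contrast. An intercept is always present.
#'
#' @param design an `event_design`.
#' @param hrf numeric FIR taps, or `NULL` for stick (deconvolution) mode.
#' @param n_sticks number of stick columns in deconvolution mode (default 9).
#' @return list of class `design_matrix`: `X` (time x regressors with column
#'   labels), `stim_cols` (indices of stimulus columns), `catch_col`
#'   (index or NA), `intercept_col`.
#' @export
build_design <- function(design, hrf = NULL, n_sticks = 9L) {
  stopifnot(inherits(design, "event_design"))
  n <- design$n_volumes
  on <- design$onsets
  if (any(on$onset < 0 | on$onset >= n))
    stop(vol_error("onsets outside the run length", "bad_onsets"))
  stim_on <- on$onset[!on$is_catch]
  if (is.null(hrf)) {
    X <- vapply(seq_len(n_sticks) - 1L, function(lag)
      convolve_onsets(stim_on + lag, 1, n), numeric(n))
    colnames(X) <- paste0("stick_", seq_len(n_sticks))
    stim_cols <- seq_len(n_sticks)
  } else {
    X <- matrix(convolve_onsets(stim_on, hrf, n), ncol = 1,
                dimnames = list(NULL, "stimulus"))
    stim_cols <- 1L
  }
  catch_col <- NA_integer_
  if (any(on$is_catch)) {
    cc <- if (is.null(hrf)) convolve_onsets(on$onset[on$is_catch], rep(1, n_sticks) / n_sticks, n)
          else convolve_onsets(on$onset[on$is_catch], hrf, n)
    X <- cbind(X, catch = cc)
    catch_col <- ncol(X)
  }
  X <- cbind(X, intercept = 1)
  if (qr(X)$rank < ncol(X))
    stop(vol_error("design matrix is rank deficient", "rank_deficient"))
  structure(list(X = X, stim_cols = stim_cols, catch_col = catch_col,
                 intercept_col = ncol(X)),
            class = "design_matrix")
}

## flatten a 4-D volume (or pass through a matrix) to time x voxels
as_timeseries <- function(run) {
  if (inherits(run, "volume")) {
    d <- dim(run$data)
    t(matrix(run$data, prod(d[1:3]), d[4]))
  } else as.matrix(run)
}

## concatenate runs in time with per-run versions of a column-builder
concat_design <- function(Xs) {
  p <- ncol(Xs[[1]])
  n_runs <- length(Xs)
  rows <- vapply(Xs, nrow, 1L)
  X <- matrix(0, sum(rows), p - 1 + n_runs)
  off <- 0L
  for (r in seq_len(n_runs)) {
    idx <- off + seq_len(rows[r])
    X[idx, seq_len(p - 1)] <- Xs[[r]][, seq_len(p - 1), drop = FALSE]
    X[idx, p - 1 + r] <- 1          # run-wise intercept
    off <- off + rows[r]
  }
  X
}

#' Ordinary least squares fit of one run
#'
#' @param Y time x voxels matrix, or a 4-D `volume`.
#' @param X design matrix (full column rank).
#' @param contrast_col column whose coefficient is the effect of interest.
#' @return list: `beta`, `se` (per voxel, for `contrast_col`), `dof`,
#'   `coef` (all coefficients, p x voxels), `resid`.
#' @export
fit_glm <- function(Y, X, contrast_col = 1L) {
  Y <- as_timeseries(Y)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop(vol_error("design matrix is rank deficient", "rank_deficient"))
  coef <- qr.coef(qx, Y)
  res <- Y - X %*% coef
  dof <- nrow(X) - qx$rank
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[contrast_col, contrast_col])
  list(beta = coef[contrast_col, ], se = se, dof = dof, coef = coef,
       resid = res)
}

#' FIR deconvolution of the hemodynamic response
#'
#' Estimates a per-voxel 9-tap FIR response by least squares on the
#' concatenated training runs (stick design, run-wise intercepts), then
#' returns a single subject-level HRF: the peak-normalized average over the
#' top-decile most responsive mask voxels (responsiveness = stick-model F
#' statistic). Voxels are deemed responsive only if their F-test survives a
#' Bonferroni-corrected 0.05 level; with no responsive voxel the fit is
#' refused with a `subcortaud_no_responsive_voxels` condition.
#'
#' @param runs list of training runs (4-D `volume`s or time x voxel matrices).
#' @param designs list of `event_design`, one per run.
#' @param mask optional logical/0-1 vector or mask `volume` restricting the
#'   voxels considered.
#' @param n_sticks FIR length (default 9).
#' @param per_voxel if `TRUE` return the full tap matrix instead of the
#'   aggregated subject-level HRF.
#' @return an `hrf_estimate`: list(`taps` unit-peak numeric, `n_sticks`), or
#'   the taps matrix when `per_voxel = TRUE`.
#' @export
deconvolve_hrf <- function(runs, designs, mask = NULL, n_sticks = 9L,
                           per_voxel = FALSE) {
  Ys <- lapply(runs, as_timeseries)
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "volume")) as.vector(mask$data != 0) else as.logical(mask)
    Ys <- lapply(Ys, function(Y) Y[, mv, drop = FALSE])
  }
  sf <- stick_fit(Ys, designs, n_sticks)
  if (per_voxel) return(sf$taps)
  aggregate_hrf(sf, n_sticks)
}

## one concatenated stick-model fit shared by pool selection and HRF
## deconvolution: per-voxel FIR taps plus the stimulus-block F statistic
stick_fit <- function(Ys, designs, n_sticks = 9L) {
  Y <- do.call(rbind, Ys)
  Xs <- lapply(designs, function(d) build_design(d, hrf = NULL, n_sticks = n_sticks)$X)
  X <- concat_design(Xs)
  if (nrow(X) < ncol(X))
    stop(vol_error("fewer time points than regressors", "underdetermined"))
  fit <- fit_glm(Y, X)
  fstat <- stim_f_stat(Y, X, seq_len(n_sticks), fit)
  list(taps = fit$coef[seq_len(n_sticks), , drop = FALSE],
       F = fstat$F, df1 = fstat$df1, df2 = fstat$df2)
}

## peak-normalized average of FIR taps over the top-decile responsive voxels
aggregate_hrf <- function(sf, n_sticks) {
  n_vox <- length(sf$F)
  pf_ <- stats::pf(sf$F, sf$df1, sf$df2, lower.tail = FALSE)
  responsive <- which(pf_ < 0.05 / n_vox)
  if (length(responsive) == 0L)
    stop(vol_error("no responsive voxels: cannot aggregate an HRF",
                   "no_responsive_voxels"))
  ord <- responsive[order(sf$F[responsive], decreasing = TRUE)]
  top <- ord[seq_len(max(1L, ceiling(length(ord) / 10)))]
  h <- rowMeans(sf$taps[, top, drop = FALSE])
  structure(list(taps = h / max(h), n_sticks = n_sticks), class = "hrf_estimate")
}

## F statistic of the stimulus block vs the reduced (nuisance-only) model
stim_f_stat <- function(Y, X, stim_cols, fit = NULL) {
  if (is.null(fit)) fit <- fit_glm(Y, X)
  X0 <- X[, -stim_cols, drop = FALSE]
  res0 <- Y - X0 %*% qr.coef(qr(X0), Y)
  rss1 <- colSums(fit$resid^2)
  rss0 <- colSums(res0^2)
  df1 <- length(stim_cols)
  df2 <- fit$dof
  list(F = pmax(0, (rss0 - rss1) / df1 / (rss1 / df2)), df1 = df1, df2 = df2)
}

#' Select the noise pool of non-responsive voxels
#'
#' Voxelwise F test of the full stimulus (stick) model against the
#' intercept-only model on the concatenated training runs; the pool consists
#' of brain voxels whose F statistic falls below the critical value at
#' `f_alpha` (i.e. voxels not significant at that uncorrected level).
#'
#' @param runs,designs training runs and their designs.
#' @param brain_mask mask `volume` of voxels to consider.
#' @param f_alpha pool-selection significance level (default 0.05).
#' @param n_sticks FIR length for the stimulus model.
#' @return a `binary_mask` `volume`; attribute `"F"` carries the statistics.
#' @export
select_noise_pool <- function(runs, designs, brain_mask, f_alpha = 0.05,
                              n_sticks = 9L) {
  stopifnot(inherits(brain_mask, "volume"))
  mv <- as.vector(brain_mask$data != 0)
  Ys <- lapply(runs, function(r) as_timeseries(r)[, mv, drop = FALSE])
  sf <- stick_fit(Ys, designs, n_sticks)
  pool_from_f(sf, f_alpha, brain_mask)
}

pool_from_f <- function(sf, f_alpha, brain_mask) {
  mv <- as.vector(brain_mask$data != 0)
  crit <- stats::qf(1 - f_alpha, sf$df1, sf$df2)
  pool_v <- sf$F < crit
  if (!any(pool_v))
    stop(vol_error("noise pool is empty", "empty_pool"))
  arr <- array(0L, dim(brain_mask$data)[1:3])
  arr[mv] <- as.integer(pool_v)
  out <- as_mask(volume(arr, brain_mask$affine))
  attr(out, "F") <- sf$F
  out
}

#' Principal-component noise regressors of one run
#'
#' Pool voxel time courses are centered and variance-normalized; the top `k`
#' principal-component time courses are returned, orthonormalized.
#'
#' @param run a 4-D `volume` or time x voxel matrix.
#' @param pool pool `binary_mask` (or logical vector over voxels).
#' @param k number of components (0 allowed; must not exceed the pool rank).
#' @return time x k matrix with orthonormal columns.
#' @export
compute_noise_regressors <- function(run, pool, k) {
  Y <- as_timeseries(run)
  pv <- if (inherits(pool, "volume")) as.vector(pool$data != 0) else as.logical(pool)
  if (k == 0L) return(matrix(0, nrow(Y), 0))
  P <- scale_pool(Y[, pv, drop = FALSE])
  if (k >= nrow(Y) || k > ncol(P))
    stop(vol_error("k exceeds the rank of the pool time course matrix",
                   "k_too_large"))
  sv <- svd(P, nu = k, nv = 0)
  if (sv$d[k] < 1e-12 * sv$d[1])
    stop(vol_error("k exceeds the rank of the pool time course matrix",
                   "k_too_large"))
  sv$u
}

## center and unit-variance scale pool time courses; flat voxels become zero
## columns so column alignment across runs is preserved
scale_pool <- function(P) {
  P <- sweep(P, 2, colMeans(P))
  s <- sqrt(colSums(P^2) / (nrow(P) - 1))
  sweep(P, 2, pmax(s, 1e-12), "/")
}

#' Choose the number of noise regressors by inner cross-validation
#'
#' For each `k` in `0..k_max` and each leave-one-run-out inner fold, the
#' stimulus-plus-noise model is fitted on the inner-training runs and scored
#' on the held-out run by cross-validated variance explained. The noise
#' regressors share one spatial basis - the principal components of the
#' concatenated inner-training pool - so their voxel loadings learned on the
#' training runs transfer to the held-out run, whose regressors are obtained
#' by projecting that spatial basis onto its own pool time courses. Scores
#' are the median over the scored voxels; k values whose score lies within
#' `tol` of the maximum count as ties, and ties resolve to the smallest k
#' (parsimony).
#'
#' By default all brain voxels are scored: under a planted noise model whose
#' structured components live outside the responsive regions, non-pool voxels
#' carry no structured variance and a score restricted to them is flat in k,
#' leaving the number of components unidentifiable. Scoring the pool voxels -
#' against regressors whose loadings were learned on the other runs - restores
#' identifiability; `score_voxels = "nonpool"` gives the restricted variant.
#'
#' @param runs,designs training runs and their designs (at least 2 runs).
#' @param pool noise-pool `binary_mask`.
#' @param brain_mask analysis mask `volume`.
#' @param hrf `hrf_estimate` or numeric taps for the stimulus regressor.
#' @param k_max maximum number of components tried.
#' @param score_voxels `"brain"` (default) or `"nonpool"`.
#' @param tol tie tolerance on the variance-explained score.
#' @param max_basis_voxels,max_score_voxels caps on the number of pool voxels
#'   entering the PCA basis and of voxels entering the score median; larger
#'   sets are subsampled with a fixed internal seed (the estimates are
#'   medians/principal subspaces, insensitive to seeded subsampling).
#' @return list: `k` (selected), `scores` (median CV score per k, names
#'   "0".."k_max").
#' @export
optimize_k <- function(runs, designs, pool, brain_mask, hrf = hrf_taps(),
                       k_max = 4L, score_voxels = c("brain", "nonpool"),
                       tol = 0.005, max_basis_voxels = 20000L,
                       max_score_voxels = 10000L) {
  score_voxels <- match.arg(score_voxels)
  if (length(runs) < 2L)
    stop(vol_error("optimize_k needs at least two training runs", "too_few_runs"))
  taps <- if (inherits(hrf, "hrf_estimate")) hrf$taps else hrf
  Ys <- lapply(runs, as_timeseries)
  if (k_max >= min(vapply(Ys, nrow, 1L)))
    stop(vol_error("k_max must be smaller than the run length", "k_too_large"))
  mv <- as.vector(brain_mask$data != 0)
  pv <- as.vector(pool$data != 0)
  score_v <- if (score_voxels == "brain") mv else mv & !pv
  ## seeded subsampling for tractability; RNG state restored afterwards
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else { stats::runif(1); old_seed <- get(".Random.seed", envir = globalenv()) }
  on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(920L)
  if (sum(pv) > max_basis_voxels) {
    idx <- which(pv)
    pv[] <- FALSE
    pv[sample(idx, max_basis_voxels)] <- TRUE
  }
  if (sum(score_v) > max_score_voxels) {
    idx <- which(score_v)
    score_v[] <- FALSE
    score_v[sample(idx, max_score_voxels)] <- TRUE
  }
  stim <- lapply(designs, function(d)
    convolve_onsets(d$onsets$onset[!d$onsets$is_catch], taps, d$n_volumes))
  n_runs <- length(runs)
  scores <- matrix(NA_real_, n_runs, k_max + 1L)
  for (te in seq_len(n_runs)) {
    tr <- setdiff(seq_len(n_runs), te)
    Ptr <- lapply(Ys[tr], function(Y) scale_pool(Y[, pv, drop = FALSE]))
    rows <- vapply(Ptr, nrow, 1L)
    Pcat <- do.call(rbind, Ptr)
    sv <- svd(Pcat, nu = k_max, nv = 0)
    ## component time courses in pool units on both sides: N = P V with
    ## V = P' U D^-1 the training spatial basis, so Ntr = U D and the
    ## held-out run gets the same basis projected onto its own pool
    Ntr <- sv$u %*% diag(sv$d[seq_len(k_max)], k_max)
    Pte <- scale_pool(Ys[[te]][, pv, drop = FALSE])
    Nte <- Pte %*% (t(Pcat) %*% sv$u) %*% diag(1 / sv$d[seq_len(k_max)], k_max)
    y_te <- Ys[[te]][, score_v, drop = FALSE]
    y_te <- sweep(y_te, 2, colMeans(y_te))
    x_te <- stim[[te]] - mean(stim[[te]])
    tss <- colSums(y_te^2)
    Ytr <- do.call(rbind, lapply(Ys[tr], function(Y) Y[, score_v, drop = FALSE]))
    for (k in 0:k_max) {
      Xtr <- cbind(do.call(c, stim[tr]),
                   if (k > 0) Ntr[, seq_len(k), drop = FALSE])
      Xtr <- concat_design(split_rows(cbind(Xtr, 1), rows))
      cf <- qr.coef(qr(Xtr), Ytr)
      pred <- outer(x_te, cf[1, ])
      if (k > 0) {
        Nk <- sweep(Nte[, seq_len(k), drop = FALSE], 2,
                    colMeans(Nte[, seq_len(k), drop = FALSE]))
        pred <- pred + Nk %*% cf[1 + seq_len(k), , drop = FALSE]
      }
      scores[te, k + 1L] <- stats::median(1 - colSums((y_te - pred)^2) / tss)
    }
  }
  med <- colMeans(scores)
  names(med) <- as.character(0:k_max)
  list(k = which(med >= max(med) - tol)[1] - 1L, scores = med)
}

split_rows <- function(X, rows) {
  off <- cumsum(c(0L, rows))
  lapply(seq_along(rows), function(r) X[off[r] + seq_len(rows[r]), , drop = FALSE])
}

#' Fixed-effects combination of per-fold estimates
#'
#' Inverse-variance weighted mean of the per-run contrast estimates:
#' `beta = sum(b/se^2) / sum(1/se^2)`, combined variance `1/sum(1/se^2)`,
#' `t = beta/se`, degrees of freedom summed. P-values are one-sided positive
#' by default (activation mapping of sound versus silence); set
#' `sided = "two"` for two-sided.
#'
#' @param fits list of lists with elements `beta`, `se` (vectors) and `dof`.
#' @param sided `"one"` (default) or `"two"`.
#' @return list: `beta`, `se`, `t`, `p`, `dof`.
#' @export
fixed_effects_combine <- function(fits, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(length(fits) >= 1L)
  b <- do.call(rbind, lapply(fits, `[[`, "beta"))
  s <- do.call(rbind, lapply(fits, `[[`, "se"))
  if (any(s == 0)) {
    zi <- which(s == 0, arr.ind = TRUE)
    for (v in unique(zi[, 2]))
      if (length(unique(b[s[, v] == 0, v])) > 1L)
        stop(vol_error("zero standard error with disagreeing betas",
                       "inconsistent_folds"))
  }
  w <- 1 / s^2
  beta <- colSums(b * w) / colSums(w)
  se <- sqrt(1 / colSums(w))
  dof <- sum(vapply(fits, `[[`, 1, "dof"))
  t <- beta / se
  p <- if (sided == "one") stats::pt(t, dof, lower.tail = FALSE)
       else 2 * stats::pt(abs(t), dof, lower.tail = FALSE)
  list(beta = beta, se = se, t = t, p = p, dof = dof)
}

#' Cross-validated denoised GLM for one subject
#'
#' Implements the full single-subject chain: each run serves once as the test
#' set of an outer fold; on the fold's training runs the noise pool is
#' selected (F below the `f_alpha` critical value), the number of
#' principal-component noise regressors is optimized by inner
#' cross-validation, and the subject-level HRF is estimated by FIR
#' deconvolution. The test run is then fitted by OLS with the HRF-convolved
#' stimulus regressor plus its own pool-derived noise regressors, and all
#' test-run estimates are combined across folds by fixed effects into
#' sound-versus-silence t and p maps.
#'
#' @param runs list of 4-D run `volume`s.
#' @param designs list of `event_design`, one per run.
#' @param brain_mask analysis mask `volume`.
#' @param f_alpha noise-pool selection level.
#' @param k_max maximum number of noise regressors tried.
#' @param n_sticks FIR length.
#' @param sided contrast sidedness, `"one"` or `"two"`.
#' @return list of class `glm_result`: `beta`, `se`, `t`, `p` `volume`s,
#'   `dof`, plus `k` (selected per fold) and `hrf` (per-fold estimates).
#' @export
analyze_subject <- function(runs, designs, brain_mask, f_alpha = 0.05,
                            k_max = 4L, n_sticks = 9L, sided = "one") {
  n_runs <- length(runs)
  stopifnot(n_runs >= 2L)
  mv <- as.vector(brain_mask$data != 0)
  Ys <- lapply(runs, as_timeseries)
  fits <- vector("list", n_runs)
  ks <- integer(n_runs)
  hrfs <- vector("list", n_runs)
  for (te in seq_len(n_runs)) {
    tr <- setdiff(seq_len(n_runs), te)
    ## one concatenated stick fit per fold feeds both the noise pool and HRF
    sf <- stick_fit(lapply(Ys[tr], function(Y) Y[, mv, drop = FALSE]),
                    designs[tr], n_sticks)
    pool <- pool_from_f(sf, f_alpha, brain_mask)
    hrf <- aggregate_hrf(sf, n_sticks)
    k <- optimize_k(Ys[tr], designs[tr], pool, brain_mask, hrf = hrf,
                    k_max = k_max)$k
    N <- compute_noise_regressors(Ys[[te]], pool, k)
    dm <- build_design(designs[[te]], hrf = hrf$taps)
    X <- cbind(dm$X[, -dm$intercept_col, drop = FALSE], N, intercept = 1)
    fit <- fit_glm(Ys[[te]][, mv, drop = FALSE], X, contrast_col = 1L)
    fits[[te]] <- fit[c("beta", "se", "dof")]
    ks[te] <- k
    hrfs[[te]] <- hrf
  }
  comb <- fixed_effects_combine(fits, sided = sided)
  to_vol <- function(x, fill = 0) {
    arr <- array(fill, dim(brain_mask$data)[1:3])
    arr[mv] <- x
    volume(arr, brain_mask$affine)
  }
  structure(list(beta = to_vol(comb$beta), se = to_vol(comb$se),
                 t = to_vol(comb$t), p = to_vol(comb$p, fill = 1),
                 dof = comb$dof, k = ks, hrf = hrfs),
            class = "glm_result")
}
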