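test_that("extract_peaks resolves single, orthogonal and nearby lobes", {
  dirs <- sphere_directions(150)
  shape <- c(1L, 1L, 1L)
  lobe <- function(mu, kappa = 20) exp(kappa * (dirs %*% mu)^2)
  ## single lobe along z: one peak within a sampling step of the axis
  odf1 <- array(lobe(c(0, 0, 1)), c(shape, nrow(dirs)))
  pk1 <- extract_peaks(odf1, dirs, min_sep_deg = 25)
  expect_equal(pk1$n_peaks[1, 1, 1], 1L)
  ang_z <- acos(min(1, abs(pk1$peaks[1, 1, 1, 1, 3]))) * 180 / pi
  expect_lt(ang_z, 12)
  ## two orthogonal lobes: two peaks about 90 degrees apart
  odf2 <- array(lobe(c(0, 0, 1)) + lobe(c(1, 0, 0)), c(shape, nrow(dirs)))
  pk2 <- extract_peaks(odf2, dirs, min_sep_deg = 25)
  expect_equal(pk2$n_peaks[1, 1, 1], 2L)
  sep <- acos(min(1, abs(sum(pk2$peaks[1, 1, 1, 1, ] * pk2$peaks[1, 1, 1, 2, ])))) * 180 / pi
  expect_gt(sep, 75); expect_lt(sep, 105)
  ## two lobes 5 degrees apart with min_sep 10: suppressed to one
  mu2 <- c(sin(5 * pi / 180), 0, cos(5 * pi / 180))
  odf3 <- array(lobe(c(0, 0, 1), 60) + lobe(mu2, 60), c(shape, nrow(dirs)))
  pk3 <- extract_peaks(odf3, dirs, min_sep_deg = 10)
  expect_equal(pk3$n_peaks[1, 1, 1], 1L)
  expect_error(extract_peaks(odf1, matrix(0, 0, 3)),
               class = "subcortaud_empty_directions")
})

test_that("extract_peaks equals an exhaustive sphere-scan oracle", {
  dirs <- sphere_directions(120)
  ang <- acos(pmin(abs(tcrossprod(dirs, dirs)), 1)) * 180 / pi
  diag(ang) <- Inf
  nn_gap <- max(apply(ang, 1, min))
  set.seed(15)
  for (rep in 1:50) {
    n_fib <- sample(1:2, 1)
    mus <- matrix(rnorm(3 * n_fib), ncol = 3)
    mus <- mus / sqrt(rowSums(mus^2))
    a <- rowSums(vapply(seq_len(n_fib),
                        function(i) exp(18 * (dirs %*% mus[i, ])^2),
                        numeric(nrow(dirs))))
    got <- extract_peaks(array(a, c(1, 1, 1, nrow(dirs))), dirs,
                         min_sep_deg = 20, max_peaks = 5, rel_threshold = 0.4)
    ## oracle: brute-force local maxima + greedy suppression
    is_max <- vapply(seq_len(nrow(dirs)), function(i)
      a[i] >= max(a[ang[i, ] <= 1.5 * nn_gap + 1e-9]), TRUE)
    cand <- which(is_max & a >= 0.4 * max(a))
    cand <- cand[order(a[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (ci in cand) {
      if (length(kept) >= 5) break
      if (length(kept) == 0 || min(ang[ci, kept], Inf) >= 20) kept <- c(kept, ci)
    }
    expect_equal(got$n_peaks[1, 1, 1], length(kept))
    if (length(kept))
      expect_equal(matrix(got$peaks[1, 1, 1, seq_along(kept), ], ncol = 3),
                   unname(dirs[kept, , drop = FALSE]))
  }
})

test_that("dilate_mask is a Euclidean ball dilation", {
  aff <- diag(c(0.2, 0.2, 0.2, 1))     # 200 um voxels
  a <- array(0L, c(11, 11, 11)); a[6, 6, 6] <- 1L
  m <- as_mask(volume(a, aff))
  ## radius 0 is the identity
  expect_equal(dilate_mask(m, 0)$data, m$data)
  ## 2.5 voxels at 200 um reaches exactly the voxel centers within 500 um
  d25 <- dilate_mask(m, 2.5)
  idx <- which(d25$data != 0)
  pos <- arrayInd(idx, dim(a)) - 6
  expect_true(all(sqrt(rowSums(pos^2)) <= 2.5 + 1e-9))
  g <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  expect_equal(length(idx), sum(rowSums(g^2) <= 2.5^2))
  expect_equal(dilation_extent_um(2.5, 200), 500)
  ## extensivity on random masks
  for (s in 1:3) {
    rm <- rand_mask(c(9L, 9L, 9L), p = 0.1, seed = 80 + s)
    expect_true(all(dilate_mask(rm, 1.5)$data >= rm$data))
  }
})

test_that("straight-tube tracking delivers streamlines end to end", {
  pf <- make_peak_field(fiber_phantom_spec("straight"))
  seedarr <- array(0L, dim(pf$n_peaks)); seedarr[9:13, 9:13, 2] <- 1L
  seeds <- volume(seedarr, pf$affine)
  sl <- track(pf, seeds, tracking_spec(max_angle_deg = 45, fa_stop = 0.1,
                                       n_seeds = 200, seed = 2))
  expect_gt(length(sl), 100)
  ## >= 95 percent reach within one voxel of the far end
  far <- mean(vapply(sl, function(l) max(l[, 3]) > 21 - 2, TRUE))
  expect_gte(far, 0.95)
  ## lengths equal the tube length within 2 steps + seed offset
  lens <- vapply(sl, function(l) (nrow(l) - 1) * attr(sl, "step_mm"), 1)
  expect_true(all(abs(lens - 21) < 3))
  ## consecutive spacing equals step_mm
  dd <- diff(sl[[1]])
  expect_lt(max(abs(sqrt(rowSums(dd^2)) - attr(sl, "step_mm"))), 1e-6)
  ## bit-reproducible given the seed
  sl2 <- track(pf, seeds, tracking_spec(max_angle_deg = 45, fa_stop = 0.1,
                                        n_seeds = 200, seed = 2))
  expect_identical(sl[[1]], sl2[[1]])
  ## seeds below the FA stop produce nothing
  lowfa <- pf; lowfa$fa <- volume(array(0, dim(pf$n_peaks)), pf$affine)
  expect_length(track(lowfa, seeds, tracking_spec(fa_stop = 0.1, n_seeds = 50)), 0)
})

test_that("turning-angle stopping follows bends only when gentle enough", {
  pf <- make_peak_field(fiber_phantom_spec("bent", bend_angle_deg = 90,
                                           shape = c(25L, 25L, 25L)))
  tr <- attr(pf, "truth")$centerlines[[1]]
  start <- tr$points[1, ]
  seedarr <- array(0L, dim(pf$n_peaks))
  ci <- round(start)                     # world == voxel+0.5 at 1 mm spacing
  seedarr[ci[1] + 1, ci[2] + 1, 3] <- 1L
  seeds <- volume(seedarr, pf$affine)
  ## gentle per-step turning at small steps: the bend is followed
  sl <- track(pf, seeds, tracking_spec(step_mm = 0.5, max_angle_deg = 45,
                                       fa_stop = 0.1, n_seeds = 50, seed = 3))
  lens <- vapply(sl, function(l) (nrow(l) - 1) * 0.5, 1)
  arc_len <- sum(sqrt(rowSums(diff(tr$points)^2)))
  expect_gt(max(lens), 0.7 * arc_len)
  ## a sharp single-voxel 90-degree corner kills propagation
  sharp <- make_peak_field(fiber_phantom_spec("crossing"))
  ## remove one arm so the corner voxel offers only a perpendicular peak
  d <- dim(sharp$n_peaks)
  half <- sharp
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3]))
    if (z > 11 && half$n_peaks[x, y, z] > 0) {
      half$n_peaks[x, y, z] <- 0L
      half$fa$data[x, y, z] <- 0
    }
  seedarr2 <- array(0L, d); seedarr2[11, 11, 2] <- 1L
  sl2 <- track(half, volume(seedarr2, sharp$affine),
               tracking_spec(step_mm = 0.5, max_angle_deg = 45, fa_stop = 0.1,
                             n_seeds = 30, seed = 4))
  ## streamlines stop near the corner: none continue along x beyond it
  if (length(sl2))
    expect_lt(max(vapply(sl2, function(l) max(abs(l[, 1] - 10.5)), 1)), 4)
})

test_that("filter_streamlines agrees with a point-in-ROI membership oracle", {
  pf <- make_peak_field(fiber_phantom_spec("crossing"))
  seedarr <- array(0L, dim(pf$n_peaks))
  seedarr[10:12, 10:12, 2] <- 1L       # on the z tube
  seedarr[2, 10:12, 10:12] <- 2L       # on the x tube
  seeds <- volume(seedarr, pf$affine)
  sl <- track(pf, seeds, tracking_spec(max_angle_deg = 60, fa_stop = 0.1,
                                       n_seeds = 100, seed = 5))
  rois <- subcortaud:::phantom_end_rois(pf, fiber_phantom_spec("crossing"))
  fl <- filter_streamlines(sl, rois, rois)
  ## oracle per streamline
  seed_pts <- attr(sl, "seed_point")
  in_roi <- function(pt, lab_vol) {
    ci <- floor(solve(lab_vol$affine)[1:3, ] %*% c(pt, 1) + 0.5)
    d <- dim(lab_vol$data)
    if (any(ci < 0) || any(ci >= d)) return(0L)
    lab_vol$data[ci[1] + 1, ci[2] + 1, ci[3] + 1]
  }
  keep_orc <- vapply(seq_along(sl), function(i) {
    in_roi(seed_pts[i, ], rois) > 0 &&
      any(apply(sl[[i]], 1, in_roi, lab_vol = rois) > 0)
  }, TRUE)
  expect_equal(length(fl), sum(keep_orc))
  ## a streamline with no ROI contact is dropped, one through two ROIs kept
  expect_true(all(vapply(fl, function(l)
    length(subcortaud:::streamline_labels(l, rois)) > 0, TRUE)))
})

test_that("connectivity matrices count label pairs as percentages", {
  aff <- diag(4)
  lab <- array(0L, c(10, 10, 10))
  lab[2, 2, 2] <- 1L; lab[8, 2, 2] <- 2L; lab[2, 8, 8] <- 3L
  rois <- volume(lab, aff)
  ## two synthetic bundles: one through A and B, one through C only
  ab <- cbind(seq(1, 7, by = 0.5), 1, 1)
  cc <- cbind(1, seq(5, 8, by = 0.5), 7)
  s <- structure(list(ab, ab, cc, cc), class = "streamline_set",
                 seed_point = rbind(ab[1, ], ab[1, ], cc[1, ], cc[1, ]))
  cm <- connectivity_matrix(s, rois)
  expect_equal(unname(cm["1", "2"]), 50)
  expect_equal(unname(cm["3", "3"]), 50)
  expect_equal(unname(cm["1", "1"]), 0)
  expect_equal(unname(cm), t(unname(cm)))
  ## all streamlines in one ROI only: 100 on that diagonal
  s1 <- structure(list(cc, cc), class = "streamline_set")
  cm1 <- connectivity_matrix(s1, rois)
  expect_equal(unname(cm1["3", "3"]), 100)
  expect_error(connectivity_matrix(structure(list(), class = "streamline_set"),
                                   rois), class = "subcortaud_empty_streamlines")
})

test_that("ROI dilation and downsampling both recover adjacent-tube connectivity", {
  ## tube along z; ROI blocks sit beside the tube so the undilated boxes
  ## barely touch the streamlines
  pf <- make_peak_field(fiber_phantom_spec("straight", tube_radius_voxels = 1.5))
  d <- dim(pf$n_peaks)
  lab <- array(0L, d)
  lab[12:14, 10:13, 2:3] <- 1L         # near the bottom end, off the tube
  lab[12:14, 10:13, 18:20] <- 2L       # near the top end, off the tube
  rois <- volume(lab, pf$affine)
  seedarr <- array(0L, d); seedarr[10:11, 10:11, 2:3] <- 1L
  seeds <- volume(seedarr, pf$affine)
  sl <- track(pf, seeds, tracking_spec(max_angle_deg = 45, fa_stop = 0.1,
                                       n_seeds = 150, seed = 6))
  ab_entry <- function(rois_used) {
    fl <- filter_streamlines(sl, seeds, rois_used)
    if (length(fl) == 0) return(0)
    cm <- try(connectivity_matrix(fl, rois_used), silent = TRUE)
    if (inherits(cm, "try-error")) 0 else unname(cm["1", "2"])
  }
  e0 <- ab_entry(rois)
  e1 <- ab_entry(dilate_mask(rois, 2.5))
  expect_gte(e1, e0)
  expect_gt(e1, 0)
  ## downsampling the ROI grid (partial voluming) also grows the entry
  rois_ds <- resample(rois, 5 * voxel_size(rois), method = "nearest")
  ## nearest keeps labels; a coarse voxel overlapping the tube counts as ROI
  e2 <- ab_entry(rois_ds)
  expect_gte(e2, e0)
})

test_that("trk files round trip streamlines through voxmm space", {
  pf <- make_peak_field(fiber_phantom_spec("straight"))
  seedarr <- array(0L, dim(pf$n_peaks)); seedarr[10:12, 10:12, 2] <- 1L
  sl <- track(pf, volume(seedarr, pf$affine),
              tracking_spec(max_angle_deg = 45, fa_stop = 0.1, n_seeds = 40,
                            seed = 7))
  f <- tempfile(fileext = ".trk")
  write_trk(sl, f, pf$affine, dim(pf$n_peaks))
  s2 <- read_trk(f)
  expect_length(s2, length(sl))
  for (i in seq_along(sl))
    expect_lt(max(abs(s2[[i]] - sl[[i]])), 1e-4)   # float32 storage
  f2 <- tempfile(fileext = ".tsv")
  write_streamlines_tsv(sl, f2)
  tab <- read.delim(f2)
  expect_equal(nrow(tab), sum(vapply(sl, nrow, 1L)))
})
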