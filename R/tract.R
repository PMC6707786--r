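## axis angle (degrees) between orientation vectors, antipodally identified
axis_angle_deg <- function(a, b) {
  m <- abs(tcrossprod(a, b))
  m[m > 1] <- 1
  acos(m) * 180 / pi
}

#' Extract ODF peaks on a sampled sphere
#'
#' Local maxima of the per-voxel ODF amplitudes over an angular-proximity
#' neighbour graph of the sampled directions (antipodal pairs identified) are
#' collected greedily in descending amplitude, discarding any candidate within
#' `min_sep_deg` of an already-kept peak, any below `rel_threshold` times the
#' voxel's maximum, and at most `max_peaks` per voxel. The defaults mirror the
#' postmortem analysis (10 degrees, 5 peaks); in vivo data used 25 degrees.
#'
#' @param odf array \[x,y,z,n_dirs\] of ODF amplitudes.
#' @param sphere_dirs antipodally symmetric n_dirs x 3 unit vectors.
#' @param min_sep_deg minimum separation angle between kept peaks.
#' @param max_peaks maximum peaks per voxel.
#' @param rel_threshold minimum amplitude relative to the voxel maximum.
#' @param fa FA `volume` to attach.
#' @param affine grid affine (taken from `fa` when supplied).
#' @return a `peak_field`.
#' @export
extract_peaks <- function(odf, sphere_dirs, min_sep_deg = 10, max_peaks = 5L,
                          rel_threshold = 0.5, fa = NULL, affine = NULL) {
  if (is.null(dim(sphere_dirs)) || nrow(sphere_dirs) == 0L)
    stop(vol_error("empty direction set", "empty_directions"))
  nd <- nrow(sphere_dirs)
  shape <- dim(odf)[1:3]
  stopifnot(dim(odf)[4] == nd)
  ## neighbour graph: axis-angle within 1.5x the largest nearest-neighbour gap
  ang <- axis_angle_deg(sphere_dirs, sphere_dirs)
  diag(ang) <- Inf
  nn_gap <- max(apply(ang, 1, min))
  nbr <- lapply(seq_len(nd), function(i) which(ang[i, ] <= 1.5 * nn_gap + 1e-9))
  A <- matrix(odf, prod(shape), nd)
  vox <- which(pmax_rows(A) > 0)
  peaks <- array(0, c(shape, max_peaks, 3))
  amp <- array(0, c(shape, max_peaks))
  n_peaks <- array(0L, shape)
  for (v in vox) {
    a <- A[v, ]
    amax <- max(a)
    is_max <- vapply(seq_len(nd), function(i) a[i] >= max(a[nbr[[i]]]), TRUE)
    cand <- which(is_max & a >= rel_threshold * amax)
    cand <- cand[order(a[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (ci in cand) {
      if (length(kept) >= max_peaks) break
      if (length(kept) == 0L ||
          min(axis_angle_deg(sphere_dirs[ci, , drop = FALSE],
                             sphere_dirs[kept, , drop = FALSE])) >= min_sep_deg)
        kept <- c(kept, ci)
    }
    pos <- arrayInd(v, shape)
    for (s in seq_along(kept)) {
      peaks[pos[1], pos[2], pos[3], s, ] <- sphere_dirs[kept[s], ]
      amp[pos[1], pos[2], pos[3], s] <- a[kept[s]]
    }
    n_peaks[v] <- length(kept)
  }
  if (is.null(affine)) affine <- if (!is.null(fa)) fa$affine else diag(4)
  if (is.null(fa)) fa <- volume(array(1, shape), affine)
  structure(list(peaks = peaks, amp = amp, n_peaks = n_peaks, fa = fa,
                 affine = affine, max_peaks = max_peaks),
            class = "peak_field")
}

pmax_rows <- function(m) apply(m, 1, max)

#' Morphological dilation by a Euclidean ball
#'
#' Dilates a mask by all voxel offsets whose Euclidean norm (in voxel units)
#' is at most `radius_voxels`; e.g. 2.5 voxels at 200 um spacing reaches
#' 500 um, including the white matter neighbouring a grey-matter ROI.
#'
#' @param mask a `binary_mask` or integer label `volume` (labels dilated
#'   jointly as non-zero).
#' @param radius_voxels nonnegative dilation radius in voxel units.
#' @return dilated `binary_mask` (or label volume when `mask` has labels:
#'   each label dilated separately, later labels winning ties).
#' @export
dilate_mask <- function(mask, radius_voxels) {
  stopifnot(inherits(mask, "volume"), radius_voxels >= 0)
  r <- floor(radius_voxels)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  offs <- g[rowSums(g^2) <= radius_voxels^2, , drop = FALSE]
  vals <- sort(unique(as.vector(mask$data)))
  vals <- vals[vals > 0]
  d <- dim(mask$data)[1:3]
  out <- array(0L, d)
  for (val in vals) {
    cur <- array(FALSE, d)
    src <- mask$data == val
    for (ri in seq_len(nrow(offs))) {
      o <- offs[ri, ]
      dst <- src_rng <- vector("list", 3)
      for (ax in 1:3) {
        dst[[ax]] <- max(1L, 1L + o[ax]):min(d[ax], d[ax] + o[ax])
        src_rng[[ax]] <- dst[[ax]] - o[ax]
      }
      cur[dst[[1]], dst[[2]], dst[[3]]] <-
        cur[dst[[1]], dst[[2]], dst[[3]]] |
        src[src_rng[[1]], src_rng[[2]], src_rng[[3]]]
    }
    out[cur] <- as.integer(val)
  }
  res <- volume(out, mask$affine)
  if (length(vals) <= 1L) res <- as_mask(res)
  res
}

#' Tracking parameters
#'
#' @param step_mm propagation step (default: half the smallest voxel size,
#'   resolved at tracking time when `NULL`).
#' @param max_angle_deg maximum turning angle per step (75 for the postmortem
#'   protocol, 45 in vivo).
#' @param fa_stop FA termination threshold (0.001 postmortem, 0.023 in vivo).
#' @param n_seeds total seed budget placed uniformly in the seed mask; a
#'   literal per-voxel seeding mode is available via `seeds_per_voxel`.
#' @param seeds_per_voxel if not `NULL`, overrides `n_seeds` with
#'   `seeds_per_voxel * n_seed_voxels`.
#' @param min_length_mm minimum streamline length kept (default: 3 steps,
#'   resolved at tracking time when `NULL`).
#' @param max_steps hard cap on steps per direction.
#' @param seed RNG seed.
#' @return list of class `tracking_spec`.
#' @export
tracking_spec <- function(step_mm = NULL, max_angle_deg = 45, fa_stop = 0.023,
                          n_seeds = 1000L, seeds_per_voxel = NULL,
                          min_length_mm = NULL, max_steps = 2000L, seed = 1L) {
  stopifnot(max_angle_deg > 0, max_angle_deg <= 90, fa_stop >= 0, fa_stop < 1)
  structure(list(step_mm = step_mm, max_angle_deg = max_angle_deg,
                 fa_stop = fa_stop, n_seeds = as.integer(n_seeds),
                 seeds_per_voxel = seeds_per_voxel,
                 min_length_mm = min_length_mm,
                 max_steps = as.integer(max_steps), seed = as.integer(seed)),
            class = "tracking_spec")
}

## trilinear FA interpolation at continuous 0-based voxel coords (n x 3)
interp_fa <- function(fa_arr, ci) {
  d <- dim(fa_arr)
  ci <- pmin(pmax(ci, 0), matrix(rep(d - 1, each = nrow(ci)), ncol = 3))
  lo <- pmin(floor(ci), matrix(rep(d - 2, each = nrow(ci)), ncol = 3))
  lo <- pmax(lo, 0)
  w <- ci - lo
  out <- numeric(nrow(ci))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (cx * w[, 1] + (1 - cx) * (1 - w[, 1])) *
      (cy * w[, 2] + (1 - cy) * (1 - w[, 2])) *
      (cz * w[, 3] + (1 - cz) * (1 - w[, 3]))
    out <- out + wt * fa_arr[cbind(lo[, 1] + cx, lo[, 2] + cy, lo[, 3] + cz) + 1L]
  }
  out
}

#' Deterministic peak-following streamline tracking
#'
#' Seeds are placed uniformly at random (seeded RNG) within the seed-mask
#' voxels and propagated bidirectionally along the initial principal peak. At
#' each step the FA is interpolated trilinearly and propagation stops when FA
#' falls below `fa_stop` or the position leaves the grid; otherwise the peak
#' of the nearest voxel whose axis is closest to the incoming direction is
#' chosen, sign-aligned, and followed for `step_mm` - stopping if the turning
#' angle exceeds `max_angle_deg`. Streamlines shorter than `min_length_mm`
#' are discarded.
#'
#' @param pf a `peak_field`.
#' @param seed_mask `binary_mask` or label `volume` of seed voxels (labels are
#'   recorded as per-streamline provenance).
#' @param spec a `tracking_spec`.
#' @return a `streamline_set`: list of polylines (n x 3 world mm matrices),
#'   with attributes `seed_label` (integer vector) and `spec`.
#' @export
track <- function(pf, seed_mask, spec = tracking_spec()) {
  stopifnot(inherits(pf, "peak_field"), inherits(seed_mask, "volume"))
  if (all(pf$n_peaks == 0L))
    stop(vol_error("peak field has no peaks anywhere", "no_peaks"))
  seeds_idx <- which(seed_mask$data != 0)
  if (length(seeds_idx) == 0L)
    stop(vol_error("seed mask is empty", "empty_mask"))
  vsz <- sqrt(colSums(pf$affine[1:3, 1:3]^2))
  step <- if (is.null(spec$step_mm)) min(vsz) / 2 else spec$step_mm
  min_len <- if (is.null(spec$min_length_mm)) 3 * step else spec$min_length_mm
  d <- dim(pf$n_peaks)
  inv_aff <- solve(pf$affine)
  cos_max <- cos(spec$max_angle_deg * pi / 180)
  n_seeds <- if (!is.null(spec$seeds_per_voxel))
    as.integer(spec$seeds_per_voxel * length(seeds_idx)) else spec$n_seeds
  set.seed(spec$seed)
  sv <- seeds_idx[sample.int(length(seeds_idx), n_seeds, replace = TRUE)]
  sp <- arrayInd(sv, d) - 1L + matrix(stats::runif(3L * n_seeds, -0.5, 0.5),
                                      ncol = 3)
  to_world <- function(ci) t(pf$affine %*% rbind(t(ci), 1))[, 1:3, drop = FALSE]
  to_vox <- function(w) t(inv_aff %*% rbind(t(w), 1))[, 1:3, drop = FALSE]
  voxel_peaks <- function(vi) {
    np <- pf$n_peaks[vi[1], vi[2], vi[3]]
    if (np == 0L) return(NULL)
    matrix(pf$peaks[vi[1], vi[2], vi[3], seq_len(np), ], ncol = 3)
  }
  propagate <- function(p0, dir) {
    pts <- list()
    p <- p0; dcur <- dir
    for (s in seq_len(spec$max_steps)) {
      pn <- p + step * dcur
      ci <- to_vox(matrix(pn, 1))
      if (any(ci < -0.5) || any(ci > d - 0.5)) break
      if (interp_fa(pf$fa$data, ci) < spec$fa_stop) break
      vi <- pmin(pmax(round(ci[1, ]) + 1L, 1L), d)
      pk <- voxel_peaks(vi)
      if (is.null(pk)) break
      cosang <- pk %*% dcur
      best <- which.max(abs(cosang))
      if (abs(cosang[best]) < cos_max) break
      dcur <- pk[best, ] * sign(cosang[best])
      pts[[length(pts) + 1L]] <- pn
      p <- pn
    }
    if (length(pts)) do.call(rbind, pts) else matrix(0, 0, 3)
  }
  lines <- list(); labels <- integer(0); seed_pts <- list()
  for (i in seq_len(n_seeds)) {
    ci <- sp[i, , drop = FALSE]
    vi <- pmin(pmax(round(ci[1, ]) + 1L, 1L), d)
    if (interp_fa(pf$fa$data, ci) < spec$fa_stop) next
    pk <- voxel_peaks(vi)
    if (is.null(pk)) next
    p0 <- to_world(ci)[1, ]
    fwd <- propagate(p0, pk[1, ])
    bwd <- propagate(p0, -pk[1, ])
    line <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                  matrix(p0, 1), fwd)
    if (nrow(line) < 2L) next
    if ((nrow(line) - 1L) * step < min_len) next
    lines[[length(lines) + 1L]] <- line
    labels <- c(labels, as.integer(seed_mask$data[vi[1], vi[2], vi[3]]))
    seed_pts[[length(seed_pts) + 1L]] <- p0
  }
  structure(lines, class = "streamline_set", seed_label = labels,
            seed_point = if (length(seed_pts)) do.call(rbind, seed_pts)
                         else matrix(0, 0, 3),
            spec = spec, step_mm = step)
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("<streamline_set> ", length(x), " streamlines\n", sep = "")
  invisible(x)
}

## labels of the ROI voxels a streamline's points fall in (half-open boxes)
streamline_labels <- function(line, rois, inv_aff = solve(rois$affine)) {
  ci <- t(inv_aff %*% rbind(t(line), 1))[, 1:3, drop = FALSE]
  vi <- floor(ci + 0.5)
  d <- dim(rois$data)[1:3]
  ok <- vi[, 1] >= 0 & vi[, 1] < d[1] & vi[, 2] >= 0 & vi[, 2] < d[2] &
    vi[, 3] >= 0 & vi[, 3] < d[3]
  if (!any(ok)) return(integer(0))
  l <- rois$data[vi[ok, , drop = FALSE] + 1L]
  sort(unique(l[l > 0]))
}

#' Filter streamlines by seed and waypoint ROIs
#'
#' Keeps streamlines whose seed point lies in a seed ROI and which intersect
#' at least one waypoint ROI voxel (point-in-voxel test on world coordinates,
#' half-open voxel boxes).
#'
#' @param s a `streamline_set`.
#' @param seed_rois label `volume` of permitted seed regions.
#' @param waypoint_rois label `volume` of waypoint regions.
#' @return filtered `streamline_set` (possibly empty).
#' @export
filter_streamlines <- function(s, seed_rois, waypoint_rois) {
  inv_s <- solve(seed_rois$affine)
  inv_w <- solve(waypoint_rois$affine)
  seed_pts <- attr(s, "seed_point")
  keep <- vapply(seq_along(s), function(i) {
    seedpt <- if (!is.null(seed_pts) && nrow(seed_pts) >= i)
      seed_pts[i, , drop = FALSE] else s[[i]][1, , drop = FALSE]
    length(streamline_labels(seedpt, seed_rois, inv_s)) > 0 &&
      length(streamline_labels(s[[i]], waypoint_rois, inv_w)) > 0
  }, TRUE)
  out <- unclass(s)[keep]
  structure(out, class = "streamline_set",
            seed_label = attr(s, "seed_label")[keep],
            seed_point = if (!is.null(seed_pts)) seed_pts[keep, , drop = FALSE],
            spec = attr(s, "spec"), step_mm = attr(s, "step_mm"))
}

#' ROI connectivity matrix from streamlines
#'
#' For each streamline the set of ROI labels it intersects is found;
#' off-diagonal entry (i,j) counts streamlines touching both i and j, the
#' diagonal (i,i) counts streamlines touching only i, and all entries are
#' expressed as a percentage of the total streamline count (most streamlines
#' passing through just one region show up on the diagonal).
#'
#' @param s a non-empty `streamline_set`.
#' @param rois integer label `volume`.
#' @param label_names optional label names.
#' @return a `connectivity_matrix`: symmetric percentage matrix with
#'   attribute `"n_streamlines"`.
#' @export
connectivity_matrix <- function(s, rois, label_names = NULL) {
  if (length(s) == 0L)
    stop(vol_error("empty streamline set", "empty_streamlines"))
  vals <- sort(unique(as.vector(rois$data)))
  vals <- vals[vals > 0]
  if (is.null(label_names)) label_names <- as.character(vals)
  m <- matrix(0, length(vals), length(vals),
              dimnames = list(label_names, label_names))
  inv_aff <- solve(rois$affine)
  for (line in s) {
    labs <- match(streamline_labels(line, rois, inv_aff), vals)
    if (length(labs) == 1L) m[labs, labs] <- m[labs, labs] + 1
    else if (length(labs) > 1L)
      for (pair in utils::combn(labs, 2, simplify = FALSE)) {
        m[pair[1], pair[2]] <- m[pair[1], pair[2]] + 1
        m[pair[2], pair[1]] <- m[pair[2], pair[1]] + 1
      }
  }
  structure(100 * m / length(s), class = c("connectivity_matrix", "matrix"),
            n_streamlines = length(s))
}
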