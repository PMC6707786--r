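#' Antipodally symmetric sphere sampling directions
#'
#' A Fibonacci-lattice hemisphere of `n_hemi` points together with its
#' antipodes, giving `2 * n_hemi` unit vectors suitable for sampling
#' orientation distribution functions.
#'
#' @param n_hemi points per hemisphere (>= 50 recommended).
#' @return `2*n_hemi` x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n_hemi = 100L) {
  i <- seq_len(n_hemi) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n_hemi                       # upper hemisphere only
  r <- sqrt(1 - z^2)
  d <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(d, -d)
}

#' Fiber phantom specification
#'
#' Tube phantoms standing in for subcortical auditory tracts (e.g. the lateral
#' lemniscus): a straight tube, a bent tube turning by `bend_angle_deg`
#' end-to-end, or two crossing tubes.
#'
#' @param geometry `"straight"`, `"bent"` or `"crossing"`.
#' @param bend_angle_deg total tangent rotation of the bent tube.
#' @param tube_radius_voxels tube radius in voxel units.
#' @param fa_inside,fa_outside fractional anisotropy inside/outside the tube
#'   (`fa_inside > fa_outside`).
#' @param shape grid voxel counts.
#' @param voxel_mm isotropic spacing (mm).
#' @param seed RNG seed (reserved for randomized variants).
#' @return list of class `fiber_phantom_spec`.
#' @export
fiber_phantom_spec <- function(geometry = c("straight", "bent", "crossing"),
                               bend_angle_deg = 60, tube_radius_voxels = 2,
                               fa_inside = 0.8, fa_outside = 0,
                               shape = c(21L, 21L, 21L), voxel_mm = 1,
                               seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(fa_inside > fa_outside, fa_inside > 0, fa_inside <= 1,
            fa_outside >= 0, tube_radius_voxels > 0)
  structure(list(geometry = geometry, bend_angle_deg = bend_angle_deg,
                 tube_radius_voxels = tube_radius_voxels,
                 fa_inside = fa_inside, fa_outside = fa_outside,
                 shape = as.integer(shape), voxel_mm = voxel_mm,
                 seed = as.integer(seed)),
            class = "fiber_phantom_spec")
}

## centerlines (finely sampled polyline + unit tangents) of each tube, world mm
phantom_centerlines <- function(spec) {
  shape <- spec$shape; v <- spec$voxel_mm
  ext <- shape * v
  ctr <- (shape - 1) / 2 * v
  n <- 400L
  if (spec$geometry == "straight") {
    z <- seq(0.5 * v, ext[3] - 0.5 * v, length.out = n)
    list(list(points = cbind(ctr[1], ctr[2], z),
              tangents = matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)))
  } else if (spec$geometry == "crossing") {
    z <- seq(0.5 * v, ext[3] - 0.5 * v, length.out = n)
    x <- seq(0.5 * v, ext[1] - 0.5 * v, length.out = n)
    list(list(points = cbind(ctr[1], ctr[2], z),
              tangents = matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)),
         list(points = cbind(x, ctr[2], ctr[3]),
              tangents = matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)))
  } else {
    ## arc in the x-z plane: starts pointing +z, turns by bend_angle toward +x
    ang <- spec$bend_angle_deg * pi / 180
    margin <- 1.5 * v
    chord <- min(ext[1], ext[3]) - 2 * margin
    R <- chord / (2 * sin(ang / 2))
    th <- seq(0, ang, length.out = n)
    ## circle center sits at (x0 + R, z0); start point (x0, z0)
    x0 <- margin; z0 <- margin + if (ang > pi / 2) R * 0 else 0
    pts <- cbind(x0 + R * (1 - cos(th)), ctr[2], z0 + R * sin(th))
    tans <- cbind(sin(th), 0, cos(th))
    list(list(points = pts, tangents = tans))
  }
}

#' Fiber phantom as a peak field
#'
#' Inside each tube every voxel carries a unit peak along the local tangent
#' and FA `fa_inside`; in the crossing region voxels carry both peaks; outside
#' FA is `fa_outside` with no peaks. The planted truth (centerlines, tangents,
#' per-tube masks) is attached so tracking output can be scored.
#'
#' @param spec a `fiber_phantom_spec`.
#' @return a `peak_field`: list(`peaks` \[x,y,z,max_peaks,3\], `amp`
#'   \[x,y,z,max_peaks\], `n_peaks` \[x,y,z\], `fa` `volume`, `affine`) with
#'   attribute `"truth"`.
#' @export
make_peak_field <- function(spec) {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  shape <- spec$shape; v <- spec$voxel_mm
  aff <- diag(c(v, v, v, 1)); aff[1:3, 4] <- v / 2
  tmpl <- volume(array(0, shape), aff)
  lines <- phantom_centerlines(spec)
  max_peaks <- length(lines)
  peaks <- array(0, c(shape, max_peaks, 3))
  amp <- array(0, c(shape, max_peaks))
  n_peaks <- array(0L, shape)
  fa <- array(spec$fa_outside, shape)
  r_mm <- spec$tube_radius_voxels * v
  idx_all <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2]),
                                   seq_len(shape[3]))) - 1L
  w_all <- voxel_to_world(tmpl, idx_all)
  tube_masks <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    pts <- lines[[li]]$points; tans <- lines[[li]]$tangents
    ## nearest centerline sample for every voxel center
    near <- nearest_point(w_all, pts)
    inside <- near$dist <= r_mm
    tube_masks[[li]] <- as_mask(volume(array(as.integer(inside), shape), aff))
    vox <- which(inside)
    for (jj in seq_along(vox)) {
      vi <- idx_all[vox[jj], ] + 1L
      slot <- n_peaks[vi[1], vi[2], vi[3]] + 1L
      peaks[vi[1], vi[2], vi[3], slot, ] <- tans[near$which[vox[jj]], ]
      amp[vi[1], vi[2], vi[3], slot] <- 1
      n_peaks[vi[1], vi[2], vi[3]] <- slot
      fa[vi[1], vi[2], vi[3]] <- spec$fa_inside
    }
  }
  structure(list(peaks = peaks, amp = amp, n_peaks = n_peaks,
                 fa = volume(fa, aff), affine = aff,
                 max_peaks = max_peaks),
            class = "peak_field",
            truth = list(centerlines = lines, tube_masks = tube_masks))
}

nearest_point <- function(A, B, chunk = 2048L) {
  b2 <- rowSums(B^2)
  wh <- integer(nrow(A)); dist <- numeric(nrow(A))
  for (s in seq.int(1L, nrow(A), by = chunk)) {
    i <- s:min(s + chunk - 1L, nrow(A))
    d2 <- outer(rowSums(A[i, , drop = FALSE]^2), b2, "+") -
      2 * A[i, , drop = FALSE] %*% t(B)
    wh[i] <- apply(d2, 1, which.min)
    dist[i] <- sqrt(pmax(0, d2[cbind(seq_along(i), wh[i])]))
  }
  list(which = wh, dist = dist)
}

#' Sample ODF amplitudes for a phantom
#'
#' Per-voxel orientation distribution function sampled on `sphere_dirs`:
#' the sum over true fibers of the symmetric axial kernel
#' `exp(kappa * (d . mu)^2)`; voxels without fibers have amplitude 0.
#'
#' @param pf a `peak_field` (typically from [make_peak_field()]).
#' @param sphere_dirs antipodally symmetric direction set (>= 100 directions).
#' @param kappa kernel concentration.
#' @return array \[x, y, z, n_dirs\] of nonnegative amplitudes.
#' @export
make_odf_samples <- function(pf, sphere_dirs = sphere_directions(100L),
                             kappa = 20) {
  stopifnot(inherits(pf, "peak_field"))
  if (is.null(dim(sphere_dirs)) || nrow(sphere_dirs) == 0L)
    stop(vol_error("empty direction set", "empty_directions"))
  if (nrow(sphere_dirs) < 100L)
    stop(vol_error("need at least 100 sphere directions", "too_few_directions"))
  shape <- dim(pf$n_peaks)
  nd <- nrow(sphere_dirs)
  odf <- array(0, c(shape, nd))
  vox <- which(pf$n_peaks > 0L)
  pos <- arrayInd(vox, shape)
  for (jj in seq_along(vox)) {
    vi <- pos[jj, ]
    a <- numeric(nd)
    for (s in seq_len(pf$n_peaks[vox[jj]])) {
      mu <- pf$peaks[vi[1], vi[2], vi[3], s, ]
      a <- a + exp(kappa * (sphere_dirs %*% mu)^2)
    }
    odf[vi[1], vi[2], vi[3], ] <- a
  }
  odf
}
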