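#' 3-D/4-D volume with a voxel-to-world affine
#'
#' A `volume` is the basic spatial container of the package: a numeric or
#' integer array (3-D, or 4-D with time along the 4th axis) plus a 4x4 affine
#' mapping 0-based voxel indices to world RAS+ millimetre coordinates. The
#' world point of voxel (i,j,k) is the voxel *center*.
#'
#' @param data numeric or integer array, 3-D or 4-D.
#' @param affine 4x4 invertible matrix; columns 1:3 give the world step per
#'   voxel index, column 4 the world position of voxel (0,0,0).
#' @return an object of class `volume`.
#' @export
volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop(vol_error("data must be a 3-D or 4-D array", "bad_data"))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop(vol_error("affine must be 4x4", "bad_affine"))
  if (abs(det(affine)) < 1e-12)
    stop(vol_error("affine is not invertible", "singular_affine"))
  structure(list(data = data, affine = affine), class = "volume")
}

vol_error <- function(msg, subclass, call = sys.call(-1)) {
  errorCondition(msg, class = c(paste0("subcortaud_", subclass), "subcortaud_error"),
                 call = call)
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(voxel_size(x), 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Per-axis voxel spacing in mm
#'
#' Derived as the Euclidean norms of the first three affine columns.
#' @param v a `volume`.
#' @return numeric length-3 vector of strictly positive spacings (mm).
#' @export
voxel_size <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Voxel volume in cubic millimetres
#' @param v a `volume`.
#' @export
voxel_volume_mm3 <- function(v) abs(det(v$affine[1:3, 1:3]))

is_int_data <- function(x) {
  is.integer(x) || (is.numeric(x) && all(x == round(x)))
}

#' World coordinates of voxel centers
#'
#' @param v a `volume`.
#' @param idx n x 3 matrix of 0-based voxel indices; default all voxels.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  t(v$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  t(solve(v$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data)[1:3], dim(b$data)[1:3]) &&
    max(abs(a$affine - b$affine)) < tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop(vol_error("volumes are not on the same grid", "grid_mismatch"))
}

#' Read a NIfTI-1 volume
#'
#' Loads data and the sform affine. Integer-typed files keep exact integer
#' values. Raises distinct conditions for a missing file
#' (`subcortaud_missing_file`), a non-NIfTI payload (`subcortaud_bad_nifti`)
#' and a non-invertible affine (`subcortaud_singular_affine`).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(vol_error(paste0("file does not exist: ", path), "missing_file"))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(vol_error(paste0("not a readable NIfTI file: ", path),
                                   "bad_nifti")))
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  dat <- array(as.vector(img), dim = dim(img))
  volume(dat, aff)
}

#' Write a volume as NIfTI-1
#'
#' The affine is stored in the sform with code 2. Integer arrays are written
#' with an integer datatype so label volumes round-trip exactly.
#'
#' @param v a `volume`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (!dir.exists(dirname(path)))
    stop(vol_error(paste0("parent directory does not exist: ", dirname(path)),
                   "unwritable_path"))
  dt <- if (is.integer(v$data)) "int32" else "double"
  img <- RNifti::asNifti(v$data, datatype = dt)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## reflect an arbitrary integer index into 1..n (mirror boundary, period 2n)
reflect_index <- function(k, n) {
  if (n == 1L) return(rep(1L, length(k)))
  m <- (k - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

## separable 1-D convolution along the first axis with reflective padding
conv_axis1 <- function(arr, kernel) {
  d <- dim(arr)
  n <- d[1]
  r <- (length(kernel) - 1L) %/% 2L
  pad_idx <- reflect_index(seq.int(1L - r, n + r), n)
  m <- matrix(arr, nrow = n)[pad_idx, , drop = FALSE]
  K <- matrix(0, n, n + 2L * r)
  for (i in seq_len(n)) K[i, i:(i + 2L * r)] <- kernel
  array(K %*% m, dim = d)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian filtering with per-axis
#' `sigma_voxels = fwhm_mm / (2 sqrt(2 ln 2)) / voxel_size_mm[axis]` and
#' reflective boundary handling (mass-conserving near edges). 4-D volumes are
#' smoothed frame by frame. The default 1.5 mm FWHM is the mild smoothing
#' applied to upsampled functional maps.
#'
#' @param v a `volume`.
#' @param fwhm_mm full width at half maximum of the Gaussian, in mm (> 0).
#' @return smoothed `volume` (always floating point).
#' @export
gaussian_smooth <- function(v, fwhm_mm = 1.5) {
  stopifnot(inherits(v, "volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop(vol_error("fwhm_mm must be a positive scalar", "bad_fwhm"))
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size(v)
  smooth3 <- function(a) {
    for (ax in 1:3) {
      a <- aperm(a, c(ax, setdiff(1:3, ax)))
      a <- conv_axis1(a, gaussian_kernel(sig[ax]))
      a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
    }
    a
  }
  d <- dim(v$data)
  out <- if (length(d) == 3L) smooth3(v$data * 1.0) else {
    res <- array(0, d)
    for (t in seq_len(d[4])) res[, , , t] <- smooth3(v$data[, , , t] * 1.0)
    res
  }
  volume(out, v$affine)
}

#' FWHM to Gaussian sigma
#' @param fwhm full width at half maximum.
#' @return `fwhm / (2 sqrt(2 ln 2))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

axis_aligned <- function(aff, tol = 1e-9) {
  R <- aff[1:3, 1:3]
  all(abs(R - diag(diag(R))) < tol)
}

## separable 1-D resampling of the first axis onto continuous indices `ci`
## (0-based, clamped); method "nearest" or "trilinear"
resample_axis1 <- function(arr, ci, method) {
  d <- dim(arr)
  n <- d[1]
  ci <- pmin(pmax(ci, 0), n - 1)
  m <- matrix(arr, nrow = n)
  if (method == "nearest") {
    out <- m[round(ci) + 1L, , drop = FALSE]
  } else {
    lo <- pmin(floor(ci), n - 1 - (n > 1))
    w <- ci - lo
    out <- m[lo + 1L, , drop = FALSE] * (1 - w) +
      m[pmin(lo + 2L, n), , drop = FALSE] * w
  }
  array(out, dim = c(length(ci), d[-1]))
}

#' Resample a volume to a new voxel size
#'
#' Axis-aligned grid resampling. The output shape is
#' `ceiling(extent / target)` per axis so the field of view is never cropped;
#' the world corner of the field of view is preserved. `method = "nearest"` is
#' required for integer label/mask volumes; requesting trilinear interpolation
#' on integer data is refused.
#'
#' @param v a 3-D `volume` with an axis-aligned affine.
#' @param target_voxel_mm positive spacing, length 1 or 3 (mm).
#' @param method `"nearest"` or `"trilinear"`.
#' @return resampled `volume`.
#' @export
resample <- function(v, target_voxel_mm, method = c("trilinear", "nearest")) {
  stopifnot(inherits(v, "volume"), length(dim(v$data)) == 3L)
  method <- match.arg(method)
  tgt <- rep(as.numeric(target_voxel_mm), length.out = 3)
  if (any(tgt <= 0)) stop(vol_error("target spacing must be positive", "bad_spacing"))
  if (!axis_aligned(v$affine))
    stop(vol_error("resample requires an axis-aligned affine", "oblique_affine"))
  if (method == "trilinear" && is_int_data(v$data) && length(unique(as.vector(v$data))) <= 64)
    stop(vol_error("trilinear interpolation refused on an integer label volume; use method = \"nearest\"",
                   "label_interp"))
  d <- dim(v$data)
  sp <- voxel_size(v)
  sgn <- sign(diag(v$affine[1:3, 1:3]))
  extent <- d * sp
  nd <- as.integer(ceiling(extent / tgt - 1e-9))
  ## world corner of the FOV = center of voxel 0 minus half a voxel step
  corner <- v$affine %*% c(-0.5, -0.5, -0.5, 1)
  naff <- diag(4)
  diag(naff)[1:3] <- sgn * tgt
  naff[1:3, 4] <- corner[1:3] + 0.5 * sgn * tgt
  ## continuous input index of each output center, per axis (separable)
  ci <- lapply(1:3, function(ax) ((seq_len(nd[ax]) - 1) * tgt[ax] + 0.5 * tgt[ax] - 0.5 * sp[ax]) / sp[ax])
  a <- v$data * 1.0
  for (ax in 1:3) {
    a <- aperm(a, c(ax, setdiff(1:3, ax)))
    a <- resample_axis1(a, ci[[ax]], method)
    a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
  }
  if (method == "nearest" && is.integer(v$data)) storage.mode(a) <- "integer"
  volume(a, naff)
}

#' Minimum-intensity projection over slabs
#'
#' Along the chosen axis, consecutive non-overlapping slabs of
#' `floor(slab_mm / voxel_size)` slices (at least 1) are each reduced to their
#' voxelwise minimum, one output slice per slab. Used to render vasculature
#' from T2*-weighted postmortem data (default slab 1.1 mm). A trailing
#' partial slab is projected if it holds at least half the nominal slice
#' count (`partial = "half"`), always (`"keep"`), or never (`"drop"`).
#'
#' @param v a 3-D `volume`.
#' @param axis projection axis, 1, 2 or 3.
#' @param slab_mm slab thickness in mm; must cover at least one voxel.
#' @param partial trailing-slab policy, see above.
#' @return `volume` with one slice per slab along `axis`.
#' @export
min_intensity_projection <- function(v, axis = 2L, slab_mm = 1.1,
                                     partial = c("half", "keep", "drop")) {
  stopifnot(inherits(v, "volume"), length(dim(v$data)) == 3L, axis %in% 1:3)
  partial <- match.arg(partial)
  sp <- voxel_size(v)[axis]
  n_per <- floor(slab_mm / sp + 1e-9)
  if (n_per < 1)
    stop(vol_error(sprintf("slab_mm must be at least one voxel (minimum %g mm)", sp),
                   "slab_too_thin"))
  n <- dim(v$data)[axis]
  starts <- seq.int(1L, n, by = n_per)
  ends <- pmin(starts + n_per - 1L, n)
  counts <- ends - starts + 1L
  keep <- counts == n_per |
    switch(partial, half = counts >= n_per / 2, keep = TRUE, drop = FALSE)
  starts <- starts[keep]; ends <- ends[keep]
  a <- aperm(v$data, c(axis, setdiff(1:3, axis)))
  m <- matrix(a, nrow = n)
  proj <- t(vapply(seq_along(starts), function(s) {
    do.call(pmin, lapply(starts[s]:ends[s], function(i) m[i, ]))
  }, numeric(ncol(m))))
  if (length(starts) == 1L) proj <- matrix(proj, nrow = 1L)
  out <- array(proj, dim = c(length(starts), dim(a)[2:3]))
  out <- aperm(out, order(c(axis, setdiff(1:3, axis))))
  naff <- v$affine
  step <- naff[1:3, axis]
  ## first output slice center sits at the center of the first slab
  naff[1:3, 4] <- naff[1:3, 4] + step * (n_per - 1) / 2
  naff[1:3, axis] <- step * n_per
  volume(out, naff)
}

#' Coerce a volume to a binary mask
#'
#' @param v a `volume` (non-zero treated as 1) or logical/numeric array.
#' @param affine affine when `v` is a bare array.
#' @return `volume` with integer 0/1 data and class `binary_mask` prepended.
#' @export
as_mask <- function(v, affine = NULL) {
  if (inherits(v, "volume")) {
    dat <- v$data; aff <- v$affine
  } else {
    dat <- v; aff <- if (is.null(affine)) diag(4) else affine
  }
  m <- array(as.integer(dat != 0), dim = dim(dat))
  out <- volume(m, aff)
  class(out) <- c("binary_mask", class(out))
  out
}

#' Number of non-zero voxels in a mask
#' @param m a mask `volume`.
#' @export
mask_size <- function(m) sum(m$data != 0)
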