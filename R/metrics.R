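#' Dice coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`. Defined as 1 when both masks are empty (two empty
#' segmentations agree perfectly).
#'
#' @param a,b `binary_mask` `volume`s on a shared grid.
#' @return Dice overlap in `[0,1]`.
#' @export
dice <- function(a, b) {
  stopifnot_same_grid(a, b)
  na <- sum(a$data != 0); nb <- sum(b$data != 0)
  if (na + nb == 0L) return(1)
  2 * sum(a$data != 0 & b$data != 0) / (na + nb)
}

mask_coords <- function(m) {
  idx <- which(m$data != 0)
  if (length(idx) == 0L)
    stop(vol_error("average Hausdorff distance needs non-empty masks", "empty_mask"))
  voxel_to_world(m, arrayInd(idx, dim(m$data)[1:3]) - 1L)
}

## for each row of A, the distance to the nearest row of B (chunked O(n*m))
nn_dist <- function(A, B, chunk = 512L) {
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq.int(1L, nrow(A), by = chunk)) {
    i <- s:min(s + chunk - 1L, nrow(A))
    d2 <- outer(rowSums(A[i, , drop = FALSE]^2), b2, "+") -
      2 * A[i, , drop = FALSE] %*% t(B)
    out[i] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Average (or maximum) Hausdorff distance between two masks
#'
#' Symmetric average of the directed mean nearest-neighbour distances between
#' member-voxel world centers:
#' `(mean_x min_y d(x,y) + mean_y min_x d(x,y)) / 2`. Distances are taken over
#' all member voxels (determinate even for one-voxel-thick structures); set
#' `boundary_only = TRUE` to use boundary voxels, or `variant = "max"` for the
#' classical maximum Hausdorff distance.
#'
#' @param a,b non-empty `binary_mask` `volume`s on a shared grid.
#' @param variant `"average"` (default) or `"max"`.
#' @param boundary_only restrict to voxels with at least one 6-neighbour
#'   outside the mask.
#' @return distance in mm.
#' @export
average_hausdorff <- function(a, b, variant = c("average", "max"),
                              boundary_only = FALSE) {
  variant <- match.arg(variant)
  stopifnot_same_grid(a, b)
  if (boundary_only) {
    a <- boundary_mask(a); b <- boundary_mask(b)
  }
  A <- mask_coords(a); B <- mask_coords(b)
  dab <- nn_dist(A, B); dba <- nn_dist(B, A)
  if (variant == "average") (mean(dab) + mean(dba)) / 2
  else max(max(dab), max(dba))
}

boundary_mask <- function(m) {
  d <- dim(m$data)[1:3]
  inside <- m$data != 0
  core <- inside
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    shifted <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    dst[[ax]] <- seq_len(d[ax] - 1L) + (s == -1L)
    src[[ax]] <- seq_len(d[ax] - 1L) + (s == 1L)
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- inside[src[[1]], src[[2]], src[[3]]]
    core <- core & shifted
  }
  as_mask(volume(array(as.integer(inside & !core), d), m$affine))
}

#' Per-label volumes of a segmentation
#'
#' Voxel count times voxel volume for every positive integer label, the
#' volumetry used to compare structure definitions across sources and
#' probabilistic-map thresholds.
#'
#' @param labels integer label `volume` (or a list of them, giving one volume
#'   column per source).
#' @param label_names optional names for the label values.
#' @return data.frame with `label`, `n_voxels`, `volume_mm3` (or one
#'   `volume_mm3.<source>` column per input when a list is given).
#' @export
label_volumes <- function(labels, label_names = NULL) {
  if (inherits(labels, "volume")) labels <- list(labels)
  for (lv in labels)
    if (!is_int_data(lv$data))
      stop(vol_error("label volume must hold integer labels", "bad_labels"))
  vals <- sort(unique(unlist(lapply(labels, function(lv) unique(as.vector(lv$data))))))
  vals <- vals[vals > 0]
  if (is.null(label_names)) label_names <- as.character(vals)
  out <- data.frame(label = label_names)
  for (s in seq_along(labels)) {
    lv <- labels[[s]]
    vv <- voxel_volume_mm3(lv)
    n <- vapply(vals, function(v) sum(lv$data == v), 1)
    out[[if (length(labels) == 1L) "n_voxels" else paste0("n_voxels.", s)]] <- n
    out[[if (length(labels) == 1L) "volume_mm3" else paste0("volume_mm3.", s)]] <- n * vv
  }
  out
}
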