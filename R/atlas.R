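#' Benjamini-Hochberg FDR mask with an auxiliary p threshold
#'
#' Benjamini-Hochberg step-up over the voxels of `analysis_mask` at level `q`,
#' intersected with an additional uncorrected threshold `p < p_extra` (the
#' default q = 0.05 and p < 0.001 reproduce the single-subject thresholding of
#' sound-versus-silence maps).
#'
#' @param p a p-value `volume` (values in `[0,1]`).
#' @param q FDR level.
#' @param p_extra extra uncorrected p threshold; `NULL` disables it.
#' @param analysis_mask mask `volume` of voxels entering the correction.
#' @return a `binary_mask` `volume`.
#' @export
fdr_mask <- function(p, q = 0.05, p_extra = 0.001, analysis_mask = NULL) {
  stopifnot(inherits(p, "volume"))
  if (is.null(analysis_mask))
    analysis_mask <- as_mask(volume(array(1L, dim(p$data)[1:3]), p$affine))
  mv <- as.vector(analysis_mask$data != 0)
  if (!any(mv)) stop(vol_error("analysis mask is empty", "empty_mask"))
  pv <- as.vector(p$data)[mv]
  if (any(pv < 0 | pv > 1)) stop(vol_error("p values outside [0,1]", "bad_p"))
  rej <- stats::p.adjust(pv, method = "BH") <= q
  if (!is.null(p_extra)) rej <- rej & pv < p_extra
  arr <- array(0L, dim(p$data)[1:3])
  arr[mv] <- as.integer(rej)
  as_mask(volume(arr, p$affine))
}

## neighbor offsets for a given 3-D connectivity
connectivity_offsets <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  n <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = n == 1, "18" = n >= 1 & rowSums(g != 0) <= 2,
                 "26" = n >= 1)
  g[keep, , drop = FALSE]
}

## connected-component labels of a 3-D 0/1 array; 0 where background
label_components <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  idx <- which(arr != 0)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  pos <- arrayInd(idx, d)
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  offs <- connectivity_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (o[1] < 0 || (o[1] == 0 && (o[2] < 0 || (o[2] == 0 && o[3] < 0))))
      next                                   # each undirected pair once
    nb <- sweep(pos, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    j <- id_of[nb[ok, , drop = FALSE]]
    i <- seq_along(idx)[ok]
    keep <- j > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(i[keep], j[keep])
  }
  g <- igraph::graph_from_edgelist(if (length(edges)) do.call(rbind, edges)
                                   else matrix(0L, 0, 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Remove suprathreshold clusters below a volume threshold
#'
#' Connected components of the mask (6-, 18- or 26-connectivity) whose volume
#' is below `min_mm3` are removed. The default 3.37 mm^3 corresponds to 27
#' voxels on a 0.5 mm isotropic grid.
#'
#' @param mask a `binary_mask` `volume`.
#' @param min_mm3 minimum cluster volume (mm^3) to retain.
#' @param connectivity 6, 18 or 26.
#' @return filtered `binary_mask`.
#' @export
cluster_filter <- function(mask, min_mm3 = 3.37, connectivity = 26L) {
  stopifnot(inherits(mask, "volume"), min_mm3 >= 0)
  lab <- label_components(mask$data, connectivity)
  if (max(lab) == 0L) return(as_mask(volume(array(0L, dim(mask$data)), mask$affine)))
  vv <- voxel_volume_mm3(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * vv >= min_mm3)
  as_mask(volume(array(as.integer(lab %in% keep), dim(mask$data)), mask$affine))
}

#' Probabilistic map from binarized subject masks
#'
#' Voxelwise integer count of subjects whose thresholded maps include each
#' voxel: a value of N means all N subjects exhibited a significant response
#' there.
#'
#' @param masks list of `binary_mask` `volume`s on a shared grid.
#' @return a `prob_map`: list(`counts` integer `volume`, `n_subjects`).
#' @export
probabilistic_map <- function(masks) {
  stopifnot(length(masks) >= 1L)
  for (m in masks[-1]) stopifnot_same_grid(masks[[1]], m)
  counts <- Reduce(`+`, lapply(masks, function(m) m$data != 0))
  structure(list(counts = volume(array(as.integer(counts), dim(masks[[1]]$data)),
                                 masks[[1]]$affine),
                 n_subjects = length(masks)),
            class = "prob_map")
}

#' Leave-one-out probabilistic maps
#'
#' The i-th output is the probabilistic map over all masks except the i-th
#' (the atlas built from the other subjects, used to test generalization to
#' the left-out one). All maps share the input grid; warping to individual
#' anatomies is an external registration step.
#'
#' @param masks list of at least two `binary_mask` `volume`s.
#' @return list of `prob_map`, one per left-out subject.
#' @export
leave_one_out_maps <- function(masks) {
  if (length(masks) < 2L)
    stop(vol_error("leave-one-out needs at least two masks", "too_few_masks"))
  lapply(seq_along(masks), function(i) probabilistic_map(masks[-i]))
}

#' Threshold a probabilistic map at a minimum subject count
#'
#' @param pm a `prob_map`.
#' @param min_subjects retain voxels significant in at least this many
#'   subjects (default 3, the display threshold used for group maps).
#' @return a `binary_mask`.
#' @export
threshold_prob_map <- function(pm, min_subjects = 3L) {
  stopifnot(inherits(pm, "prob_map"))
  if (min_subjects < 1L || min_subjects > pm$n_subjects)
    stop(vol_error("min_subjects out of range", "bad_threshold"))
  as_mask(volume(array(as.integer(pm$counts$data >= min_subjects),
                       dim(pm$counts$data)), pm$counts$affine))
}

#' Centroid of a mask in world coordinates
#'
#' Unweighted mean of the member-voxel world centers.
#' @param mask a non-empty `binary_mask`.
#' @return length-3 world mm coordinate.
#' @export
centroid <- function(mask) {
  idx <- which(mask$data != 0)
  if (length(idx) == 0L)
    stop(vol_error("no activation: centroid of an empty mask", "empty_mask"))
  colMeans(voxel_to_world(mask, arrayInd(idx, dim(mask$data)[1:3]) - 1L))
}

#' Leave-one-out atlas validation
#'
#' For every subject and structure, both the thresholded leave-one-out map and
#' the subject's own mask are restricted to the structure's label region;
#' overlap is `100 * |LOO  intersect  subject| / |LOO|` (the leave-one-out map
#' is the denominator) and the centroid distance is the Euclidean distance
#' between the two restricted centroids. Cells with an empty restricted LOO
#' region are reported as missing, not zero.
#'
#' @param loo_maps list of `prob_map` from [leave_one_out_maps()].
#' @param subject_masks list of per-subject `binary_mask`s (same order).
#' @param structure_labels integer label `volume` naming the nuclei regions.
#' @param min_subjects threshold applied to each leave-one-out map.
#' @param label_names optional names for the label values (defaults to the
#'   sorted positive values).
#' @return data.frame (subject, structure, overlap_pct, centroid_dist_mm,
#'   loo_voxels, subject_voxels) with attribute `"medians"` = list(overlap,
#'   distance) over all non-missing cells.
#' @export
loo_validation <- function(loo_maps, subject_masks, structure_labels,
                           min_subjects = 3L, label_names = NULL) {
  stopifnot(length(loo_maps) == length(subject_masks))
  vals <- sort(unique(as.vector(structure_labels$data)))
  vals <- vals[vals > 0]
  if (is.null(label_names)) label_names <- as.character(vals)
  out <- list()
  for (i in seq_along(loo_maps)) {
    loo_thr <- threshold_prob_map(loo_maps[[i]], min_subjects)
    for (l in seq_along(vals)) {
      region <- structure_labels$data == vals[l]
      A <- loo_thr$data != 0 & region
      B <- subject_masks[[i]]$data != 0 & region
      if (!any(A)) {
        ov <- NA_real_; dist <- NA_real_
      } else {
        ov <- 100 * sum(A & B) / sum(A)
        dist <- if (any(B)) {
          ca <- centroid(as_mask(volume(array(as.integer(A), dim(A)),
                                        structure_labels$affine)))
          cb <- centroid(as_mask(volume(array(as.integer(B), dim(B)),
                                        structure_labels$affine)))
          sqrt(sum((ca - cb)^2))
        } else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        subject = i, structure = label_names[l], overlap_pct = ov,
        centroid_dist_mm = dist, loo_voxels = sum(A), subject_voxels = sum(B))
    }
  }
  tab <- do.call(rbind, out)
  attr(tab, "medians") <- list(
    overlap = stats::median(tab$overlap_pct, na.rm = TRUE),
    distance = stats::median(tab$centroid_dist_mm, na.rm = TRUE))
  tab
}
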