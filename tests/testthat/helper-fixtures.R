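## shared fixture builders; everything is generated in code, seeded

rand_volume <- function(shape = c(8L, 8L, 8L), voxel = 0.5, seed = 1,
                        origin = -(shape - 1) / 2 * voxel) {
  set.seed(seed)
  aff <- diag(c(rep(voxel, 3), 1))
  aff[1:3, 4] <- origin
  volume(array(rnorm(prod(shape)), shape), aff)
}

rand_mask <- function(shape = c(12L, 12L, 12L), p = 0.2, voxel = 1, seed = 1) {
  set.seed(seed)
  aff <- diag(c(rep(voxel, 3), 1))
  as_mask(volume(array(as.integer(runif(prod(shape)) < p), shape), aff))
}

## small two-ROI cohort template used by the GLM tests
small_cohort <- function(n_subjects = 1L, shape = c(20L, 20L, 20L),
                         radius = 2, jitter = 0, ...) {
  tm <- cohort_template(shape)
  sp <- cohort_spec(n_subjects = n_subjects, roi_radius_mm = radius,
                    jitter_sd_mm = jitter, ...)
  sp$roi_centers_mm <- sp$roi_centers_mm[1:2, , drop = FALSE] * 0.3
  rois <- make_cohort_rois(sp, tm)
  brain <- as_mask(volume(array(1L, dim(tm$data)), tm$affine))
  list(template = tm, spec = sp, rois = rois, brain = brain)
}

## brute-force flood fill, the oracle for cluster_filter
flood_fill_components <- function(arr, connectivity) {
  d <- dim(arr)
  offs <- subcortaud:::connectivity_offsets(connectivity)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(arr != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(start, d)[1, ])
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (arr[q[1], q[2], q[3]] != 0 && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

## brute-force Benjamini-Hochberg step-up, the oracle for fdr_mask
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(below)) rej[ord[seq_len(max(below))]] <- TRUE
  rej
}
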