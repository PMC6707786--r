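#' Sparse event-related stimulation design
#'
#' Event onsets (in volume units) with inter-stimulus gaps drawn uniformly
#' from `isi_volumes[1]..isi_volumes[3]`; the default (3,4,5) gives the sparse
#' design with a mean inter-stimulus interval of four volumes. Deterministic
#' given `seed`.
#'
#' @param n_volumes run length in volumes.
#' @param n_events number of stimulus events to place.
#' @param isi_volumes integer triple (min, mean, max) gap in volumes.
#' @param n_catch number of additional catch trials (stimulus repetitions,
#'   modelled separately and excluded from contrasts) interleaved at random.
#' @param seed RNG seed.
#' @return an `event_design`: list with `n_volumes`, `onsets` (data.frame of
#'   `onset` 0-based volume index, `condition`, `is_catch`) and `isi_volumes`.
#' @export
make_event_design <- function(n_volumes, n_events, isi_volumes = c(3L, 4L, 5L),
                              n_catch = 0L, seed = 1L) {
  stopifnot(length(isi_volumes) == 3, isi_volumes[1] <= isi_volumes[3])
  n_total <- n_events + n_catch
  if (n_total * isi_volumes[3] + 1 > n_volumes)
    stop(vol_error(sprintf("cannot place %d events at maximum ISI %d in %d volumes",
                           n_total, isi_volumes[3], n_volumes), "infeasible_design"))
  set.seed(seed)
  gaps <- sample(seq.int(isi_volumes[1], isi_volumes[3]), n_total, replace = TRUE)
  onsets <- cumsum(gaps)                    # lead-in gap before the first event
  is_catch <- rep(FALSE, n_total)
  if (n_catch > 0) is_catch[sample.int(n_total, n_catch)] <- TRUE
  structure(list(n_volumes = as.integer(n_volumes),
                 onsets = data.frame(onset = as.integer(onsets),
                                     condition = ifelse(is_catch, "catch", "sound"),
                                     is_catch = is_catch),
                 isi_volumes = as.integer(isi_volumes)),
            class = "event_design")
}

#' Write / read an events table as TSV
#'
#' BIDS-style events table with columns `onset` (volume units), `condition`
#' and `is_catch`.
#' @param design an `event_design`.
#' @param path TSV path.
#' @export
write_events_tsv <- function(design, path) {
  utils::write.table(design$onsets, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param n_volumes run length to attach to the design read back.
#' @export
read_events_tsv <- function(path, n_volumes) {
  on <- utils::read.delim(path)
  structure(list(n_volumes = as.integer(n_volumes),
                 onsets = data.frame(onset = as.integer(on$onset),
                                     condition = as.character(on$condition),
                                     is_catch = as.logical(on$is_catch)),
                 isi_volumes = NA_integer_),
            class = "event_design")
}

#' Canonical simulation HRF as FIR taps
#'
#' Difference-of-gammas hemodynamic response sampled at one volume interval
#' and normalized to unit peak. This fixed shape is the simulation ground
#' truth; the analysis side never assumes it and instead estimates the HRF by
#' FIR deconvolution.
#'
#' @param n_taps number of taps (default 9, matching the 9-stick FIR model).
#' @param t_volume_s volume-to-volume interval in seconds.
#' @param peak_s,undershoot_s gamma peak times (s).
#' @param undershoot_ratio relative undershoot amplitude.
#' @return numeric vector of `n_taps` coefficients, max = 1.
#' @export
hrf_taps <- function(n_taps = 9L, t_volume_s = 2.6, peak_s = 6,
                     undershoot_s = 16, undershoot_ratio = 1 / 6) {
  t <- (seq_len(n_taps) - 1) * t_volume_s
  h <- stats::dgamma(t, shape = peak_s, scale = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s, scale = 1)
  h / max(h)
}

#' Default synthetic cohort specification
#'
#' Ten subjects; eight spherical nuclei (bilateral CN, SOC, IC, MGB analogs,
#' radius 2 mm) arranged in an anatomically inspired layout inside a
#' brainstem-sized field of view; per-subject, per-nucleus center jitter of
#' 0.5 mm SD; sound-evoked effect of 3 percent signal change against 1 percent
#' white noise; three shared structured-noise components confined outside the
#' nuclei.
#'
#' @param n_subjects cohort size.
#' @param jitter_sd_mm per-axis Gaussian SD of nucleus-center jitter (mm).
#' @param roi_radius_mm nucleus sphere radius (mm).
#' @param effect_size sound response amplitude, percent signal change.
#' @param noise_sd white-noise SD, percent signal change.
#' @param n_noise_components number of planted structured-noise components.
#' @param noise_component_sd loading SD of each structured component.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L, jitter_sd_mm = 0.5,
                        roi_radius_mm = 2, effect_size = 3, noise_sd = 1,
                        n_noise_components = 3L, noise_component_sd = 2,
                        seed = 1L) {
  centers <- rbind(
    CN_L  = c(-6, -4, -6), CN_R  = c(6, -4, -6),
    SOC_L = c(-2.5, 0, -4), SOC_R = c(2.5, 0, -4),
    IC_L  = c(-2.5, 1, 3),  IC_R  = c(2.5, 1, 3),
    MGB_L = c(-6, -1, 6),   MGB_R = c(6, -1, 6))
  stopifnot(jitter_sd_mm >= 0, noise_sd >= 0, noise_component_sd >= 0,
            roi_radius_mm > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 roi_centers_mm = centers,
                 jitter_sd_mm = jitter_sd_mm, roi_radius_mm = roi_radius_mm,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_noise_components = as.integer(n_noise_components),
                 noise_component_sd = noise_component_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Template grid for the synthetic cohort
#'
#' A 0.5 mm isotropic grid centered on the world origin, sized to hold the
#' default nucleus layout (20 mm cube by default).
#' @param shape integer triple of voxel counts.
#' @param voxel_mm isotropic spacing (mm).
#' @return an all-zero `volume`.
#' @export
cohort_template <- function(shape = c(40L, 40L, 40L), voxel_mm = 0.5) {
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * voxel_mm
  volume(array(0, shape), aff)
}

sphere_mask_idx <- function(template, center_mm, radius_mm) {
  d <- dim(template$data)[1:3]
  ## voxel index bounding box around the sphere
  ci <- world_to_voxel(template, matrix(center_mm, 1))
  sp <- voxel_size(template)
  r_vox <- ceiling(radius_mm / sp) + 1
  rng <- lapply(1:3, function(ax)
    max(0, floor(ci[ax] - r_vox[ax])):min(d[ax] - 1, ceiling(ci[ax] + r_vox[ax])))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  w <- voxel_to_world(template, g)
  keep <- rowSums(sweep(w, 2, center_mm)^2) <= radius_mm^2
  g[keep, , drop = FALSE]
}

#' Per-subject jittered nucleus label volumes
#'
#' Each subject's nuclei are spheres of `roi_radius_mm` around the canonical
#' centers plus independent per-axis Gaussian jitter (SD `jitter_sd_mm`,
#' drawn per subject and per nucleus). The planted ground truth - the actual
#' jittered centers - is returned alongside.
#'
#' @param spec a `cohort_spec`.
#' @param template grid `volume` (spacing must not exceed the sphere radius).
#' @return list with `labels` (per-subject integer label `volume`s, labels in
#'   the row order of `spec$roi_centers_mm`), `true_centers` (data.frame:
#'   subject, structure, x, y, z) and `label_names`.
#' @export
make_cohort_rois <- function(spec, template = cohort_template()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(voxel_size(template) > spec$roi_radius_mm))
    stop(vol_error("grid spacing exceeds the ROI radius", "grid_too_coarse"))
  set.seed(spec$seed)
  labs <- rownames(spec$roi_centers_mm)
  d <- dim(template$data)[1:3]
  fov_lo <- voxel_to_world(template, matrix(c(0, 0, 0), 1))
  fov_hi <- voxel_to_world(template, matrix(d - 1, 1))
  vols <- vector("list", spec$n_subjects)
  cen <- list()
  for (s in seq_len(spec$n_subjects)) {
    lab_arr <- array(0L, d)
    for (l in seq_along(labs)) {
      ctr <- spec$roi_centers_mm[l, ] + stats::rnorm(3, 0, spec$jitter_sd_mm)
      if (any(ctr - spec$roi_radius_mm < fov_lo) || any(ctr + spec$roi_radius_mm > fov_hi))
        stop(vol_error(sprintf("jittered sphere %s exits the grid", labs[l]),
                       "roi_outside_grid"))
      idx <- sphere_mask_idx(template, ctr, spec$roi_radius_mm)
      lab_arr[idx + 1L] <- l
      cen[[length(cen) + 1L]] <- data.frame(subject = s, structure = labs[l],
                                            x = ctr[1], y = ctr[2], z = ctr[3])
    }
    vols[[s]] <- volume(lab_arr, template$affine)
  }
  list(labels = vols, true_centers = do.call(rbind, cen), label_names = labs)
}

#' Simulate sparse event-related 4-D runs for one subject
#'
#' Signal model: `baseline + effect_size * (onset indicator convolved with
#' hrf)` inside nucleus voxels (percent-signal units, baseline 100).
#' Structured noise: `n_noise_components` shared random time courses (one set
#' per run) times fixed random spatial loadings supported strictly outside the
#' nuclei - the planted "noise pool". Independent white noise everywhere.
#' Deterministic given `seed`.
#'
#' @param spec a `cohort_spec` (noise/effect parameters).
#' @param rois the subject's integer label `volume` (non-zero = nucleus).
#' @param designs list of `event_design`, one per run.
#' @param hrf numeric FIR taps used as simulation truth (see [hrf_taps()]).
#' @param seed RNG seed.
#' @param baseline mean signal level.
#' @return list with `runs` (list of 4-D `volume`s), and `truth`: the active
#'   mask, noise loadings matrix, per-run component time courses, and the
#'   noiseless stimulus time course per run.
#' @export
simulate_subject_runs <- function(spec, rois, designs, hrf = hrf_taps(),
                                  seed = 1L, baseline = 100) {
  stopifnot(inherits(rois, "volume"))
  if (any(vapply(designs, function(d) d$n_volumes, 1L) < length(hrf)))
    stop(vol_error("run length shorter than the HRF support", "run_too_short"))
  set.seed(seed)
  d <- dim(rois$data)[1:3]
  nv <- prod(d)
  active <- as.vector(rois$data != 0)
  n_out <- sum(!active)
  k <- spec$n_noise_components
  loadings <- matrix(0, nv, k)
  if (k > 0)
    loadings[!active, ] <- matrix(stats::rnorm(n_out * k, 0, spec$noise_component_sd),
                                  n_out, k)
  runs <- vector("list", length(designs))
  tcs <- vector("list", length(designs))
  stim <- vector("list", length(designs))
  for (r in seq_along(designs)) {
    des <- designs[[r]]
    conv <- convolve_onsets(des$onsets$onset[!des$onsets$is_catch],
                            hrf, des$n_volumes)
    Tn <- des$n_volumes
    Y <- matrix(stats::rnorm(Tn * nv, 0, spec$noise_sd), Tn, nv)
    if (k > 0) {
      U <- matrix(stats::rnorm(Tn * k), Tn, k)
      Y <- Y + U %*% t(loadings)
      tcs[[r]] <- U
    }
    Y[, active] <- Y[, active] + spec$effect_size * conv
    Y <- Y + baseline
    runs[[r]] <- volume(array(t(Y), dim = c(d, Tn)), rois$affine)
    stim[[r]] <- conv
  }
  list(runs = runs,
       truth = list(active_mask = as_mask(volume(array(as.integer(active), d),
                                                 rois$affine)),
                    loadings = loadings, time_courses = tcs,
                    stimulus = stim))
}

## onset indicator (0-based onsets) convolved with FIR taps, truncated to n
convolve_onsets <- function(onsets, taps, n) {
  x <- numeric(n)
  for (o in onsets) {
    idx <- o + seq_along(taps)       # 0-based onset -> 1-based volume o+1
    ok <- idx <= n & idx >= 1
    x[idx[ok]] <- x[idx[ok]] + taps[ok]
  }
  x
}
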