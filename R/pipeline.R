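#' Default pipeline configuration
#'
#' Central registry of the analysis defaults: FDR q = 0.05 with an extra
#' p < 0.001 voxel threshold, 3.37 mm^3 cluster-extent filter
#' (26-connectivity), probabilistic-map display threshold of 3 subjects,
#' 9-tap FIR deconvolution, 1.5 mm FWHM smoothing on the 0.5 mm grid,
#' peak separation 10 degrees (postmortem) / 25 degrees (in vivo), streamline
#' angle thresholds 75 / 45 degrees with FA stops 0.001 / 0.023, ROI dilation
#' 2.5 voxels, and 1.1 mm minimum-intensity-projection slabs.
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    threshold = list(fdr_q = 0.05, p_extra = 0.001, min_cluster_mm3 = 3.37,
                     connectivity = 26L, min_subjects = 3L),
    glm = list(n_sticks = 9L, f_alpha = 0.05, k_max = 4L, sided = "one"),
    smoothing = list(fwhm_mm = 1.5, apply = FALSE),
    cohort = list(n_subjects = 10L, jitter_sd_mm = 0.5, roi_radius_mm = 2,
                  effect_size = 3, noise_sd = 1, n_noise_components = 3L,
                  noise_component_sd = 2, center_scale = 1),
    simulation = list(n_runs = 4L, n_volumes = 120L, n_events = 23L,
                      grid_shape = c(40L, 40L, 40L), voxel_mm = 0.5),
    tracking = list(postmortem = list(min_sep_deg = 10, max_angle_deg = 75,
                                      fa_stop = 0.001, max_peaks = 5L),
                    invivo = list(min_sep_deg = 25, max_angle_deg = 45,
                                  fa_stop = 0.023, max_peaks = 5L),
                    dilation_voxels = 2.5, n_seeds = 1000L),
    mip = list(slab_mm = 1.1),
    phantom = list(geometry = "straight", shape = c(21L, 21L, 21L),
                   voxel_mm = 1, tube_radius_voxels = 2, fa_inside = 0.8,
                   fa_outside = 0)),
    class = "pipeline_config")
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown fields are rejected and missing fields fall back to
#' [default_config()]; validation failures name the offending field in a
#' `subcortaud_bad_config` condition.
#'
#' @param path YAML file.
#' @return validated `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(vol_error(paste0("config file does not exist: ", path), "missing_file"))
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw) || length(raw) == 0L)
    stop(vol_error("config file is empty", "bad_config"))
  validate_config(modify_config(default_config(), raw, path = character(0)))
}

modify_config <- function(base, upd, path) {
  for (nm in names(upd)) {
    if (!nm %in% names(base))
      stop(vol_error(paste0("unknown config field: ",
                            paste(c(path, nm), collapse = ".")), "bad_config"))
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
      modify_config(base[[nm]], upd[[nm]], c(path, nm)) else upd[[nm]]
  }
  base
}

#' @rdname read_config
#' @param config a `pipeline_config` list to validate.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field)
    if (!isTRUE(ok)) stop(vol_error(paste0("invalid config field: ", field),
                                    "bad_config"))
  th <- config$threshold
  chk(th$fdr_q > 0 && th$fdr_q < 1, "threshold.fdr_q")
  chk(th$p_extra > 0 && th$p_extra < 1, "threshold.p_extra")
  chk(th$min_cluster_mm3 >= 0, "threshold.min_cluster_mm3")
  chk(th$connectivity %in% c(6, 18, 26), "threshold.connectivity")
  chk(th$min_subjects >= 1, "threshold.min_subjects")
  chk(config$glm$n_sticks >= 1, "glm.n_sticks")
  chk(config$glm$f_alpha > 0 && config$glm$f_alpha < 1, "glm.f_alpha")
  chk(config$cohort$n_subjects >= 2, "cohort.n_subjects")
  chk(config$cohort$jitter_sd_mm >= 0, "cohort.jitter_sd_mm")
  chk(config$simulation$n_runs >= 2, "simulation.n_runs")
  chk(config$tracking$dilation_voxels >= 0, "tracking.dilation_voxels")
  chk(config$mip$slab_mm > 0, "mip.slab_mm")
  class(config) <- "pipeline_config"
  config
}

write_manifest <- function(outdir, config, seed, outputs) {
  manifest <- list(package = "subcortaud",
                   version = as.character(utils::packageVersion("subcortaud")),
                   seed = seed, config = unclass(config), outputs = outputs)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
}

#' Run the synthetic-cohort functional atlas pipeline
#'
#' Generates the synthetic cohort (jittered nuclei, sparse event-related runs
#' with planted structured noise), runs the cross-validated denoised GLM per
#' subject, thresholds (BH-FDR + p, cluster-extent filter), builds the
#' probabilistic and leave-one-out maps, and validates them by per-structure
#' overlap and centroid distance against each left-out subject.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param outdir output directory; when given, t-maps, masks, probabilistic
#'   and leave-one-out maps (NIfTI), the validation table (TSV) and a
#'   run manifest are written. `NULL` skips writing.
#' @param seed overrides `config$seed`.
#' @return (invisibly) list: `subject_masks`, `glm_results`, `prob_map`,
#'   `loo_maps`, `validation` (data.frame with `"medians"` attribute),
#'   `rois`, `median_centroid_distance_mm`, `median_overlap_pct`.
#' @export
run_functional_atlas <- function(config = default_config(), outdir = NULL,
                                 seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- config$simulation; ch <- config$cohort; th <- config$threshold
  template <- cohort_template(sim$grid_shape, sim$voxel_mm)
  spec <- cohort_spec(n_subjects = ch$n_subjects, jitter_sd_mm = ch$jitter_sd_mm,
                      roi_radius_mm = ch$roi_radius_mm,
                      effect_size = ch$effect_size, noise_sd = ch$noise_sd,
                      n_noise_components = ch$n_noise_components,
                      noise_component_sd = ch$noise_component_sd,
                      seed = config$seed)
  spec$roi_centers_mm <- spec$roi_centers_mm * ch$center_scale
  rois <- make_cohort_rois(spec, template)
  brain <- as_mask(volume(array(1L, dim(template$data)), template$affine))
  designs <- lapply(seq_len(sim$n_runs), function(r)
    make_event_design(sim$n_volumes, sim$n_events, seed = config$seed * 1000L + r))
  masks <- vector("list", spec$n_subjects)
  glms <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sim_s <- simulate_subject_runs(spec, rois$labels[[s]], designs,
                                   seed = config$seed * 100L + s)
    res <- analyze_subject(sim_s$runs, designs, brain,
                           f_alpha = config$glm$f_alpha,
                           k_max = config$glm$k_max,
                           n_sticks = config$glm$n_sticks,
                           sided = config$glm$sided)
    p <- res$p
    if (isTRUE(config$smoothing$apply)) {
      ## optional: smooth the t map and recompute p at the combined dof
      tsm <- gaussian_smooth(res$t, config$smoothing$fwhm_mm)
      p <- volume(array(stats::pt(tsm$data, res$dof, lower.tail = FALSE),
                        dim(tsm$data)), tsm$affine)
      res$t <- tsm
    }
    m <- fdr_mask(p, q = th$fdr_q, p_extra = th$p_extra, analysis_mask = brain)
    masks[[s]] <- cluster_filter(m, th$min_cluster_mm3, th$connectivity)
    glms[[s]] <- res
  }
  pm <- probabilistic_map(masks)
  loo <- leave_one_out_maps(masks)
  label_vol <- consensus_labels(rois, template)
  val <- loo_validation(loo, masks, label_vol, min_subjects = th$min_subjects,
                        label_names = rois$label_names)
  med <- attr(val, "medians")
  out <- list(subject_masks = masks, glm_results = glms, prob_map = pm,
              loo_maps = loo, validation = val, rois = rois,
              median_centroid_distance_mm = med$distance,
              median_overlap_pct = med$overlap)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (s in seq_along(masks)) {
      f1 <- file.path(outdir, sprintf("sub-%02d_tmap.nii.gz", s))
      f2 <- file.path(outdir, sprintf("sub-%02d_mask.nii.gz", s))
      write_volume(glms[[s]]$t, f1); write_volume(masks[[s]], f2)
      files <- c(files, f1, f2)
    }
    fp <- file.path(outdir, "probabilistic_map.nii.gz")
    write_volume(pm$counts, fp); files <- c(files, fp)
    for (s in seq_along(loo)) {
      f <- file.path(outdir, sprintf("loo-%02d_map.nii.gz", s))
      write_volume(loo[[s]]$counts, f); files <- c(files, f)
    }
    ft <- file.path(outdir, "loo_validation.tsv")
    utils::write.table(val, ft, sep = "\t", row.names = FALSE, quote = FALSE)
    fc <- file.path(outdir, "true_centers.tsv")
    utils::write.table(rois$true_centers, fc, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, ft, fc)
    write_manifest(outdir, config, config$seed, basename(files))
  }
  invisible(out)
}

## region assignment for per-nucleus metrics: sphere of 1.5x radius around the
## canonical (unjittered) centers
consensus_labels <- function(rois, template) {
  spec_centers <- stats::aggregate(cbind(x, y, z) ~ structure,
                                   data = rois$true_centers, FUN = mean)
  arr <- array(0L, dim(template$data)[1:3])
  for (l in seq_along(rois$label_names)) {
    ctr <- spec_centers[spec_centers$structure == rois$label_names[l],
                        c("x", "y", "z")]
    idx <- sphere_mask_idx(template, as.numeric(ctr), 3.5)
    arr[idx + 1L] <- l
  }
  volume(arr, template$affine)
}

#' Run the phantom tractography pipeline
#'
#' Builds the requested fiber phantom, defines end-of-tube ROIs, optionally
#' dilates them, tracks from one ROI with all ROIs as waypoints, and writes
#' streamlines (.trk and TSV) plus the percentage connectivity matrix.
#'
#' @param config a `pipeline_config`.
#' @param outdir optional output directory.
#' @param seed overrides `config$seed`.
#' @param dilate apply the configured ROI dilation.
#' @param protocol `"invivo"` or `"postmortem"` parameter set.
#' @return (invisibly) list: `streamlines`, `filtered`, `connectivity`,
#'   `rois`, `peak_field`.
#' @export
run_tractography <- function(config = default_config(), outdir = NULL,
                             seed = NULL, dilate = TRUE,
                             protocol = c("invivo", "postmortem")) {
  config <- validate_config(config)
  protocol <- match.arg(protocol)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  ph <- config$phantom
  prm <- config$tracking[[protocol]]
  spec <- fiber_phantom_spec(geometry = ph$geometry, shape = ph$shape,
                             voxel_mm = ph$voxel_mm,
                             tube_radius_voxels = ph$tube_radius_voxels,
                             fa_inside = ph$fa_inside,
                             fa_outside = ph$fa_outside, seed = config$seed)
  pf <- make_peak_field(spec)
  rois <- phantom_end_rois(pf, spec)
  rois_used <- if (dilate) dilate_mask(rois, config$tracking$dilation_voxels)
               else rois
  seed_mask <- rois_used
  ts <- tracking_spec(max_angle_deg = prm$max_angle_deg, fa_stop = prm$fa_stop,
                      n_seeds = config$tracking$n_seeds, seed = config$seed)
  sl <- track(pf, seed_mask, ts)
  fl <- filter_streamlines(sl, rois_used, rois_used)
  cm <- connectivity_matrix(fl, rois_used)
  out <- list(streamlines = sl, filtered = fl, connectivity = cm,
              rois = rois_used, peak_field = pf)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_trk(fl, file.path(outdir, "streamlines.trk"), pf$affine,
              dim(pf$n_peaks))
    write_streamlines_tsv(fl, file.path(outdir, "streamlines.tsv"))
    utils::write.table(cbind(label = rownames(cm), as.data.frame(unclass(cm))),
                       file.path(outdir, "connectivity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_volume(rois_used, file.path(outdir, "rois.nii.gz"))
    write_manifest(outdir, config, config$seed,
                   c("streamlines.trk", "streamlines.tsv", "connectivity.tsv",
                     "rois.nii.gz"))
  }
  invisible(out)
}

## small box ROIs at the ends of each phantom tube (labels 1, 2, ... per end)
phantom_end_rois <- function(pf, spec) {
  d <- dim(pf$n_peaks)
  arr <- array(0L, d)
  truth <- attr(pf, "truth")
  lab <- 0L
  for (tube in truth$centerlines) {
    for (endpt in list(tube$points[1, ], tube$points[nrow(tube$points), ])) {
      lab <- lab + 1L
      tmpl <- volume(array(0, d), pf$affine)
      ci <- round(world_to_voxel(tmpl, matrix(endpt, 1)))
      rng <- lapply(1:3, function(ax)
        max(0, ci[ax] - 1):min(d[ax] - 1, ci[ax] + 1))
      g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      arr[g + 1L] <- lab
    }
  }
  volume(arr, pf$affine)
}

#' Printed-protocol arithmetic
#'
#' Small derived constants of the acquisition and analysis protocol, computed
#' rather than hard-coded: the cluster-extent threshold in voxels, the
#' cross-validation fold layout, the diffusion protocol volume count, and the
#' dilation radius in micrometres.
#'
#' @param min_mm3 cluster threshold in mm^3.
#' @param voxel_mm isotropic voxel size in mm.
#' @return `cluster_extent_voxels`: the smallest voxel count whose volume
#'   reaches `min_mm3` (27 for 3.37 mm^3 at 0.5 mm).
#' @export
cluster_extent_voxels <- function(min_mm3 = 3.37, voxel_mm = 0.5) {
  as.integer(ceiling(min_mm3 / voxel_mm^3 - 1e-9))
}

#' @rdname cluster_extent_voxels
#' @param n_sounds total distinct stimuli in the experiment.
#' @param n_sets number of stimulus sets (= cross-validation folds).
#' @param runs_per_session functional runs per session.
#' @param n_sessions number of sessions.
#' @return `cv_fold_plan`: list with per-fold `train_runs` / `test_runs` (per
#'   session), `train_sounds`, `test_sounds`, and `n_folds`. Each set of
#'   sounds is presented in `runs_per_session / n_sets` runs per session;
#'   each fold holds one set out.
#' @export
cv_fold_plan <- function(n_sounds, n_sets = 4L, runs_per_session = 12L,
                         n_sessions = 2L) {
  stopifnot(runs_per_session %% n_sets == 0L, n_sounds %% n_sets == 0L)
  runs_per_set <- runs_per_session %/% n_sets
  sounds_per_set <- n_sounds %/% n_sets
  list(n_folds = as.integer(n_sets),
       test_runs = as.integer(runs_per_set),
       train_runs = as.integer(runs_per_session - runs_per_set),
       test_sounds = as.integer(sounds_per_set),
       train_sounds = as.integer(n_sounds - sounds_per_set),
       n_sessions = as.integer(n_sessions))
}

#' @rdname cluster_extent_voxels
#' @param n_shells number of diffusion gradient strengths (b-values).
#' @param n_directions gradient directions per shell.
#' @param n_b0 additional b = 0 volumes per shell.
#' @param n_phase_encodings repeats with reversed phase encoding.
#' @return `dwi_volume_count`: total volumes acquired
#'   (3 x (66 + 11) x 2 = 462 for the in vivo protocol).
#' @export
dwi_volume_count <- function(n_shells = 3L, n_directions = 66L, n_b0 = 11L,
                             n_phase_encodings = 2L) {
  as.integer(n_shells * (n_directions + n_b0) * n_phase_encodings)
}

#' @rdname cluster_extent_voxels
#' @param radius_voxels dilation radius in voxel units.
#' @param voxel_um voxel size in micrometres.
#' @return `dilation_extent_um`: the dilation reach in micrometres
#'   (2.5 voxels at 200 um = 500 um).
#' @export
dilation_extent_um <- function(radius_voxels = 2.5, voxel_um = 200) {
  radius_voxels * voxel_um
}
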