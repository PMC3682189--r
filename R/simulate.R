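#' Describe an ellipsoidal region of interest
#'
#' ROIs are axis-aligned ellipsoids on the acquisition grid, identified by a
#' region label (e.g. \code{"HC"}, \code{"EPC"}, \code{"PHC"}) and hemisphere.
#' \code{signal_present = FALSE} marks a "sclerotic-like" region: its voxels
#' respond to every trial with the same class-independent pattern, so it
#' carries univariate activation but no memory-specific information.
#'
#' @param label region name.
#' @param hemisphere "L" or "R".
#' @param centre voxel-index triple (1-based) of the ellipsoid centre.
#' @param radii semi-axes in voxels (length 3).
#' @param signal_present logical; does this ROI carry class-specific patterns?
#' @return a \code{roi_spec} list.
#' @export
roi_spec <- function(label, hemisphere = c("L", "R"), centre, radii,
                     signal_present = TRUE) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(length(centre) == 3, length(radii) == 3, all(radii > 0))
  structure(list(label = label, hemisphere = hemisphere,
                 centre = as.numeric(centre), radii = as.numeric(radii),
                 signal_present = isTRUE(signal_present)),
            class = "roi_spec")
}

#' Rasterise an ROI specification to a binary mask
#'
#' @param spec a [roi_spec()].
#' @param grid_shape integer triple of grid dimensions.
#' @return an \code{roi_mask} object (see [roi_mask()]).
#' @export
make_roi_mask <- function(spec, grid_shape) {
  stopifnot(inherits(spec, "roi_spec"), length(grid_shape) == 3)
  idx <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                               y = seq_len(grid_shape[2]),
                               z = seq_len(grid_shape[3])))
  d2 <- ((idx[, 1] - spec$centre[1]) / spec$radii[1])^2 +
        ((idx[, 2] - spec$centre[2]) / spec$radii[2])^2 +
        ((idx[, 3] - spec$centre[3]) / spec$radii[3])^2
  mask <- array(d2 <= 1, dim = grid_shape)
  if (!any(mask)) stop("ROI '", spec$label, "' rasterises to zero voxels")
  roi_mask(spec$label, spec$hemisphere, mask)
}

#' Configuration for a synthetic single-subject scanning session
#'
#' Bundles every parameter of the simulated experiment.  Defaults encode the
#' modelled acquisition and task: TR 3.5 s, 7 s recall windows, 3 memories
#' recalled 20 times each in pseudo-random no-repeat order, isotropic
#' partial-volume voxels, linear scanner drift and i.i.d. Gaussian noise, and
#' a behavioural exclusion rate of 0.4 so that on average ~36 of 60 trials
#' survive screening.
#'
#' @param grid_shape integer triple, acquisition grid in voxels.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param tr_s repetition time (s).
#' @param n_classes number of memories.
#' @param n_trials_per_class recall repetitions per memory.
#' @param recall_duration_s recall window length (s).
#' @param inter_trial_gap_s gap between recall offset and next cue onset (s).
#' @param cue_duration_s cue length (s).
#' @param signal_amplitude planted pattern strength in noise-SD units
#'   (multiplies the HRF-convolved boxcar regressor; 0 = pure-noise mode).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param drift_slope linear scanner drift, signal units per volume.
#' @param roi_specs list of [roi_spec()] objects; must be pairwise disjoint
#'   and lie inside the grid.
#' @param exclusion_rate behavioural exclusion rate in [0, 1).
#' @param n_dummy_volumes leading equilibration volumes prepended to the run.
#' @param seed integer RNG seed; everything is deterministic given it.
#' @param hrf_params list passed to [canonical_hrf()] overrides.
#' @return a validated \code{synth_config} list.
#' @export
synth_config <- function(grid_shape = c(24, 24, 12), voxel_size_mm = 1.5,
                         tr_s = 3.5, n_classes = 3, n_trials_per_class = 20,
                         recall_duration_s = 7, inter_trial_gap_s = 12,
                         cue_duration_s = 2, signal_amplitude = 1,
                         noise_sd = 1, drift_slope = 0.05,
                         roi_specs = default_roi_specs(),
                         exclusion_rate = 0.4, n_dummy_volumes = 6,
                         seed = 1, hrf_params = list()) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, tr_s = tr_s,
              n_classes = as.integer(n_classes),
              n_trials_per_class = as.integer(n_trials_per_class),
              recall_duration_s = recall_duration_s,
              inter_trial_gap_s = inter_trial_gap_s,
              cue_duration_s = cue_duration_s,
              signal_amplitude = signal_amplitude, noise_sd = noise_sd,
              drift_slope = drift_slope, roi_specs = roi_specs,
              exclusion_rate = exclusion_rate,
              n_dummy_volumes = as.integer(n_dummy_volumes),
              seed = as.integer(seed), hrf_params = hrf_params)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 1),
            cfg$voxel_size_mm > 0, cfg$tr_s > 0,
            cfg$n_trials_per_class >= 1, cfg$recall_duration_s > 0,
            cfg$inter_trial_gap_s >= 0, cfg$noise_sd >= 0,
            cfg$exclusion_rate >= 0, cfg$exclusion_rate < 1)
  if (cfg$n_classes < 2) stop("n_classes must be >= 2")
  if (cfg$signal_amplitude < 0) stop("signal_amplitude must be nonnegative")
  masks <- lapply(cfg$roi_specs, make_roi_mask, grid_shape = cfg$grid_shape)
  occupancy <- Reduce(`+`, lapply(masks, function(m) m$mask + 0L))
  if (any(occupancy > 1L)) stop("ROI specifications overlap")
  for (sp in cfg$roi_specs) {
    lo <- sp$centre - sp$radii
    hi <- sp$centre + sp$radii
    if (any(lo < 0.5) || any(hi > cfg$grid_shape + 0.5))
      stop("ROI '", sp$label, "' extends outside the grid")
  }
  invisible(cfg)
}

#' Default six-region MTL-like ROI layout
#'
#' Three bilateral region pairs (HC, EPC, PHC) as small disjoint ellipsoids
#' on the default 24 x 24 x 12 grid.  \code{silent} names regions (as
#' "label_hemisphere", e.g. \code{"HC_L"}) whose class-specific signal is
#' switched off, emulating a sclerotic region.  Neighbouring ellipsoids are
#' kept more than two voxels apart so the default 3 mm smoothing kernel
#' cannot couple one region's planted patterns into another.
#'
#' @param silent character vector of "label_hemisphere" ids to silence.
#' @param radii semi-axes (voxels) shared by all six ellipsoids.
#' @return list of [roi_spec()] objects.
#' @export
default_roi_specs <- function(silent = character(), radii = c(2.5, 2, 1.5)) {
  layout <- list(
    list("HC",  "L", c(5, 5, 6)),  list("HC",  "R", c(20, 5, 6)),
    list("EPC", "L", c(5, 12, 6)), list("EPC", "R", c(20, 12, 6)),
    list("PHC", "L", c(5, 19, 6)), list("PHC", "R", c(20, 19, 6))
  )
  lapply(layout, function(l) {
    id <- paste(l[[1]], l[[2]], sep = "_")
    roi_spec(l[[1]], l[[2]], l[[3]], radii,
             signal_present = !(id %in% silent))
  })
}

#' Simulate one event-related BOLD run
#'
#' Generates a complete synthetic subject session.  Each signal-bearing ROI
#' is assigned one fixed spatial pattern per memory class (i.i.d. standard
#' normal over its voxels); on every trial the pattern of the cued class is
#' added, scaled by \code{signal_amplitude} and by a regressor formed by
#' convolving a boxcar over the recall window with the canonical HRF and
#' sampling at the TR.  Signal-absent ROIs and out-of-ROI voxels receive a
#' class-independent evoked response (one fixed pattern used for every
#' trial), so regions differ in information content, not in activation.
#' Per-voxel linear drift and i.i.d. Gaussian noise are added throughout,
#' and \code{n_dummy_volumes} leading equilibration volumes are prepended.
#'
#' Trial onsets in the returned table are relative to the first post-dummy
#' volume; the planted responses are offset accordingly.
#'
#' @param config a [synth_config()].
#' @return a list with elements \code{run} ([bold_run()]), \code{masks}
#'   (list of [roi_mask()]), \code{trials} (trial table including simulated
#'   behaviour) and \code{truth} (planted patterns and schedule).
#' @export
simulate_run <- function(config) {
  validate_synth_config(config)
  cfg <- config
  sched <- make_schedule(cfg$n_classes, cfg$n_trials_per_class,
                         seed = cfg$seed,
                         recall_duration_s = cfg$recall_duration_s,
                         inter_trial_gap_s = cfg$inter_trial_gap_s,
                         cue_duration_s = cfg$cue_duration_s)
  trials <- simulate_behaviour(sched, cfg$exclusion_rate, seed = cfg$seed + 1L)

  masks <- lapply(cfg$roi_specs, make_roi_mask, grid_shape = cfg$grid_shape)
  nvox <- prod(cfg$grid_shape)
  # run length: cover the last trial's shifted extraction window generously
  last_onset <- max(sched$recall_onset_s)
  tail_s <- cfg$recall_duration_s + 32            # HRF support past offset
  n_task_vols <- ceiling((last_onset + tail_s) / cfg$tr_s) + 1L
  n_vols <- cfg$n_dummy_volumes + n_task_vols

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed + 2L)

  # planted patterns: one per class per signal ROI, plus one shared
  # class-independent pattern per silent ROI / background
  class_patterns <- list()
  common_patterns <- list()
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    nv <- sum(m$mask)
    id <- paste(m$label, m$hemisphere, sep = "_")
    if (cfg$roi_specs[[i]]$signal_present) {
      pats <- matrix(rnorm(nv * cfg$n_classes), nrow = cfg$n_classes)
      class_patterns[[id]] <- pats
    } else {
      common_patterns[[id]] <- rnorm(nv)
    }
  }
  background_pattern <- rnorm(nvox)   # class-independent, whole grid

  # per-trial regressor sampled at TR: boxcar over recall window (*) HRF.
  # (boxcar * h)(u) = H(min(u, 32)) - H(clamp(u - dur, 0, 32)) where H is the
  # running integral of the (peak-1) HRF, tabulated once on a fine grid.
  dt <- 0.01
  tt <- seq(0, 32, by = dt)
  h <- canonical_hrf_raw(tt, cfg$hrf_params)
  H <- cumsum(c(0, (h[-1] + h[-length(h)]) / 2 * dt))
  Hfun <- stats::approxfun(tt, H, rule = 2)
  vol_times <- (seq_len(n_task_vols) - 1) * cfg$tr_s   # post-dummy times
  reg <- matrix(0, nrow = nrow(trials), ncol = n_task_vols)
  for (tr in seq_len(nrow(trials))) {
    rel <- vol_times - trials$recall_onset_s[tr]
    keep <- rel > 0 & rel <= cfg$recall_duration_s + 32
    if (any(keep)) {
      u <- rel[keep]
      reg[tr, keep] <- Hfun(pmin(u, 32)) -
        Hfun(pmin(pmax(u - cfg$recall_duration_s, 0), 32))
    }
  }

  # assemble: signal volumes (post-dummy), then prepend dummies
  signal <- matrix(0, nrow = nvox, ncol = n_task_vols)
  in_any_roi <- rep(FALSE, nvox)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    vix <- which(m$mask)
    in_any_roi[vix] <- TRUE
    id <- paste(m$label, m$hemisphere, sep = "_")
    if (cfg$roi_specs[[i]]$signal_present) {
      pats <- class_patterns[[id]]
      class_reg <- rowsum(reg, trials$class_label)   # n_classes x volumes
      signal[vix, ] <- signal[vix, ] +
        cfg$signal_amplitude * (t(pats) %*% class_reg)
    } else {
      p <- common_patterns[[id]]
      total_reg <- colSums(reg)
      signal[vix, ] <- signal[vix, ] +
        cfg$signal_amplitude * outer(p, total_reg)
    }
  }
  # out-of-ROI voxels: class-independent evoked response
  bg <- which(!in_any_roi)
  if (length(bg)) {
    total_reg <- colSums(reg)
    signal[bg, ] <- signal[bg, ] +
      cfg$signal_amplitude * outer(background_pattern[bg], total_reg)
  }

  full <- matrix(0, nrow = nvox, ncol = n_vols)
  full[, (cfg$n_dummy_volumes + 1L):n_vols] <- signal
  drift <- cfg$drift_slope * (seq_len(n_vols) - 1L)
  full <- full + rep(drift, each = nvox)
  full <- full + rnorm(length(full), sd = cfg$noise_sd)

  run <- bold_run(array(full, dim = c(cfg$grid_shape, n_vols)),
                  tr_s = cfg$tr_s, voxel_size_mm = cfg$voxel_size_mm)
  truth <- list(class_patterns = class_patterns,
                common_patterns = common_patterns,
                schedule = sched,
                regressors = reg)
  list(run = run, masks = masks, trials = trials, truth = truth)
}

# un-normalised-grid HRF evaluation helper used by the trial regressor:
# same curve as canonical_hrf (peak-1 normalised), evaluated pointwise
canonical_hrf_raw <- function(t, hrf_params) {
  p <- list(peak_delay = 6, undershoot_delay = 16, ratio = 6, dispersion = 1)
  p[names(hrf_params)] <- hrf_params
  f <- function(tt) {
    stats::dgamma(tt, shape = p$peak_delay / p$dispersion + 1,
                  rate = 1 / p$dispersion) -
      stats::dgamma(tt, shape = p$undershoot_delay / p$dispersion + 1,
                    rate = 1 / p$dispersion) / p$ratio
  }
  pk <- stats::optimize(f, c(0, p$undershoot_delay), maximum = TRUE)$objective
  f(t) / pk
}
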