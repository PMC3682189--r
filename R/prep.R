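#' Construct a BOLD run object
#'
#' A thin container for a 4-D functional series: voxel grid x volumes, with
#' its repetition time and isotropic voxel size.
#'
#' @param data 4-D numeric array (x, y, z, volume), all finite.
#' @param tr_s repetition time (s).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @return object of class \code{bold_run}.
#' @export
bold_run <- function(data, tr_s, voxel_size_mm) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr_s > 0,
            voxel_size_mm > 0)
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  structure(list(data = data, tr_s = tr_s, voxel_size_mm = voxel_size_mm),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d voxels, %d volumes, TR %.2f s, %.2f mm\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$voxel_size_mm))
  invisible(x)
}

#' Construct an ROI mask object
#'
#' @param label region name (e.g. "HC").
#' @param hemisphere "L" or "R".
#' @param mask 3-D logical array on the run grid with >= 1 TRUE voxel.
#' @return object of class \code{roi_mask}.
#' @export
roi_mask <- function(label, hemisphere = c("L", "R"), mask) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("ROI mask has no voxels")
  structure(list(label = label, hemisphere = hemisphere, mask = mask),
            class = "roi_mask")
}

#' ROI volume in cubic millimetres
#' @param mask a [roi_mask()].
#' @param voxel_size_mm isotropic voxel size (mm).
#' @return volume in mm^3.
#' @export
roi_volume_mm3 <- function(mask, voxel_size_mm) {
  sum(mask$mask) * voxel_size_mm^3
}

#' Discard leading dummy volumes
#'
#' Removes the first \code{n} volumes of a run (T1-equilibration scans).
#' Trial onsets in this package are defined relative to the first retained
#' volume, so no onset rewrite is needed; [adjust_onsets()] converts raw
#' volume indices where required.
#'
#' @param run a [bold_run()].
#' @param n number of volumes to drop (default 6).
#' @return the shortened [bold_run()].
#' @export
discard_dummies <- function(run, n = 6L) {
  stopifnot(inherits(run, "bold_run"), n >= 0)
  nt <- dim(run$data)[4]
  if (n >= nt) stop("cannot discard ", n, " volumes from a ", nt, "-volume run")
  if (n == 0L) return(run)
  bold_run(run$data[, , , (n + 1L):nt, drop = FALSE], run$tr_s,
           run$voxel_size_mm)
}

#' Convert raw-run volume indices to post-discard indices
#'
#' @param volume_index 1-based volume index into the raw run.
#' @param n_dummies number of discarded leading volumes.
#' @return 1-based index into the shortened run.
#' @export
adjust_onsets <- function(volume_index, n_dummies = 6L) {
  out <- volume_index - n_dummies
  if (any(out < 1L)) stop("volume index falls inside the discarded dummies")
  out
}

#' Spatially smooth each volume with an isotropic Gaussian kernel
#'
#' Minimal spatial smoothing: each volume is convolved with an isotropic
#' Gaussian of the given full width at half maximum.  The kernel sigma in
#' voxels is \code{fwhm / (2 sqrt(2 log 2)) / voxel_size}; boundaries use
#' nearest-neighbour replication so edge-of-ROI voxels are not deflated.
#' \code{fwhm_mm = 0} is the identity.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm kernel FWHM in millimetres (default 3).
#' @return the smoothed [bold_run()].
#' @export
smooth_gaussian <- function(run, fwhm_mm = 3) {
  stopifnot(inherits(run, "bold_run"))
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(run)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / run$voxel_size_mm
  out <- cpp_smooth_gaussian(run$data, sigma_vox)
  bold_run(out, run$tr_s, run$voxel_size_mm)
}

#' Remove per-voxel linear trends
#'
#' For every voxel the least-squares line in volume index (intercept +
#' slope) is subtracted, removing slow scanner drift; each output series has
#' zero mean and zero linear trend.  The operation is a projection, hence
#' idempotent.
#'
#' @param run a [bold_run()].
#' @return the detrended [bold_run()].
#' @export
linear_detrend <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  nt <- d[4]
  if (nt < 3) stop("need at least 3 volumes to detrend")
  M <- matrix(run$data, ncol = nt)          # voxels x time
  X <- cbind(1, seq_len(nt) - 1)
  P <- X %*% solve(crossprod(X), t(X))      # hat matrix, nt x nt
  R <- M - M %*% t(P)
  bold_run(array(R, dim = d), run$tr_s, run$voxel_size_mm)
}

#' Convolve every voxel time series with an HRF kernel
#'
#' Causal convolution of each voxel series with a kernel sampled at the TR,
#' truncated to the original series length: the output at volume t depends
#' only on volumes <= t (no future leakage).  Convolving data already
#' containing haemodynamic responses with the canonical HRF sharpens the
#' trial signal relative to the noise at the cost of roughly doubling the
#' effective haemodynamic delay.
#'
#' @param run a [bold_run()].
#' @param hrf numeric kernel sampled at the run TR (e.g.
#'   \code{canonical_hrf(seq(0, 32, by = run$tr_s))}).
#' @return the convolved [bold_run()].
#' @export
hrf_convolve <- function(run, hrf) {
  stopifnot(inherits(run, "bold_run"))
  if (length(hrf) == 0) stop("empty HRF kernel")
  d <- dim(run$data)
  nt <- d[4]
  M <- matrix(run$data, ncol = nt)
  out <- matrix(0, nrow = nrow(M), ncol = nt)
  for (k in seq_along(hrf)) {
    lag <- k - 1L
    if (lag >= nt) break
    out[, (lag + 1L):nt] <- out[, (lag + 1L):nt] +
      hrf[k] * M[, 1:(nt - lag), drop = FALSE]
  }
  bold_run(array(out, dim = d), run$tr_s, run$voxel_size_mm)
}

#' Onset shift in volumes for the combined haemodynamic delay
#'
#' The HRF convolution of data that already carries the natural BOLD delay
#' roughly doubles the lag, giving a total delay of about 12 s; onsets are
#' shifted forward by the nearest whole number of volumes.  Rounding of
#' exact halves is away from zero, so \code{compute_onset_shift(3.5, 12)}
#' is 3 volumes.
#'
#' @param tr_s repetition time (s), positive.
#' @param total_delay_s total haemodynamic delay to compensate (s).
#' @return integer number of volumes.
#' @export
compute_onset_shift <- function(tr_s, total_delay_s = 12) {
  if (tr_s <= 0) stop("TR must be positive")
  if (total_delay_s < 0) stop("delay must be nonnegative")
  x <- total_delay_s / tr_s
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Flag trials excluded by the behavioural screening rules
#'
#' A trial is included when the button press fell inside the allowed window
#' (latency in [\code{min_press_s}, \code{max_press_s}], press present) and
#' both ratings reached \code{min_rating}.  Boundary values are inclusive
#' (exclusion applies to presses strictly before 5.5 s or after 10 s, and to
#' ratings strictly below 3).  Excluded trials get a reason code:
#' \code{too_fast}, \code{too_slow} (including missing presses) or
#' \code{low_rating}; the first triggered rule wins.
#'
#' @param trials trial table with \code{press_latency_s}, \code{vividness},
#'   \code{accuracy}.
#' @param min_press_s earliest allowed press (s).
#' @param max_press_s latest allowed press (s).
#' @param min_rating minimum allowed rating on both scales.
#' @return the table with logical \code{included} and character
#'   \code{exclude_reason} (NA when included) appended.
#' @export
filter_trials <- function(trials, min_press_s = 5.5, max_press_s = 10,
                          min_rating = 3L) {
  stopifnot(is.data.frame(trials))
  rt <- c(trials$vividness, trials$accuracy)
  if (any(!is.na(rt) & (rt < 1 | rt > 5))) stop("ratings must lie in 1..5")
  lat <- trials$press_latency_s
  reason <- rep(NA_character_, nrow(trials))
  reason[!is.na(lat) & lat < min_press_s] <- "too_fast"
  slow <- is.na(lat) | lat > max_press_s
  reason[slow & is.na(reason)] <- "too_slow"
  low <- (is.na(trials$vividness) | trials$vividness < min_rating) |
         (is.na(trials$accuracy) | trials$accuracy < min_rating)
  reason[low & is.na(reason)] <- "low_rating"
  trials$included <- is.na(reason)
  trials$exclude_reason <- reason
  trials
}

#' Extract per-trial multivoxel patterns from a preprocessed run
#'
#' For every included trial, \code{n_vols_per_trial} consecutive volumes are
#' taken starting at \code{floor(recall_onset / TR) + shift_volumes}
#' (1-based: that volume index plus one), averaged voxelwise (default) and
#' restricted to the ROI mask, giving one pattern row per trial.  With
#' \code{average = FALSE} each volume becomes its own row (exploratory
#' per-volume mode) and labels are repeated accordingly.
#'
#' @param run a preprocessed [bold_run()].
#' @param trials trial table after [filter_trials()] (or with an
#'   \code{included} column; absent means all included).
#' @param mask a [roi_mask()] on the run grid.
#' @param shift_volumes onset shift from [compute_onset_shift()].
#' @param n_vols_per_trial number of volumes per trial window (default 4).
#' @param average average the window into one row per trial (default TRUE).
#' @return a \code{trial_pattern_set}: list with matrix \code{X} (trials x
#'   voxels), integer labels \code{y}, \code{voxel_coords} (voxels x 3,
#'   1-based), \code{roi_label}, \code{hemisphere}, \code{trial_index}.
#' @export
extract_trial_patterns <- function(run, trials, mask, shift_volumes,
                                   n_vols_per_trial = 4L, average = TRUE) {
  stopifnot(inherits(run, "bold_run"), inherits(mask, "roi_mask"),
            n_vols_per_trial >= 1)
  if (!identical(dim(mask$mask), dim(run$data)[1:3]))
    stop("mask grid does not match the run grid")
  inc <- if ("included" %in% names(trials)) which(trials$included)
         else seq_len(nrow(trials))
  nt <- dim(run$data)[4]
  vix <- which(mask$mask)
  coords <- which(mask$mask, arr.ind = TRUE)
  M <- matrix(run$data, ncol = nt)[vix, , drop = FALSE]   # voxels x time

  rows <- list(); labs <- integer(0); tix <- integer(0)
  for (i in inc) {
    start <- floor(trials$recall_onset_s[i] / run$tr_s) + shift_volumes + 1L
    end <- start + n_vols_per_trial - 1L
    if (start < 1L || end > nt)
      stop("trial ", trials$trial_index[i],
           ": extraction window [", start, ", ", end,
           "] falls outside the run (", nt, " volumes)")
    W <- M[, start:end, drop = FALSE]
    if (average) {
      rows[[length(rows) + 1L]] <- rowMeans(W)
      labs <- c(labs, trials$class_label[i])
      tix <- c(tix, trials$trial_index[i])
    } else {
      for (j in seq_len(ncol(W))) {
        rows[[length(rows) + 1L]] <- W[, j]
        labs <- c(labs, trials$class_label[i])
        tix <- c(tix, trials$trial_index[i])
      }
    }
  }
  X <- if (length(rows)) do.call(rbind, rows)
       else matrix(numeric(0), nrow = 0, ncol = length(vix))
  structure(list(X = X, y = labs, voxel_coords = coords,
                 roi_label = mask$label, hemisphere = mask$hemisphere,
                 trial_index = tix, tr_s = run$tr_s,
                 shift_volumes = shift_volumes),
            class = "trial_pattern_set")
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat(sprintf("<trial_pattern_set> %s (%s): %d trials x %d voxels\n",
              x$roi_label, x$hemisphere, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Run the full preprocessing chain on a raw run
#'
#' Applies, in order: dummy-volume discard, Gaussian smoothing, linear
#' detrending and HRF convolution.  Motion realignment and distortion
#' correction are assumed already done on real data (and unnecessary for
#' synthetic runs); a notice is emitted so the omission is auditable.
#'
#' @param run raw [bold_run()].
#' @param n_dummies dummy volumes to discard.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param hrf_params overrides passed to [canonical_hrf()].
#' @param notice emit the realignment pass-through message?
#' @return the preprocessed [bold_run()].
#' @export
preprocess_run <- function(run, n_dummies = 6L, fwhm_mm = 3,
                           hrf_params = list(), notice = FALSE) {
  if (notice)
    message("assuming input volumes are already realigned/unwarped")
  run <- discard_dummies(run, n_dummies)
  run <- smooth_gaussian(run, fwhm_mm)
  run <- linear_detrend(run)
  kern <- do.call(canonical_hrf,
                  c(list(t_grid = seq(0, 32, by = run$tr_s)), hrf_params))
  hrf_convolve(run, kern)
}
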