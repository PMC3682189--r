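#' Write / read a BOLD run as NIfTI-1
#'
#' The TR is stored in the NIfTI time dimension pixdim and the voxel size in
#' the spatial pixdims.
#'
#' @param run a [bold_run()].
#' @param path output file (".nii" or ".nii.gz").
#' @return \code{write_bold_nifti} returns \code{path} invisibly;
#'   \code{read_bold_nifti} returns a [bold_run()].
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  pd <- attr(img, "pixdim")
  pd[1:4] <- c(rep(run$voxel_size_mm, 3), run$tr_s)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold_run(array(as.numeric(img), dim = dim(img)),
           tr_s = pd[4], voxel_size_mm = pd[1])
}

#' Write / read a binary ROI mask as NIfTI-1 (0/1 integers)
#'
#' @param mask a [roi_mask()].
#' @param path output file.
#' @param label,hemisphere region metadata supplied on read (NIfTI carries
#'   no label field).
#' @return \code{write_roi_nifti} returns \code{path} invisibly;
#'   \code{read_roi_nifti} returns a [roi_mask()].
#' @export
write_roi_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)),
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_roi_nifti
#' @export
read_roi_nifti <- function(path, label, hemisphere) {
  img <- RNifti::readNifti(path)
  roi_mask(label, hemisphere, array(as.numeric(img) != 0, dim = dim(img)))
}

#' Write / read a trial table as tab-separated text
#'
#' Columns: trial_index, class_label, cue_onset_s, recall_onset_s,
#' press_latency_s, vividness, accuracy (+ included / exclude_reason when
#' present).
#'
#' @param trials trial table data frame.
#' @param path output .tsv file.
#' @return \code{write_trials_tsv} returns \code{path} invisibly;
#'   \code{read_trials_tsv} returns the data frame.
#' @export
write_trials_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a trial pattern set as CSV plus JSON header
#'
#' The trials-by-voxels matrix goes to \code{<path>.csv} (one row per
#' trial); metadata (labels, voxel coordinates, ROI, TR, onset shift) to
#' \code{<path>.json}.
#'
#' @param patterns a \code{trial_pattern_set}.
#' @param path base path without extension.
#' @return \code{write_pattern_set} returns \code{path} invisibly;
#'   \code{read_pattern_set} returns the pattern set.
#' @export
write_pattern_set <- function(patterns, path) {
  stopifnot(inherits(patterns, "trial_pattern_set"))
  utils::write.table(patterns$X, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(y = patterns$y, trial_index = patterns$trial_index,
               voxel_coords = unname(apply(patterns$voxel_coords, 1,
                                           as.integer, simplify = FALSE)),
               roi_label = patterns$roi_label,
               hemisphere = patterns$hemisphere,
               tr_s = patterns$tr_s, shift_volumes = patterns$shift_volumes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(X) <- NULL
  vc <- meta$voxel_coords
  if (!is.matrix(vc)) vc <- do.call(rbind, lapply(vc, as.integer))
  storage.mode(vc) <- "integer"
  structure(list(X = X, y = as.integer(meta$y),
                 voxel_coords = vc,
                 roi_label = meta$roi_label, hemisphere = meta$hemisphere,
                 trial_index = as.integer(meta$trial_index),
                 tr_s = meta$tr_s, shift_volumes = meta$shift_volumes),
            class = "trial_pattern_set")
}

#' Write a decoding result as JSON plus a one-line CSV summary
#'
#' @param result a \code{decoding_result} from [loto_crossval()].
#' @param path base path without extension.
#' @param subject subject identifier for the summary line.
#' @return \code{path} invisibly.
#' @export
write_decoding_result <- function(result, path, subject = NA) {
  stopifnot(inherits(result, "decoding_result"))
  jsonlite::write_json(list(folds = result$folds, accuracy = result$accuracy,
                            n_folds = result$n_folds,
                            roi_label = result$roi_label,
                            hemisphere = result$hemisphere),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  line <- data.frame(subject = subject, roi = result$roi_label,
                     hemisphere = result$hemisphere,
                     n_trials = result$n_folds, accuracy = result$accuracy)
  utils::write.table(line, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
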