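#' Cross-validated decoding score of one voxel set
#'
#' Leave-one-trial-out accuracy of the ECOC/SVM classifier on the supplied
#' patterns, computed entirely within those trials.  During feature
#' selection this is applied to the training portion of an outer fold
#' (nested cross-validation), keeping selection independent of the test
#' trial.  Nested folds that would strip a dichotomy of one side (a class
#' with a single trial) are skipped and the score taken over the remaining
#' folds.
#'
#' @param patterns a \code{trial_pattern_set}, or any list with matrix
#'   \code{X} and integer labels \code{y}; columns may already be restricted
#'   to a sphere.
#' @param codebook ECOC codebook; default exhaustive over the labels present.
#' @param c_param SVM regularisation constant (default 1).
#' @return accuracy in [0, 1].
#' @export
score_searchlight <- function(patterns, codebook = NULL, c_param = 1) {
  X <- as.matrix(patterns$X); y <- as.integer(patterns$y)
  if (is.null(codebook)) codebook <- ecoc_codebook(max(y))
  if (!all(seq_len(nrow(codebook)) %in% y))
    stop("every codebook class must be present in the patterns")
  pred <- cpp_loto_predict(X, y, codebook, c_param)
  ok <- pred != 0L
  if (!any(ok)) stop("all cross-validation folds were degenerate")
  mean(pred[ok] == y[ok])
}

#' Select the most informative searchlight on training data
#'
#' Scores every candidate sphere with [score_searchlight()] on the training
#' trials and returns the best one; ties break to the sphere with the lowest
#' centre index (the searchlight list order), making selection
#' deterministic.
#'
#' @param train_patterns pattern set containing only training trials.
#' @param searchlights list from [build_searchlights()].
#' @param codebook ECOC codebook; default exhaustive.
#' @param c_param SVM regularisation constant.
#' @param score_mode \code{"nested"} (leave-one-trial-out within the
#'   training set, default) or \code{"training"} (training-set accuracy).
#' @return the winning searchlight, with its score attached as
#'   \code{$score}.
#' @export
select_features <- function(train_patterns, searchlights, codebook = NULL,
                            c_param = 1, score_mode = c("nested", "training")) {
  score_mode <- match.arg(score_mode)
  stopifnot(length(searchlights) >= 1)
  X <- as.matrix(train_patterns$X); y <- as.integer(train_patterns$y)
  if (is.null(codebook)) codebook <- ecoc_codebook(max(y))
  scores <- vapply(searchlights, function(sl) {
    Xs <- X[, sl$members, drop = FALSE]
    if (score_mode == "nested") {
      score_searchlight(list(X = Xs, y = y), codebook, c_param)
    } else {
      fit <- ecoc_train(list(X = Xs, y = y), codebook, c_param)
      mean(vapply(seq_len(nrow(Xs)), function(i)
        ecoc_predict(fit, codebook, Xs[i, ]) == y[i], logical(1)))
    }
  }, numeric(1))
  best <- which.max(scores)   # first maximum = lowest centre index
  out <- searchlights[[best]]
  out$score <- scores[best]
  out
}

#' Leave-one-trial-out decoding of an ROI pattern set
#'
#' The decoder core: k-fold cross-validation with k equal to the number of
#' trials.  For each fold the held-out trial is set aside, the most
#' informative searchlight is selected on the remaining trials (nested
#' leave-one-trial-out scoring by default), the ECOC/SVM classifier is
#' trained on those trials restricted to the winning sphere, and the
#' held-out trial is predicted by Hamming decoding.  Overall accuracy is the
#' proportion of correct guesses across all folds.  The whole procedure is
#' deterministic given the patterns.
#'
#' @param patterns a \code{trial_pattern_set}.
#' @param searchlights list from [build_searchlights()]; defaults to spheres
#'   of radius \code{radius_voxels} built from the pattern set's voxel
#'   coordinates.
#' @param codebook ECOC codebook; default exhaustive over the labels.
#' @param c_param SVM regularisation constant (default 1).
#' @param radius_voxels sphere radius used when \code{searchlights} is NULL.
#' @param score_mode sphere scoring mode, \code{"nested"} (default) or
#'   \code{"training"}.
#' @return a \code{decoding_result}: \code{folds} data frame (test trial,
#'   true and predicted label, selected sphere centre), \code{accuracy},
#'   \code{n_folds}, \code{roi_label}, \code{hemisphere}.
#' @export
loto_crossval <- function(patterns, searchlights = NULL, codebook = NULL,
                          c_param = 1, radius_voxels = 3,
                          score_mode = c("nested", "training")) {
  score_mode <- match.arg(score_mode)
  X <- as.matrix(patterns$X); y <- as.integer(patterns$y)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 trials")
  counts <- table(factor(y, levels = sort(unique(y))))
  if (any(counts < 2))
    stop("every class needs >= 2 trials for leave-one-trial-out decoding ",
         "(training folds would lose a class): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (is.null(codebook)) codebook <- ecoc_codebook(max(y))
  if (is.null(searchlights))
    searchlights <- build_searchlights(patterns$voxel_coords, radius_voxels)
  members <- lapply(searchlights, `[[`, "members")
  res <- cpp_decode_roi(X, y, members, codebook, c_param,
                        ifelse(score_mode == "nested", 0L, 1L))
  centres <- t(vapply(searchlights, `[[`, numeric(3), "centre"))
  folds <- data.frame(
    test_trial = if (!is.null(patterns$trial_index)) patterns$trial_index
                 else seq_len(n),
    true_label = y,
    predicted_label = as.integer(res$predicted),
    sphere_index = as.integer(res$selected),
    sphere_x = centres[res$selected, 1],
    sphere_y = centres[res$selected, 2],
    sphere_z = centres[res$selected, 3]
  )
  structure(list(folds = folds,
                 accuracy = mean(folds$predicted_label == folds$true_label),
                 n_folds = n,
                 roi_label = patterns$roi_label,
                 hemisphere = patterns$hemisphere),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s (%s): %.1f%% over %d folds (chance %.1f%%)\n",
              x$roi_label %||% "?", x$hemisphere %||% "?",
              100 * x$accuracy, x$n_folds,
              100 / length(unique(x$folds$true_label))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
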