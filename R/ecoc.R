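#' Exhaustive error-correcting output codebook
#'
#' Builds the exhaustive ECOC codebook for \code{n_classes} classes: one
#' column per non-trivial bipartition of the class set, i.e.
#' \eqn{2^{K-1} - 1} dichotomies, each encoded as a +1/-1 column.  For three
#' classes this reduces to the three one-versus-rest dichotomies.  Rows
#' (codewords) are pairwise distinct and no column is constant.
#'
#' @param n_classes number of classes (>= 2).
#' @return integer matrix, classes x dichotomies, entries +1/-1, with class
#'   labels as rownames.
#' @export
ecoc_codebook <- function(n_classes) {
  stopifnot(n_classes >= 2)
  k <- as.integer(n_classes)
  cols <- list()
  # enumerate sign patterns of classes 2..K (class 1 fixed to +1),
  # excluding the all-+1 pattern (constant column)
  for (m in seq_len(2^(k - 1) - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(k - 1)]
    cols[[m]] <- c(1L, ifelse(bits == 1L, -1L, 1L))
  }
  code <- do.call(cbind, cols)
  rownames(code) <- seq_len(k)
  code
}

#' Train one binary classifier per ECOC dichotomy
#'
#' Relabels the training data according to each codebook column and trains a
#' linear SVM on each dichotomy.
#'
#' @param patterns a \code{trial_pattern_set} (or list with \code{X},
#'   \code{y}).
#' @param codebook matrix from [ecoc_codebook()].
#' @param c_param SVM regularisation constant.
#' @return list of \code{linear_svm} objects, one per codebook column.
#' @export
ecoc_train <- function(patterns, codebook, c_param = 1) {
  X <- patterns$X; y <- patterns$y
  stopifnot(all(y >= 1), all(y <= nrow(codebook)))
  lapply(seq_len(ncol(codebook)), function(j) {
    ybin <- codebook[y, j]
    if (length(unique(ybin)) < 2)
      stop("dichotomy column ", j, " has an empty side in the training data")
    train_binary(X, ybin, c_param)
  })
}

#' Predict a class label by Hamming decoding
#'
#' Applies every binary classifier to the feature vector, forms the +1/-1
#' bit vector of decision-value signs (0 maps to +1) and returns the class
#' whose codeword is nearest in Hamming distance; ties break to the lowest
#' class label.
#'
#' @param classifiers list from [ecoc_train()].
#' @param codebook matrix from [ecoc_codebook()].
#' @param x feature vector (or 1-row matrix).
#' @return integer class label.
#' @export
ecoc_predict <- function(classifiers, codebook, x) {
  x <- matrix(as.numeric(x), nrow = 1)
  bits <- vapply(classifiers, function(cl) {
    f <- predict(cl, x, type = "decision")
    if (f >= 0) 1L else -1L
  }, integer(1))
  hamming_nearest(bits, codebook)
}

#' Nearest codeword by Hamming distance
#'
#' @param bits +1/-1 vector of binary predictions.
#' @param codebook classes x dichotomies +1/-1 matrix.
#' @return the 1-based row index of the nearest codeword (lowest index wins
#'   ties).
#' @export
hamming_nearest <- function(bits, codebook) {
  d <- rowSums(sweep(codebook, 2, bits, `!=`))
  unname(which.min(d))  # first minimum: lowest class label wins ties
}
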