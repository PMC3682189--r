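#' Train a soft-margin linear support vector machine
#'
#' Solves the standard C-SVC problem (minimise \eqn{\tfrac12\|w\|^2 +
#' C\sum_i \xi_i} subject to \eqn{y_i(w\cdot x_i + b) \ge 1 - \xi_i}) via its
#' dual with an SMO solver on the linear-kernel Gram matrix.  The decision
#' value is \eqn{w\cdot x + b}; a decision value of exactly 0 is mapped to
#' class +1 by convention.
#'
#' @param X numeric matrix, trials x features.
#' @param y labels in \{-1, +1\}; both must be present.
#' @param c_param regularisation constant C (default 1).
#' @return object of class \code{linear_svm} with \code{weights},
#'   \code{bias}, \code{alpha} and \code{c_param}.
#' @export
train_binary <- function(X, y, c_param = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), c_param > 0)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  fit <- cpp_svm_train(X, y, c_param)
  structure(list(weights = drop(fit$weights), bias = fit$bias,
                 alpha = drop(fit$alpha), c_param = c_param,
                 iterations = fit$iterations),
            class = "linear_svm")
}

#' Decision values and predictions from a linear SVM
#'
#' @param object a \code{linear_svm} from [train_binary()].
#' @param newdata matrix of feature rows.
#' @param type "class" for -1/+1 predictions, "decision" for raw values.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  f <- drop(as.matrix(newdata) %*% object$weights + object$bias)
  if (type == "decision") f else ifelse(f >= 0, 1L, -1L)
}
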