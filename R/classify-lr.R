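#' Train sparse logistic regression
#'
#' Fits the binary model \eqn{P(y = 1 \mid x) = 1 / (1 + e^{-(w \cdot x +
#' b)})} by minimizing the (optionally ridge-penalized) negative
#' log-likelihood with a deterministic quasi-Newton optimizer (L-BFGS)
#' initialized at zero. All matrix products use the sparse representation;
#' the design matrix is never densified. The bias is never penalized.
#'
#' @param x a [DocTermMatrix-class] (TF-IDF weights) or a
#'   \code{dgCMatrix}.
#' @param y binary 0/1 label vector; both classes must be present.
#' @param l2 non-negative ridge penalty on the weights (default
#'   \code{1e-4}; keeps separable problems finite).
#' @param tol convergence tolerance on the infinity-norm of the gradient.
#' @param max_iter maximum optimizer iterations.
#' @return A [LogisticModel-class]; a warning reports the final gradient
#'   norm if the tolerance was not reached within \code{max_iter}.
#' @export
trainLogistic <- function(x, y, l2 = 1e-4, tol = 1e-6,
                          max_iter = 500L) {
  X <- if (is(x, "DocTermMatrix")) x@weights else x
  feat <- if (is(x, "DocTermMatrix")) x@vocabulary else
    (colnames(X) %||% paste0("x", seq_len(ncol(X))))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y must be parallel to the matrix rows")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (l2 < 0) stop("l2 must be non-negative")
  m <- ncol(X)

  objective <- function(par) {
    w <- par[seq_len(m)]; b <- par[m + 1L]
    eta <- as.numeric(X %*% w) + b
    # stable -loglik: sum(log(1 + exp(eta)) - y * eta)
    ll <- sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
    ll + l2 / 2 * sum(w^2)
  }
  gradient <- function(par) {
    w <- par[seq_len(m)]; b <- par[m + 1L]
    eta <- as.numeric(X %*% w) + b
    p <- 1 / (1 + exp(-eta))
    r <- p - y
    c(as.numeric(Matrix::crossprod(X, r)) + l2 * w, sum(r))
  }

  fit <- stats::optim(rep(0, m + 1L), fn = objective, gr = gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = as.integer(max_iter),
                                     factr = 10, pgtol = tol / 10))
  g <- gradient(fit$par)
  gradNorm <- max(abs(g))
  converged <- gradNorm <= tol
  if (!converged)
    warning("optimizer stopped with gradient norm ",
            format(gradNorm), " > tol ", format(tol))
  new("LogisticModel",
      weights = setNames(fit$par[seq_len(m)], feat),
      bias = fit$par[m + 1L], featureNames = feat,
      converged = converged,
      iterations = as.integer(fit$counts[["function"]]),
      objective = fit$value, gradNorm = gradNorm, l2 = l2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted probabilities from a logistic model
#'
#' Elementwise sigmoid of the (augmented) inner product
#' \eqn{w \cdot x + b}; a zero feature row yields \eqn{\sigma(b)}.
#'
#' @param model a [LogisticModel-class].
#' @param x a [DocTermMatrix-class] or matrix with the model's feature
#'   count.
#' @return Numeric probability vector in \eqn{(0, 1)}.
#' @export
predictLogistic <- function(model, x) {
  X <- if (is(x, "DocTermMatrix")) x@weights else x
  if (ncol(X) != length(model@weights))
    stop("feature count mismatch: model has ", length(model@weights),
         ", data has ", ncol(X))
  eta <- as.numeric(X %*% model@weights) + model@bias
  1 / (1 + exp(-eta))
}

#' Augmented weight vector
#'
#' The augmented form \eqn{(w^{(1)}, \ldots, w^{(m)}, b)^T}, which pairs
#' with inputs extended by a constant 1.
#'
#' @param model a [LogisticModel-class].
#' @return Numeric vector of length \eqn{m + 1}.
#' @export
augmentedWeights <- function(model) {
  c(model@weights, bias = model@bias)
}

setMethod("show", "LogisticModel", function(object) {
  cat("LogisticModel:", length(object@weights), "features, bias =",
      format(object@bias, digits = 4), "\n")
  cat("  converged:", object@converged, " objective =",
      format(object@objective, digits = 6), " |grad| =",
      format(object@gradNorm, digits = 3), "\n")
})

#' One-vs-rest multiclass logistic regression
#'
#' Extends the binary sparse logistic model to a label set (e.g. the 7
#' emotion categories) by fitting one binary model per class and predicting
#' by the maximum class probability.
#'
#' @param x a [DocTermMatrix-class] or \code{dgCMatrix}.
#' @param labels per-document class labels; every level must occur.
#' @param ... passed to [trainLogistic()].
#' @return List of class \code{"OvrLogisticModel"} with one
#'   [LogisticModel-class] per label.
#' @export
trainLogisticMulticlass <- function(x, labels, ...) {
  labels <- as.character(labels)
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 2L) stop("need at least two classes")
  models <- lapply(classes, function(cl)
    trainLogistic(x, as.integer(labels == cl), ...))
  structure(list(classes = classes, models = setNames(models, classes)),
            class = "OvrLogisticModel")
}

#' @rdname trainLogisticMulticlass
#' @param model an \code{"OvrLogisticModel"}.
#' @param type \code{"prob"} for the class-probability matrix (rows
#'   renormalized over classes), \code{"class"} for argmax labels.
#' @export
predictLogisticMulticlass <- function(model, x,
                                      type = c("class", "prob")) {
  type <- match.arg(type)
  probs <- vapply(model$models, predictLogistic, x = x,
                  numeric(if (is(x, "DocTermMatrix")) nrow(x@weights)
                          else nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  colnames(probs) <- model$classes
  if (type == "class")
    model$classes[max.col(probs, ties.method = "first")]
  else probs / rowSums(probs)
}
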