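#' Train a multinomial naive-Bayes text classifier
#'
#' Multinomial model with additive smoothing: class priors are label
#' frequencies and the probability of word \eqn{w} in class \eqn{c} is
#' \eqn{(n_{cw} + a) / (n_c + aM)} with smoothing constant \eqn{a}.
#' Deterministic.
#'
#' @param x a [DocTermMatrix-class] of raw counts (see
#'   [termCountMatrix()]) or a \code{dgCMatrix}.
#' @param labels per-document class labels (binary 0/1 polarity or the 7
#'   emotion categories); every level must occur at least once.
#' @param smoothing positive additive smoothing constant (default 1).
#' @return A [NaiveBayesModel-class].
#' @export
trainNaiveBayes <- function(x, labels, smoothing = 1) {
  if (smoothing <= 0) stop("smoothing must be positive")
  mat <- if (is(x, "DocTermMatrix")) x@weights else x
  vocab <- if (is(x, "DocTermMatrix")) x@vocabulary else colnames(mat)
  labels <- as.character(labels)
  if (nrow(mat) != length(labels))
    stop("labels must be parallel to the matrix rows")
  if (anyNA(labels)) stop("labels must not be missing")
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 1L) stop("no classes in training data")
  M <- ncol(mat)
  logProb <- matrix(NA_real_, length(classes), M,
                    dimnames = list(classes, vocab))
  prior <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    rows <- labels == classes[ci]
    prior[ci] <- mean(rows)
    cnt <- Matrix::colSums(mat[rows, , drop = FALSE])
    logProb[ci, ] <- log((cnt + smoothing) / (sum(cnt) + smoothing * M))
  }
  new("NaiveBayesModel", classes = classes,
      logPrior = setNames(log(prior), classes), logProb = logProb,
      vocabulary = vocab, smoothing = smoothing)
}

# Coerce tokens / token lists / DocTermMatrix to a dense count matrix over
# the model vocabulary; out-of-vocabulary tokens are ignored.
.countsOver <- function(newdata, vocabulary) {
  if (is(newdata, "Corpus")) newdata <- newdata@tokens
  if (is(newdata, "DocTermMatrix")) {
    idx <- match(vocabulary, newdata@vocabulary)
    out <- matrix(0, nrow(newdata@weights), length(vocabulary))
    ok <- !is.na(idx)
    out[, ok] <- as.matrix(newdata@weights[, idx[ok], drop = FALSE])
    return(out)
  }
  if (is.character(newdata)) newdata <- list(newdata)
  t(vapply(newdata, function(tk) {
    idx <- match(tk, vocabulary)
    tabulate(idx[!is.na(idx)], nbins = length(vocabulary))
  }, numeric(length(vocabulary))))
}

#' Posterior class probabilities from a naive-Bayes model
#'
#' For an empty document (or one with no vocabulary tokens) the posterior
#' falls back to the class priors.
#'
#' @param model a [NaiveBayesModel-class].
#' @param newdata a [Corpus-class], a list of token vectors, a single
#'   token vector, or a [DocTermMatrix-class] of counts.
#' @param type \code{"posterior"} for the documents-by-classes probability
#'   matrix, \code{"class"} for the maximum-posterior labels.
#' @return Numeric matrix or character vector.
#' @export
predictNaiveBayes <- function(model, newdata,
                              type = c("posterior", "class")) {
  type <- match.arg(type)
  counts <- .countsOver(newdata, model@vocabulary)
  logpost <- counts %*% t(model@logProb) +
    matrix(model@logPrior, nrow(counts), length(model@classes),
           byrow = TRUE)
  logpost <- logpost - apply(logpost, 1L, max)
  post <- exp(logpost)
  post <- post / rowSums(post)
  colnames(post) <- model@classes
  if (type == "class") model@classes[max.col(post, ties.method = "first")]
  else post
}

#' Positive-class probability (s-hat) under a binary naive-Bayes model
#'
#' Convenience wrapper returning \eqn{\hat{s} = P(y = 1 \mid d)}, the
#' quantity rescaled by [shiftScore()] before daily aggregation.
#'
#' @inheritParams predictNaiveBayes
#' @return Numeric vector of probabilities in \eqn{[0, 1]}.
#' @export
sentimentProbabilityNB <- function(model, newdata) {
  if (!"1" %in% model@classes)
    stop("model has no class labelled '1'")
  unname(predictNaiveBayes(model, newdata)[, "1"])
}

setMethod("show", "NaiveBayesModel", function(object) {
  cat("NaiveBayesModel:", length(object@classes), "classes over",
      length(object@vocabulary), "words (smoothing =",
      object@smoothing, ")\n")
  cat("  priors:", paste(object@classes,
                         sprintf("%.3f", exp(object@logPrior)),
                         sep = "=", collapse = " "), "\n")
})
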