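#' Extract biterms from a token sequence
#'
#' A biterm is an unordered pair of tokens co-occurring in the same short
#' document. Following the short-text convention, all within-document
#' position pairs are extracted (no sliding window) unless a finite
#' \code{window} is given; pairs of identical words at distinct positions
#' are kept. Each pair is normalized so the smaller vocabulary index comes
#' first.
#'
#' @param tokens character vector of tokens (one document).
#' @param vocabulary character vector; tokens outside it are skipped.
#' @param window maximum positional distance between pair members
#'   (default \code{Inf}: all pairs).
#' @return Integer matrix with 2 columns of 1-based vocabulary indices;
#'   documents with fewer than 2 usable tokens yield 0 rows.
#' @examples
#' extractBiterms(c("a", "b", "c"), c("a", "b", "c"))  # 3 rows
#' @export
extractBiterms <- function(tokens, vocabulary, window = Inf) {
  idx <- match(tokens, vocabulary)
  idx <- idx[!is.na(idx)]
  m <- length(idx)
  if (m < 2L) return(matrix(integer(), ncol = 2L))
  first <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  second <- sequence((m - 1L):1L) + first
  if (is.finite(window)) {
    ok <- (second - first) <= window
    first <- first[ok]; second <- second[ok]
  }
  a <- idx[first]; b <- idx[second]
  cbind(pmin(a, b), pmax(a, b))
}

.corpusBiterms <- function(corpus, vocabulary, window = Inf) {
  do.call(rbind, lapply(corpus@tokens, extractBiterms,
                        vocabulary = vocabulary, window = window))
}

#' Fit a biterm topic model by collapsed Gibbs sampling
#'
#' Models the corpus-wide biterm set with \code{K} topics: a biterm is
#' generated by drawing a topic \eqn{z} from the corpus topic distribution
#' \eqn{\theta} and its two words independently from the topic's word
#' distribution \eqn{\phi_z}. After the final sweep the estimators are
#' \deqn{\theta_k = (n_k + \alpha) / (|B| + K\alpha), \quad
#'       \phi_{k,w} = (n_{w|k} + \beta) / (2 n_k + M\beta)}
#' with \eqn{n_k} the biterms assigned to topic \eqn{k} and
#' \eqn{n_{w|k}} the occurrences of word \eqn{w} in them.
#'
#' @param corpus tokenized [Corpus-class] with at least one biterm.
#' @param K number of topics (\eqn{\ge 1}).
#' @param alpha,beta symmetric Dirichlet priors; defaults
#'   \eqn{\alpha = 50/K}, \eqn{\beta = 0.01}.
#' @param iterations Gibbs sweeps (default 1000).
#' @param seed RNG seed; fixed seed gives bit-identical fits.
#' @param vocabulary optional fixed vocabulary (default: built from the
#'   corpus).
#' @param window biterm window passed to [extractBiterms()].
#' @return A [BtmModel-class].
#' @export
fitBTM <- function(corpus, K, alpha = 50 / K, beta = 0.01,
                   iterations = 1000L, seed = 1L, vocabulary = NULL,
                   window = Inf) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1")
  if (is.null(vocabulary)) vocabulary <- buildVocabulary(corpus)
  biterms <- .corpusBiterms(corpus, vocabulary, window)
  if (!nrow(biterms)) stop("corpus contains no biterms")
  M <- length(vocabulary)

  set.seed(seed)
  fit <- .btm_gibbs(biterms - 1L, M, K, alpha, beta,
                    as.integer(iterations))
  nk <- fit$nk
  theta <- (nk + alpha) / (nrow(biterms) + K * alpha)
  phi <- (fit$nwk + beta) / (2 * nk + M * beta)
  dimnames(phi) <- list(NULL, vocabulary)
  new("BtmModel", K = K, theta = as.numeric(theta), phi = phi,
      vocabulary = vocabulary, biterms = biterms,
      assignments = as.integer(fit$z) + 1L, alpha = alpha, beta = beta,
      iterations = as.integer(iterations), seed = as.integer(seed))
}

#' Probability of a biterm under a fitted model
#'
#' \eqn{p(w_1, w_2) = \sum_k \theta_k \phi_{k,w_1} \phi_{k,w_2}}; summing
#' over all ordered word pairs gives 1.
#'
#' @param model a [BtmModel-class].
#' @param w1,w2 words (must be in the model vocabulary).
#' @return Probability in \eqn{(0, 1]}.
#' @export
bitermProbability <- function(model, w1, w2) {
  i <- match(w1, model@vocabulary)
  j <- match(w2, model@vocabulary)
  if (is.na(i) || is.na(j))
    stop("word(s) not in model vocabulary: ",
         paste(c(w1, w2)[is.na(c(i, j))], collapse = ", "))
  sum(model@theta * model@phi[, i] * model@phi[, j])
}

#' Per-document topic distributions under a biterm topic model
#'
#' Standard BTM document inference:
#' \eqn{p(k \mid d) \propto \sum_{b \in d} p(k \mid b)} with
#' \eqn{p(k \mid b) \propto \theta_k \phi_{k,w_1} \phi_{k,w_2}}. Documents
#' contributing no biterm fall back to the corpus distribution
#' \eqn{\theta}.
#'
#' @param model a [BtmModel-class].
#' @param corpus tokenized [Corpus-class].
#' @return Numeric matrix (documents x K); rows sum to 1.
#' @export
btmDocTopics <- function(model, corpus) {
  out <- matrix(NA_real_, nDocs(corpus), model@K)
  for (d in seq_len(nDocs(corpus))) {
    bt <- extractBiterms(corpus@tokens[[d]], model@vocabulary)
    if (!nrow(bt)) {
      out[d, ] <- model@theta
      next
    }
    pk <- numeric(model@K)
    for (r in seq_len(nrow(bt))) {
      pb <- model@theta * model@phi[, bt[r, 1L]] * model@phi[, bt[r, 2L]]
      pk <- pk + pb / sum(pb)
    }
    out[d, ] <- pk / sum(pk)
  }
  out
}

#' Top words of each topic
#'
#' @param model a [BtmModel-class] or [LdaModel-class].
#' @param n number of words per topic.
#' @return data.frame with columns \code{topic}, \code{rank}, \code{word},
#'   \code{probability}.
#' @export
topTopicWords <- function(model, n = 10L) {
  do.call(rbind, lapply(seq_len(model@K), function(k) {
    ord <- order(-model@phi[k, ], model@vocabulary)[seq_len(
      min(n, ncol(model@phi)))]
    data.frame(topic = k, rank = seq_along(ord),
               word = model@vocabulary[ord],
               probability = unname(model@phi[k, ord]),
               stringsAsFactors = FALSE)
  }))
}

setMethod("show", "BtmModel", function(object) {
  cat("BtmModel: K =", object@K, "topics,", length(object@vocabulary),
      "words,", nrow(object@biterms), "biterms\n")
  cat("  alpha =", object@alpha, " beta =", object@beta,
      " iterations =", object@iterations, " seed =", object@seed, "\n")
})

#' Save / load a topic model as plain text
#'
#' Writes a key:value header (class, K, alpha, beta, iterations, seed), the
#' theta vector and the phi matrix in MatrixMarket format, and the
#' vocabulary.
#'
#' @param model a [BtmModel-class] or [LdaModel-class].
#' @param prefix path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writeTopicModel <- function(model, prefix) {
  hdr <- c(paste0("class: ", class(model)),
           paste0("K: ", model@K),
           paste0("alpha: ", format(model@alpha, digits = 17)),
           paste0("beta: ", format(model@beta, digits = 17)),
           paste0("iterations: ", model@iterations),
           paste0("seed: ", model@seed))
  writeLines(hdr, paste0(prefix, ".header.txt"))
  writeLines(model@vocabulary, paste0(prefix, ".vocab.txt"),
             useBytes = TRUE)
  utils::write.table(
    if (is(model, "BtmModel")) data.frame(theta = model@theta)
    else data.frame(theta = colMeans(model@docTopic)),
    paste0(prefix, ".theta.txt"), row.names = FALSE)
  Matrix::writeMM(as(Matrix::Matrix(model@phi, sparse = TRUE),
                     "CsparseMatrix"),
                  paste0(prefix, ".phi.mtx"))
  invisible(prefix)
}
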