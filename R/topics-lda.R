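#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Standard collapsed Gibbs over per-token topic assignments with symmetric
#' Dirichlet priors; the defaults follow common practice for short-text
#' opinion corpora: \eqn{\alpha = 50/K} on document-topic distributions,
#' \eqn{\beta = 0.01} on topic-word distributions, 1000 sweeps. Estimates
#' are taken from the counts at the final sweep.
#'
#' @param corpus tokenized, non-empty [Corpus-class].
#' @param K number of topics (\eqn{\ge 1}).
#' @param seed RNG seed; fixed seed gives bit-identical fits.
#' @param alpha,beta Dirichlet hyperparameters.
#' @param iterations Gibbs sweeps.
#' @param vocabulary optional fixed vocabulary.
#' @return An [LdaModel-class].
#' @export
fitLDA <- function(corpus, K, seed = 1L, alpha = 50 / K, beta = 0.01,
                   iterations = 1000L, vocabulary = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1")
  if (!nDocs(corpus)) stop("corpus must be non-empty")
  if (is.null(vocabulary)) vocabulary <- buildVocabulary(corpus)
  tok <- .tokenStream(corpus, vocabulary)
  if (!length(tok$word)) stop("no vocabulary tokens in corpus")
  M <- length(vocabulary)
  D <- nDocs(corpus)

  set.seed(seed)
  fit <- .lda_gibbs(tok$doc - 1L, tok$word - 1L, D, M, K, alpha, beta,
                    as.integer(iterations))
  ndk <- fit$ndk
  docTopic <- (ndk + alpha) / (rowSums(ndk) + K * alpha)
  nk <- rowSums(fit$nwk)
  phi <- (fit$nwk + beta) / (nk + M * beta)
  dimnames(phi) <- list(NULL, vocabulary)
  new("LdaModel", K = K, docTopic = docTopic, phi = phi,
      vocabulary = vocabulary, docIds = docIds(corpus),
      alpha = alpha, beta = beta, iterations = as.integer(iterations),
      seed = as.integer(seed))
}

# Flatten a corpus into parallel (doc index, word index) token vectors,
# skipping out-of-vocabulary tokens.
.tokenStream <- function(corpus, vocabulary) {
  docs <- integer(0); words <- integer(0)
  for (d in seq_len(nDocs(corpus))) {
    idx <- match(corpus@tokens[[d]], vocabulary)
    idx <- idx[!is.na(idx)]
    docs <- c(docs, rep.int(d, length(idx)))
    words <- c(words, idx)
  }
  list(doc = docs, word = words)
}

setMethod("show", "LdaModel", function(object) {
  cat("LdaModel: K =", object@K, "topics,", length(object@vocabulary),
      "words,", length(object@docIds), "documents\n")
  cat("  alpha =", object@alpha, " beta =", object@beta,
      " iterations =", object@iterations, " seed =", object@seed, "\n")
})

#' Held-out perplexity of a topic model
#'
#' Computes \eqn{\exp(-\sum_d \sum_{w \in d} \log p(w \mid d) / N)} over
#' in-vocabulary tokens of a held-out corpus, where \eqn{p(w \mid d)}
#' mixes the fitted topic-word distributions with a per-document topic
#' mixture (for LDA inferred by folding-in Gibbs sweeps with topic-word
#' distributions held fixed; for the biterm model via [btmDocTopics()]).
#'
#' Two estimators are available. The default, \code{"completion"}
#' (document completion), infers each held-out document's topic mixture
#' from its odd-position tokens only and scores the even-position tokens,
#' so a model with spurious extra topics cannot improve its score by
#' adapting to the very tokens being predicted; this gives the U-shaped
#' perplexity-versus-K curve used by [selectK()]. \code{"fold-in"} infers
#' the mixture from the whole document and scores every token.
#' Out-of-vocabulary tokens are skipped and reported via the
#' \code{coverage} attribute (fraction of scored-position tokens that were
#' in vocabulary).
#'
#' @param model a fitted [BtmModel-class] or [LdaModel-class].
#' @param heldout tokenized [Corpus-class].
#' @param method \code{"completion"} or \code{"fold-in"}.
#' @param infer_iterations fold-in sweeps for LDA inference.
#' @param seed RNG seed for the fold-in sampler.
#' @return Positive number (\eqn{\ge 1}), with attribute \code{coverage}.
#' @export
setGeneric("perplexity", function(model, heldout, ...)
  standardGeneric("perplexity"))

#' @rdname perplexity
#' @param ... passed between methods.
#' @export
setMethod("perplexity", "LdaModel",
  function(model, heldout, method = c("completion", "fold-in"),
           infer_iterations = 50L, seed = 1L, ...) {
    method <- match.arg(method)
    parts <- .splitHeldout(heldout, method)
    tokInfer <- .tokenStream(parts$infer, model@vocabulary)
    .perplexityCore(model, parts, function() {
      set.seed(seed)
      ndk <- .lda_infer(tokInfer$doc - 1L, tokInfer$word - 1L, model@phi,
                        nDocs(heldout), model@alpha,
                        as.integer(infer_iterations))
      (ndk + model@alpha) / (rowSums(ndk) + model@K * model@alpha)
    })
  })

#' @rdname perplexity
#' @export
setMethod("perplexity", "BtmModel",
  function(model, heldout, method = c("completion", "fold-in"), ...) {
    method <- match.arg(method)
    parts <- .splitHeldout(heldout, method)
    .perplexityCore(model, parts,
                    function() btmDocTopics(model, parts$infer))
  })

# Split held-out documents into the token set used for mixture inference
# and the token set that is scored.
.splitHeldout <- function(heldout, method) {
  if (method == "fold-in") {
    return(list(infer = heldout, eval = heldout@tokens))
  }
  odd <- lapply(heldout@tokens, function(tk)
    tk[seq_along(tk) %% 2L == 1L])
  even <- lapply(heldout@tokens, function(tk)
    tk[seq_along(tk) %% 2L == 0L])
  infer <- heldout
  infer@tokens <- odd
  list(infer = infer, eval = even)
}

.perplexityCore <- function(model, parts, mixtureFn) {
  evalTok <- parts$eval
  nTotal <- sum(lengths(evalTok))
  doc <- integer(0); word <- integer(0)
  for (d in seq_along(evalTok)) {
    idx <- match(evalTok[[d]], model@vocabulary)
    idx <- idx[!is.na(idx)]
    doc <- c(doc, rep.int(d, length(idx)))
    word <- c(word, idx)
  }
  if (!length(word))
    stop("held-out corpus has no in-vocabulary tokens to score")
  docTopic <- mixtureFn()
  pword <- docTopic[doc, , drop = FALSE] *
    t(model@phi)[word, , drop = FALSE]
  logp <- log(rowSums(pword))
  out <- exp(-sum(logp) / length(logp))
  attr(out, "coverage") <- length(word) / nTotal
  out
}

#' Select the topic count by minimum held-out perplexity
#'
#' Splits the corpus into training and test documents, fits one model per
#' candidate \code{K} on the training split, and returns the \code{K}
#' minimizing held-out perplexity; ties resolve to the smaller \code{K}.
#'
#' @param corpus tokenized [Corpus-class].
#' @param k_grid integer vector of candidate topic counts.
#' @param seed RNG seed controlling both the split and the fits.
#' @param method \code{"btm"} or \code{"lda"}.
#' @param train_frac fraction of documents used for training.
#' @param iterations Gibbs sweeps per fit.
#' @param ... further arguments passed to [fitBTM()] / [fitLDA()].
#' @return Selected integer \code{K}, with attribute \code{perplexities}
#'   (named by candidate).
#' @export
selectK <- function(corpus, k_grid, seed = 1L, method = c("btm", "lda"),
                    train_frac = 0.7, iterations = 200L, ...) {
  method <- match.arg(method)
  if (!length(k_grid)) stop("k_grid must be non-empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  n <- nDocs(corpus)
  set.seed(seed)
  trainIdx <- sort(sample.int(n, max(2L, floor(train_frac * n))))
  train <- corpus[trainIdx]
  test <- corpus[setdiff(seq_len(n), trainIdx)]
  vocab <- buildVocabulary(train)
  perp <- vapply(k_grid, function(K) {
    model <- if (method == "btm")
      fitBTM(train, K, iterations = iterations, seed = seed,
             vocabulary = vocab, ...)
    else
      fitLDA(train, K, seed = seed, iterations = iterations,
             vocabulary = vocab, ...)
    as.numeric(perplexity(model, test, seed = seed))
  }, numeric(1))
  names(perp) <- k_grid
  out <- k_grid[which.min(perp)]  # which.min takes the first = smallest K
  attr(out, "perplexities") <- perp
  out
}

#' Chi-square topic weights over temporal strata
#'
#' Builds the topic-by-stratum (e.g. month) contingency table of
#' dominant-topic counts and weights each topic by its chi-square
#' contribution \eqn{\sum_s (O - E)^2 / E}, normalized to sum to 1. Topics
#' whose prevalence varies most over time receive the largest weight; a
#' perfectly uniform table yields uniform weights.
#'
#' @param dominant_topics integer vector: each document's dominant topic.
#' @param strata per-document stratum labels (e.g. "2020-07").
#' @param K total topic count (defaults to \code{max(dominant_topics)}).
#' @return Named numeric weight vector of length \code{K} summing to 1.
#' @export
topicWeightsChisq <- function(dominant_topics, strata,
                              K = max(dominant_topics)) {
  if (length(dominant_topics) != length(strata))
    stop("dominant_topics and strata must be parallel")
  tab <- table(factor(dominant_topics, levels = seq_len(K)), strata)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("contingency table has empty expected cells; use coarser strata")
  contrib <- rowSums((tab - expected)^2 / expected)
  if (sum(contrib) < 1e-12) {
    w <- rep(1 / K, K)
  } else {
    w <- contrib / sum(contrib)
  }
  setNames(as.numeric(w), seq_len(K))
}
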