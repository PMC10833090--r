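#' Embedding provider contract
#'
#' An embedding provider is a named object exposing a deterministic
#' \code{embed} function from a word to a fixed-dimension numeric vector.
#' The package ships a self-contained default built from the corpus itself
#' ([ppmiEmbedding()]); providers backed by external pretrained models can
#' be supplied with the same shape.
#'
#' @param name provider identifier.
#' @param dimension embedding dimension.
#' @param embed function(word) -> numeric vector of length
#'   \code{dimension}.
#' @param vocabulary optional character vector of covered words.
#' @return List of class \code{"EmbeddingProvider"}.
#' @export
embeddingProvider <- function(name, dimension, embed, vocabulary = NULL) {
  stopifnot(is.function(embed), dimension >= 1)
  structure(list(name = name, dimension = as.integer(dimension),
                 embed = embed, vocabulary = vocabulary),
            class = "EmbeddingProvider")
}

#' Deterministic corpus-based word embeddings (PPMI + truncated SVD)
#'
#' Builds word vectors from the corpus alone: a word-word co-occurrence
#' matrix over within-document pairs, transformed to positive pointwise
#' mutual information (PPMI), then factorized by truncated SVD; the vector
#' of word \eqn{w} is row \eqn{w} of \eqn{U_r \sqrt{\Sigma_r}}. Fully
#' deterministic for a fixed corpus, so cluster-based vocabulary reduction
#' is reproducible without downloads.
#'
#' @param corpus tokenized [Corpus-class].
#' @param dimension embedding dimension (capped at the vocabulary size).
#' @param vocabulary optional fixed vocabulary.
#' @return An [embeddingProvider()] covering the vocabulary; unknown words
#'   raise an error.
#' @export
ppmiEmbedding <- function(corpus, dimension = 25L, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- buildVocabulary(corpus)
  M <- length(vocabulary)
  dimension <- min(as.integer(dimension), M)
  C <- matrix(0, M, M)
  for (tk in corpus@tokens) {
    idx <- match(tk, vocabulary)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2L) next
    bt <- extractBiterms(vocabulary[idx], vocabulary)
    for (r in seq_len(nrow(bt))) {
      C[bt[r, 1L], bt[r, 2L]] <- C[bt[r, 1L], bt[r, 2L]] + 1
      if (bt[r, 1L] != bt[r, 2L])
        C[bt[r, 2L], bt[r, 1L]] <- C[bt[r, 2L], bt[r, 1L]] + 1
    }
  }
  total <- sum(C)
  if (total == 0) stop("no co-occurrences; corpus too small to embed")
  rowp <- rowSums(C) / total
  pmi <- log(pmax(C / total, .Machine$double.xmin) /
               pmax(outer(rowp, rowp), .Machine$double.xmin))
  pmi[C == 0] <- 0
  ppmi <- pmax(pmi, 0)
  sv <- svd(ppmi, nu = dimension, nv = 0)
  vecs <- sv$u %*% diag(sqrt(sv$d[seq_len(dimension)]), dimension)
  rownames(vecs) <- vocabulary
  embeddingProvider(
    name = "ppmi-svd", dimension = dimension,
    embed = function(word) {
      if (!word %in% vocabulary) stop("word not covered: ", word)
      vecs[word, ]
    },
    vocabulary = vocabulary)
}

#' Cluster the vocabulary and pick representative words
#'
#' Runs k-means (Euclidean, seeded initialization) on the words' embedding
#' vectors; each cluster's representative is its highest-corpus-frequency
#' member (ties broken lexicographically), and the map sends every word to
#' its cluster's representative. Representatives map to themselves.
#'
#' @param vocabulary character vector of words to cluster.
#' @param provider an [embeddingProvider()] covering the vocabulary.
#' @param n_clusters number of clusters (\eqn{\le} vocabulary size).
#' @param frequencies named numeric vector of corpus frequencies.
#' @param seed RNG seed for the k-means initialization.
#' @return Named character vector: word -> representative word, with
#'   attribute \code{representatives}.
#' @export
clusterVocabulary <- function(vocabulary, provider, n_clusters,
                              frequencies, seed = 1L) {
  M <- length(vocabulary)
  if (n_clusters > M)
    stop("n_clusters exceeds the vocabulary size")
  if (n_clusters == M) {
    map <- setNames(vocabulary, vocabulary)
    attr(map, "representatives") <- vocabulary
    return(map)
  }
  E <- t(vapply(vocabulary, provider$embed, numeric(provider$dimension)))
  set.seed(seed)
  km <- stats::kmeans(E, centers = n_clusters, nstart = 10L,
                      iter.max = 100L)
  freq <- frequencies[vocabulary]
  freq[is.na(freq)] <- 0
  reps <- character(n_clusters)
  for (cl in seq_len(n_clusters)) {
    members <- vocabulary[km$cluster == cl]
    f <- freq[members]
    best <- members[f == max(f)]
    reps[cl] <- sort(best, method = "radix")[1L]
  }
  map <- setNames(reps[km$cluster], vocabulary)
  attr(map, "representatives") <- sort(unique(reps), method = "radix")
  map
}

#' Corpus token frequencies
#'
#' @param corpus tokenized [Corpus-class].
#' @return Named numeric vector of token-type frequencies.
#' @export
corpusFrequencies <- function(corpus) {
  tab <- table(unlist(corpus@tokens, use.names = FALSE))
  setNames(as.numeric(tab), names(tab))
}

#' Replace every token by its cluster representative
#'
#' Shrinks the corpus vocabulary by substituting each word with the
#' representative of its embedding cluster; token counts are preserved and
#' the resulting vocabulary is a subset of the representative set.
#'
#' @param corpus tokenized [Corpus-class].
#' @param map named character vector from [clusterVocabulary()].
#' @return The reduced [Corpus-class].
#' @export
reduceCorpus <- function(corpus, map) {
  vocab <- unique(unlist(corpus@tokens, use.names = FALSE))
  uncovered <- setdiff(vocab, names(map))
  if (length(uncovered))
    stop("tokens not covered by the cluster map: ",
         paste(head(uncovered, 10L), collapse = ", "))
  corpus@tokens <- lapply(corpus@tokens, function(tk)
    unname(map[tk]))
  corpus
}
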