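#' Build a stable vocabulary from a tokenized corpus
#'
#' Words with corpus frequency at least \code{min_count}, sorted
#' lexicographically in the C locale so the order is stable across
#' platforms and document orderings.
#'
#' @param corpus tokenized [Corpus-class].
#' @param min_count minimum corpus frequency (default 1).
#' @return Character vector of vocabulary words (column order for
#'   [tfidfMatrix()]).
#' @export
buildVocabulary <- function(corpus, min_count = 1L) {
  freq <- table(unlist(corpus@tokens, use.names = FALSE))
  words <- names(freq)[freq >= min_count]
  if (!length(words)) stop("empty vocabulary after frequency filtering")
  sort(words, method = "radix")
}

#' Term frequency of a word in a document
#'
#' \eqn{tf(w, D_i) = C(w) / |D_i|} where \eqn{C(w)} counts occurrences of
#' the word and \eqn{|D_i|} is the document's token count.
#'
#' @param word a single word.
#' @param tokens the document's token vector (non-empty).
#' @return Fraction in \eqn{[0, 1]}.
#' @export
termFrequency <- function(word, tokens) {
  if (!length(tokens)) stop("term frequency is undefined for an empty document")
  sum(tokens == word) / length(tokens)
}

#' Inverse document frequency within a document set
#'
#' \eqn{idf(w) = \log(D / (1 + \sum_i I(w, D_i)))} with \eqn{D} the number
#' of documents and \eqn{I} the containment indicator. A word present in
#' every document makes the raw value negative; it is clamped at 0 so
#' weights stay non-negative.
#'
#' @param word a single word.
#' @param docs a [Corpus-class] or a list of token vectors (non-empty).
#' @param clamp clamp negative values at 0 (default \code{TRUE}).
#' @return Non-negative number (natural logarithm).
#' @export
inverseDocumentFrequency <- function(word, docs, clamp = TRUE) {
  toks <- if (is(docs, "Corpus")) docs@tokens else docs
  if (!length(toks)) stop("document set must be non-empty")
  df <- sum(vapply(toks, function(tk) word %in% tk, logical(1)))
  v <- log(length(toks) / (1 + df))
  if (clamp) max(v, 0) else v
}

#' Sparse TF-IDF document-term matrix
#'
#' Builds the sparse matrix whose entry \eqn{(i, j)} is
#' \eqn{tf(w_j, D_i) \times idf(w_j)} over the supplied document set; zero
#' entries are not stored. The IDF is computed within the same document set
#' that is passed in, so passing one day's documents gives day-scoped
#' weights and passing a whole training corpus gives corpus-scoped weights.
#' Documents containing no vocabulary word are dropped with a warning.
#'
#' @param corpus tokenized [Corpus-class] (documents non-empty after
#'   preprocessing).
#' @param vocabulary character vector from [buildVocabulary()]; defaults to
#'   the vocabulary of \code{corpus}.
#' @param normalize optionally L2-normalize each row (default off; raw
#'   \eqn{tf \times idf} matches the weighting equations).
#' @return A [DocTermMatrix-class].
#' @export
tfidfMatrix <- function(corpus, vocabulary = NULL, normalize = FALSE) {
  if (is.null(vocabulary)) vocabulary <- buildVocabulary(corpus)
  toks <- corpus@tokens
  keep <- vapply(toks, function(tk) any(tk %in% vocabulary), logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " document(s) without vocabulary tokens dropped: ",
            paste(head(docIds(corpus)[!keep], 5L), collapse = ", "))
    corpus <- corpus[keep]
    toks <- corpus@tokens
  }
  D <- length(toks)
  if (!D) stop("no documents left to featurize")

  counts <- .tripletCounts(toks, vocabulary)
  docLen <- lengths(toks)
  # (i, j) triplets are unique, so tabulating j gives document frequency
  dfreq <- tabulate(counts$j, nbins = length(vocabulary))
  idf <- pmax(log(D / (1 + dfreq)), 0)

  vals <- counts$x / docLen[counts$i] * idf[counts$j]
  w <- Matrix::sparseMatrix(i = counts$i, j = counts$j, x = vals,
                            dims = c(D, length(vocabulary)))
  w <- Matrix::drop0(w)
  if (normalize) {
    nrm <- sqrt(Matrix::rowSums(w^2))
    nrm[nrm == 0] <- 1
    w <- w / nrm
  }
  new("DocTermMatrix", weights = as(w, "CsparseMatrix"),
      docIds = docIds(corpus), vocabulary = vocabulary)
}

#' Sparse raw term-count matrix
#'
#' Companion to [tfidfMatrix()] holding raw occurrence counts; used by the
#' multinomial naive-Bayes classifier.
#'
#' @inheritParams tfidfMatrix
#' @return A [DocTermMatrix-class] whose weights are integer counts.
#' @export
termCountMatrix <- function(corpus, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- buildVocabulary(corpus)
  counts <- .tripletCounts(corpus@tokens, vocabulary)
  w <- Matrix::sparseMatrix(i = counts$i, j = counts$j, x = counts$x,
                            dims = c(nDocs(corpus), length(vocabulary)))
  new("DocTermMatrix", weights = as(w, "CsparseMatrix"),
      docIds = docIds(corpus), vocabulary = vocabulary)
}

# Unique (doc, word) -> count triplets over the vocabulary.
.tripletCounts <- function(toks, vocabulary) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(toks)) {
    idx <- match(toks[[d]], vocabulary)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    tab <- table(idx)
    ii <- c(ii, rep.int(d, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  list(i = ii, j = jj, x = xx)
}

setMethod("show", "DocTermMatrix", function(object) {
  cat("DocTermMatrix:", nrow(object@weights), "documents x",
      ncol(object@weights), "words,",
      length(object@weights@x), "stored entries\n")
})

#' @describeIn DocTermMatrix dimensions (documents, words).
#' @param x,object a [DocTermMatrix-class].
#' @export
setMethod("dim", "DocTermMatrix", function(x) dim(x@weights))

#' Write / read a document-term matrix in MatrixMarket format
#'
#' Writes \code{<prefix>.mtx} (coordinate format) plus the sidecar files
#' \code{<prefix>.vocab.txt} and \code{<prefix>.docs.txt} holding column
#' and row identities.
#'
#' @param dtm a [DocTermMatrix-class].
#' @param prefix path prefix for the three files.
#' @return \code{prefix}, invisibly (write) or a [DocTermMatrix-class]
#'   (read).
#' @export
writeDocTermMatrix <- function(dtm, prefix) {
  Matrix::writeMM(dtm@weights, paste0(prefix, ".mtx"))
  writeLines(dtm@vocabulary, paste0(prefix, ".vocab.txt"), useBytes = TRUE)
  writeLines(dtm@docIds, paste0(prefix, ".docs.txt"), useBytes = TRUE)
  invisible(prefix)
}

#' @rdname writeDocTermMatrix
#' @export
readDocTermMatrix <- function(prefix) {
  w <- Matrix::readMM(paste0(prefix, ".mtx"))
  new("DocTermMatrix",
      weights = as(as(w, "CsparseMatrix"), "dMatrix"),
      docIds = readLines(paste0(prefix, ".docs.txt"), encoding = "UTF-8"),
      vocabulary = readLines(paste0(prefix, ".vocab.txt"),
                             encoding = "UTF-8"))
}
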