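#' @import methods
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom Matrix sparseMatrix t colSums rowSums crossprod readMM writeMM
#' @importFrom stats kmeans optim rbinom runif setNames dbinom aggregate
#' @importFrom utils read.csv write.csv head
#' @useDynLib opinionminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("dgCMatrixOrNULL", c("dgCMatrix", "NULL"))

#' Emotion taxonomy: seven main categories over twenty-one subcategories
#'
#' The taxonomy used throughout the package follows the Dalian University of
#' Technology emotion-lexicon design: seven main emotion categories
#' (\code{anger}, \code{disgust}, \code{fear}, \code{sadness},
#' \code{surprise}, \code{good}, \code{happy}), each containing one or more
#' of twenty-one subcategory codes, and a polarity map sending the four
#' negative categories to \eqn{-1} and the three positive ones to \eqn{+1}.
#'
#' @slot mainCategories character vector of the 7 main category names.
#' @slot subcategoryMap named character vector mapping each of the 21
#'   subcategory codes to its main category.
#' @slot polarityMap named integer vector mapping each main category to
#'   \code{-1L} or \code{+1L}.
#'
#' @seealso [defaultTaxonomy()], [mainCategoryOf()]
#' @exportClass EmotionTaxonomy
setClass("EmotionTaxonomy",
  representation(
    mainCategories = "character",
    subcategoryMap = "character",
    polarityMap    = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@mainCategories) != 7L)
      msg <- c(msg, "taxonomy must have exactly 7 main categories")
    if (anyDuplicated(object@mainCategories))
      msg <- c(msg, "main categories must be unique")
    if (!all(object@subcategoryMap %in% object@mainCategories))
      msg <- c(msg, "every subcategory must map to a main category")
    if (is.null(names(object@subcategoryMap)) ||
        anyDuplicated(names(object@subcategoryMap)))
      msg <- c(msg, "subcategory codes must be unique and named")
    if (!setequal(names(object@polarityMap), object@mainCategories))
      msg <- c(msg, "polarityMap must cover exactly the main categories")
    if (!all(object@polarityMap %in% c(-1L, 1L)))
      msg <- c(msg, "polarities must be -1 or +1")
    if (length(msg)) msg else TRUE
  }
)

#' Corpus of short documents
#'
#' A \code{Corpus} holds an ordered collection of short documents with their
#' metadata (date, region label, optional polarity and emotion labels) and,
#' after tokenization, a per-document token sequence. Documents are stored
#' row-wise in a data frame; tokens are a parallel list.
#'
#' @slot docs data.frame with columns \code{doc_id}, \code{text},
#'   \code{date} (class \code{Date}, may be \code{NA}), \code{region},
#'   \code{polarity_label} (integer 0/1 or \code{NA}), \code{emotion_label}.
#' @slot tokens list of character vectors, one per document (empty until
#'   tokenization).
#' @slot metadata free-form list of annotations (source, generator seed, ...).
#'
#' @seealso [readCorpus()], [tokenizeCorpus()], [partitionByDay()]
#' @exportClass Corpus
setClass("Corpus",
  representation(docs = "data.frame", tokens = "list", metadata = "list"),
  validity = function(object) {
    msg <- character()
    need <- c("doc_id", "text", "date", "region",
              "polarity_label", "emotion_label")
    if (!all(need %in% names(object@docs)))
      msg <- c(msg, paste("docs must have columns:",
                          paste(setdiff(need, names(object@docs)),
                                collapse = ", ")))
    else {
      if (anyDuplicated(object@docs$doc_id))
        msg <- c(msg, "doc_id values must be unique within a corpus")
      if (!inherits(object@docs$date, "Date"))
        msg <- c(msg, "date column must have class Date")
      pl <- object@docs$polarity_label
      if (!all(is.na(pl) | pl %in% c(0L, 1L)))
        msg <- c(msg, "polarity_label must be 0, 1 or NA")
    }
    if (length(object@tokens) != nrow(object@docs))
      msg <- c(msg, "tokens list must be parallel to docs")
    bad <- vapply(object@tokens, function(tk) {
      length(tk) > 0L && (any(!nzchar(tk)) || any(grepl("\\s", tk)))
    }, logical(1))
    if (any(bad))
      msg <- c(msg, "tokens must be non-empty strings without whitespace")
    if (length(msg)) msg else TRUE
  }
)

#' Sentiment lexicon
#'
#' A table of emotion-bearing words in the Dalian-lexicon layout: word, part
#' of speech, number of senses, emotion subcategory, intensity (odd levels 1,
#' 3, 5, 7, 9 canonically; any integer 1--9 accepted), signed polarity, and
#' an optional auxiliary subcategory. A word may carry several entries
#' (senses); scoring resolves multi-sense words to the maximum-intensity
#' entry.
#'
#' @slot entries data.frame with columns \code{word}, \code{pos},
#'   \code{sense_count}, \code{subcategory}, \code{intensity},
#'   \code{polarity}, \code{auxiliary}.
#' @slot taxonomy an [EmotionTaxonomy-class] covering all subcategory codes
#'   used by the entries.
#'
#' @seealso [loadLexicon()], [makeLexicon()], [wordSentiment()]
#' @exportClass SentimentLexicon
setClass("SentimentLexicon",
  representation(entries = "data.frame", taxonomy = "EmotionTaxonomy"),
  validity = function(object) {
    msg <- character()
    need <- c("word", "pos", "sense_count", "subcategory", "intensity",
              "polarity", "auxiliary")
    if (!all(need %in% names(object@entries)))
      msg <- c(msg, paste("entries must have columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(object@entries)) {
      e <- object@entries
      if (!all(e$intensity %in% 1:9))
        msg <- c(msg, "intensity must be an integer in 1..9")
      if (!all(e$polarity %in% c(-1L, 1L)))
        msg <- c(msg, "polarity must be -1 or +1")
      if (!all(e$subcategory %in% names(object@taxonomy@subcategoryMap)))
        msg <- c(msg, "unknown subcategory code in entries")
      if (!all(e$sense_count >= 1L))
        msg <- c(msg, "sense_count must be positive")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Sparse document-term matrix of TF-IDF weights
#'
#' Triplet-backed sparse matrix whose entry \eqn{(i, j)} is the TF-IDF
#' weight of vocabulary word \eqn{j} in document \eqn{i}; zero entries are
#' not stored. Row identity is kept through \code{docIds} and column
#' identity through the vocabulary.
#'
#' @slot weights a \code{Matrix::dgCMatrix} (documents x words).
#' @slot docIds character vector of document identifiers, one per row.
#' @slot vocabulary character vector of words, one per column.
#'
#' @seealso [tfidfMatrix()], [writeDocTermMatrix()]
#' @exportClass DocTermMatrix
setClass("DocTermMatrix",
  representation(weights = "dgCMatrix", docIds = "character",
                 vocabulary = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@weights) != length(object@docIds))
      msg <- c(msg, "docIds must match the number of rows")
    if (ncol(object@weights) != length(object@vocabulary))
      msg <- c(msg, "vocabulary must match the number of columns")
    if (length(object@weights@x) && any(!is.finite(object@weights@x)))
      msg <- c(msg, "weights must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Biterm topic model state
#'
#' State of a biterm topic model (BTM) fitted by collapsed Gibbs sampling.
#' The BTM models the corpus-wide set of biterms (unordered word pairs
#' co-occurring in a document): a corpus-level topic distribution
#' \eqn{\theta} of length \eqn{K} and a \eqn{K \times M} matrix \eqn{\phi}
#' of per-topic word distributions.
#'
#' @slot K integer topic count.
#' @slot theta numeric length-\code{K} corpus topic distribution (sums to 1).
#' @slot phi numeric \code{K x M} matrix; each row sums to 1.
#' @slot vocabulary character vector of the M words indexing \code{phi}.
#' @slot biterms integer matrix (|B| x 2) of 1-based word indices, each row
#'   ordered so the first index is not larger than the second.
#' @slot assignments integer vector of per-biterm topic indices (1-based).
#' @slot alpha,beta symmetric Dirichlet hyperparameters.
#' @slot iterations,seed sampler settings used for the fit.
#'
#' @seealso [fitBTM()], [bitermProbability()], [perplexity()]
#' @exportClass BtmModel
setClass("BtmModel",
  representation(K = "integer", theta = "numeric", phi = "matrix",
                 vocabulary = "character", biterms = "matrix",
                 assignments = "integer", alpha = "numeric",
                 beta = "numeric", iterations = "integer", seed = "integer"),
  validity = function(object) .validTopicModel(object)
)

#' Latent Dirichlet allocation model state
#'
#' State of an LDA model fitted by collapsed Gibbs sampling over per-token
#' topic assignments, with symmetric priors \eqn{\alpha = 50/K} on the
#' document-topic distributions and \eqn{\beta = 0.01} on the topic-word
#' distributions by default.
#'
#' @slot K integer topic count.
#' @slot docTopic numeric D x K matrix of document-topic distributions.
#' @slot phi numeric K x M matrix of topic-word distributions.
#' @slot vocabulary character vector of the M words.
#' @slot docIds character vector of the D document identifiers.
#' @slot alpha,beta Dirichlet hyperparameters.
#' @slot iterations,seed sampler settings used for the fit.
#'
#' @seealso [fitLDA()], [perplexity()], [selectK()]
#' @exportClass LdaModel
setClass("LdaModel",
  representation(K = "integer", docTopic = "matrix", phi = "matrix",
                 vocabulary = "character", docIds = "character",
                 alpha = "numeric", beta = "numeric",
                 iterations = "integer", seed = "integer"),
  validity = function(object) {
    msg <- .validTopicModel(object)
    if (isTRUE(msg)) msg <- character()
    if (nrow(object@docTopic) &&
        any(abs(rowSums(object@docTopic) - 1) > 1e-9))
      msg <- c(msg, "every docTopic row must sum to 1")
    if (length(msg)) msg else TRUE
  }
)

.validTopicModel <- function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (nrow(object@phi) != object@K)
    msg <- c(msg, "phi must have K rows")
  if (ncol(object@phi) != length(object@vocabulary))
    msg <- c(msg, "phi columns must match the vocabulary")
  if (nrow(object@phi) && any(abs(rowSums(object@phi) - 1) > 1e-9))
    msg <- c(msg, "every phi row must sum to 1 within 1e-9")
  if (any(object@phi < 0))
    msg <- c(msg, "phi must be non-negative")
  if (is(object, "BtmModel")) {
    if (length(object@theta) != object@K)
      msg <- c(msg, "theta must have length K")
    if (length(object@theta) && abs(sum(object@theta) - 1) > 1e-9)
      msg <- c(msg, "theta must sum to 1 within 1e-9")
  }
  if (length(msg)) msg else TRUE
}

#' Multinomial naive-Bayes text classifier
#'
#' Class priors and additively smoothed per-class word probabilities over a
#' fixed vocabulary, for binary polarity or multi-class emotion prediction.
#'
#' @slot classes character vector of class labels (ordered).
#' @slot logPrior named numeric vector of log class priors.
#' @slot logProb numeric classes x words matrix of log word probabilities;
#'   each row exponentiates to a distribution.
#' @slot vocabulary character vector of words.
#' @slot smoothing additive smoothing constant used for the fit.
#'
#' @seealso [trainNaiveBayes()], [predictNaiveBayes()]
#' @exportClass NaiveBayesModel
setClass("NaiveBayesModel",
  representation(classes = "character", logPrior = "numeric",
                 logProb = "matrix", vocabulary = "character",
                 smoothing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(exp(object@logPrior)) - 1) > 1e-8)
      msg <- c(msg, "class priors must sum to 1")
    if (nrow(object@logProb) != length(object@classes))
      msg <- c(msg, "logProb must have one row per class")
    if (nrow(object@logProb) &&
        any(abs(rowSums(exp(object@logProb)) - 1) > 1e-6))
      msg <- c(msg, "per-class word probabilities must sum to 1")
    if (length(msg)) msg else TRUE
  }
)

#' Sparse logistic-regression model
#'
#' Binary logistic regression \eqn{P(y = 1 \mid x) = 1 / (1 + e^{-(w \cdot x
#' + b)})} fitted on a sparse document-term matrix by a deterministic
#' quasi-Newton optimizer initialized at zero. The augmented form
#' \eqn{(w^{(1)}, \ldots, w^{(m)}, b)^T} is available via
#' [augmentedWeights()].
#'
#' @slot weights numeric weight vector of length M (named by feature).
#' @slot bias numeric intercept (may be 0).
#' @slot featureNames character vector of feature (word) names.
#' @slot converged logical; did the optimizer meet the gradient tolerance.
#' @slot iterations number of optimizer iterations used.
#' @slot objective final penalized negative log-likelihood.
#' @slot gradNorm final infinity-norm of the gradient.
#' @slot l2 ridge penalty used (0 for none; never applied to the bias).
#'
#' @seealso [trainLogistic()], [predictLogistic()]
#' @exportClass LogisticModel
setClass("LogisticModel",
  representation(weights = "numeric", bias = "numeric",
                 featureNames = "character", converged = "logical",
                 iterations = "integer", objective = "numeric",
                 gradNorm = "numeric", l2 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@weights) != length(object@featureNames))
      msg <- c(msg, "weights must be parallel to featureNames")
    if (any(!is.finite(object@weights)) || !is.finite(object@bias))
      msg <- c(msg, "parameters must be finite")
    if (length(msg)) msg else TRUE
  }
)
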