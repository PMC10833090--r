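## Tokenizer registry ------------------------------------------------------

.tokenizers <- new.env(parent = emptyenv())

#' Register a tokenizer
#'
#' Tokenizers are deterministic functions from a string to an ordered
#' character vector of whitespace-free tokens. The package registers a
#' language-independent \code{"whitespace"} tokenizer (punctuation stripped,
#' split on whitespace; intra-word apostrophes, hyphens and underscores are
#' kept). Segmenters for unsegmented scripts (e.g. a CJK word segmenter) can
#' be plugged in under their own name.
#'
#' @param name tokenizer identifier.
#' @param fn function taking a character scalar and returning a character
#'   vector of tokens.
#' @return \code{name}, invisibly.
#' @export
registerTokenizer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .tokenizers)
  invisible(name)
}

#' @rdname registerTokenizer
#' @export
getTokenizer <- function(name) {
  .ensureDefaultTokenizer()
  if (!exists(name, envir = .tokenizers, inherits = FALSE))
    stop("no tokenizer registered under name: ", name)
  get(name, envir = .tokenizers, inherits = FALSE)
}

.whitespaceTokenize <- function(x) {
  x <- gsub("[.,!?;:\"()%<>\\[\\]{}]", " ", x, perl = TRUE)
  tk <- strsplit(trimws(x), "\\s+")[[1]]
  tk[nzchar(tk)]
}

.ensureDefaultTokenizer <- function() {
  if (!exists("whitespace", envir = .tokenizers, inherits = FALSE))
    registerTokenizer("whitespace", .whitespaceTokenize)
}

## Config and resource files -----------------------------------------------

#' Preprocessing configuration
#'
#' Bundles the settings of the seven-step cleaning ladder: duplicate
#' removal, useless-character and tag removal, segmentation with an optional
#' user dictionary, stop-word removal, low-frequency-word removal, and
#' missing-value imputation.
#'
#' @param stopword_path optional path to a stop-word file (UTF-8, one token
#'   per line, \code{#} comments ignored).
#' @param user_dictionary_path optional path to a user dictionary (one
#'   multi-word term per line); dictionary terms are never split by the
#'   tokenizer.
#' @param min_token_count non-negative integer; token types with corpus
#'   frequency below this are removed (1 disables the filter).
#' @param strip_html remove HTML/XML tags and URLs during cleaning.
#' @param tokenizer_name name of a registered tokenizer.
#' @return A named list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(stopword_path = NULL,
                             user_dictionary_path = NULL,
                             min_token_count = 1L,
                             strip_html = TRUE,
                             tokenizer_name = "whitespace") {
  min_token_count <- as.integer(min_token_count)
  if (is.na(min_token_count) || min_token_count < 0L)
    stop("min_token_count must be a non-negative integer")
  getTokenizer(tokenizer_name)  # fails early if unregistered
  structure(list(stopword_path = stopword_path,
                 user_dictionary_path = user_dictionary_path,
                 min_token_count = min_token_count,
                 strip_html = isTRUE(strip_html),
                 tokenizer_name = tokenizer_name),
            class = "PreprocessConfig")
}

#' Read a stop-word list
#'
#' @param path UTF-8 text file, one token per line; blank lines and lines
#'   starting with \code{#} are ignored.
#' @return Character vector of stop words.
#' @export
readStopwords <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a user dictionary of multi-word terms
#'
#' @param path UTF-8 text file, one term per line.
#' @return Character vector of terms.
#' @export
readUserDictionary <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

## The ladder --------------------------------------------------------------

#' Clean raw text
#'
#' Removes URLs, HTML/XML tags (to a fixed point, so nested fragments cannot
#' survive) and characters outside letters, digits, whitespace and basic
#' punctuation; runs of whitespace are collapsed. The operation is total and
#' idempotent: \code{cleanText(cleanText(x))} equals \code{cleanText(x)}.
#'
#' @param text character vector.
#' @param strip_html also remove tags and URLs (default \code{TRUE}).
#' @return Cleaned character vector of the same length.
#' @examples
#' cleanText("<b>risk</b>!")  # "risk!"
#' @export
cleanText <- function(text, strip_html = TRUE) {
  text[is.na(text)] <- ""
  if (strip_html) {
    text <- gsub("(https?://|www\\.)[^[:space:]]+", " ", text, perl = TRUE)
    repeat {
      out <- gsub("<[^<>]*>", "", text, perl = TRUE)
      if (identical(out, text)) break
      text <- out
    }
  }
  text <- gsub("[^\\p{L}\\p{N}\\s.,!?;:'\"()%_-]", " ", text, perl = TRUE)
  trimws(gsub("\\s+", " ", text, perl = TRUE))
}

#' Remove exact-duplicate documents
#'
#' Keeps the first occurrence of each exact text string (intended to run
#' after [cleanText()]); later duplicates are dropped and order preserved.
#'
#' @param corpus a [Corpus-class].
#' @return The deduplicated [Corpus-class].
#' @export
deduplicateCorpus <- function(corpus) {
  corpus[!duplicated(docTexts(corpus))]
}

#' Tokenize every document
#'
#' Applies a registered tokenizer to each document's text. Terms of the
#' user dictionary are protected before segmentation by joining their
#' internal whitespace with \code{"_"}, so each term survives as a single
#' token (e.g. \code{"nucleic acid testing"} becomes
#' \code{"nucleic_acid_testing"}).
#'
#' @param corpus a [Corpus-class] (cleaned text).
#' @param tokenizer name of a registered tokenizer or a tokenizer function.
#' @param user_dictionary optional character vector of multi-word terms.
#' @return The [Corpus-class] with tokens populated.
#' @export
tokenizeCorpus <- function(corpus, tokenizer = "whitespace",
                           user_dictionary = NULL) {
  fn <- if (is.function(tokenizer)) tokenizer else getTokenizer(tokenizer)
  texts <- docTexts(corpus)
  if (length(user_dictionary)) {
    terms <- user_dictionary[order(-nchar(user_dictionary))]
    for (term in terms) {
      glued <- gsub("\\s+", "_", term)
      texts <- gsub(term, glued, texts, fixed = TRUE)
    }
  }
  corpus@tokens <- lapply(texts, fn)
  validObject(corpus)
  corpus
}

#' Remove stop words from every document
#'
#' @param corpus tokenized [Corpus-class].
#' @param stoplist character vector of stop words (may be empty).
#' @return The [Corpus-class] with stop words dropped; documents may become
#'   empty.
#' @export
removeStopwords <- function(corpus, stoplist) {
  if (!length(stoplist)) return(corpus)
  corpus@tokens <- lapply(corpus@tokens, function(tk)
    tk[!(tk %in% stoplist)])
  corpus
}

#' Remove low-frequency token types
#'
#' Drops every token whose corpus-wide frequency is below \code{min_count},
#' so all surviving token types have frequency \eqn{\ge} \code{min_count}.
#'
#' @param corpus tokenized [Corpus-class].
#' @param min_count non-negative integer (0 or 1 keeps everything).
#' @return Filtered [Corpus-class].
#' @export
filterLowFrequency <- function(corpus, min_count) {
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 0L)
    stop("min_count must be a non-negative integer")
  if (min_count <= 1L) return(corpus)
  freq <- table(unlist(corpus@tokens, use.names = FALSE))
  keep <- names(freq)[freq >= min_count]
  corpus@tokens <- lapply(corpus@tokens, function(tk) tk[tk %in% keep])
  corpus
}

#' Impute missing metadata with a depth-1 decision tree
#'
#' Fills missing values of one metadata column (by default \code{region})
#' with a single-split decision rule learned from complete records: every
#' candidate predictor (the other metadata columns; dates are binarized at
#' every midpoint threshold) is scored by information gain on the target,
#' the best split is kept, and a missing record receives the majority
#' target value within its stratum, falling back to the global mode when
#' the stratum is unseen or the predictor itself is missing. Imputed
#' records are flagged in an \code{imputed} column.
#'
#' @param corpus a [Corpus-class].
#' @param column target column, \code{"region"} or \code{"date"}.
#' @return The [Corpus-class] with the column filled and a logical
#'   \code{imputed} column added to the document table.
#' @export
imputeMissing <- function(corpus, column = c("region", "date")) {
  column <- match.arg(column)
  docs <- corpus@docs
  target <- as.character(docs[[column]])
  miss <- is.na(target)
  docs$imputed <- miss
  if (!any(!miss))
    stop("column '", column, "' has no observed values to learn from")
  if (!any(miss)) {
    docs$imputed <- FALSE
    corpus@docs <- docs
    return(corpus)
  }

  candidates <- setdiff(c("date", "region", "polarity_label",
                          "emotion_label"), column)
  y <- target[!miss]
  globalMode <- .modeOf(y)
  best <- list(gain = -Inf)
  for (cand in candidates) {
    xs <- docs[[cand]][!miss]
    if (all(is.na(xs))) next
    if (cand == "date") {
      vals <- sort(unique(as.numeric(xs[!is.na(xs)])))
      if (length(vals) < 2L) next
      thr <- (head(vals, -1L) + vals[-1L]) / 2
      for (t in thr) {
        g <- .infoGain(y, ifelse(as.numeric(xs) <= t, "lo", "hi"))
        if (!is.na(g) && g > best$gain)
          best <- list(gain = g, predictor = cand, threshold = t)
      }
    } else {
      g <- .infoGain(y, as.character(xs))
      if (!is.na(g) && g > best$gain)
        best <- list(gain = g, predictor = cand, threshold = NULL)
    }
  }

  strat <- function(idx) {
    if (!is.finite(best$gain)) return(NA_character_)
    v <- docs[[best$predictor]][idx]
    if (is.na(v)) return(NA_character_)
    if (!is.null(best$threshold))
      return(if (as.numeric(v) <= best$threshold) "lo" else "hi")
    as.character(v)
  }
  keyAll <- vapply(which(!miss), strat, character(1))
  for (i in which(miss)) {
    k <- strat(i)
    pool <- if (!is.na(k)) y[!is.na(keyAll) & keyAll == k] else character()
    target[i] <- if (length(pool)) .modeOf(pool) else globalMode
  }
  if (column == "date") {
    docs$date <- as.Date(target)
  } else {
    docs[[column]] <- target
  }
  corpus@docs <- docs
  corpus
}

.modeOf <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}

.entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

.infoGain <- function(y, stratum) {
  ok <- !is.na(stratum)
  if (!any(ok)) return(NA_real_)
  y <- y[ok]; stratum <- stratum[ok]
  h <- .entropy(y)
  cond <- sum(vapply(split(y, stratum), function(g)
    length(g) / length(y) * .entropy(g), numeric(1)))
  h - cond
}

#' Run the full preprocessing ladder
#'
#' Applies cleaning, exact deduplication, tokenization (with user
#' dictionary), stop-word removal and low-frequency filtering in order.
#' Because tokenization always re-derives tokens from the (cleaned) text,
#' applying the ladder twice equals applying it once.
#'
#' @param corpus a [Corpus-class].
#' @param config a [preprocessConfig()] list.
#' @return The preprocessed [Corpus-class].
#' @export
preprocessCorpus <- function(corpus, config = preprocessConfig()) {
  corpus@docs$text <- cleanText(docTexts(corpus), config$strip_html)
  corpus <- deduplicateCorpus(corpus)
  dict <- if (!is.null(config$user_dictionary_path))
    readUserDictionary(config$user_dictionary_path) else NULL
  corpus <- tokenizeCorpus(corpus, config$tokenizer_name, dict)
  stops <- if (!is.null(config$stopword_path))
    readStopwords(config$stopword_path) else character()
  corpus <- removeStopwords(corpus, stops)
  filterLowFrequency(corpus, max(config$min_token_count, 1L))
}
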