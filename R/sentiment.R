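#' Signed sentiment value of a lexicon entry
#'
#' The sentiment value of a word is the product of its intensity and its
#' signed polarity, \eqn{s(w) = v(w)\,p(w)}; its sign equals the polarity
#' sign and its magnitude equals the intensity.
#'
#' @param entry a single-row data.frame as returned by [lexiconLookup()]
#'   (or any list with \code{intensity} and \code{polarity}).
#' @return Signed numeric sentiment value.
#' @examples
#' wordSentiment(list(intensity = 7, polarity = -1))  # -7
#' @export
wordSentiment <- function(entry) {
  as.numeric(entry$intensity) * as.numeric(entry$polarity)
}

# One resolved row per word: the maximum-intensity sense, ties broken by
# subcategory code then polarity for determinism.
.resolveLexicon <- function(lexicon) {
  e <- lexicon@entries
  if (!nrow(e)) {
    return(data.frame(word = character(), category = character(),
                      intensity = integer(), s = numeric()))
  }
  ord <- order(e$word, -e$intensity, e$subcategory, e$polarity)
  e <- e[ord, , drop = FALSE]
  e <- e[!duplicated(e$word), , drop = FALSE]
  data.frame(word = e$word,
             category = mainCategoryOf(e$subcategory, lexicon@taxonomy),
             intensity = e$intensity,
             s = e$intensity * e$polarity,
             stringsAsFactors = FALSE)
}

#' Multidimensional emotion profile of a token sequence
#'
#' Scans the tokens against the lexicon; every hit adds the word's
#' intensity to its main category's running total and its signed sentiment
#' value \eqn{s(w) = v(w) p(w)} to the polarity score. Tokens absent from
#' the lexicon are ignored. Multi-sense words are resolved to their
#' maximum-intensity entry.
#'
#' @param tokens character vector of tokens.
#' @param lexicon a [SentimentLexicon-class].
#' @return Named list with \code{totals} (named numeric over the 7 main
#'   categories), \code{polarity_score}, \code{matched_count} and
#'   \code{dominant} (main category name, or \code{NA} when no token
#'   matched).
#' @export
emotionProfile <- function(tokens, lexicon) {
  res <- .resolveLexicon(lexicon)
  .profileOne(tokens, res, lexicon@taxonomy)
}

.profileOne <- function(tokens, resolved, taxonomy) {
  totals <- setNames(numeric(length(taxonomy@mainCategories)),
                     taxonomy@mainCategories)
  idx <- match(tokens, resolved$word)
  hit <- !is.na(idx)
  idx <- idx[hit]
  for (i in idx)
    totals[[resolved$category[i]]] <-
      totals[[resolved$category[i]]] + resolved$intensity[i]
  list(totals = totals,
       polarity_score = if (length(idx)) sum(resolved$s[idx]) else 0,
       matched_count = length(idx),
       dominant = .dominantCategory(totals, length(idx)))
}

.dominantCategory <- function(totals, matched_count) {
  if (matched_count == 0L) return(NA_character_)
  totals <- totals[.CATEGORY_ORDER]  # fixed tie-break order
  names(totals)[which.max(totals)]
}

#' Emotion profiles for every document of a corpus
#'
#' @param corpus tokenized [Corpus-class].
#' @param lexicon a [SentimentLexicon-class].
#' @param threshold polarity threshold passed to [classifyPolarity()].
#' @return data.frame with one row per document: \code{doc_id}, the 7
#'   per-category intensity totals, \code{polarity_score},
#'   \code{matched_count}, \code{dominant} and the thresholded
#'   \code{predicted} binary label.
#' @export
emotionProfiles <- function(corpus, lexicon, threshold = 0) {
  res <- .resolveLexicon(lexicon)
  cats <- lexicon@taxonomy@mainCategories
  rows <- lapply(corpus@tokens, .profileOne, resolved = res,
                 taxonomy = lexicon@taxonomy)
  out <- data.frame(doc_id = docIds(corpus), stringsAsFactors = FALSE)
  for (ct in cats)
    out[[ct]] <- vapply(rows, function(r) r$totals[[ct]], numeric(1))
  out$polarity_score <- vapply(rows, `[[`, numeric(1), "polarity_score")
  out$matched_count <- vapply(rows, `[[`, numeric(1), "matched_count")
  out$dominant <- vapply(rows, function(r)
    if (is.na(r$dominant)) NA_character_ else r$dominant, character(1))
  out$predicted <- classifyPolarity(out$polarity_score, threshold)
  out
}

#' Threshold polarity classification
#'
#' @param score numeric polarity score(s), or a profile list from
#'   [emotionProfile()].
#' @param threshold decision threshold (default 0).
#' @return Integer label(s): 1 (positive) when the score exceeds the
#'   threshold, else 0 (negative).
#' @export
classifyPolarity <- function(score, threshold = 0) {
  if (is.list(score) && !is.null(score$polarity_score))
    score <- score$polarity_score
  as.integer(score > threshold)
}

#' Proportion of negative-emotion-dominated documents
#'
#' Fraction of profiles whose dominant main category is one of anger,
#' disgust, fear, sadness. Ties among matched categories resolve by the
#' fixed order anger > disgust > fear > sadness > surprise > good > happy;
#' profiles with no lexicon match have no dominant category and do not
#' count as negative.
#'
#' @param profiles data.frame from [emotionProfiles()] (or any data.frame
#'   with a \code{dominant} column).
#' @return Fraction in \eqn{[0, 1]}.
#' @export
negativeEmotionProportion <- function(profiles) {
  if (!NROW(profiles)) stop("profiles must be non-empty")
  mean(profiles$dominant %in% .NEGATIVE_CATEGORIES)
}

#' Write emotion profiles to CSV
#'
#' @param profiles data.frame from [emotionProfiles()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEmotionProfiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
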