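.CORPUS_COLUMNS <- c("doc_id", "text", "date", "region",
                     "polarity_label", "emotion_label")

#' Construct a corpus of short documents
#'
#' @param doc_id character vector of unique document identifiers.
#' @param text character vector of raw document text.
#' @param date document dates (\code{Date} or ISO-8601 strings); optional.
#' @param region region labels; optional.
#' @param polarity_label optional binary sentiment labels (0 = negative,
#'   1 = positive).
#' @param emotion_label optional main emotion category labels.
#' @param tokens optional list of token vectors (normally left empty and
#'   filled by [tokenizeCorpus()]).
#' @param metadata free-form list of corpus-level annotations.
#' @return A [Corpus-class] object.
#' @examples
#' corp <- Corpus(doc_id = c("u1", "u2"),
#'                text = c("masks sold out", "vaccine works"))
#' nDocs(corp)
#' @export
Corpus <- function(doc_id, text, date = NA, region = NA_character_,
                   polarity_label = NA_integer_,
                   emotion_label = NA_character_,
                   tokens = NULL, metadata = list()) {
  n <- length(doc_id)
  docs <- data.frame(
    doc_id = as.character(doc_id),
    text = as.character(text),
    date = .asDate(rep_len(date, max(n, 0L)), as.character(doc_id)),
    region = as.character(rep_len(region, n)),
    polarity_label = .asPolarityLabel(rep_len(polarity_label, n)),
    emotion_label = as.character(rep_len(emotion_label, n)),
    stringsAsFactors = FALSE
  )
  if (is.null(tokens)) tokens <- rep(list(character()), n)
  new("Corpus", docs = docs, tokens = tokens, metadata = metadata)
}

.asDate <- function(x, ids = NULL) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonmiss <- !is.na(x) & nzchar(x)
  if (any(nonmiss)) {
    parsed <- as.Date(x[nonmiss], format = "%Y-%m-%d")
    bad <- is.na(parsed)
    if (any(bad)) {
      which_ids <- if (!is.null(ids)) ids[nonmiss][bad] else
        which(nonmiss)[bad]
      stop("unparseable date(s) for doc_id: ",
           paste(which_ids, collapse = ", "))
    }
    out[nonmiss] <- parsed
  }
  out
}

.asPolarityLabel <- function(x) {
  x <- suppressWarnings(as.integer(x))
  if (!all(is.na(x) | x %in% c(0L, 1L)))
    stop("polarity_label must be 0, 1 or NA")
  x
}

#' @describeIn Corpus number of documents in the corpus.
#' @param x,object a [Corpus-class].
#' @export
nDocs <- function(x) nrow(x@docs)

#' Corpus accessors
#'
#' Read the identifier, text, date, region, label and token fields of a
#' [Corpus-class].
#'
#' @param x a [Corpus-class].
#' @return The requested per-document vector (or list, for tokens).
#' @name corpus-accessors
NULL

#' @rdname corpus-accessors
#' @export
docIds <- function(x) x@docs$doc_id

#' @rdname corpus-accessors
#' @export
docTexts <- function(x) x@docs$text

#' @rdname corpus-accessors
#' @export
docDates <- function(x) x@docs$date

#' @rdname corpus-accessors
#' @export
docRegions <- function(x) x@docs$region

#' @rdname corpus-accessors
#' @export
polarityLabels <- function(x) x@docs$polarity_label

#' @rdname corpus-accessors
#' @export
emotionLabels <- function(x) x@docs$emotion_label

#' @rdname corpus-accessors
#' @export
docTokens <- function(x) x@tokens

#' Subset a corpus by document position
#'
#' @param x a [Corpus-class].
#' @param i integer or logical index over documents.
#' @param j,drop,... ignored.
#' @return A [Corpus-class] containing the selected documents, in order.
#' @export
setMethod("[", "Corpus", function(x, i, j, ..., drop = FALSE) {
  new("Corpus", docs = x@docs[i, , drop = FALSE],
      tokens = x@tokens[i], metadata = x@metadata)
})

setMethod("show", "Corpus", function(object) {
  tokenized <- sum(lengths(object@tokens) > 0L)
  cat("Corpus with", nDocs(object), "documents (", tokenized,
      "tokenized )\n")
  dr <- range(object@docs$date, na.rm = ifelse(
    all(is.na(object@docs$date)), FALSE, TRUE))
  if (!all(is.na(dr))) cat("  dates:", format(dr[1]), "to",
                           format(dr[2]), "\n")
  regs <- unique(object@docs$region)
  regs <- regs[!is.na(regs)]
  if (length(regs)) cat("  regions:", length(regs), "\n")
})

#' Read a corpus from CSV or JSONL
#'
#' Reads one document per record. Required fields are \code{doc_id} and
#' \code{text}; \code{date} (ISO-8601), \code{region},
#' \code{polarity_label} (0/1) and \code{emotion_label} are optional.
#' Records are kept in file order.
#'
#' @param path path to the input file.
#' @param format \code{"csv"} (comma-separated, UTF-8, header required) or
#'   \code{"jsonl"} (one JSON object per line).
#' @return A [Corpus-class] with empty token lists.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("doc_id,text", "u1,masks sold out"), f)
#' readCorpus(f)
#' @export
readCorpus <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      df <- data.frame(doc_id = character(), text = character())
    } else {
      recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
      keys <- unique(unlist(lapply(recs, names)))
      df <- as.data.frame(
        lapply(setNames(keys, keys), function(k)
          vapply(recs, function(r)
            if (is.null(r[[k]]) || length(r[[k]]) == 0) NA_character_
            else as.character(r[[k]]), character(1))),
        stringsAsFactors = FALSE)
    }
  }
  missing_cols <- setdiff(c("doc_id", "text"), names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$doc_id))
    stop("duplicate doc_id values: ",
         paste(unique(df$doc_id[duplicated(df$doc_id)]), collapse = ", "))
  get <- function(col, default) {
    if (col %in% names(df)) {
      v <- df[[col]]
      v[!is.na(v) & !nzchar(v)] <- NA
      v
    } else rep(default, nrow(df))
  }
  Corpus(doc_id = df$doc_id, text = df$text,
         date = get("date", NA_character_),
         region = get("region", NA_character_),
         polarity_label = get("polarity_label", NA_integer_),
         emotion_label = get("emotion_label", NA_character_),
         metadata = list(source = path))
}

#' Write a corpus to CSV or JSONL
#'
#' Inverse of [readCorpus()]: all six document fields are written so that
#' reading the file back reproduces them exactly. Token lists are not
#' serialized.
#'
#' @param corpus a [Corpus-class].
#' @param path output file path.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @return \code{path}, invisibly.
#' @export
writeCorpus <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- corpus@docs
  df$date <- ifelse(is.na(df$date), NA_character_, format(df$date))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- rec[!vapply(rec, is.na, logical(1))]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Partition a corpus into per-day document sets
#'
#' Splits the corpus by calendar date. The day sets cover the corpus
#' exactly once and are returned in ascending date order.
#'
#' @param corpus a [Corpus-class]; every document must have a date.
#' @return Named list of [Corpus-class] objects keyed by ISO date.
#' @examples
#' corp <- Corpus(c("a", "b"), c("x", "y"),
#'                date = c("2020-07-31", "2020-08-02"))
#' names(partitionByDay(corp))
#' @export
partitionByDay <- function(corpus) {
  dates <- docDates(corpus)
  if (anyNA(dates))
    stop("documents without a date: ",
         paste(docIds(corpus)[is.na(dates)], collapse = ", "))
  if (!nDocs(corpus)) return(setNames(list(), character()))
  keys <- sort(unique(dates))
  out <- lapply(keys, function(d) corpus[dates == d])
  setNames(out, format(keys))
}
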