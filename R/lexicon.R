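#' Construct a sentiment lexicon from an entries table
#'
#' @param entries data.frame with columns \code{word}, \code{pos},
#'   \code{sense_count}, \code{subcategory}, \code{intensity},
#'   \code{polarity}, \code{auxiliary}.
#' @param taxonomy an [EmotionTaxonomy-class]; defaults to the built-in
#'   7-category / 21-subcategory taxonomy.
#' @return A [SentimentLexicon-class].
#' @export
SentimentLexicon <- function(entries, taxonomy = defaultTaxonomy()) {
  entries$word <- as.character(entries$word)
  entries$pos <- as.character(entries$pos)
  entries$sense_count <- as.integer(entries$sense_count)
  entries$subcategory <- as.character(entries$subcategory)
  entries$intensity <- as.integer(entries$intensity)
  entries$polarity <- as.integer(entries$polarity)
  entries$auxiliary <- as.character(entries$auxiliary)
  new("SentimentLexicon", entries = entries, taxonomy = taxonomy)
}

#' Load a sentiment lexicon from a delimited file
#'
#' Reads a tab- or comma-separated table with columns \code{word},
#' \code{pos}, \code{sense_count}, \code{subcategory}, \code{intensity},
#' \code{polarity}, \code{auxiliary} (header required; the delimiter is
#' detected from the header line). Validation rules:
#' \itemize{
#'   \item intensity must be an integer in 1--9; the canonical grid has the
#'     5 odd levels 1, 3, 5, 7, 9 and off-grid values trigger a warning but
#'     are accepted (published lexicon samples contain 4 and 6);
#'   \item polarity may be signed (\eqn{-1}/\eqn{+1}) or coded 0/1
#'     (0 = negative); the 0 coding is mapped to \eqn{-1} at parse time, and
#'     the signed form is stored;
#'   \item the subcategory code must exist in the taxonomy.
#' }
#' Rows violating a rule are reported by row number in a single error.
#'
#' @param path path to the lexicon file.
#' @param taxonomy an [EmotionTaxonomy-class].
#' @return A [SentimentLexicon-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("word\tpos\tsense_count\tsubcategory\tintensity\tpolarity\tauxiliary",
#'              "fearful\tAdjective\t1\tNI\t5\t-1\tNG"), f)
#' lex <- loadLexicon(f)
#' @export
loadLexicon <- function(path, taxonomy = defaultTaxonomy()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("word", "pos", "sense_count", "subcategory", "intensity",
            "polarity", "auxiliary")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("lexicon file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(df))
    return(SentimentLexicon(.emptyLexiconEntries(), taxonomy))

  intensity <- suppressWarnings(as.integer(df$intensity))
  polarity <- suppressWarnings(as.integer(df$polarity))
  polarity[!is.na(polarity) & polarity == 0L] <- -1L  # 0/1 coding -> signed
  sense <- suppressWarnings(as.integer(df$sense_count))

  bad <- is.na(intensity) | intensity < 1L | intensity > 9L |
    is.na(polarity) | !(polarity %in% c(-1L, 1L)) |
    is.na(sense) | sense < 1L |
    !(df$subcategory %in% names(taxonomy@subcategoryMap))
  if (any(bad))
    stop("invalid lexicon row(s): ", paste(which(bad), collapse = ", "))
  off_grid <- !(intensity %in% c(1L, 3L, 5L, 7L, 9L))
  if (any(off_grid))
    warning("intensity off the canonical {1,3,5,7,9} grid in row(s): ",
            paste(which(off_grid), collapse = ", "))

  aux <- df$auxiliary
  aux[is.na(aux) | !nzchar(aux) | aux %in% c("NaN", "NA")] <- NA_character_
  SentimentLexicon(
    data.frame(word = df$word, pos = df$pos, sense_count = sense,
               subcategory = df$subcategory, intensity = intensity,
               polarity = polarity, auxiliary = aux,
               stringsAsFactors = FALSE),
    taxonomy
  )
}

.emptyLexiconEntries <- function() {
  data.frame(word = character(), pos = character(),
             sense_count = integer(), subcategory = character(),
             intensity = integer(), polarity = integer(),
             auxiliary = character(), stringsAsFactors = FALSE)
}

#' Write a sentiment lexicon to a TSV file
#'
#' @param lexicon a [SentimentLexicon-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLexicon <- function(lexicon, path) {
  utils::write.table(lexicon@entries, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up a word in the lexicon
#'
#' Returns all entries (senses) for a word. Absence is signalled by a
#' zero-row result, never by a default entry.
#'
#' @param lexicon a [SentimentLexicon-class].
#' @param word a single word.
#' @return data.frame of matching entries (possibly zero rows).
#' @export
lexiconLookup <- function(lexicon, word) {
  lexicon@entries[lexicon@entries$word == word, , drop = FALSE]
}

#' @describeIn SentimentLexicon number of entries.
#' @param x,object a [SentimentLexicon-class].
#' @export
nEntries <- function(x) nrow(x@entries)

setMethod("show", "SentimentLexicon", function(object) {
  cat("SentimentLexicon with", nrow(object@entries), "entries over",
      length(unique(object@entries$word)), "words\n")
  tab <- table(mainCategoryOf(object@entries$subcategory, object@taxonomy))
  if (length(tab))
    cat("  per category:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})
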