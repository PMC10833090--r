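.NEGATIVE_CATEGORIES <- c("anger", "disgust", "fear", "sadness")
.POSITIVE_CATEGORIES <- c("surprise", "good", "happy")
# Fixed dominance/tie-break order used wherever a single category must win.
.CATEGORY_ORDER <- c("anger", "disgust", "fear", "sadness",
                     "surprise", "good", "happy")

#' Default seven-category / twenty-one-subcategory emotion taxonomy
#'
#' Builds the package's built-in emotion taxonomy, patterned on the Dalian
#' University of Technology emotion lexicon: 7 main categories and 21
#' subcategory codes. The anger subcategory uses the code \code{NAU}
#' (avoiding the string \code{"NA"}, which collides with the missing-value
#' literal in delimited files); the remaining codes are the standard Dalian
#' codes.
#'
#' Main categories and their subcategory codes:
#' \itemize{
#'   \item happy: PA (joy), PE (relief)
#'   \item good: PD (respect), PH (praise), PG (belief), PB (fondness),
#'     PK (wish)
#'   \item anger: NAU (anger)
#'   \item sadness: NB (sadness), NJ (disappointment), NH (guilt),
#'     PF (yearning)
#'   \item fear: NI (panic), NC (fear), NG (shame)
#'   \item disgust: ND (vexation), NE (loathing), NN (censure),
#'     NK (jealousy), NL (suspicion)
#'   \item surprise: PC (surprise)
#' }
#'
#' The polarity map sends anger, disgust, fear and sadness to \eqn{-1} and
#' surprise, good and happy to \eqn{+1}.
#'
#' @return An [EmotionTaxonomy-class] object.
#' @examples
#' tx <- defaultTaxonomy()
#' length(tx@mainCategories)   # 7
#' length(tx@subcategoryMap)   # 21
#' @export
defaultTaxonomy <- function() {
  sub <- c(
    PA = "happy", PE = "happy",
    PD = "good", PH = "good", PG = "good", PB = "good", PK = "good",
    NAU = "anger",
    NB = "sadness", NJ = "sadness", NH = "sadness", PF = "sadness",
    NI = "fear", NC = "fear", NG = "fear",
    ND = "disgust", NE = "disgust", NN = "disgust", NK = "disgust",
    NL = "disgust",
    PC = "surprise"
  )
  pol <- setNames(
    ifelse(.CATEGORY_ORDER %in% .NEGATIVE_CATEGORIES, -1L, 1L),
    .CATEGORY_ORDER
  )
  new("EmotionTaxonomy",
      mainCategories = .CATEGORY_ORDER,
      subcategoryMap = sub,
      polarityMap = pol)
}

#' Main emotion category of a subcategory code
#'
#' @param subcategory character vector of subcategory codes (e.g.
#'   \code{"NI"}, \code{"PH"}).
#' @param taxonomy an [EmotionTaxonomy-class]; defaults to
#'   [defaultTaxonomy()].
#' @return Character vector of main category names.
#' @examples
#' mainCategoryOf("NI")  # "fear"
#' mainCategoryOf("PH")  # "good"
#' @export
mainCategoryOf <- function(subcategory, taxonomy = defaultTaxonomy()) {
  unknown <- setdiff(subcategory, names(taxonomy@subcategoryMap))
  if (length(unknown))
    stop("unknown subcategory code(s): ", paste(unknown, collapse = ", "))
  unname(taxonomy@subcategoryMap[subcategory])
}

#' Polarity sign of a main emotion category
#'
#' @param category character vector of main category names.
#' @param taxonomy an [EmotionTaxonomy-class].
#' @return Integer vector of \code{-1}/\code{+1}.
#' @export
categoryPolarity <- function(category, taxonomy = defaultTaxonomy()) {
  unknown <- setdiff(category, names(taxonomy@polarityMap))
  if (length(unknown))
    stop("unknown main category: ", paste(unknown, collapse = ", "))
  unname(taxonomy@polarityMap[category])
}

setMethod("show", "EmotionTaxonomy", function(object) {
  cat("EmotionTaxonomy:", length(object@mainCategories),
      "main categories,", length(object@subcategoryMap),
      "subcategories\n")
  for (mc in object@mainCategories) {
    codes <- names(object@subcategoryMap)[object@subcategoryMap == mc]
    cat(sprintf("  %-8s (%+d): %s\n", mc, object@polarityMap[[mc]],
                paste(codes, collapse = " ")))
  }
})
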