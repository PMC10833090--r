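#' Rescale a positive-class probability to a signed score
#'
#' Maps \eqn{\hat{s} \in [0, 1]} onto \eqn{[-1, 1]} by the affine map
#' \eqn{2\hat{s} - 1}, the unique affine bijection of the unit interval
#' onto \eqn{[-1, 1]}: scores below 0.5 become negative, 0.5 maps to 0.
#' (A plain shift \eqn{\hat{s} - 1} could never produce positive values,
#' so the affine rescaling is used for the "lowered" score.)
#'
#' @param shat numeric vector of probabilities in \eqn{[0, 1]}.
#' @return Signed scores in \eqn{[-1, 1]}.
#' @examples
#' shiftScore(c(0, 0.5, 1))  # -1 0 1
#' @export
shiftScore <- function(shat) {
  if (any(is.na(shat)) || any(shat < 0 | shat > 1))
    stop("shat must lie in [0, 1]")
  2 * shat - 1
}

#' Daily aggregated sentiment score
#'
#' For the day's documents \eqn{d_1, \ldots, d_m} with classifier
#' probabilities \eqn{\hat{s}_i}, the daily score is the mean of the
#' shifted scores, \eqn{S_D = \frac{1}{m} \sum_i (2 \hat{s}_i - 1)},
#' bounded in \eqn{[-1, 1]} and invariant to document order.
#'
#' @param shat numeric vector of per-document probabilities for one day
#'   (non-empty).
#' @return List with \code{m} (document count) and \code{S_D}.
#' @export
dailyScore <- function(shat) {
  if (!length(shat)) stop("a day must contain at least one document")
  list(m = length(shat), S_D = mean(shiftScore(shat)))
}

#' Daily sentiment series for a corpus
#'
#' Partitions the corpus by day and applies a scorer (a function returning
#' \eqn{\hat{s}} per document) to each day's documents.
#'
#' @param corpus dated [Corpus-class].
#' @param scorer function(Corpus) -> numeric vector of probabilities.
#' @return data.frame with columns \code{date}, \code{m}, \code{S_D}.
#' @export
dailyScores <- function(corpus, scorer) {
  days <- partitionByDay(corpus)
  out <- do.call(rbind, lapply(names(days), function(d) {
    sc <- dailyScore(scorer(days[[d]]))
    data.frame(date = as.Date(d), m = sc$m, S_D = sc$S_D)
  }))
  if (is.null(out))
    out <- data.frame(date = as.Date(character()), m = integer(),
                      S_D = numeric())
  out
}

#' Monthly aggregation of daily sentiment
#'
#' Document-weighted mean of the daily scores per calendar month, in
#' chronological order.
#'
#' @param daily data.frame from [dailyScores()] (columns \code{date},
#'   \code{m}, \code{S_D}).
#' @return data.frame with columns \code{month} ("YYYY-MM"), \code{n}
#'   (documents) and \code{score}.
#' @export
monthlyAggregate <- function(daily) {
  if (!nrow(daily))
    return(data.frame(month = character(), n = integer(),
                      score = numeric()))
  month <- format(daily$date, "%Y-%m")
  agg <- lapply(split(seq_len(nrow(daily)), month), function(idx) {
    data.frame(n = sum(daily$m[idx]),
               score = sum(daily$m[idx] * daily$S_D[idx]) /
                 sum(daily$m[idx]))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(month = names(agg), n = out$n, score = out$score,
                    stringsAsFactors = FALSE)
  out[order(out$month), , drop = FALSE]
}

#' Stage partition of the study window
#'
#' An ordered list of named, inclusive, non-overlapping date ranges. The
#' default partition is the three pandemic phases used for spatiotemporal
#' aggregation: stage 1 July--October 2020, stage 2 November
#' 2020--February 2021, stage 3 March--June 2021.
#'
#' @param stages character vector of stage names.
#' @param starts,ends inclusive range bounds (\code{Date} or ISO strings).
#' @return data.frame of class \code{"StagePartition"} with columns
#'   \code{stage}, \code{start}, \code{end}.
#' @export
stagePartition <- function(stages, starts, ends) {
  starts <- as.Date(starts); ends <- as.Date(ends)
  stopifnot(length(stages) == length(starts),
            length(starts) == length(ends))
  if (any(ends < starts)) stop("stage end before start")
  ord <- order(starts)
  stages <- stages[ord]; starts <- starts[ord]; ends <- ends[ord]
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("stage ranges must not overlap")
  structure(data.frame(stage = stages, start = starts, end = ends,
                       stringsAsFactors = FALSE),
            class = c("StagePartition", "data.frame"))
}

#' @rdname stagePartition
#' @export
defaultStagePartition <- function() {
  stagePartition(c("stage1", "stage2", "stage3"),
                 c("2020-07-01", "2020-11-01", "2021-03-01"),
                 c("2020-10-31", "2021-02-28", "2021-06-30"))
}

#' Assign dates to stages
#'
#' @param date \code{Date} vector (or ISO strings).
#' @param partition a [stagePartition()].
#' @return Character vector of stage names; dates outside every range
#'   raise an error.
#' @examples
#' assignStage("2020-08-15")  # "stage1"
#' @export
assignStage <- function(date, partition = defaultStagePartition()) {
  date <- as.Date(date)
  out <- rep(NA_character_, length(date))
  for (i in seq_len(nrow(partition))) {
    hit <- !is.na(date) & date >= partition$start[i] &
      date <= partition$end[i]
    out[hit] <- partition$stage[i]
  }
  if (anyNA(out))
    stop("date(s) outside the study window: ",
         paste(format(date[is.na(out)]), collapse = ", "))
  out
}

#' Per-region, per-stage negative-emotion summary
#'
#' For every (region, stage) cell: the document count and the proportion
#' of documents whose dominant lexicon emotion is negative (anger,
#' disgust, fear or sadness). Cells with no documents are reported with
#' count 0 and a missing proportion.
#'
#' @param corpus tokenized [Corpus-class]; every document needs a region
#'   and a date.
#' @param lexicon a [SentimentLexicon-class].
#' @param partition a [stagePartition()].
#' @return data.frame with columns \code{region}, \code{stage}, \code{n},
#'   \code{neg_proportion}.
#' @export
regionStageSummary <- function(corpus, lexicon,
                               partition = defaultStagePartition()) {
  if (anyNA(docRegions(corpus)) || anyNA(docDates(corpus)))
    stop("every document needs a region and a date")
  stage <- assignStage(docDates(corpus), partition)
  profiles <- emotionProfiles(corpus, lexicon)
  regions <- sort(unique(docRegions(corpus)), method = "radix")
  grid <- expand.grid(region = regions, stage = partition$stage,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$neg_proportion <- NA_real_
  for (r in seq_len(nrow(grid))) {
    sel <- docRegions(corpus) == grid$region[r] & stage == grid$stage[r]
    grid$n[r] <- sum(sel)
    if (any(sel))
      grid$neg_proportion[r] <-
        negativeEmotionProportion(profiles[sel, , drop = FALSE])
  }
  grid
}

#' Adjacent-stage differences in negative-emotion proportions
#'
#' For each region and each adjacent stage pair, the change
#' \eqn{\Delta = p_{t+1} - p_t}. Pairs where the region is missing (count
#' 0) in either stage yield a missing delta, flagged in \code{complete}.
#'
#' @param summaries data.frame from [regionStageSummary()].
#' @param stage_order stage names in temporal order; defaults to their
#'   order of appearance.
#' @return data.frame with columns \code{region}, \code{from}, \code{to},
#'   \code{delta}, \code{complete}.
#' @export
stageDifference <- function(summaries, stage_order = NULL) {
  if (is.null(stage_order)) stage_order <- unique(summaries$stage)
  out <- list()
  for (region in unique(summaries$region)) {
    for (i in seq_len(length(stage_order) - 1L)) {
      a <- summaries[summaries$region == region &
                       summaries$stage == stage_order[i], ]
      b <- summaries[summaries$region == region &
                       summaries$stage == stage_order[i + 1L], ]
      ok <- nrow(a) == 1L && nrow(b) == 1L &&
        !is.na(a$neg_proportion) && !is.na(b$neg_proportion)
      out[[length(out) + 1L]] <- data.frame(
        region = region, from = stage_order[i], to = stage_order[i + 1L],
        delta = if (ok) b$neg_proportion - a$neg_proportion else NA_real_,
        complete = ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Jenks natural-breaks classification
#'
#' Exact Fisher--Jenks dynamic program: partitions the sorted values into
#' \code{n_classes} contiguous classes minimizing the total within-class
#' sum of squared deviations. Deterministic; class edges are reported as
#' inclusive upper bounds.
#'
#' @param values numeric vector; must contain at least \code{n_classes}
#'   distinct values.
#' @param n_classes number of classes (\eqn{\ge 1}).
#' @return List with \code{breaks} (upper bound of each class),
#'   \code{class} (1-based class index per input value, monotone in the
#'   value), \code{n_classes} and \code{ssd} (optimal within-class sum of
#'   squared deviations).
#' @examples
#' jenksBreaks(c(1, 2, 9, 10), 2)$class  # 1 1 2 2
#' @export
jenksBreaks <- function(values, n_classes) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  vals <- values[!is.na(values)]
  if (length(unique(vals)) < n_classes)
    stop("need at least n_classes distinct values")
  x <- sort(vals)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssdRange <- function(i, j) {   # within-class SSD of x[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  cost <- matrix(Inf, n_classes, n)
  back <- matrix(0L, n_classes, n)
  for (j in seq_len(n)) cost[1L, j] <- ssdRange(1L, j)
  if (n_classes > 1L) {
    for (k in 2L:n_classes) {
      for (j in k:n) {
        for (i in k:j) {   # class k covers x[i..j]
          c_ <- cost[k - 1L, i - 1L] + ssdRange(i, j)
          if (c_ < cost[k, j] - 1e-12) {
            cost[k, j] <- c_
            back[k, j] <- i
          }
        }
      }
    }
  }
  # recover class boundaries
  upper <- numeric(n_classes)
  j <- n
  for (k in n_classes:1L) {
    upper[k] <- x[j]
    i <- if (k > 1L) back[k, j] else 1L
    j <- i - 1L
  }
  cls <- findInterval(values, upper[-n_classes] + 0,
                      left.open = TRUE) + 1L
  cls[is.na(values)] <- NA_integer_
  list(breaks = upper, class = cls, n_classes = n_classes,
       ssd = cost[n_classes, n])
}

#' Build or read a region adjacency graph
#'
#' Adjacency is an undirected edge list over opaque region labels.
#' \code{makeAdjacency()} builds standard topologies for simulation;
#' \code{readAdjacency()} reads a two-column CSV (\code{region_a},
#' \code{region_b}).
#'
#' @param regions character vector of region labels (\eqn{\ge 2}).
#' @param topology \code{"chain"}, \code{"grid"} (near-square) or
#'   \code{"custom"}.
#' @param pairs for \code{topology = "custom"}: two-column matrix or
#'   data.frame of region pairs.
#' @return data.frame with columns \code{region_a}, \code{region_b}.
#' @export
makeAdjacency <- function(regions, topology = c("chain", "grid", "custom"),
                          pairs = NULL) {
  topology <- match.arg(topology)
  n <- length(regions)
  if (n < 2L) stop("need at least two regions")
  if (topology == "chain") {
    out <- data.frame(region_a = regions[-n], region_b = regions[-1L],
                      stringsAsFactors = FALSE)
  } else if (topology == "grid") {
    ncols <- ceiling(sqrt(n))
    row <- (seq_len(n) - 1L) %/% ncols
    col <- (seq_len(n) - 1L) %% ncols
    a <- character(0); b <- character(0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if ((row[i] == row[j] && abs(col[i] - col[j]) == 1L) ||
          (col[i] == col[j] && abs(row[i] - row[j]) == 1L)) {
        a <- c(a, regions[i]); b <- c(b, regions[j])
      }
    }
    out <- data.frame(region_a = a, region_b = b,
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(pairs)) stop("custom topology requires pairs")
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs) <- c("region_a", "region_b")
    unknown <- setdiff(unique(c(pairs$region_a, pairs$region_b)), regions)
    if (length(unknown))
      stop("pairs reference unknown regions: ",
           paste(unknown, collapse = ", "))
    out <- pairs
  }
  out
}

#' @rdname makeAdjacency
#' @param path CSV file of region pairs.
#' @export
readAdjacency <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!all(c("region_a", "region_b") %in% names(df)))
    stop("adjacency file needs columns region_a, region_b")
  df[c("region_a", "region_b")]
}

#' Spatial similarity of regional proportions
#'
#' Statistic: the mean absolute difference of the regional proportions
#' across adjacent region pairs (small when neighbours are similar).
#' Significance is assessed against a permutation null in which the
#' proportions are shuffled over the regions; the one-sided p-value is
#' \eqn{(1 + \#\{\text{perm} \le \text{obs}\}) / (P + 1)}.
#'
#' @param proportions named numeric vector (region -> proportion) or a
#'   one-stage subset of [regionStageSummary()] output.
#' @param adjacency data.frame from [makeAdjacency()] covering all
#'   regions present.
#' @param n_perm number of permutations (\eqn{\ge 1}; default 999).
#' @param seed RNG seed.
#' @return List with \code{statistic}, \code{p_value}, \code{n_perm} and
#'   \code{null} (the permuted statistics).
#' @export
spatialSimilarity <- function(proportions, adjacency, n_perm = 999L,
                              seed = 1L) {
  if (is.data.frame(proportions))
    proportions <- setNames(proportions$neg_proportion,
                            proportions$region)
  if (!nrow(adjacency)) stop("adjacency must contain at least one edge")
  regions <- names(proportions)
  missing_regions <- setdiff(unique(c(adjacency$region_a,
                                      adjacency$region_b)), regions)
  if (length(missing_regions))
    stop("no proportion for region(s): ",
         paste(missing_regions, collapse = ", "))
  ia <- match(adjacency$region_a, regions)
  ib <- match(adjacency$region_b, regions)
  stat <- function(p) mean(abs(p[ia] - p[ib]))
  observed <- stat(proportions)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    stat(sample(proportions)), numeric(1))
  list(statistic = observed,
       p_value = (1 + sum(null <= observed)) / (n_perm + 1),
       n_perm = as.integer(n_perm), null = null)
}

#' Write the tidy region-stage summary CSV
#'
#' Combines the per-cell summary with natural-breaks class indices and
#' previous-stage deltas into one tidy table (region, stage, n,
#' neg_proportion, class_index, delta_prev_stage).
#'
#' @param summaries data.frame from [regionStageSummary()].
#' @param path output path.
#' @param n_classes natural-breaks class count (default 5).
#' @return The tidy data.frame, invisibly written to \code{path}.
#' @export
writeRegionStageSummary <- function(summaries, path, n_classes = 5L) {
  vals <- summaries$neg_proportion
  ok <- !is.na(vals)
  summaries$class_index <- NA_integer_
  if (sum(ok) && length(unique(vals[ok])) >= n_classes) {
    jb <- jenksBreaks(vals[ok], n_classes)
    summaries$class_index[ok] <- jb$class
  }
  deltas <- stageDifference(summaries)
  key <- paste(deltas$region, deltas$to)
  summaries$delta_prev_stage <-
    deltas$delta[match(paste(summaries$region, summaries$stage), key)]
  utils::write.csv(summaries, path, row.names = FALSE, na = "")
  invisible(summaries)
}
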