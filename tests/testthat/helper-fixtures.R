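# Shared fixtures and independent oracles, all built in code at test time.

# Six-row lexicon fixture transcribing the published sample table
# (word, part of speech, subcategory, intensity, polarity, auxiliary);
# sense_count is 1 throughout.
table4File <- function() {
  path <- tempfile(fileext = ".tsv")
  rows <- c(
    "word\tpos\tsense_count\tsubcategory\tintensity\tpolarity\tauxiliary",
    "Anger\tAdjective\t1\tNAU\t7\t-1\tNaN",
    "Fear\tAdjective\t1\tNI\t5\t-1\tNG",
    "Grief\tVerb\t1\tNB\t7\t-1\tNJ",
    "Surprise\tAdjective\t1\tPC\t6\t1\tNaN",
    "Hope\tNoun\t1\tPD\t4\t1\tPH",
    "Pleasure\tVerb\t1\tPA\t4\t1\tPE")
  writeLines(rows, path)
  path
}

loadTable4 <- function() {
  suppressWarnings(loadLexicon(table4File()))
}

# Small tokenized corpus straight from token lists.
tokenCorpus <- function(tokenLists, ...) {
  n <- length(tokenLists)
  Corpus(doc_id = sprintf("t%03d", seq_len(n)),
         text = vapply(tokenLists, paste, character(1), collapse = " "),
         tokens = tokenLists, ...)
}

# Dense brute-force TF-IDF oracle: direct double loop over documents and
# vocabulary, with clamped natural-log IDF.
denseTfidfOracle <- function(tokenLists, vocabulary) {
  D <- length(tokenLists)
  out <- matrix(0, D, length(vocabulary))
  for (j in seq_along(vocabulary)) {
    w <- vocabulary[j]
    df <- sum(vapply(tokenLists, function(tk) w %in% tk, logical(1)))
    idf <- max(log(D / (1 + df)), 0)
    for (i in seq_len(D)) {
      tk <- tokenLists[[i]]
      out[i, j] <- sum(tk == w) / length(tk) * idf
    }
  }
  out
}

# Counting oracle for classification metrics.
metricsOracle <- function(truth, predicted, labels) {
  per <- lapply(labels, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1,
      support = sum(truth == cl))
  })
  m <- do.call(rbind, per)
  list(metrics = m, accuracy = mean(truth == predicted))
}

# Exhaustive Jenks oracle: enumerate every split of the sorted values into
# n_classes contiguous groups and return the minimal within-class SSD.
jenksOracle <- function(values, n_classes) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (n_classes == 1L) return(ssd(x))
  best <- Inf
  cuts <- utils::combn(n - 1L, n_classes - 1L)
  for (ci in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, ci], n)
    total <- 0
    for (g in seq_len(n_classes))
      total <- total + ssd(x[(bounds[g] + 1L):bounds[g + 1L]])
    best <- min(best, total)
  }
  best
}

# Direct likelihood-maximization oracle for ridge logistic regression:
# dense Newton iterations on the augmented design.
newtonLogisticOracle <- function(X, y, l2 = 1e-4, iters = 100L) {
  X <- cbind(as.matrix(X), 1)
  m <- ncol(X)
  beta <- rep(0, m)
  pen <- diag(c(rep(l2, m - 1L), 0))
  for (i in seq_len(iters)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- as.numeric(t(X) %*% (p - y)) + pen %*% beta
    H <- t(X) %*% (X * (p * (1 - p))) + pen
    step <- solve(H, g)
    beta <- as.numeric(beta - step)
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# Greedy matching of estimated topics to true topics by maximal phi inner
# product; returns the estimated index matched to each true topic.
matchTopics <- function(trueMat, estMat) {
  apply(trueMat %*% t(estMat), 1L, which.max)
}
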