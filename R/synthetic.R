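#' Synthetic sentiment lexicon
#'
#' Generates a valid lexicon covering all 21 subcategories with synthetic
#' word identifiers (\code{emo_<code>_<i>}), intensities drawn from the
#' canonical grid \{1, 3, 5, 7, 9\} and polarities taken from the
#' taxonomy's polarity map. Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param words_per_subcategory number of words per subcategory code.
#' @param taxonomy an [EmotionTaxonomy-class].
#' @return A [SentimentLexicon-class].
#' @export
makeLexicon <- function(seed = 1L, words_per_subcategory = 5L,
                        taxonomy = defaultTaxonomy()) {
  if (words_per_subcategory < 1L)
    stop("words_per_subcategory must be >= 1")
  set.seed(seed)
  codes <- names(taxonomy@subcategoryMap)
  rows <- lapply(codes, function(code) {
    main <- taxonomy@subcategoryMap[[code]]
    data.frame(
      word = sprintf("emo_%s_%d", tolower(code),
                     seq_len(words_per_subcategory)),
      pos = sample(c("Adjective", "Noun", "Verb"),
                   words_per_subcategory, replace = TRUE),
      sense_count = 1L,
      subcategory = code,
      intensity = sample(c(1L, 3L, 5L, 7L, 9L),
                         words_per_subcategory, replace = TRUE),
      polarity = taxonomy@polarityMap[[main]],
      auxiliary = NA_character_,
      stringsAsFactors = FALSE)
  })
  SentimentLexicon(do.call(rbind, rows), taxonomy)
}

#' Configuration for the synthetic microblog-corpus generator
#'
#' The defaults emulate the study conditions the pipeline targets: 2000
#' screened short comments (5--30 tokens) spanning three pandemic stages
#' (July 2020--June 2021) over provincial regions, 12 latent topics, an
#' emotion-word injection rate of 0.3 per token, and per-stage negativity
#' (0.8, 0.5, 0.2) encoding the negative-to-positive trend, modulated by a
#' spatially smooth regional effect.
#'
#' @param seed RNG seed; everything the generator emits is reproducible
#'   from it.
#' @param n_documents number of documents.
#' @param doc_length_range integer (min, max) tokens per document; min
#'   \eqn{\ge 2} so every document can contribute biterms.
#' @param K_true number of latent topics.
#' @param vocab_size size of the (non-emotion) topic vocabulary.
#' @param topic_concentration Dirichlet concentration of each topic's
#'   distribution over its own vocabulary block (small = peaked).
#' @param topic_separation probability mass a topic keeps on its own
#'   vocabulary block (1 = disjoint topic vocabularies).
#' @param emotion_word_rate per-stage probability that a token is replaced
#'   by an emotion word (scalar recycled to 3 stages).
#' @param stage_negativity per-stage probability that an injected emotion
#'   word is negative-category.
#' @param regions character vector of region labels.
#' @param region_topology adjacency topology for [makeAdjacency()].
#' @param region_effect_sd standard deviation of the pre-smoothing
#'   regional noise added to the stage negativity.
#' @param stage_partition a [stagePartition()] giving the per-stage date
#'   ranges.
#' @param words_per_subcategory lexicon size knob for [makeLexicon()].
#' @param mixture if \code{TRUE}, documents draw each token's topic
#'   independently from a document-specific mixture (LDA-style); default
#'   \code{FALSE} (single-topic documents, the short-text assumption).
#' @return Validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(seed = 1L,
                            n_documents = 2000L,
                            doc_length_range = c(5L, 30L),
                            K_true = 12L,
                            vocab_size = 600L,
                            topic_concentration = 0.1,
                            topic_separation = 0.9,
                            emotion_word_rate = 0.3,
                            stage_negativity = c(0.8, 0.5, 0.2),
                            regions = paste0("province_",
                                             sprintf("%02d", 1:10)),
                            region_topology = "chain",
                            region_effect_sd = 0.1,
                            stage_partition = defaultStagePartition(),
                            words_per_subcategory = 5L,
                            mixture = FALSE) {
  n_stages <- nrow(stage_partition)
  emotion_word_rate <- rep_len(emotion_word_rate, n_stages)
  stage_negativity <- rep_len(stage_negativity, n_stages)
  if (any(emotion_word_rate < 0 | emotion_word_rate > 1) ||
      any(stage_negativity < 0 | stage_negativity > 1))
    stop("rates must lie in [0, 1]")
  if (doc_length_range[1L] < 2L)
    stop("minimum document length must be >= 2 (biterms must exist)")
  if (K_true < 1L) stop("K_true must be >= 1")
  if (vocab_size < K_true) stop("vocab_size must be >= K_true")
  structure(list(seed = as.integer(seed),
                 n_documents = as.integer(n_documents),
                 doc_length_range = as.integer(doc_length_range),
                 K_true = as.integer(K_true),
                 vocab_size = as.integer(vocab_size),
                 topic_concentration = topic_concentration,
                 topic_separation = topic_separation,
                 emotion_word_rate = emotion_word_rate,
                 stage_negativity = stage_negativity,
                 regions = regions,
                 region_topology = region_topology,
                 region_effect_sd = region_effect_sd,
                 stage_partition = stage_partition,
                 words_per_subcategory = as.integer(words_per_subcategory),
                 mixture = isTRUE(mixture)),
            class = "GeneratorConfig")
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# Regional negativity shifts: independent noise smoothed twice over the
# adjacency graph, planting positive spatial autocorrelation.
.smoothRegionEffect <- function(regions, adjacency, sd) {
  e <- stats::rnorm(length(regions), 0, sd)
  names(e) <- regions
  nb <- lapply(regions, function(r)
    c(adjacency$region_b[adjacency$region_a == r],
      adjacency$region_a[adjacency$region_b == r]))
  names(nb) <- regions
  for (pass in 1:2) {
    e <- vapply(regions, function(r)
      mean(c(e[[r]], e[nb[[r]]])), numeric(1))
  }
  e
}

#' Generate a synthetic microblog corpus with ground truth
#'
#' Every document receives a stage (uniform over stages), a date (uniform
#' within the stage's range), a region (uniform), a latent topic, and
#' tokens drawn from that topic's word distribution; each token is then
#' replaced, with the stage's emotion-word rate, by an emotion word from
#' the synthetic lexicon whose category sign is negative with probability
#' \code{stage_negativity + region_effect} (clamped to \eqn{[0, 1]}). The
#' binary polarity label is 0 when injected negative words outnumber
#' positive ones, else 1; the emotion label is the most-injected main
#' category (missing when nothing was injected). Token strings are
#' synthetic identifiers, so the corpus passes the preprocessing ladder
#' unchanged.
#'
#' @param config a [generatorConfig()].
#' @return List with elements \code{corpus} (a [Corpus-class]),
#'   \code{truth} (topic-word matrix, per-document topics, injected-word
#'   records, per-region/stage negativity rates, labels, region effects)
#'   and \code{lexicon}.
#' @export
makeCorpus <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  n <- config$n_documents
  K <- config$K_true
  V <- config$vocab_size
  part <- config$stage_partition
  n_stages <- nrow(part)
  vocab <- sprintf("w%04d", seq_len(V))
  lexicon <- makeLexicon(config$seed + 1L, config$words_per_subcategory)
  lexWords <- split(lexicon@entries$word,
                    mainCategoryOf(lexicon@entries$subcategory,
                                   lexicon@taxonomy))
  negCats <- .NEGATIVE_CATEGORIES
  posCats <- .POSITIVE_CATEGORIES

  # block-structured topic-word distributions
  blocks <- split(seq_len(V), rep(seq_len(K), length.out = V))
  topicWord <- matrix(0, K, V, dimnames = list(NULL, vocab))
  for (k in seq_len(K)) {
    own <- blocks[[k]]
    inBlock <- .rdirichlet(rep(config$topic_concentration, length(own)))
    topicWord[k, own] <- config$topic_separation * inBlock
    if (V > length(own))
      topicWord[k, -own] <- (1 - config$topic_separation) /
        (V - length(own))
  }

  adjacency <- makeAdjacency(config$regions, config$region_topology)
  regionEffect <- .smoothRegionEffect(config$regions, adjacency,
                                      config$region_effect_sd)
  regionRates <- outer(regionEffect, config$stage_negativity, `+`)
  regionRates <- pmin(pmax(regionRates, 0), 1)
  dimnames(regionRates) <- list(config$regions, part$stage)

  if (!n) {
    return(list(corpus = Corpus(character(), character()),
                truth = list(topic_word = topicWord,
                             doc_topic = integer(),
                             injected = list(),
                             region_rates = regionRates,
                             region_effect = regionEffect,
                             doc_stage = character(),
                             doc_length = integer(),
                             polarity_label = integer()),
                lexicon = lexicon,
                adjacency = adjacency))
  }

  stage_i <- sample.int(n_stages, n, replace = TRUE)
  region <- sample(config$regions, n, replace = TRUE)
  lenr <- config$doc_length_range
  len <- sample(seq(lenr[1L], lenr[2L]), n, replace = TRUE)
  dates <- as.Date(vapply(stage_i, function(s) {
    span <- as.integer(part$end[s] - part$start[s])
    format(part$start[s] + sample.int(span + 1L, 1L) - 1L)
  }, character(1)))
  docTopic <- sample.int(K, n, replace = TRUE)

  tokensList <- vector("list", n)
  injected <- vector("list", n)
  polarity <- integer(n)
  emoLabel <- rep(NA_character_, n)
  for (d in seq_len(n)) {
    if (config$mixture) {
      mix <- .rdirichlet(rep(50 / K, K))
      zs <- sample.int(K, len[d], replace = TRUE, prob = mix)
      tk <- vapply(zs, function(z)
        sample(vocab, 1L, prob = topicWord[z, ]), character(1))
    } else {
      tk <- sample(vocab, len[d], replace = TRUE,
                   prob = topicWord[docTopic[d], ])
    }
    inject <- stats::runif(len[d]) < config$emotion_word_rate[stage_i[d]]
    recs <- NULL
    if (any(inject)) {
      pNeg <- regionRates[region[d], stage_i[d]]
      isNeg <- stats::rbinom(sum(inject), 1L, pNeg) == 1L
      cat_ <- ifelse(isNeg,
                     sample(negCats, sum(inject), replace = TRUE),
                     sample(posCats, sum(inject), replace = TRUE))
      word_ <- vapply(cat_, function(cc)
        sample(lexWords[[cc]], 1L), character(1))
      tk[inject] <- word_
      recs <- data.frame(position = which(inject), word = word_,
                         category = cat_, negative = isNeg,
                         stringsAsFactors = FALSE)
    }
    injected[[d]] <- recs
    nNeg <- if (is.null(recs)) 0L else sum(recs$negative)
    nPos <- if (is.null(recs)) 0L else sum(!recs$negative)
    polarity[d] <- if (nNeg > nPos) 0L else 1L
    if (!is.null(recs)) {
      tab <- table(factor(recs$category, levels = .CATEGORY_ORDER))
      emoLabel[d] <- names(tab)[which.max(tab)]
    }
    tokensList[[d]] <- tk
  }

  corpus <- Corpus(
    doc_id = sprintf("d%05d", seq_len(n)),
    text = vapply(tokensList, paste, character(1), collapse = " "),
    date = dates, region = region,
    polarity_label = polarity, emotion_label = emoLabel,
    tokens = tokensList,
    metadata = list(source = "synthetic", seed = config$seed))

  list(corpus = corpus,
       truth = list(topic_word = topicWord,
                    doc_topic = docTopic,
                    injected = injected,
                    region_rates = regionRates,
                    region_effect = regionEffect,
                    doc_stage = part$stage[stage_i],
                    doc_length = len,
                    polarity_label = polarity),
       lexicon = lexicon,
       adjacency = adjacency)
}

#' Closed-form expected negative-label fraction per stage
#'
#' Conditional-expectation oracle for the generator: given each document's
#' realized stage, region and length, the probability that injected
#' negative words outnumber positive ones is
#' \deqn{P(\mathrm{label} = 0) = \sum_{j} {\rm Bin}(j; \ell, r)\,
#'   P(X > j / 2), \quad X \sim {\rm Bin}(j, p)}
#' with \eqn{r} the stage's injection rate and \eqn{p} the cell's
#' negativity. Averaging over documents gives the expected per-stage
#' fraction the empirical labels should match.
#'
#' @param sim output of [makeCorpus()].
#' @param config the [generatorConfig()] used.
#' @return Named numeric vector: expected negative fraction per stage.
#' @export
expectedStageNegativity <- function(sim, config) {
  part <- config$stage_partition
  stage_i <- match(sim$truth$doc_stage, part$stage)
  region <- docRegions(sim$corpus)
  len <- sim$truth$doc_length
  pNegDoc <- sim$truth$region_rates[
    cbind(match(region, rownames(sim$truth$region_rates)), stage_i)]
  rate <- config$emotion_word_rate[stage_i]
  pLabel0 <- vapply(seq_along(len), function(d) {
    j <- 0:len[d]
    pj <- stats::dbinom(j, len[d], rate[d])
    pmore <- vapply(j, function(jj) {
      if (jj == 0L) return(0)
      k <- seq_len(jj)
      sum(stats::dbinom(k, jj, pNegDoc[d])[k > jj / 2])
    }, numeric(1))
    sum(pj * pmore)
  }, numeric(1))
  tapply(pLabel0, part$stage[stage_i], mean)
}
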