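vocab_ab <- c("a", "b")

btmWith <- function(theta, phi, vocab) {
  new("BtmModel", K = length(theta), theta = theta, phi = phi,
      vocabulary = vocab,
      biterms = matrix(c(1L, 2L), 1), assignments = 1L,
      alpha = 1, beta = 0.01, iterations = 0L, seed = 1L)
}

test_that("biterm extraction enumerates within-document pairs", {
  v <- c("a", "b", "c")
  bt <- extractBiterms(c("a", "b", "c"), v)
  expect_equal(nrow(bt), 3L)
  expect_equal(bt[, 1], pmin(bt[, 1], bt[, 2]))  # normalized order
  expect_equal(nrow(extractBiterms("a", v)), 0L)
  expect_equal(nrow(extractBiterms(character(), v)), 0L)
  # repeated words at distinct positions are kept
  expect_equal(nrow(extractBiterms(c("a", "a"), v)), 1L)
  for (n in c(2, 5, 9)) {
    toks <- sample(v, n, replace = TRUE)
    expect_equal(nrow(extractBiterms(toks, v)), n * (n - 1) / 2)
  }
  # window restricts pair distance
  expect_equal(nrow(extractBiterms(c("a", "b", "c"), v, window = 1)), 2L)
})

test_that("K = 1 closed forms hold exactly for BTM and LDA", {
  corp <- tokenCorpus(list(c("a", "b"), c("a", "a", "b")))
  m <- fitBTM(corp, K = 1, iterations = 10, seed = 2)
  expect_identical(m@theta, 1)
  B <- nrow(m@biterms)
  # biterms: (a,b); (a,a),(a,b),(a,b) -> word slots a: 5, b: 3
  nw <- c(a = 5, b = 3)
  expect_equal(as.numeric(m@phi[1, ]),
               as.numeric((nw + m@beta) / (2 * B + 2 * m@beta)))

  l <- fitLDA(corp, K = 1, seed = 2, iterations = 5)
  expect_equal(as.numeric(l@docTopic), c(1, 1))
  nw2 <- c(a = 3, b = 2)
  expect_equal(as.numeric(l@phi[1, ]),
               as.numeric((nw2 + l@beta) / (5 + 2 * l@beta)))
})

test_that("samplers are bit-reproducible for a fixed seed", {
  set.seed(77)
  toks <- replicate(25, sample(letters[1:8], sample(3:7, 1), TRUE),
                    simplify = FALSE)
  corp <- tokenCorpus(toks)
  m1 <- fitBTM(corp, K = 3, iterations = 30, seed = 42)
  m2 <- fitBTM(corp, K = 3, iterations = 30, seed = 42)
  expect_identical(m1@phi, m2@phi)
  expect_identical(m1@theta, m2@theta)
  expect_identical(m1@assignments, m2@assignments)
  l1 <- fitLDA(corp, K = 3, seed = 42, iterations = 30)
  l2 <- fitLDA(corp, K = 3, seed = 42, iterations = 30)
  expect_identical(l1@phi, l2@phi)
  expect_identical(l1@docTopic, l2@docTopic)
})

test_that("estimated distributions are proper", {
  set.seed(13)
  toks <- replicate(20, sample(letters[1:6], 5, TRUE), simplify = FALSE)
  corp <- tokenCorpus(toks)
  m <- fitBTM(corp, K = 4, iterations = 20, seed = 1)
  expect_lt(abs(sum(m@theta) - 1), 1e-9)
  expect_true(all(abs(rowSums(m@phi) - 1) < 1e-9))
  expect_true(all(m@phi >= 0))
  l <- fitLDA(corp, K = 4, seed = 1, iterations = 20)
  expect_true(all(abs(rowSums(l@phi) - 1) < 1e-9))
  expect_true(all(abs(rowSums(l@docTopic) - 1) < 1e-9))
})

test_that("biterm probabilities are symmetric and sum to one", {
  m <- btmWith(theta = 1, phi = matrix(c(0.3, 0.7), 1), vocab_ab)
  expect_equal(bitermProbability(m, "a", "b"), 1 * 0.3 * 0.7)
  expect_error(bitermProbability(m, "a", "zzz"), "not in model vocabulary")

  set.seed(31)
  toks <- replicate(15, sample(letters[1:5], 4, TRUE), simplify = FALSE)
  fit <- fitBTM(tokenCorpus(toks), K = 2, iterations = 20, seed = 9)
  total <- 0
  for (w1 in fit@vocabulary) for (w2 in fit@vocabulary) {
    p <- bitermProbability(fit, w1, w2)
    expect_equal(p, bitermProbability(fit, w2, w1))
    total <- total + p
  }
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("perplexity matches closed forms", {
  # uniform topic-word distribution: perplexity equals vocabulary size
  V <- 7L
  vocab <- letters[1:V]
  uni <- btmWith(theta = 1, phi = matrix(1 / V, 1, V), vocab)
  held <- tokenCorpus(list(sample(vocab, 9, TRUE), sample(vocab, 4, TRUE)))
  expect_equal(as.numeric(perplexity(uni, held)), V, tolerance = 1e-12)

  # hand-computable 2-word case under document completion:
  # tokens (a b b a): infer on positions 1,3 -> eval on b (pos 2), a (pos 4)
  m <- btmWith(theta = 1, phi = matrix(c(0.3, 0.7), 1), vocab_ab)
  held2 <- tokenCorpus(list(c("a", "b", "b", "a")))
  expect_equal(as.numeric(perplexity(m, held2)),
               exp(-(log(0.7) + log(0.3)) / 2), tolerance = 1e-12)

  # perplexity is at least 1, OOV tokens are reported via coverage
  set.seed(17)
  toks <- replicate(12, sample(letters[1:6], 6, TRUE), simplify = FALSE)
  corp <- tokenCorpus(toks)
  fit <- fitBTM(corp, K = 2, iterations = 20, seed = 4)
  p <- perplexity(fit, corp)
  expect_gte(as.numeric(p), 1)
  expect_lte(attr(p, "coverage"), 1)
  expect_error(perplexity(fit, tokenCorpus(list(c("zz", "qq")))),
               "no in-vocabulary tokens")
})

test_that("selectK handles single candidates and exact ties", {
  set.seed(23)
  toks <- replicate(40, sample(letters[1:6], 6, TRUE), simplify = FALSE)
  corp <- tokenCorpus(toks)
  expect_equal(as.integer(selectK(corp, 3L, iterations = 10)), 3L)

  # degenerate one-word vocabulary: every K fits identically, so the
  # tie rule must return the smallest candidate
  ties <- tokenCorpus(replicate(20, rep("a", 4), simplify = FALSE))
  k <- selectK(ties, c(1L, 2L, 3L), iterations = 5)
  expect_equal(as.integer(k), 1L)
  expect_true(all(abs(attr(k, "perplexities") - 1) < 1e-12))
})

test_that("two disjoint-vocabulary topics are recovered", {
  set.seed(55)
  blockA <- sprintf("a%02d", 1:15)
  blockB <- sprintf("b%02d", 1:15)
  toks <- lapply(1:150, function(i) {
    if (i %% 2) sample(blockA, 8, TRUE) else sample(blockB, 8, TRUE)
  })
  corp <- tokenCorpus(toks)
  fit <- fitBTM(corp, K = 2, iterations = 100, seed = 8)
  truth <- rbind(
    ifelse(fit@vocabulary %in% blockA, 1 / 15, 0),
    ifelse(fit@vocabulary %in% blockB, 1 / 15, 0))
  perm <- matchTopics(truth, fit@phi)
  expect_equal(sort(perm), 1:2)  # one estimated topic per true topic
  l1 <- sapply(1:2, function(k) sum(abs(truth[k, ] - fit@phi[perm[k], ])))
  expect_lt(mean(l1), 0.2)
})

test_that("recovery error shrinks as the corpus grows", {
  l1At <- function(n) {
    cfg <- generatorConfig(seed = 31, n_documents = n, K_true = 2,
                           vocab_size = 100, emotion_word_rate = 0,
                           topic_separation = 1,
                           doc_length_range = c(5, 15))
    sim <- makeCorpus(cfg)
    fit <- fitBTM(sim$corpus, K = 2, iterations = 100, seed = 7)
    truth <- sim$truth$topic_word[, fit@vocabulary, drop = FALSE]
    truth <- truth / rowSums(truth)
    perm <- matchTopics(truth, fit@phi)
    mean(sapply(1:2, function(k)
      sum(abs(truth[k, ] - fit@phi[perm[k], ]))))
  }
  expect_lt(l1At(2000), l1At(200))
})

test_that("embedding clusters map words to high-frequency representatives", {
  vocab <- c("alpha", "beta", "gamma", "delta")
  freqs <- c(alpha = 5, beta = 9, gamma = 2, delta = 7)
  # two well-separated planted blobs in 2-D
  coords <- rbind(alpha = c(0, 0), beta = c(0.2, 0), gamma = c(10, 10),
                  delta = c(10.2, 10))
  prov <- embeddingProvider("planted", 2, function(w) coords[w, ])

  idmap <- clusterVocabulary(vocab, prov, 4, freqs, seed = 1)
  expect_identical(unname(idmap[vocab]), vocab)

  map <- clusterVocabulary(vocab, prov, 2, freqs, seed = 1)
  expect_identical(unname(map["alpha"]), "beta")   # beta outranks alpha
  expect_identical(unname(map["gamma"]), "delta")  # delta outranks gamma
  reps <- attr(map, "representatives")
  expect_identical(unname(map[reps]), reps)        # reps map to themselves
  expect_error(clusterVocabulary(vocab, prov, 9, freqs), "exceeds")
})

test_that("the corpus-derived embedding provider is deterministic", {
  set.seed(71)
  toks <- replicate(25, sample(letters[1:8], 6, TRUE), simplify = FALSE)
  corp <- tokenCorpus(toks)
  p1 <- ppmiEmbedding(corp, dimension = 4)
  p2 <- ppmiEmbedding(corp, dimension = 4)
  for (w in p1$vocabulary)
    expect_identical(p1$embed(w), p2$embed(w))
  expect_error(p1$embed("zzz"), "not covered")
})

test_that("reduceCorpus substitutes representatives and shrinks vocabulary", {
  corp <- tokenCorpus(list(c("a", "b", "r"), c("b", "r")))
  idmap <- setNames(c("a", "b", "r"), c("a", "b", "r"))
  expect_identical(reduceCorpus(corp, idmap)@tokens, corp@tokens)

  map <- setNames(c("r", "r", "r"), c("a", "b", "r"))
  red <- reduceCorpus(corp, map)
  expect_identical(red@tokens, list(c("r", "r", "r"), c("r", "r")))
  expect_equal(sum(lengths(red@tokens)), sum(lengths(corp@tokens)))
  expect_identical(unique(unlist(red@tokens)), "r")
  expect_error(reduceCorpus(corp, map[1:2]), "not covered")
})

test_that("chi-square topic weights highlight stage-specific topics", {
  expect_equal(unname(topicWeightsChisq(rep(1L, 10),
                                        rep(c("m1", "m2"), 5), K = 1L)),
               1.0)
  # perfectly uniform table: uniform weights
  dom <- rep(1:2, times = 6)
  months <- rep(c("m1", "m2", "m3"), each = 4)
  expect_equal(unname(topicWeightsChisq(dom, months, K = 2L)),
               c(0.5, 0.5))
  # a topic concentrated in one month gets the largest weight
  dom2 <- c(rep(1L, 6), rep(2L, 6), rep(3L, 6))
  months2 <- c(rep("m1", 6), rep(c("m1", "m2", "m3"), 2),
               rep(c("m1", "m2", "m3"), 2))
  w <- topicWeightsChisq(dom2, months2, K = 3L)
  expect_equal(unname(which.max(w)), 1L)
  expect_equal(sum(w), 1)
  # the unnormalized contributions sum to the chi-square statistic
  tab <- table(dom2, months2)
  chi <- suppressWarnings(stats::chisq.test(tab)$statistic)
  expect_equal(unname(w), unname(rowSums(
    (tab - outer(rowSums(tab), colSums(tab)) / sum(tab))^2 /
      (outer(rowSums(tab), colSums(tab)) / sum(tab)))) / unname(chi),
    tolerance = 1e-12)
  expect_error(topicWeightsChisq(c(1L, 1L), c("m1", "m2"), K = 2L),
               "empty expected cells")
})
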