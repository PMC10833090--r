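test_that("cleanText strips tags and foreign characters and is idempotent", {
  expect_equal(cleanText("<b>risk</b>!"), "risk!")
  expect_equal(cleanText(""), "")
  plain <- "masks are doubling the price! Really no conscience!"
  expect_equal(cleanText(plain), plain)
  expect_equal(cleanText("see https://example.org/x now"), "see now")
  # tag removal runs to a fixed point, so nested tag fragments cannot
  # reassemble into surviving markup
  expect_equal(cleanText("<i>plain</i> tag"), "plain tag")

  set.seed(7)
  pieces <- c("word", "<i>", "</i>", "!", "©", "#", "http://a.b/c",
              "  ", "don't", "50%", "疫情")
  for (i in 1:25) {
    s <- paste(sample(pieces, 8, replace = TRUE), collapse = " ")
    once <- cleanText(s)
    expect_identical(cleanText(once), once)
  }
})

test_that("deduplication keeps first occurrences only", {
  corp <- Corpus(c("a", "b", "c"), c("same", "same", "other"))
  expect_identical(docIds(deduplicateCorpus(corp)), c("a", "c"))

  distinct <- Corpus(c("a", "b"), c("x", "y"))
  expect_identical(deduplicateCorpus(distinct)@docs, distinct@docs)

  many <- Corpus(paste0("d", 1:100), rep("copy", 100))
  expect_equal(nDocs(deduplicateCorpus(many)), 1L)
})

test_that("tokenization splits on whitespace and honors the user dictionary", {
  corp <- Corpus("a", "pandemic spread fast")
  expect_identical(tokenizeCorpus(corp)@tokens[[1]],
                   c("pandemic", "spread", "fast"))

  nat <- Corpus("a", "daily nucleic acid testing required")
  tk <- tokenizeCorpus(nat, user_dictionary = "nucleic acid testing")
  expect_true("nucleic_acid_testing" %in% tk@tokens[[1]])
  expect_length(tk@tokens[[1]], 3L)

  expect_identical(tokenizeCorpus(Corpus("a", ""))@tokens[[1]],
                   character(0))
  expect_error(tokenizeCorpus(corp, "no-such-tokenizer"),
               "no tokenizer registered")
})

test_that("stop-word and low-frequency filters behave like their oracles", {
  corp <- tokenCorpus(list(c("the", "virus", "is", "dangerous")))
  expect_identical(removeStopwords(corp, c("the", "is"))@tokens[[1]],
                   c("virus", "dangerous"))
  expect_identical(removeStopwords(corp, character())@tokens, corp@tokens)

  fl <- tokenCorpus(list(c("x", "y"), c("y", "z")))
  expect_identical(filterLowFrequency(fl, 1L)@tokens, fl@tokens)
  expect_identical(filterLowFrequency(fl, 2L)@tokens,
                   list("y", "y"))
  expect_error(filterLowFrequency(fl, -1L), "non-negative")

  set.seed(11)
  toks <- replicate(30, sample(letters[1:8], sample(2:9, 1), TRUE),
                    simplify = FALSE)
  rc <- tokenCorpus(toks)
  for (mc in c(2L, 3L, 5L)) {
    freq <- table(unlist(toks))
    keep <- names(freq)[freq >= mc]
    oracle <- lapply(toks, function(tk) tk[tk %in% keep])
    expect_identical(filterLowFrequency(rc, mc)@tokens, oracle)
  }
})

test_that("depth-1 imputation fills from the best single split", {
  # constant region among complete records
  corp <- Corpus(paste0("d", 1:4), rep("t", 4),
                 region = c("R", "R", "R", NA))
  out <- imputeMissing(corp)
  expect_identical(docRegions(out), rep("R", 4))
  expect_identical(out@docs$imputed, c(FALSE, FALSE, FALSE, TRUE))

  # no missing values: identity, no flags
  full <- Corpus(c("a", "b"), c("x", "y"), region = c("R1", "R2"))
  out2 <- imputeMissing(full)
  expect_identical(docRegions(out2), c("R1", "R2"))
  expect_false(any(out2@docs$imputed))

  expect_error(imputeMissing(Corpus("a", "x")), "no observed values")

  # region determined by a date threshold: the rule recovers >= 90%
  set.seed(3)
  n <- 200
  dates <- as.Date("2020-07-01") + sample(0:299, n, TRUE)
  region <- ifelse(dates <= as.Date("2020-11-15"), "north", "south")
  mask <- sample(n, 60)
  obs <- region
  obs[mask] <- NA
  corp3 <- Corpus(paste0("d", 1:n), rep("t", n), date = dates,
                  region = obs)
  got <- docRegions(imputeMissing(corp3))
  expect_gte(mean(got[mask] == region[mask]), 0.9)
})

test_that("the full ladder is idempotent and never grows the corpus", {
  stopfile <- tempfile()
  writeLines(c("# common words", "the", "is", "a"), stopfile)
  cfg <- preprocessConfig(stopword_path = stopfile, min_token_count = 2L)
  raw <- Corpus(
    paste0("d", 1:6),
    c("the virus <b>is</b> spreading fast",
      "the virus is spreading fast",
      "a vaccine is coming soon",
      "vaccine doses arriving now",
      "masks masks everywhere",
      "the lone word"))
  once <- preprocessCorpus(raw, cfg)
  twice <- preprocessCorpus(once, cfg)
  expect_identical(twice@tokens, once@tokens)
  expect_identical(twice@docs$text, once@docs$text)
  expect_lte(nDocs(once), nDocs(raw))
  expect_lte(sum(lengths(once@tokens)), sum(lengths(
    tokenizeCorpus(raw)@tokens)))
})

test_that("a reachable pretreatment example survives the ladder", {
  stopfile <- tempfile()
  writeLines(c("now", "the", "is", "are", "really"), stopfile)
  raw <- Corpus("r1", paste("Now the pandemic is spreading, the whole",
                            "network selling masks are doubling the",
                            "price! Really no conscience!"))
  cfg <- preprocessConfig(stopword_path = stopfile)
  out <- preprocessCorpus(raw, cfg)
  expect_true(all(c("pandemic", "masks", "price", "no", "conscience")
                  %in% out@tokens[[1]]))
  expect_false(any(c("the", "is", "are") %in% out@tokens[[1]]))
})
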