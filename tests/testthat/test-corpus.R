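test_that("CSV and JSONL corpora round-trip all fields exactly", {
  corp <- Corpus(
    doc_id = c("u1", "u2", "u3"),
    text = c("masks sold out", "vaccine approved", "stay home"),
    date = c("2020-07-31", "2020-08-02", NA),
    region = c("Jilin Province", NA, "Beijing City"),
    polarity_label = c(0L, 1L, NA_integer_),
    emotion_label = c("fear", "happy", NA))
  cols <- c("doc_id", "text", "date", "region", "polarity_label",
            "emotion_label")
  for (fmt in c("csv", "jsonl")) {
    f <- tempfile(fileext = paste0(".", fmt))
    writeCorpus(corp, f, fmt)
    back <- readCorpus(f, fmt)
    expect_identical(back@docs[cols], corp@docs[cols])
  }
})

test_that("readCorpus handles empty files, preserves order, flags errors", {
  f <- tempfile(fileext = ".csv")
  writeLines("doc_id,text", f)
  expect_equal(nDocs(readCorpus(f)), 0L)

  writeLines(c("doc_id,text", "u1,a", "u2,b"), f)
  expect_identical(docIds(readCorpus(f)), c("u1", "u2"))

  writeLines(c("doc_id,text", "u1,a", "u1,b"), f)
  expect_error(readCorpus(f), "duplicate doc_id.*u1")

  writeLines(c("text", "a"), f)
  expect_error(readCorpus(f), "missing required column.*doc_id")

  writeLines(c("doc_id,text,date", "u9,a,July 2020"), f)
  expect_error(readCorpus(f), "unparseable date.*u9")
})

test_that("a transcription of the sample-comment table reads with regions", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "doc_id,text,date,region",
    "User 1,hoped the test reagents reach every city,2020-10-15,Jilin Province",
    "User 2,the virus is still in its initial stage,2021-01-24,Guangdong Province",
    "User 3,strictly control the price of masks,2021-04-08,Beijing City",
    "User 4,the country will control the pandemic,2021-06-17,Sichuan Province"),
    f)
  corp <- readCorpus(f)
  expect_equal(nDocs(corp), 4L)
  expect_setequal(docRegions(corp),
                  c("Jilin Province", "Guangdong Province",
                    "Beijing City", "Sichuan Province"))
})

test_that("partitionByDay forms an ordered exact partition", {
  one <- Corpus(c("a", "b", "c"), c("x", "y", "z"), date = "2020-07-31")
  p <- partitionByDay(one)
  expect_length(p, 1L)
  expect_equal(nDocs(p[[1]]), 3L)

  two <- Corpus(c("a", "b"), c("x", "y"),
                date = c("2020-08-02", "2020-07-31"))
  p2 <- partitionByDay(two)
  expect_identical(names(p2), c("2020-07-31", "2020-08-02"))

  expect_length(partitionByDay(Corpus(character(), character())), 0L)

  nodate <- Corpus(c("a", "b"), c("x", "y"),
                   date = c("2020-07-31", NA))
  expect_error(partitionByDay(nodate), "without a date.*b")

  # partition property: day-set sizes sum to the corpus size
  set.seed(42)
  n <- 57
  corp <- Corpus(paste0("d", 1:n), rep("t", n),
                 date = as.Date("2020-07-01") + sample(0:20, n, TRUE))
  parts <- partitionByDay(corp)
  expect_equal(sum(vapply(parts, nDocs, integer(1))), n)
  expect_setequal(unlist(lapply(parts, docIds)), docIds(corp))
})

test_that("default taxonomy has the 7/21 structure with 3 positive categories", {
  tx <- defaultTaxonomy()
  expect_length(tx@mainCategories, 7L)
  expect_length(tx@subcategoryMap, 21L)
  expect_equal(sum(tx@polarityMap == 1L), 3L)
  expect_setequal(names(tx@polarityMap)[tx@polarityMap == -1L],
                  c("anger", "disgust", "fear", "sadness"))
  expect_equal(mainCategoryOf("NI"), "fear")
  expect_equal(mainCategoryOf("PH"), "good")
  expect_setequal(unique(mainCategoryOf(names(tx@subcategoryMap))),
                  tx@mainCategories)
  expect_error(mainCategoryOf("XX"), "unknown subcategory")
})

test_that("loadLexicon validates the sample-table fixture", {
  expect_warning(lex <- loadLexicon(table4File()), "off the canonical")
  expect_equal(nEntries(lex), 6L)
  fear <- lexiconLookup(lex, "Fear")
  expect_equal(fear$intensity, 5L)
  expect_equal(fear$polarity, -1L)
  expect_equal(fear$auxiliary, "NG")
  hope <- lexiconLookup(lex, "Hope")
  expect_equal(hope$intensity, 4L)  # off-grid value accepted with warning
  expect_equal(lexiconLookup(lex, "absent-word"), lex@entries[0, ],
               ignore_attr = TRUE)
})

test_that("loadLexicon rejects invalid rows and accepts edge dialects", {
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste("word", "pos", "sense_count", "subcategory",
                   "intensity", "polarity", "auxiliary", sep = "\t"),
             empty)
  expect_equal(nEntries(loadLexicon(empty)), 0L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("word\tpos\tsense_count\tsubcategory\tintensity\tpolarity\tauxiliary",
               "x\tNoun\t1\tNI\t0\t-1\t"), bad)
  expect_error(loadLexicon(bad), "invalid lexicon row.*1")

  # comma dialect with the 0/1 polarity coding: 0 maps to -1
  csv <- tempfile(fileext = ".csv")
  writeLines(c("word,pos,sense_count,subcategory,intensity,polarity,auxiliary",
               "gloom,Noun,1,NB,5,0,", "cheer,Noun,1,PA,5,1,"), csv)
  lex <- loadLexicon(csv)
  expect_equal(lexiconLookup(lex, "gloom")$polarity, -1L)
  expect_equal(lexiconLookup(lex, "cheer")$polarity, 1L)
})
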