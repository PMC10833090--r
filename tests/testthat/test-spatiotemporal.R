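test_that("shiftScore is the affine map of [0,1] onto [-1,1]", {
  expect_equal(shiftScore(0.5), 0)
  expect_equal(shiftScore(1), 1)
  expect_equal(shiftScore(0), -1)
  expect_error(shiftScore(1.2), "must lie in")
  grid <- seq(0, 1, length.out = 101)
  expect_true(all(diff(shiftScore(grid)) > 0))
  expect_true(all(shiftScore(grid) >= -1 & shiftScore(grid) <= 1))
})

test_that("daily scores average shifted probabilities", {
  expect_equal(dailyScore(rep(1, 5))$S_D, 1)
  expect_equal(dailyScore(c(0, 1, 0, 1))$S_D, 0)
  hand <- dailyScore(c(0.9, 0.6, 0.1))
  expect_equal(hand$S_D, (0.8 + 0.2 - 0.8) / 3, tolerance = 1e-12)
  expect_equal(round(hand$S_D, 4), 0.0667)
  expect_equal(hand$m, 3L)
  expect_error(dailyScore(numeric()), "at least one document")
  # order invariance
  set.seed(3)
  s <- runif(20)
  expect_equal(dailyScore(s)$S_D, dailyScore(rev(s))$S_D)
})

test_that("monthly aggregation is document-weighted and ordered", {
  one <- data.frame(date = as.Date("2020-07-15"), m = 4L, S_D = 0.3)
  expect_equal(monthlyAggregate(one)$score, 0.3)

  two <- data.frame(date = as.Date(c("2020-07-01", "2020-07-02")),
                    m = c(1L, 3L), S_D = c(1, 0))
  expect_equal(monthlyAggregate(two)$score, 0.25)

  multi <- data.frame(
    date = as.Date(c("2020-09-01", "2020-07-01", "2020-08-01")),
    m = 1L, S_D = 0)
  expect_identical(monthlyAggregate(multi)$month,
                   c("2020-07", "2020-08", "2020-09"))
})

test_that("stage assignment follows the three-phase partition", {
  expect_equal(assignStage("2020-08-15"), "stage1")
  expect_equal(assignStage("2021-01-25"), "stage2")
  expect_equal(assignStage("2021-06-26"), "stage3")
  expect_equal(assignStage("2020-10-31"), "stage1")
  expect_equal(assignStage("2020-11-01"), "stage2")
  expect_error(assignStage("2022-01-01"), "outside the study window")
  expect_error(stagePartition(c("a", "b"),
                              c("2020-01-01", "2020-02-01"),
                              c("2020-02-15", "2020-03-01")),
               "overlap")
})

test_that("region-stage summaries estimate planted negativity rates", {
  lex <- loadTable4()
  negCorp <- Corpus(paste0("d", 1:4), rep("t", 4),
                    date = c("2020-07-05", "2020-12-05", "2021-04-05",
                             "2021-05-05"),
                    region = "R",
                    tokens = rep(list(c("Fear", "Grief")), 4))
  summ <- regionStageSummary(negCorp, lex)
  expect_equal(summ$neg_proportion[summ$n > 0], rep(1, 3))
  # regions absent in a stage are flagged missing with count 0
  expect_true(all(is.na(summ$neg_proportion[summ$n == 0])))

  # sampling-bound check: with no regional effect, every cell of a stage
  # shares the planted rate; cells of ~500 docs must sit within 0.05 of
  # the large-sample pooled value
  cfg <- generatorConfig(seed = 41, n_documents = 6000,
                         regions = paste0("r", 1:4),
                         region_effect_sd = 0,
                         emotion_word_rate = 0.6)
  sim <- makeCorpus(cfg)
  summ2 <- regionStageSummary(sim$corpus, sim$lexicon)
  pooled <- tapply(seq_len(nrow(summ2)), summ2$stage, function(idx)
    sum(summ2$n[idx] * summ2$neg_proportion[idx]) / sum(summ2$n[idx]))
  for (i in seq_len(nrow(summ2)))
    expect_lt(abs(summ2$neg_proportion[i] - pooled[[summ2$stage[i]]]),
              0.05)
})

test_that("adjacent-stage differencing is antisymmetric and flagged", {
  summ <- data.frame(
    region = rep(c("A", "B"), each = 3),
    stage = rep(c("stage1", "stage2", "stage3"), 2),
    n = c(10, 10, 10, 10, 0, 10),
    neg_proportion = c(0.6, 0.4, 0.4, 0.5, NA, 0.2))
  d <- stageDifference(summ)
  dA <- d[d$region == "A", ]
  expect_equal(dA$delta, c(-0.2, 0))
  # region B is missing in stage 2: both adjacent deltas are flagged
  expect_true(all(is.na(d$delta[d$region == "B"])))
  expect_true(all(!d$complete[d$region == "B"]))
  # reversing the stage order negates the deltas
  dRev <- stageDifference(summ, stage_order = c("stage3", "stage2",
                                                "stage1"))
  expect_equal(dRev$delta[dRev$region == "A"], c(0, 0.2))
})

test_that("Jenks breaks equal the exhaustive partition optimum", {
  one <- jenksBreaks(c(3, 1, 2), 1)
  expect_equal(one$class, rep(1L, 3))

  gap <- jenksBreaks(c(1, 2, 9, 10), 2)
  expect_equal(gap$class, c(1L, 1L, 2L, 2L))

  expect_error(jenksBreaks(c(1, 1, 1), 3), "distinct values")

  set.seed(19)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    vals <- round(runif(n, 0, 100), 1)
    if (length(unique(vals)) < 4) next
    k <- sample(2:4, 1)
    got <- jenksBreaks(vals, k)
    expect_equal(got$ssd, jenksOracle(vals, k), tolerance = 1e-8)
    # assignment is monotone in the value
    ord <- order(vals)
    expect_true(all(diff(got$class[ord]) >= 0))
    expect_equal(max(got$class), k)
  }
})

test_that("spatial similarity detects planted smooth fields", {
  regions <- paste0("r", 1:6)
  adj <- makeAdjacency(regions, "chain")
  flat <- setNames(rep(0.4, 6), regions)
  res <- spatialSimilarity(flat, adj, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 0)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_error(spatialSimilarity(flat[1:3], adj), "no proportion")

  hits <- 0L
  for (s in 1:10) {
    cfg <- generatorConfig(seed = 500 + s, n_documents = 0,
                           regions = paste0("p", sprintf("%02d", 1:20)),
                           region_effect_sd = 0.15)
    sim <- makeCorpus(cfg)
    planted <- setNames(sim$truth$region_rates[, 1],
                        rownames(sim$truth$region_rates))
    res <- spatialSimilarity(planted, sim$adjacency, n_perm = 999,
                             seed = s)
    hits <- hits + (res$statistic <
                      stats::quantile(res$null, 0.05))
  }
  expect_gte(hits, 9L)
})

test_that("the tidy summary joins breaks classes and deltas", {
  set.seed(53)
  summ <- data.frame(
    region = rep(paste0("r", 1:6), each = 3),
    stage = rep(c("stage1", "stage2", "stage3"), 6),
    n = 50L,
    neg_proportion = runif(18))
  path <- tempfile(fileext = ".csv")
  tidy <- writeRegionStageSummary(summ, path, n_classes = 3)
  expect_true(file.exists(path))
  expect_true(all(c("class_index", "delta_prev_stage") %in% names(tidy)))
  expect_true(all(tidy$class_index %in% 1:3))
  expect_true(all(is.na(tidy$delta_prev_stage[tidy$stage == "stage1"])))
})
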