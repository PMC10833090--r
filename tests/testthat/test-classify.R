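test_that("naive Bayes matches a hand-computed posterior", {
  # 4 documents, 2 classes, vocabulary (good, bad, ok); smoothing 1
  toks <- list(c("good", "good", "ok"), c("good", "ok"),
               c("bad", "bad"), c("bad", "ok"))
  labels <- c(1, 1, 0, 0)
  corp <- tokenCorpus(toks)
  vocab <- c("bad", "good", "ok")
  nb <- trainNaiveBayes(termCountMatrix(corp, vocab), labels)

  # hand computation: priors 1/2 each; class 1 counts (0,3,2) of 5,
  # class 0 counts (3,0,1) of 4; smoothed with a=1, M=3
  p1 <- c(bad = 1, good = 4, ok = 3) / 8
  p0 <- c(bad = 4, good = 1, ok = 2) / 7
  doc <- c("good", "bad", "ok")
  post1 <- 0.5 * prod(p1[doc])
  post0 <- 0.5 * prod(p0[doc])
  want <- post1 / (post1 + post0)
  got <- sentimentProbabilityNB(nb, doc)
  expect_equal(got, want, tolerance = 1e-12)

  # empty document falls back to the prior
  expect_equal(sentimentProbabilityNB(nb, character()), 0.5,
               tolerance = 1e-12)
  # a document of positive-exclusive words leans positive
  expect_gt(sentimentProbabilityNB(nb, c("good", "good")), 0.5)
})

test_that("naive Bayes handles degenerate class structures", {
  toks <- list(c("a", "b"), c("a", "c"))
  nb1 <- trainNaiveBayes(termCountMatrix(tokenCorpus(toks)), c("x", "x"))
  expect_equal(unname(exp(nb1@logPrior)), 1)
  expect_identical(predictNaiveBayes(nb1, list("a"), type = "class"), "x")

  # disjoint vocabularies are perfectly separable on the training set
  toksSep <- list(c("p1", "p2"), c("p2", "p3"), c("n1", "n2"),
                  c("n3", "n1"))
  corp <- tokenCorpus(toksSep)
  labels <- c(1, 1, 0, 0)
  nb <- trainNaiveBayes(termCountMatrix(corp), labels)
  pred <- as.integer(sentimentProbabilityNB(nb, corp) > 0.5)
  expect_equal(pred, labels)
})

test_that("logistic regression matches the direct Newton oracle", {
  set.seed(61)
  n <- 60; m <- 4
  X <- matrix(rnorm(n * m), n, m)
  beta_true <- c(1.5, -2, 0.5, 0)
  y <- rbinom(n, 1, 1 / (1 + exp(-(X %*% beta_true + 0.3))))
  Xs <- as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  fit <- trainLogistic(Xs, y, l2 = 1e-3, tol = 1e-6, max_iter = 500)
  oracle <- newtonLogisticOracle(X, y, l2 = 1e-3)
  expect_equal(unname(augmentedWeights(fit)), oracle, tolerance = 1e-4)
  # first-order conditions at the solution
  expect_lte(fit@gradNorm, 1e-6)
  expect_true(fit@converged)
  # the fitted objective improves on the zero initialization
  expect_lt(fit@objective, n * log(2))
})

test_that("logistic predictions follow the sigmoid algebra", {
  zero <- new("LogisticModel", weights = c(x1 = 0, x2 = 0), bias = 0,
              featureNames = c("x1", "x2"), converged = TRUE,
              iterations = 0L, objective = 0, gradNorm = 0, l2 = 0)
  X <- matrix(c(1, -2, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(predictLogistic(zero, X), c(0.5, 0.5))

  model <- new("LogisticModel", weights = c(x1 = 0.8, x2 = -1.2),
               bias = 0.5, featureNames = c("x1", "x2"),
               converged = TRUE, iterations = 0L, objective = 0,
               gradNorm = 0, l2 = 0)
  # zero feature row gives sigmoid(bias)
  expect_equal(predictLogistic(model, matrix(0, 1, 2)),
               1 / (1 + exp(-0.5)))
  # hand-computed 2-feature case and augmented-form agreement
  x <- c(2, 1)
  eta <- sum(model@weights * x) + model@bias
  expect_equal(predictLogistic(model, matrix(x, 1)),
               1 / (1 + exp(-eta)))
  expect_equal(sum(augmentedWeights(model) * c(x, 1)), eta)
  expect_error(predictLogistic(model, matrix(0, 1, 3)),
               "feature count mismatch")
})

test_that("separable one-feature data learns the class direction", {
  X <- Matrix::Matrix(matrix(c(-2, -1.5, -1, 1, 1.5, 2), 6, 1),
                      sparse = TRUE)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- trainLogistic(as(X, "CsparseMatrix"), y, l2 = 0.1)
  expect_gt(fit@weights[[1]], 0)
  expect_error(trainLogistic(as(X, "CsparseMatrix"), rep(1, 6)),
               "both classes")
})

test_that("evaluation metrics match the counting oracle", {
  perfect <- evaluateClassifier(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$metrics[c("precision", "recall", "f1")] == 1))
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0)

  ev <- evaluateClassifier(c(1, 1, 0, 0), c(1, 0, 0, 0))
  m1 <- ev$metrics[ev$metrics$class == "1", ]
  expect_equal(m1$precision, 1.0)
  expect_equal(m1$recall, 0.5)
  expect_equal(m1$f1, 2 / 3)
  expect_equal(ev$accuracy, 0.75)

  allOne <- evaluateClassifier(c(0, 0, 1, 1), c(1, 1, 1, 1))
  expect_equal(allOne$accuracy, 0.5)
  expect_true("0:precision" %in% allOne$zero_denominator)

  expect_error(evaluateClassifier(c(1, 0), c(1, 0, 0)), "same length")

  set.seed(83)
  labels7 <- defaultTaxonomy()@mainCategories
  for (rep in 1:5) {
    n <- sample(50:1000, 1)
    truth <- sample(labels7, n, TRUE)
    pred <- sample(labels7, n, TRUE)
    ev <- evaluateClassifier(truth, pred, labels7)
    want <- metricsOracle(truth, pred, labels7)
    expect_equal(as.matrix(ev$metrics[c("precision", "recall", "f1",
                                        "support")]),
                 want$metrics, ignore_attr = TRUE)
    expect_equal(ev$accuracy, want$accuracy)
    # confusion row sums equal per-class supports
    expect_equal(unname(rowSums(ev$confusion)),
                 as.numeric(table(factor(truth, levels = labels7))))
    # weighted support sums to the total
    expect_equal(sum(ev$metrics$support), n)
  }
})

test_that("one-vs-rest extends the model to the 7 emotion classes", {
  set.seed(29)
  cats <- c("anger", "fear", "good", "happy")
  n <- 120
  lab <- sample(cats, n, TRUE)
  # class-specific marker features plus noise
  X <- matrix(rnorm(n * 6, sd = 0.3), n, 6)
  for (i in seq_along(cats)) X[lab == cats[i], i] <- X[lab == cats[i], i] + 3
  Xs <- as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  fit <- trainLogisticMulticlass(Xs, lab, l2 = 1e-2)
  pred <- predictLogisticMulticlass(fit, Xs)
  expect_gte(mean(pred == lab), 0.95)
  probs <- predictLogisticMulticlass(fit, Xs, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, n), tolerance = 1e-12)
})
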