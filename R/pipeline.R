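.PIPELINE_STAGES <- c("simulate", "preprocess", "sentiment", "topics",
                      "classify", "spacetime", "report")
.CONFIG_KEYS <- c("output_dir", "seed", .PIPELINE_STAGES)

#' Run one stage of the opinion-mining pipeline
#'
#' Thin orchestration layer wiring the package's stages into reproducible
#' runs. Each subcommand reads its inputs from (and writes its outputs and
#' a JSON manifest to) \code{output_dir}:
#' \describe{
#'   \item{simulate}{generate a synthetic corpus, lexicon and adjacency
#'     (\code{corpus.csv}, \code{lexicon.tsv}, \code{adjacency.csv}).}
#'   \item{preprocess}{run the cleaning ladder
#'     (\code{corpus_clean.csv}).}
#'   \item{sentiment}{lexicon emotion profiles (\code{profiles.csv}).}
#'   \item{topics}{perplexity-based topic-count selection and a final
#'     topic model (\code{topic_selection.csv},
#'     \code{topic_report.csv}).}
#'   \item{classify}{TF-IDF + sparse logistic regression (or naive
#'     Bayes) with held-out metrics (\code{metrics.csv},
#'     \code{predictions.csv}).}
#'   \item{spacetime}{region-stage negativity, natural breaks, deltas and
#'     the spatial-similarity permutation test
#'     (\code{region_stage.csv}, \code{spatial.json}).}
#'   \item{report}{collect the stage outputs into \code{summary.json};
#'     fails if no stage has run.}
#' }
#'
#' @param subcommand one of the stage names above.
#' @param config named list (see the per-stage sections of
#'   [pipelineConfig()]) or path to a YAML file with the same structure.
#' @param seed optional override of the configured seed.
#' @return Invisibly, a list of the stage's outputs.
#' @export
runPipeline <- function(subcommand = .PIPELINE_STAGES, config = list(),
                        seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- pipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  result <- switch(subcommand,
    simulate = .stageSimulate(config),
    preprocess = .stagePreprocess(config),
    sentiment = .stageSentiment(config),
    topics = .stageTopics(config),
    classify = .stageClassify(config),
    spacetime = .stageSpacetime(config),
    report = .stageReport(config))
  manifest <- list(
    subcommand = subcommand,
    config = config[setdiff(names(config), "stage_partition")],
    seed = config$seed,
    package_version = as.character(utils::packageVersion("opinionminer")),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3),
    outputs = result$files)
  jsonlite::write_json(manifest,
                       file.path(out_dir,
                                 paste0(subcommand, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(result)
}

#' Validated pipeline configuration
#'
#' Fills defaults for the run configuration: \code{output_dir},
#' \code{seed}, and one section per stage (\code{simulate} forwards to
#' [generatorConfig()]; \code{preprocess} holds
#' \code{stopword_path}/\code{min_token_count}; \code{sentiment} holds
#' \code{threshold}; \code{topics} holds \code{method},
#' \code{k_grid}, \code{iterations}; \code{classify} holds \code{model}
#' (\code{"lr"} or \code{"nb"}), \code{test_frac}, \code{l2};
#' \code{spacetime} holds \code{n_classes}, \code{n_perm}). Unknown keys
#' are rejected.
#'
#' @param config named list of overrides.
#' @return Completed configuration list.
#' @export
pipelineConfig <- function(config = list()) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    output_dir = "opinionminer_run",
    seed = 1L,
    simulate = list(),
    preprocess = list(stopword_path = NULL, min_token_count = 1L),
    sentiment = list(threshold = 0),
    topics = list(method = "btm", k_grid = c(2L, 3L, 4L, 6L),
                  iterations = 200L),
    classify = list(model = "lr", test_frac = 0.3, l2 = 1e-4),
    spacetime = list(n_classes = 5L, n_perm = 999L))
  for (key in names(defaults)) {
    if (is.list(defaults[[key]]) && !is.null(config[[key]])) {
      bad <- setdiff(names(config[[key]]),
                     c(names(defaults[[key]]),
                       if (key == "simulate") names(formals(generatorConfig))))
      if (length(bad))
        stop("unknown ", key, " config key(s): ",
             paste(bad, collapse = ", "))
      defaults[[key]] <- utils::modifyList(defaults[[key]],
                                           config[[key]])
    } else if (!is.null(config[[key]])) {
      defaults[[key]] <- config[[key]]
    }
  }
  defaults
}

.need <- function(path, hint) {
  if (!file.exists(path))
    stop("missing input ", path, "; run '", hint, "' first")
  path
}

.stageSimulate <- function(config) {
  args <- config$simulate
  args$seed <- config$seed
  sim <- makeCorpus(do.call(generatorConfig, args))
  out <- config$output_dir
  writeCorpus(sim$corpus, file.path(out, "corpus.csv"))
  writeLexicon(sim$lexicon, file.path(out, "lexicon.tsv"))
  utils::write.csv(sim$adjacency, file.path(out, "adjacency.csv"),
                   row.names = FALSE)
  list(files = c("corpus.csv", "lexicon.tsv", "adjacency.csv"))
}

.stagePreprocess <- function(config) {
  out <- config$output_dir
  corpus <- readCorpus(.need(file.path(out, "corpus.csv"), "simulate"))
  pc <- preprocessConfig(
    stopword_path = config$preprocess$stopword_path,
    min_token_count = config$preprocess$min_token_count)
  corpus <- preprocessCorpus(corpus, pc)
  writeCorpus(corpus, file.path(out, "corpus_clean.csv"))
  list(files = "corpus_clean.csv", corpus = corpus)
}

.loadClean <- function(config) {
  out <- config$output_dir
  corpus <- readCorpus(.need(file.path(out, "corpus_clean.csv"),
                             "preprocess"))
  tokenizeCorpus(corpus)
}

.stageSentiment <- function(config) {
  out <- config$output_dir
  lexicon <- loadLexicon(.need(file.path(out, "lexicon.tsv"), "simulate"))
  corpus <- .loadClean(config)
  profiles <- emotionProfiles(corpus, lexicon,
                              threshold = config$sentiment$threshold)
  writeEmotionProfiles(profiles, file.path(out, "profiles.csv"))
  list(files = "profiles.csv", profiles = profiles)
}

.stageTopics <- function(config) {
  out <- config$output_dir
  corpus <- .loadClean(config)
  tc <- config$topics
  k <- selectK(corpus, tc$k_grid, seed = config$seed,
               method = tc$method, iterations = tc$iterations)
  model <- if (tc$method == "btm")
    fitBTM(corpus, as.integer(k), iterations = tc$iterations,
           seed = config$seed)
  else fitLDA(corpus, as.integer(k), seed = config$seed,
              iterations = tc$iterations)
  sel <- data.frame(K = as.integer(names(attr(k, "perplexities"))),
                    perplexity = as.numeric(attr(k, "perplexities")),
                    selected = as.integer(names(attr(k, "perplexities")))
                      == as.integer(k))
  utils::write.csv(sel, file.path(out, "topic_selection.csv"),
                   row.names = FALSE)
  utils::write.csv(topTopicWords(model, 10L),
                   file.path(out, "topic_report.csv"), row.names = FALSE)
  list(files = c("topic_selection.csv", "topic_report.csv"),
       selected_k = as.integer(k), model = model)
}

.stageClassify <- function(config) {
  out <- config$output_dir
  corpus <- .loadClean(config)
  labels <- polarityLabels(corpus)
  if (anyNA(labels)) stop("classify requires polarity labels")
  cc <- config$classify
  split <- stratifiedSplit(labels, test_frac = cc$test_frac,
                           seed = config$seed)
  train <- corpus[split$train]; test <- corpus[split$test]
  vocab <- buildVocabulary(train)
  if (cc$model == "lr") {
    dtmTrain <- tfidfMatrix(train, vocab)
    dtmTest <- tfidfMatrix(test, vocab)
    keptTrain <- match(dtmTrain@docIds, docIds(train))
    keptTest <- match(dtmTest@docIds, docIds(test))
    model <- trainLogistic(dtmTrain, labels[split$train][keptTrain],
                           l2 = cc$l2)
    shat <- predictLogistic(model, dtmTest)
    truth <- labels[split$test][keptTest]
    ids <- dtmTest@docIds
  } else {
    model <- trainNaiveBayes(termCountMatrix(train, vocab),
                             labels[split$train])
    shat <- sentimentProbabilityNB(model, test)
    truth <- labels[split$test]
    ids <- docIds(test)
  }
  pred <- as.integer(shat > 0.5)
  report <- evaluateClassifier(truth, pred, label_order = c("0", "1"))
  writeMetricsReport(report, file.path(out, "metrics.csv"))
  utils::write.csv(data.frame(doc_id = ids, shat = shat,
                              predicted = pred, truth = truth),
                   file.path(out, "predictions.csv"), row.names = FALSE)
  list(files = c("metrics.csv", "predictions.csv"),
       report = report, model = model)
}

.stageSpacetime <- function(config) {
  out <- config$output_dir
  lexicon <- loadLexicon(.need(file.path(out, "lexicon.tsv"), "simulate"))
  adjacency <- readAdjacency(.need(file.path(out, "adjacency.csv"),
                                   "simulate"))
  corpus <- .loadClean(config)
  summ <- regionStageSummary(corpus, lexicon)
  tidy <- writeRegionStageSummary(summ, file.path(out, "region_stage.csv"),
                                  n_classes = config$spacetime$n_classes)
  stages <- unique(summ$stage)
  spatial <- lapply(stages, function(st) {
    sub <- summ[summ$stage == st & !is.na(summ$neg_proportion), ]
    if (nrow(sub) < 2L) return(NULL)
    adj <- adjacency[adjacency$region_a %in% sub$region &
                       adjacency$region_b %in% sub$region, ]
    if (!nrow(adj)) return(NULL)
    res <- spatialSimilarity(sub, adj,
                             n_perm = config$spacetime$n_perm,
                             seed = config$seed)
    list(stage = st, statistic = res$statistic, p_value = res$p_value)
  })
  spatial <- spatial[!vapply(spatial, is.null, logical(1))]
  jsonlite::write_json(spatial, file.path(out, "spatial.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(files = c("region_stage.csv", "spatial.json"),
       summary = tidy, spatial = spatial)
}

.stageReport <- function(config) {
  out <- config$output_dir
  produced <- list.files(out, pattern = "\\.(csv|json)$")
  produced <- setdiff(produced, "summary.json")
  if (!length(produced))
    stop("no stage outputs found in ", out, "; nothing to report")
  summary <- list(output_dir = out, files = produced)
  mfile <- file.path(out, "metrics.csv")
  if (file.exists(mfile)) {
    m <- utils::read.csv(mfile)
    summary$accuracy <- m$f1_score[m$measure == "accuracy"]
  }
  sfile <- file.path(out, "topic_selection.csv")
  if (file.exists(sfile)) {
    s <- utils::read.csv(sfile)
    summary$selected_k <- s$K[s$selected][1L]
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(files = "summary.json", summary = summary)
}
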