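# opinionminer

Topic modeling and multidimensional sentiment analysis of short
social-media texts.

## The problem

During public-health emergencies, microblog comments carry a dense
record of public emotion: what people fear, what they support, and how
that changes over time and across regions. Turning a pile of short,
noisy comments into interpretable signals requires a chain of methods —
cleaning and segmentation, emotion-lexicon scoring, topic models suited
to very short documents, supervised sentiment classifiers, and
spatiotemporal aggregation. `opinionminer` implements that chain as one
tested R package, for infodemiology researchers and analysts who need a
reproducible short-text opinion pipeline rather than a collection of
loose scripts.

## What is inside

* **Lexicon scoring** over a 7-category / 21-subcategory emotion
  taxonomy (anger, disgust, fear, sadness, surprise, good, happy).
  Word sentiment is `s(w) = v(w) p(w)` — intensity (odd levels 1–9)
  times signed polarity — accumulated into per-document emotion
  profiles and a signed polarity score.
* **Topic models for short text**: a biterm topic model (BTM) and LDA,
  both by collapsed Gibbs sampling (C++; bit-reproducible per seed),
  with held-out perplexity by document completion and automatic
  selection of the topic count `K` at the perplexity minimum.
  Embedding-based vocabulary reduction (PPMI + SVD vectors, k-means
  clusters, representative-word substitution) shrinks the input.
* **Classifiers**: TF-IDF features (`tf(w, D_i) × log(D / (1 + df))`,
  sparse matrices throughout) feeding a deterministic sparse
  logistic-regression model `P(y=1|x) = 1/(1 + exp(-(w·x + b)))` and a
  multinomial naive-Bayes model; confusion matrices with precision /
  recall / F1 / support, macro and weighted averages.
* **Spatiotemporal aggregation**: classifier scores rescaled by
  `2·ŝ − 1` into daily scores `S_D`, monthly document-weighted means,
  a three-stage partition of the study window (Jul–Oct 2020,
  Nov 2020–Feb 2021, Mar–Jun 2021), per-region negative-emotion
  proportions, adjacent-stage differences, exact Fisher–Jenks natural
  breaks, and a permutation test of neighboring-region similarity.
* **A synthetic microblog generator** with complete ground truth
  (topics, injected emotion words, regional negativity with planted
  spatial smoothness, labels), so every stage is testable without
  downloading data.

See `vignettes/opinion-mining-methods.Rmd` for the models, assumptions
and design decisions.

## Worked example

```r
library(opinionminer)

cfg <- generatorConfig(seed = 42, n_documents = 800, K_true = 3,
                       vocab_size = 200)
sim    <- makeCorpus(cfg)              # corpus + ground truth + lexicon
corpus <- preprocessCorpus(sim$corpus) # 7-step cleaning ladder

# multidimensional emotion profiles and the negative-dominance rate
profiles <- emotionProfiles(corpus, sim$lexicon)
negativeEmotionProportion(profiles)
#> [1] 0.464

# topic-count selection by minimum held-out perplexity
k <- selectK(corpus, c(2, 3, 4), seed = 42, iterations = 100)
as.integer(k)
#> [1] 3
round(attr(k, "perplexities"), 2)
#>     2     3     4
#> 70.47 55.79 55.91

# sparse TF-IDF + logistic regression on the held-out 30%
labs  <- polarityLabels(corpus)
split <- stratifiedSplit(labs, test_frac = 0.3, seed = 42)
vocab <- buildVocabulary(corpus[split$train])
model <- trainLogistic(tfidfMatrix(corpus[split$train], vocab),
                       labs[split$train])
shat  <- predictLogistic(model, tfidfMatrix(corpus[split$test], vocab))
ev    <- evaluateClassifier(labs[split$test], as.integer(shat > 0.5),
                            c("0", "1"))
round(ev$accuracy, 3)
#> [1] 0.908

# regional negativity by stage
head(regionStageSummary(corpus, sim$lexicon), 4)
#>        region  stage  n neg_proportion
#> 1 province_01 stage1 30      0.8333333
#> 2 province_02 stage1 23      0.8695652
#> 3 province_03 stage1 25      0.7600000
#> 4 province_04 stage1 26      0.6538462

# daily sentiment from classifier probabilities (2*shat - 1, averaged)
round(dailyScore(c(0.9, 0.6, 0.1))$S_D, 4)
#> [1] 0.0667
```

Reading the numbers: the generator planted three topics and a
negative-to-positive emotional trend over the three stages; `selectK`
recovers `K = 3` at the perplexity minimum, the logistic model
classifies held-out polarity at ~0.91 accuracy, and stage-1 regional
cells show the planted high negativity. The daily score averages
rescaled probabilities, so `(0.8 + 0.2 − 0.8)/3 ≈ 0.0667`.

A thin command-line wrapper over the same functions lives at
`inst/scripts/opinionminer` (subcommands `simulate`, `preprocess`,
`sentiment`, `topics`, `classify`, `spacetime`, `report`; each stage
writes its outputs and a JSON manifest into the run directory).

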