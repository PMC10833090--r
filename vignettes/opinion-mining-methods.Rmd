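---
title: "Methods: topic modeling and multidimensional sentiment analysis of short social-media texts"
author: "opinionminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic modeling and multidimensional sentiment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opinionminer)
```

# Scope

`opinionminer` implements a complete pipeline for mining public opinion
from microblog-style short texts: text cleaning and tokenization,
lexicon-based multidimensional emotion scoring, biterm and LDA topic
modeling with perplexity-driven selection of the topic count, TF-IDF
featurization with sparse logistic-regression and naive-Bayes sentiment
classifiers, and spatiotemporal aggregation of sentiment over pandemic
stages and administrative regions. Because real crawled microblog corpora
are rarely redistributable, the package ships a synthetic corpus
generator with complete ground truth; every stage of the pipeline is
exercised and validated against that generator.

This vignette records the models, their assumptions, the tunable
parameters, and the design decisions taken where the methodology left
genuine freedom.

# The emotion lexicon and word-level scoring

The scoring lexicon follows the Dalian University of Technology design:
7 main emotion categories — *anger*, *disgust*, *fear*, *sadness*
(negative, polarity $-1$) and *surprise*, *good*, *happy* (positive,
polarity $+1$) — refined into 21 subcategories. Word sentiment is the
product of intensity and polarity,

$$s(w) = v(w)\,p(w),$$

with intensity canonically on the five odd levels $\{1,3,5,7,9\}$.
Published lexicon samples also contain the even values 4 and 6, so the
validator accepts any integer in $1\!-\!9$ and warns when a value is off
the canonical grid. Polarity is stored signed; the alternative $0/1$
coding found in some lexicon files is mapped ($0 \to -1$) at parse time,
because only a signed polarity lets $s(w)$ take negative values.

A document's **emotion profile** accumulates, over every token matched in
the lexicon, the word intensity into its main category's total and
$s(w)$ into a signed polarity score. Design choices:

* **Multi-sense words** resolve to the maximum-intensity entry (ties:
  subcategory code, then polarity). The lexicon format records sense
  counts but no disambiguation rule, and tokens carry no part-of-speech
  information after segmentation.
* **No negation or intensifier handling**: scoring is plain dictionary
  matching, which is what the lexicon method specifies; grammar-aware
  scoring is out of scope.
* **Dominant category** is the argmax of the seven totals, with ties
  broken by the fixed order anger > disgust > fear > sadness > surprise >
  good > happy. A document with *no* lexicon hit has no dominant
  category (`NA`) and is not counted as negative-dominant: treating the
  all-zero tie literally would label every emotionless document as
  anger-dominant and inflate regional negativity estimates.

# Preprocessing ladder

Seven steps, applied in order: exact-duplicate removal (on cleaned
text), useless-character and HTML/URL removal, tokenization, stop-word
removal, low-frequency-word removal, and single-split decision-tree
imputation of missing metadata. Properties worth knowing:

* `cleanText()` removes tags to a fixed point and keeps letters, digits,
  CJK characters and basic punctuation; it is idempotent.
* The default tokenizer splits on whitespace after stripping punctuation,
  keeping intra-word apostrophes, hyphens and underscores. Segmenters
  for unsegmented scripts are pluggable via `registerTokenizer()`; the
  pipeline itself is language-independent. Multi-word user-dictionary
  terms are protected by joining their internal spaces with `_`, so
  "nucleic acid testing" survives as one token while the token invariant
  (no whitespace) holds.
* Because tokenization always re-derives tokens from the stored text,
  the whole ladder is idempotent: applying it twice equals applying it
  once.
* The metadata imputer is a depth-1 decision tree: each candidate
  predictor (other metadata columns; dates binarized at every midpoint
  threshold) is scored by information gain, the best single split is
  kept, and missing cells receive the majority value of their stratum
  with the global mode as fallback. Depth 1 keeps the rule
  deterministic and auditable; imputed records are flagged.

# TF-IDF features

Term frequency is $C(w)/|D_i|$ over the document's token count; inverse
document frequency is $\log\!\big(D / (1 + \mathrm{df}(w))\big)$ with
natural logarithm. The $+1$ in the denominator makes the raw value
negative for a word present in *every* document; it is clamped at 0 so
weights stay non-negative (rankings elsewhere are unaffected). Weights
are raw $tf \times idf$ with no row normalization by default (an L2 flag
exists). The IDF is always computed within the document set passed in,
so day-scoped weighting (pass one day's documents) and corpus-scoped
weighting (pass the training corpus) are the same function. Matrices
are stored sparse (`Matrix::dgCMatrix`) and round-trip through
MatrixMarket files with plain-text sidecars.

# Topic models

## Biterm topic model

Short documents give unreliable per-document word mixtures, so the BTM
models the corpus-wide set of *biterms* — unordered word pairs
co-occurring in a document. All within-document pairs are extracted (no
sliding window; a `window` parameter exists for long texts). The
collapsed Gibbs sampler draws each biterm's topic from

$$p(z_b = k \mid \cdot) \propto (n_k + \alpha)\,
\frac{(n_{w_1|k} + \beta)(n_{w_2|k} + \beta)}
     {(2 n_k + M\beta)(2 n_k + 1 + M\beta)},$$

and after the final sweep the estimators are
$\theta_k = (n_k + \alpha)/(|B| + K\alpha)$ and
$\phi_{k,w} = (n_{w|k} + \beta)/(2 n_k + M\beta)$. Estimates are taken
from the final iteration (no averaging), the simplest convention; an
averaging scheme could be added but would complicate the exact
closed-form checks. Defaults $\alpha = 50/K$, $\beta = 0.01$, 1000
sweeps; the $\gamma$ sometimes quoted for the topic-word prior is read
as $\beta$, the standard notation. Samplers are written in C++ and use
R's RNG stream, so a fixed `seed` reproduces fits bit-for-bit.

Document-level mixtures for a fitted BTM use the standard inference rule
$p(k \mid d) \propto \sum_{b \in d} p(k \mid b)$; documents with no
biterm fall back to $\theta$.

## LDA

A standard collapsed Gibbs sampler over per-token assignments with the
same priors and defaults, used both as an alternative topic model and
for mixture-style documents.

## Perplexity and choosing K

Held-out perplexity is
$\exp\!\big(-\sum_d \sum_{w \in d} \log p(w \mid d) / N\big)$. The key
design decision is *how* the held-out document's topic mixture is
inferred. Folding in the whole document lets a model with spurious extra
topics adapt to the very tokens being scored, which makes perplexity
non-increasing in $K$ and useless for selection. The default estimator
is therefore **document completion**: the mixture is inferred from the
odd-position tokens only and the even-position tokens are scored. This
is a standard held-out estimator, keeps the trivial closed forms (a
uniform topic-word model scores exactly the vocabulary size $V$), and
produces the U-shaped perplexity-versus-$K$ curve that `selectK()`
minimizes. Sequential left-to-right updating (re-estimating parameters
one word at a time) is a different, costlier estimator; the package
documents the difference and implements completion. `selectK()` splits
documents 70/30, fits one model per candidate $K$, and returns the
minimizer, resolving ties toward the smaller $K$.

## Vocabulary reduction by embedding clusters

Word vectors come from an **embedding provider** contract. The default
provider is computed from the corpus itself: a PPMI-transformed
word-word co-occurrence matrix factorized by truncated SVD
($U_r\sqrt{\Sigma_r}$ rows as vectors). It is fully deterministic and
needs no external assets; transformer-based providers can be plugged in
behind the same contract. k-means (seeded) clusters the vectors, each
cluster's highest-frequency member becomes its representative (ties:
lexicographic), and `reduceCorpus()` replaces every word by its
representative, shrinking the vocabulary before topic modeling.

## Chi-square topic weights

To weight topics by temporal specificity, the dominant-topic by month
contingency table is formed and each topic receives its chi-square
contribution $\sum_m (O - E)^2/E$, normalized to sum to 1. A perfectly
uniform table yields uniform weights; empty expected cells raise an
error suggesting coarser strata. The exact construction behind
published "chi-square topic weights" is typically unstated; the
contingency-contribution reading used here is one defensible choice and
is flagged as such.

# Sentiment classifiers

* **Multinomial naive Bayes** with additive smoothing (default 1.0):
  class priors are label frequencies, word probabilities are
  $(n_{cw} + a)/(n_c + aM)$. Used as the retrainable probabilistic
  scorer whose positive-class posterior $\hat s \in [0,1]$ feeds the
  daily score.
* **Sparse logistic regression**:
  $P(y{=}1 \mid x) = 1/(1 + e^{-(w \cdot x + b)})$, fitted by
  minimizing the ridge-penalized negative log-likelihood with
  L-BFGS from a zero start — deterministic without any seed. All
  products use sparse storage; the design matrix is never densified.
  The default ridge `l2 = 1e-4` keeps separable problems finite; the
  bias is never penalized. The multi-class (7-emotion) extension is
  one-vs-rest with argmax over class probabilities — the binary form is
  the specified model, the extension is a package design choice.
* **Evaluation**: confusion matrix over an ordered label set plus
  precision, recall, $F_1$, support per class, accuracy, unweighted
  macro and support-weighted averages. Zero-denominator metrics are
  reported as 0 and flagged, matching common classification-report
  conventions.

# Spatiotemporal aggregation

A classifier probability $\hat s \in [0,1]$ is rescaled to a signed
score by the affine map $2\hat s - 1$ — the unique affine bijection of
$[0,1]$ onto $[-1,1]$. (A plain shift $\hat s - 1$ could never produce
positive values, so "lowering" the score is implemented as the affine
rescaling; this is deliberately called out because the two readings
differ.) The daily score is the mean of shifted scores,
$S_D = \frac1m \sum_i (2\hat s_i - 1)$, and months aggregate days by
document-weighted means.

The study window splits into three fixed stages — July–October 2020,
November 2020–February 2021, March–June 2021 — and regions are opaque
labels with a user-supplied adjacency (no geocoding or shapefiles).
Per (region, stage) cell the pipeline reports the document count and the
negative-emotion proportion; adjacent stages are differenced per region;
and the proportions are classified by **exact Fisher–Jenks natural
breaks** (dynamic programming over contiguous partitions minimizing
within-class squared deviation; default 5 classes, a conventional
choropleth choice). Regional similarity is tested with a permutation
test: the statistic is the mean absolute difference of proportions
across adjacent region pairs, and the null shuffles proportions over
regions (999 permutations by default; one-sided p-value
$(1 + \#\{\mathrm{perm} \le \mathrm{obs}\})/(P+1)$).

# The synthetic corpus generator

`makeCorpus(generatorConfig())` emulates a screened microblog-comment
corpus. Defaults are fixed once to the study conditions the pipeline
targets: 2000 documents of 5–30 tokens; dates uniform within three
pandemic stages spanning July 2020–June 2021; 12 latent topics over a
600-word vocabulary; provincial region labels on a chain adjacency; an
emotion-word injection rate of 0.3 per token; per-stage negativity
(0.8, 0.5, 0.2) encoding the negative-to-positive trend; and a
spatially smooth regional effect (independent noise smoothed twice over
the adjacency graph, s.d. 0.1) added to the stage negativity. Documents
are single-topic by default (the short-text assumption behind the BTM);
a `mixture` flag generates LDA-style documents. Topic-word
distributions are block-structured: each topic places `topic_separation`
(default 0.9) of its mass on its own vocabulary block, Dirichlet-
distributed with concentration `topic_concentration` (default 0.1), and
the remainder uniformly elsewhere. Token strings are synthetic
identifiers, so no language resources are needed and the corpus passes
the preprocessing ladder unchanged.

The generator returns full ground truth (topic-word distributions,
per-document topics, injected emotion words with categories, per-cell
negativity rates, labels), and `expectedStageNegativity()` provides a
closed-form conditional-expectation oracle for the per-stage fraction
of negative labels (binomial in the injection count and the cell's
negativity), which the empirical fractions must match.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: natural-language morphology and
segmentation ambiguity, sarcasm and negation, topic drift within a
stage, user-level dependence (all documents are independent), platform
metadata (likes/forwards), and realistic label noise. Results on real
corpora depend on lexicon coverage and segmentation quality in ways the
synthetic benchmark cannot measure.

# Validation scales and numerical choices

The test suite checks the equation-level operations against independent
brute-force oracles (dense TF-IDF double loop, counting-based metrics,
exhaustive Jenks partition search, dense Newton logistic regression)
and the samplers against exact $K{=}1$/degenerate closed forms and
bit-reproducibility. Stochastic recovery checks run at the package's
chosen working scales: topic recovery and classifier accuracy on
2000-document corpora, topic-count selection across 10 seeded
replicates (well-separated disjoint-block topics, 2000-word
vocabulary), stage negativity at 3000 documents against the closed-form
oracle, and regional-smoothness detection on 20-region chains across 10
seeds. Probability vectors are validated to sum to 1 within $10^{-9}$;
oracle equivalences are asserted at $10^{-12}$ (exact arithmetic) or
$10^{-4}$ (optimizer agreement).

# Known limitations

* Lexicon scoring is unigram dictionary matching; negation, irony and
  context are invisible to it.
* Gibbs estimates come from a single final sweep; posterior uncertainty
  is not quantified.
* The chi-square topic weighting and the depth-1 imputer are the
  simplest defensible readings of loosely specified steps.
* One-vs-rest logistic regression does not calibrate probabilities
  across classes; the row-normalized probabilities are a convenience.
* Jenks classification is exact but $O(k n^2)$; it is intended for tens
  to hundreds of regional values, not large vectors.
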