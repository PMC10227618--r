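---
title: "Simulating certainty-based screening with model switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating certainty-based screening with model switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensim)
```

## The problem

A systematic review starts from a search that returns tens of thousands of
title/abstract records, of which only a handful — often well under 1% — are
relevant. Screening them all by hand is weeks of work. An active-learning
pipeline reorders that work: a classifier is trained on the records labeled
so far, every unlabeled record is scored for relevance, and the reviewer is
shown the highest-scoring record next (*certainty-based sampling*). Each new
label retrains the model, so relevant records surface early and the reviewer
can stop long before the pool is exhausted.

`screensim` simulates this loop on fully labeled corpora, where the
reviewer's decisions can be replayed mechanically, and measures what the
reordering is worth. It also simulates *model switching*: starting the
review with a light model and handing over to a different
classifier/representation mid-review once a heuristic (such as a run of
consecutive irrelevant labels) suggests the current model has stalled.

## The screening loop

`simulate_screening()` implements the loop:

1. reveal the labels of a small prior set (`select_priors()`), for example
   one relevant and ten random irrelevant records, or ten and ten;
2. rebalance the labeled set (`balance_labels()`): relevant ids are
   oversampled to a 1:1 ratio against the irrelevant ids (capped at 100
   copies per record). The balancer — not per-class loss weighting — is the
   imbalance control for every classifier, including the networks, whose
   class weighting is disabled by construction;
3. train the configured classifier on the balanced multiset, score all
   unlabeled records, and screen the highest-scoring one; ties are broken
   by canonical corpus order so runs are reproducible;
4. append the revealed label to the trajectory and repeat until a
   `stop_rule()` fires (`all_relevant_found`, `consecutive_irrelevant(k)`,
   or a screening `budget`; the first-listed rule wins on ties).

Every per-step source of randomness (balancer sampling, stochastic
trainers) is seeded from a per-step seed derived from the run seed, so a
trajectory is a pure function of its inputs. This also makes a no-op model
switch — `run_switch()` with identical from/to configurations — reproduce
the unswitched run bit for bit, which the test suite checks for the
deterministic shallow models.

The default retrains after every single label, the live-review ideal in
which the model is always as informed as the reviewer. A `train_every_n`
cadence exists for large experiments; how much a lower retraining frequency
costs is an open empirical question, which is why it is a parameter rather
than a fixed choice.

`run_switch()` runs the same engine in two phases. The trigger is a
`consecutive_irrelevant(k)` or `budget` rule evaluated alongside the stop
rules (a stop rule firing at the same step wins — the run ends). On
hand-over the full feature matrix for the incoming model is computed once
from the whole corpus, as in simulation practice where all texts are
available; labels and priors are retained, step indices continue, and the
consecutive-irrelevant counter restarts so the incoming model is not
immediately judged by the outgoing model's misses.

## Classifier registry and pairing rules

Six classifiers sit behind one train/score contract
(`train_model()` / `predict_relevance()`, scores always in [0, 1]):

* `naive_bayes` — multinomial naive Bayes with Laplace smoothing
  (`alpha = 1`), scored as the posterior relevance probability;
* `logistic_regression` — ridge-penalised logistic regression
  (`lambda = 1e-3`, fit via glmnet on the sparse matrix directly);
* `svm` — linear support-vector machine (`cost = 1`); decision values are
  mapped through the logistic function, so SVM scores are ranking scores,
  not calibrated probabilities — the loop only consumes the ordering;
* `random_forest` — probability forest with 100 trees. One hundred rather
  than the more common 500 because the engine retrains at every iteration;
  at the corpus sizes simulated here the ranking is already stable at 100
  trees and training cost scales linearly in tree count;
* `nn_2_layer` — two ReLU dense layers (128 units each) and a sigmoid
  output;
* `cnn_17` — the deep separable-convolution network below.

An `oracle` test double (scores = true labels) is registered for testing
engine mechanics independently of any trained model.

`validate_pairing()` enforces two structural exclusions: multinomial naive
Bayes cannot handle matrices containing negative values, which rules out
every dense embedding; and the neural classifiers require narrow dense
inputs, because wide sparse term matrices are not a workable network input.
All other classifier-feature pairs pass.

## Features

* `fit_tfidf()` — smoothed tf-idf (`idf = log((1+n)/(1+df)) + 1`, raw term
  counts, L2-normalised rows) over the concatenated title and abstract,
  after lowercasing, punctuation stripping and English stopword removal.
  Unigrams only, no vocabulary cap by default.
* `fit_doc_embedding()` — a count-based paragraph embedding: the positive
  pointwise-mutual-information document-term matrix is factorised by
  truncated SVD and each document keeps its `dim` leading singular
  coordinates. This spectral factorisation is the closed-form counterpart
  of skip-gram-style negative-sampling training, and was chosen over
  stochastic gradient training deliberately: it is exactly reproducible
  across platforms without a deterministic-threading caveat, has no epoch
  or window hyperparameters to pin, and at these corpus sizes costs one
  symmetric eigendecomposition. Component signs are fixed (largest-magnitude
  loading positive) so recomputation is bit-identical. The default width is
  40; `wide_doc_embedding` widens it to 120, the width the deep network is
  paired with.
* `load_precomputed_dense()` — wraps externally produced sentence
  embeddings (e.g. from a transformer sentence encoder, which this package
  deliberately does not implement) after validating row count and record-id
  alignment.

## The 17-layer separable-convolution network

`cnn_architecture()` describes the deep classifier: three blocks of two
separable 1-D convolutions (256 filters; kernel sizes 5 then 3; ReLU),
each block closed by max-pooling and dropout (rate 0.2); then flatten,
dropout (0.5), a 64-unit ReLU dense layer, dropout (0.5), and a single-unit
sigmoid dense layer producing the relevance probability. The input is the
document-embedding vector treated as a length-`dim`, single-channel
sequence.

Counting convention: the depth of the network is the number of layers in
the stack after the input — 12 in the conv blocks, flatten, two dropout and
two dense — totalling 17, with the final dense unit (the sigmoid output)
being one of the two trailing dense layers. `build_cnn()` derives the count
from the stack and refuses an architecture whose derived count disagrees
with its declared one. The per-layer dropout rates and the 64-unit dense
width are package defaults, all overridable; the fixed points are the
17-layer total, 256 filters, kernels 5 and 3, the two trailing dense
layers, and disabled class weighting.

Training uses minibatch Adam (batch 32, learning rate 1e-3) on binary
cross-entropy, with an `early_stop_rule()` on the training-loss delta:
stop once the last `patience` (default 2) epoch-to-epoch improvements are
all below `min_delta` (default 1e-3), or at `max_epochs` (default 50). The
rule exists because the training set grows every iteration, so no fixed
epoch count suits the whole review. The forward/backward passes are plain
(batch, position, channel) array arithmetic; with single-threaded BLAS two
trainings from the same seed are bit-identical.

## The synthetic corpus generator

`generate_corpus()` produces the corpora everything is tested on. Design:

* a Zipf-Mandelbrot background word distribution over a synthetic
  vocabulary (default 1,200 types) — heavy-tailed like real text;
* per-cluster topic distributions: the background perturbed log-normally,
  `topic_k ∝ background · exp(s·g)`, where `s` is `topic_sharpness`
  (default 3) and `g` blends a direction shared by all relevant clusters
  with a cluster-specific one (`shared_signal`, default 0.5). Relevant
  records in a real review all answer the same question; clusters are
  sub-topics of it;
* token-level mixture: each token of a relevant record comes from its
  cluster topic with probability `topic_mix` (default 0.3) and from the
  background otherwise, so relevant abstracts read as ordinary text with
  topical terms mixed in. This mixture is what makes a rare cluster
  genuinely *last to find*: its records look like background until one of
  them has been labeled;
* abstract lengths Poisson around 218 tokens, the mean abstract length of
  the motivating corpus; prevalence is exact by construction
  (`round(n × prevalence)`), and relevant records are allocated to clusters
  by largest-remainder rounding;
* generation is seeded with an explicitly pinned generator
  (Mersenne-Twister / inversion / rejection sampling), so a spec and seed
  give a byte-identical corpus on any platform.

The default fixture is 2,000 records at 1% prevalence with two clusters
weighted 0.85/0.15 — small enough that a full simulation suite runs in
minutes while preserving the imbalance and the rare-cluster phenomenon.
The 46,376-record / 0.14% shape of the motivating study is reachable by
configuration but is not exercised in the tests.

What the generator does **not** emulate: natural-language structure (word
order carries no signal, so the convolutional network's locality advantage
cannot show), concept drift over publication years, near-duplicate records,
and noisy labels. Passing tests therefore demonstrate that the engine,
metrics and models behave correctly and that ranking quality transfers to
corpora with token-level topical signal — not that any model ordering
observed here generalises to real review corpora.

## Metrics and their conventions

All metrics are functions of the trajectory. Conventions are fixed once and
echoed in every report, because the quantities are sensitive to them:

* priors are excluded from the pool size, the recall denominator and the
  step axis;
* `wss(traj, level)` = `(1 − s*/N) − (1 − level)` with `s*` the first step
  at which recall reaches `level`. With few relevant records the ceiling in
  "recall ≥ level" biases the random-screening expectation slightly above
  zero (for N = 100, R = 10 at the 95% level it is exactly 7/220 ≈ 0.032);
  the tests assert that exact expectation, not an idealised zero;
* `time_to_discovery()` never imputes: a record not discovered before
  termination, or given as a prior, simply has no TD in that run and is
  flagged;
* `rrf(traj, percent)` counts relevant records within the first
  `floor(percent × N)` steps and spans the whole trajectory in switched
  runs, including pre-switch steps;
* `rank_cohesion()` uses Spearman correlation on the discovery ranks of the
  relevant records common to two runs — rank-based because only the order
  is meaningful, and restricted to relevant records because irrelevant ones
  are screened mostly in bulk tails.

## Study conditions used by the tests

The dominance check runs the four shallow classifiers with tf-idf on the
default fixture (10 + 10 priors, termination on all-relevant-found) and
requires each WSS@95 to exceed the 97.5th percentile of a 1,000-permutation
random-screening null — around 0.25 under these conditions, against model
values around 0.94.

The switching check uses rare-cluster conditions (`shared_signal = 0.05`,
`topic_mix = 0.2`, priors 1 + 10): naive Bayes with tf-idf finds the common
cluster and then stalls, the consecutive-irrelevant trigger (k = 10, scaled
to the 2,000-record corpus) fires, and the run continues as logistic
regression on the wide document embedding. Over ten replicate seeds the
switched run's RRF@2% must match or exceed the unswitched naive Bayes run
in at least eight. At this corpus scale the outcome is honest equality on
nearly every replicate: both runs find the common cluster before the
trigger, and neither finds the nearly disjoint rare cluster within the 2%
budget (40 records). Probing the mechanism shows why: with almost no shared
signal, no embedding-based model ranks the unseen rare cluster above
background — indeed multinomial naive Bayes's smoothing quirk (unseen-word
mass is relatively larger in the small relevant class) ranks topical
outliers higher than the embedding models do. The large-corpus observation
that switching away from naive Bayes is almost always an improvement should
not be read into these desk-scale runs; what they verify is the hand-over
machinery and the non-inferiority of switching under stall conditions.

Problem sizes throughout the suite (200–2,000 records, vocabularies of
500–1,200, network training capped at a few epochs on 500-record fixtures)
were chosen so the full test suite and the acceptance script each run in a
few minutes on one core.

## Known limitations

* The deduplication rules (DOI, then normalised title, union-find merge,
  relevant-wins labels) are a documented stand-in; the motivating study's
  exact rules live in external scripts and are not reconstructed here.
* The spectral document embedding is a deliberate replacement for
  stochastic paragraph-vector training; it shares the objective family but
  not the training dynamics, so embedding-quality findings do not transfer
  to SGD-trained embeddings.
* Per-layer dropout rates and the dense width of the deep network are
  package defaults, not published values; only the totals named above are
  fixed points.
* Wall-clock timings recorded by `batch_simulate()` are observational
  metadata, not a benchmarking surface.
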