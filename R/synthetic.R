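# synthetic imbalanced clustered corpora: the test-bed for the whole engine.
# Relevant records are background text with cluster-topical terms mixed in
# (token-level mixture), which is what makes a rare cluster last-to-find:
# its records look like background until a record from it has been labeled.

#' Specification for a synthetic screening corpus
#'
#' Describes an imbalanced corpus of "bag of synthetic words" records in
#' which the few relevant records are concentrated in semantic clusters,
#' including (by default) one rare last-to-find cluster. Token distributions:
#' irrelevant records draw from a Zipf-Mandelbrot background over the
#' vocabulary; each token of a relevant record in cluster *k* comes with
#' probability `topic_mix` from cluster *k*'s topic distribution — the
#' background perturbed log-normally by a cluster-specific direction plus a
#' relevance direction shared by all clusters (relevant records in a real
#' review share the review question; clusters are sub-topics) — and
#' otherwise from the background, so relevant records read as ordinary text
#' with topical terms mixed in. `topic_sharpness` scales the perturbation:
#' at 0 the relevant distributions equal the background.
#'
#' @param n_records total record count.
#' @param prevalence fraction of relevant records, in (0, 1); the generated
#'   corpus holds exactly `round(n_records * prevalence)` relevant records.
#' @param n_clusters number of semantic clusters among relevant records.
#' @param cluster_weights fractions summing to 1; relevant records are
#'   allocated to clusters by largest-remainder rounding of these weights.
#' @param vocab_size synthetic vocabulary size.
#' @param topic_sharpness nonnegative concentration of the per-cluster word
#'   distributions (log-scale standard deviation of the perturbation).
#' @param shared_signal fraction in \[0, 1\] of the perturbation variance
#'   shared by all relevant clusters (0 = fully disjoint clusters).
#' @param topic_mix fraction in (0, 1\] of a relevant record's tokens drawn
#'   from its cluster topic rather than the background.
#' @param abstract_length_mean mean abstract length in tokens (Poisson).
#' @param seed integer; same spec + seed gives a byte-identical corpus.
#' @return object of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_records = 2000, prevalence = 0.01,
                                  n_clusters = 2,
                                  cluster_weights = c(0.85, 0.15),
                                  vocab_size = 1200, topic_sharpness = 3,
                                  shared_signal = 0.5, topic_mix = 0.3,
                                  abstract_length_mean = 218, seed = 1L) {
  assert_that(is_count(n_records, 1), "n_records must be a positive count")
  assert_that(prevalence > 0 && prevalence < 1, "prevalence must be in (0,1)")
  assert_that(is_count(n_clusters, 1), "n_clusters must be >= 1")
  assert_that(length(cluster_weights) == n_clusters,
              "cluster_weights length must equal n_clusters")
  assert_that(all(cluster_weights >= 0) &&
                abs(sum(cluster_weights) - 1) < 1e-9,
              "cluster_weights must be nonnegative and sum to 1")
  assert_that(topic_sharpness >= 0, "topic_sharpness must be nonnegative")
  assert_that(shared_signal >= 0 && shared_signal <= 1,
              "shared_signal must be in [0,1]")
  assert_that(topic_mix > 0 && topic_mix <= 1, "topic_mix must be in (0,1]")
  n_rel <- round(n_records * prevalence)
  if (n_rel < sum(cluster_weights > 0)) {
    stop("infeasible spec: ", n_rel, " relevant record(s) but ",
         sum(cluster_weights > 0), " positive-weight cluster(s)", call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 n_clusters = as.integer(n_clusters),
                 cluster_weights = cluster_weights,
                 vocab_size = as.integer(vocab_size),
                 topic_sharpness = topic_sharpness,
                 shared_signal = shared_signal, topic_mix = topic_mix,
                 abstract_length_mean = abstract_length_mean,
                 seed = as.integer(seed)),
            class = "synthetic_corpus_spec")
}

# exact integer allocation of n items over weights, largest remainder
largest_remainder <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic screening corpus
#'
#' @param spec a [synthetic_corpus_spec()].
#' @return list with `corpus` (a [corpus()]) and `truth`, the ground truth:
#'   `cluster_of` (named integer, cluster index per relevant record id) and
#'   `params` (echo of `spec`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  set_seed_stable(spec$seed)
  V <- spec$vocab_size
  vocab <- sprintf("w%05d", seq_len(V))
  n <- spec$n_records
  n_rel <- round(n * spec$prevalence)

  # Zipf-Mandelbrot background word distribution
  background <- 1 / (seq_len(V) + 2.7)^1.05
  background <- background / sum(background)

  g_shared <- stats::rnorm(V)
  topics <- lapply(seq_len(spec$n_clusters), function(k) {
    g_k <- stats::rnorm(V)
    g <- sqrt(spec$shared_signal) * g_shared + sqrt(1 - spec$shared_signal) * g_k
    p <- background * exp(spec$topic_sharpness * g)
    p / sum(p)
  })

  # token-level mixture: topic with prob topic_mix, else background
  mixed <- lapply(topics, function(tp) {
    spec$topic_mix * tp + (1 - spec$topic_mix) * background
  })

  alloc <- largest_remainder(n_rel, spec$cluster_weights)
  cluster_assign <- rep(seq_len(spec$n_clusters), times = alloc)

  rel_pos <- sort(sample.int(n, n_rel))
  labels <- rep("irrelevant", n)
  labels[rel_pos] <- "relevant"
  cluster_of_pos <- integer(n)
  cluster_of_pos[rel_pos] <- sample(cluster_assign) # shuffle cluster order

  lens <- pmax(10L, stats::rpois(n, spec$abstract_length_mean))
  title_lens <- pmax(3L, stats::rpois(n, 7))
  draw_doc <- function(len, dist) {
    paste(vocab[sample.int(V, len, replace = TRUE, prob = dist)], collapse = " ")
  }
  abstract <- character(n); title <- character(n)
  for (i in seq_len(n)) {
    dist <- if (labels[i] == "relevant") mixed[[cluster_of_pos[i]]] else background
    abstract[i] <- draw_doc(lens[i], dist)
    title[i] <- draw_doc(title_lens[i], dist)
  }
  ids <- sprintf("syn_%05d", seq_len(n))
  corp <- corpus(data.frame(record_id = ids, title = title,
                            abstract = abstract, label = labels,
                            stringsAsFactors = FALSE),
                 provenance = sprintf("synthetic seed=%d", spec$seed))
  cluster_of <- cluster_of_pos[rel_pos]
  names(cluster_of) <- ids[rel_pos]
  list(corpus = corp, truth = list(cluster_of = cluster_of, params = spec))
}

#' Token-overlap separability report for a synthetic corpus
#'
#' Advisory fixture sanity gate: compares mean pairwise Jaccard token
#' overlap within each relevant cluster, between clusters, and between
#' relevant records and a background sample of irrelevant records. For
#' sharply peaked topics the within-cluster overlap should strictly exceed
#' the relevant-vs-background overlap.
#'
#' @param corp a `corpus`.
#' @param truth ground truth from [generate_corpus()].
#' @param n_background number of irrelevant records sampled for the
#'   background comparison.
#' @return list with `within` (named per-cluster mean overlap), `between`
#'   (mean cross-cluster overlap, `NA` for a single cluster), and
#'   `background` (mean relevant-vs-irrelevant overlap).
#' @export
separability_check <- function(corp, truth, n_background = 50L) {
  stopifnot(inherits(corp, "corpus"))
  rel_ids <- names(truth$cluster_of)
  assert_that(all(rel_ids %in% corp$record_id),
              "ground truth ids not found in corpus")
  toks <- tokenize_text(paste(corp$title, corp$abstract))
  names(toks) <- corp$record_id
  sets <- lapply(toks, unique)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  mean_overlap <- function(ids_a, ids_b) {
    pairs <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    if (nrow(pairs) == 0L) return(NA_real_)
    mean(mapply(function(a, b) jac(sets[[a]], sets[[b]]), pairs$a, pairs$b))
  }
  clusters <- sort(unique(truth$cluster_of))
  within <- vapply(clusters, function(k) {
    ids <- rel_ids[truth$cluster_of == k]
    mean_overlap(ids, ids)
  }, numeric(1))
  names(within) <- paste0("cluster_", clusters)
  between <- if (length(clusters) < 2L) NA_real_ else {
    vals <- utils::combn(clusters, 2, function(p) {
      mean_overlap(rel_ids[truth$cluster_of == p[1]],
                   rel_ids[truth$cluster_of == p[2]])
    })
    mean(vals)
  }
  irrel_ids <- corp$record_id[!is_relevant(corp)]
  bg <- irrel_ids[seq_len(min(n_background, length(irrel_ids)))]
  background <- mean_overlap(rel_ids, bg)
  list(within = within, between = between, background = background)
}
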