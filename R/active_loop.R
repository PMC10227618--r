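# the screening engine: prior selection, rebalanced retraining,
# certainty-based sampling, stop rules, and mid-review model switching

#' Stop rule for a screening run
#'
#' @param kind `"all_relevant_found"` (terminate once every relevant record
#'   in the corpus is labeled), `"consecutive_irrelevant"` (terminate after
#'   `k` uninterrupted irrelevant labels), or `"budget"` (terminate after
#'   `n` screened records). When several listed rules fire at the same step
#'   the first-listed rule wins.
#' @param k run length for `consecutive_irrelevant`.
#' @param n screening budget for `budget`.
#' @return object of class `stop_rule`.
#' @export
stop_rule <- function(kind = c("all_relevant_found", "consecutive_irrelevant",
                               "budget"), k = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (kind == "consecutive_irrelevant") assert_that(is_count(k, 1), "k must be >= 1")
  if (kind == "budget") assert_that(is_count(n, 1), "n_screened must be >= 1")
  structure(list(kind = kind, k = k, n = n), class = "stop_rule")
}

#' Select prior knowledge
#'
#' Uniform seeded sampling without replacement within each label class.
#'
#' @param corp a `corpus`.
#' @param n_relevant,n_irrelevant how many records of each class to reveal
#'   to the model before the loop starts.
#' @param seed integer.
#' @return object of class `prior_set`: list of `relevant_ids`,
#'   `irrelevant_ids`, `seed`.
#' @export
select_priors <- function(corp, n_relevant = 1L, n_irrelevant = 10L, seed = 1L) {
  stopifnot(inherits(corp, "corpus"))
  rel <- corp$record_id[is_relevant(corp)]
  irr <- corp$record_id[corp$label == "irrelevant"]
  if (length(rel) < n_relevant || length(irr) < n_irrelevant) {
    stop(sprintf("prior error: corpus has %d relevant / %d irrelevant, need %d / %d",
                 length(rel), length(irr), n_relevant, n_irrelevant), call. = FALSE)
  }
  set_seed_stable(seed)
  structure(list(relevant_ids = sample(rel, n_relevant),
                 irrelevant_ids = sample(irr, n_irrelevant),
                 seed = as.integer(seed)),
            class = "prior_set")
}

#' Prior sweep: one prior set per relevant record
#'
#' The run-per-inclusion protocol: one run per relevant record, each seeded
#' with that single relevant record plus a common set of randomly chosen
#' irrelevant records held constant across runs.
#'
#' @param corp a `corpus`.
#' @param n_irrelevant irrelevant priors shared by every set.
#' @param seed integer (used once, for the shared irrelevant sample).
#' @return list of `prior_set`s, one per relevant record.
#' @export
sweep_priors <- function(corp, n_irrelevant = 10L, seed = 1L) {
  stopifnot(inherits(corp, "corpus"))
  rel <- corp$record_id[is_relevant(corp)]
  irr <- corp$record_id[corp$label == "irrelevant"]
  assert_that(length(rel) >= 1, "corpus has no relevant records")
  assert_that(length(irr) >= n_irrelevant, "not enough irrelevant records")
  set_seed_stable(seed)
  shared_irr <- sample(irr, n_irrelevant)
  lapply(rel, function(r) {
    structure(list(relevant_ids = r, irrelevant_ids = shared_irr,
                   seed = as.integer(seed)), class = "prior_set")
  })
}

#' Rebalance a labeled training set
#'
#' Oversamples relevant ids (with replacement for the fractional part) until
#' the relevant:irrelevant ratio reaches `target_ratio`, capped at
#' `max_dup` duplications per record. The set of distinct ids is unchanged;
#' only multiplicities change. This replaces per-class loss weighting in
#' every classifier, including the neural ones.
#'
#' @param ids record ids of the labeled rows.
#' @param labels logical or 0/1 vector aligned with `ids` (1 = relevant).
#' @param strategy `"oversample_relevant"` or `"none"`.
#' @param seed integer, drives the fractional-part sampling.
#' @param target_ratio desired relevant:irrelevant ratio (default 1).
#' @param max_dup cap on copies per relevant id (default 100).
#' @return character vector of ids, a training multiset.
#' @export
balance_labels <- function(ids, labels, strategy = c("oversample_relevant", "none"),
                           seed = 1L, target_ratio = 1, max_dup = 100L) {
  strategy <- match.arg(strategy)
  y <- as.logical(labels)
  assert_that(any(y) && any(!y), "balance error: both classes must be present")
  if (strategy == "none") return(ids)
  rel <- ids[y]; irr <- ids[!y]
  want <- min(round(length(irr) * target_ratio), length(rel) * max_dup)
  if (length(rel) >= want) return(ids)
  full <- want %/% length(rel)
  rem <- want - full * length(rel)
  set_seed_stable(seed)
  extra <- if (rem > 0) sample(rel, rem) else character(0)
  c(rep(rel, full), extra, irr)
}

new_trajectory <- function(steps, priors, corpus_size, n_priors,
                           relevant_ids, switch_step, termination, seed) {
  structure(steps,
            priors = priors, corpus_size = corpus_size, n_priors = n_priors,
            relevant_ids = relevant_ids, switch_step = switch_step,
            termination = termination, seed = seed,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d steps over %d records (%d priors), %d relevant found, terminated by %s%s\n",
              nrow(x), attr(x, "corpus_size"), attr(x, "n_priors"),
              sum(x$label == "relevant"), attr(x, "termination"),
              if (!is.na(attr(x, "switch_step")))
                sprintf(", switched at step %d", attr(x, "switch_step")) else ""))
  invisible(x)
}

# first 1-based position ending a run of k consecutive FALSE (irrelevant)
# labels, or NA if no such run exists
first_consecutive_run <- function(relevant, k) {
  run <- 0L
  for (i in seq_along(relevant)) {
    run <- if (relevant[i]) 0L else run + 1L
    if (run >= k) return(i)
  }
  NA_integer_
}

check_stop <- function(rules, found_all, consec_irrelevant, n_screened) {
  for (r in rules) {
    fired <- switch(r$kind,
      all_relevant_found = found_all,
      consecutive_irrelevant = consec_irrelevant >= r$k,
      budget = n_screened >= r$n)
    if (fired) return(r$kind)
  }
  NULL
}

# shared engine: phases is a list of list(features, model_config, tag);
# trigger (a stop_rule) moves from phase 1 to phase 2 once, if present.
run_engine <- function(corp, phases, priors, stop_rules, seed,
                       train_every_n = 1L, trigger = NULL,
                       make_features = NULL) {
  stopifnot(inherits(corp, "corpus"), inherits(priors, "prior_set"))
  ids <- corp$record_id
  truth_rel <- is_relevant(corp)
  names(truth_rel) <- ids
  prior_ids <- c(priors$relevant_ids, priors$irrelevant_ids)
  assert_that(all(prior_ids %in% ids), "prior ids not found in corpus")
  pool <- setdiff(ids, prior_ids) # canonical corpus order
  assert_that(length(pool) > 0, "simulation error: empty pool at start")
  n_rel_total <- sum(truth_rel)

  phase <- 1L
  cur <- phases[[phase]]
  if (is.null(cur$features)) cur$features <- make_features(cur)
  labeled <- prior_ids
  steps <- vector("list", length(pool))
  n_screened <- 0L; consec <- 0L
  switch_step <- NA_integer_
  termination <- "pool_exhausted"
  scores <- NULL

  repeat {
    step <- n_screened + 1L
    step_seed <- derive_seed(seed, step)
    if (is.null(scores) || (step - 1L) %% train_every_n == 0L) {
      bal <- balance_labels(labeled, truth_rel[labeled],
                            strategy = "oversample_relevant", seed = step_seed)
      cfg <- cur$model_config
      cfg$seed <- step_seed
      model <- train_model(cfg, subset_features(cur$features, bal),
                           truth_rel[bal],
                           rule = cur$rule %||% NULL)
      scores <- predict_relevance(model, subset_features(cur$features, pool))
    }
    pick <- which.max(scores) # ties: which.max takes the first = corpus order
    rid <- pool[pick]
    rel <- truth_rel[[rid]]
    n_screened <- step
    steps[[step]] <- data.frame(step = step, record_id = rid,
                                label = if (rel) "relevant" else "irrelevant",
                                model_tag = cur$tag,
                                score = unname(scores[pick]),
                                stringsAsFactors = FALSE)
    labeled <- c(labeled, rid)
    pool <- pool[-pick]
    scores <- scores[-pick]
    consec <- if (rel) 0L else consec + 1L
    found_all <- sum(truth_rel[labeled]) == n_rel_total

    fired <- check_stop(stop_rules, found_all, consec, n_screened)
    if (!is.null(fired)) { termination <- fired; break }
    if (length(pool) == 0L) break

    if (phase == 1L && !is.null(trigger)) {
      trig <- switch(trigger$kind,
        consecutive_irrelevant = consec >= trigger$k,
        budget = n_screened >= trigger$n,
        FALSE)
      if (trig) {
        switch_step <- n_screened
        phase <- 2L
        cur <- phases[[phase]]
        if (is.null(cur$features)) cur$features <- make_features(cur)
        scores <- NULL # force retrain under the new model
        consec <- 0L
      }
    }
  }
  steps <- do.call(rbind, steps[seq_len(n_screened)])
  new_trajectory(steps, priors, nrow(corp),
                 length(prior_ids),
                 setdiff(ids[truth_rel], prior_ids),
                 switch_step, termination, as.integer(seed))
}

#' Simulate a certainty-based screening run
#'
#' The core loop: train on the balanced labeled set, score every unlabeled
#' record, screen the highest-scoring record (certainty-based sampling),
#' reveal its true label, append the step, and repeat until a stop rule
#' fires or the pool empties. Score ties are broken by canonical corpus
#' order. Fully seeded: per-step training seeds are derived from `seed`, so
#' identical inputs reproduce identical trajectories.
#'
#' @param corp a labeled `corpus`.
#' @param feature_config a [feature_config()] (ignored when `features` is
#'   supplied).
#' @param model_config a [model_config()].
#' @param priors a [select_priors()] result.
#' @param stop_rules list of [stop_rule()]s, first-listed wins.
#' @param seed integer run seed.
#' @param train_every_n retrain cadence in steps (default 1: retrain after
#'   every label, the live-review ideal).
#' @param features optional pre-fitted `feature_matrix` over the corpus.
#' @param rule optional [early_stop_rule()] forwarded to neural trainers.
#' @return a `trajectory`: one row per screening step (`step`, `record_id`,
#'   `label`, `model_tag`, `score`), with priors, corpus size, switch step
#'   and the terminating rule as attributes.
#' @export
simulate_screening <- function(corp, feature_config, model_config, priors,
                               stop_rules = list(stop_rule("all_relevant_found")),
                               seed = 1L, train_every_n = 1L, features = NULL,
                               rule = NULL) {
  if (is.null(features)) features <- fit_features(corp, feature_config)
  tag <- paste0(model_config$name, "+", features$config$method)
  run_engine(corp,
             phases = list(list(features = features, model_config = model_config,
                                tag = tag, rule = rule)),
             priors = priors, stop_rules = stop_rules, seed = seed,
             train_every_n = train_every_n)
}

#' Model-switching policy
#'
#' @param trigger a [stop_rule()] of kind `consecutive_irrelevant` or
#'   `budget`; `all_relevant_found` is not a meaningful hand-over trigger.
#' @param from,to each a list with elements `feature_config` and
#'   `model_config` (and optionally `rule`).
#' @return object of class `switch_policy`.
#' @export
switch_policy <- function(trigger, from, to) {
  stopifnot(inherits(trigger, "stop_rule"))
  if (trigger$kind == "all_relevant_found") {
    stop("policy error: trigger cannot be of kind all_relevant_found", call. = FALSE)
  }
  structure(list(trigger = trigger, from = from, to = to),
            class = "switch_policy")
}

#' Run a screening simulation with mid-review model switching
#'
#' Runs the `from` model until the trigger fires, then continues with the
#' `to` model over the same corpus, retaining all revealed labels and
#' priors. Features for the `to` model are computed once at switch time from
#' the whole corpus if its feature configuration differs. Step indices
#' continue without reset and the trajectory records the switch step and the
#' per-step model tag.
#'
#' @param corp a labeled `corpus`.
#' @param policy a [switch_policy()].
#' @param priors a [select_priors()] result.
#' @param stop_rules list of [stop_rule()]s.
#' @param seed integer run seed.
#' @param train_every_n retrain cadence.
#' @return a `trajectory` (see [simulate_screening()]).
#' @export
run_switch <- function(corp, policy, priors,
                       stop_rules = list(stop_rule("all_relevant_found")),
                       seed = 1L, train_every_n = 1L) {
  stopifnot(inherits(policy, "switch_policy"))
  same_features <- identical(policy$from$feature_config, policy$to$feature_config)
  from_features <- policy$from$features %||%
    fit_features(corp, policy$from$feature_config)
  to_features <- if (same_features) from_features else policy$to$features
  phases <- list(
    list(features = from_features, model_config = policy$from$model_config,
         tag = paste0(policy$from$model_config$name, "+",
                      policy$from$feature_config$method),
         rule = policy$from$rule %||% NULL),
    list(features = to_features, model_config = policy$to$model_config,
         tag = paste0(policy$to$model_config$name, "+",
                      policy$to$feature_config$method),
         rule = policy$to$rule %||% NULL)
  )
  run_engine(corp, phases, priors, stop_rules, seed,
             train_every_n = train_every_n, trigger = policy$trigger,
             make_features = function(phase_spec) {
               fit_features(corp, policy$to$feature_config)
             })
}

#' Batch simulation over a model grid
#'
#' Runs [simulate_screening()] for every valid (feature, classifier)
#' combination with shared priors and seed; invalid pairings are skipped
#' with a logged finding, and feature matrices are fitted once per distinct
#' feature configuration. Elapsed feature-extraction and mean per-iteration
#' times are recorded as observational metadata.
#'
#' @param corp a labeled `corpus`.
#' @param grid list of `list(feature_config = , model_config = )` pairs.
#' @param priors a [select_priors()] result.
#' @param stop_rules list of [stop_rule()]s.
#' @param seed integer shared run seed.
#' @param train_every_n retrain cadence.
#' @return list with `trajectories` (named by `classifier+feature`) and
#'   `log`, a data.frame of per-combination status and timings.
#' @export
batch_simulate <- function(corp, grid, priors,
                           stop_rules = list(stop_rule("all_relevant_found")),
                           seed = 1L, train_every_n = 1L) {
  assert_that(length(grid) > 0, "batch error: empty grid")
  feature_cache <- list()
  feature_time <- list()
  trajectories <- list()
  log_rows <- list()
  for (g in grid) {
    fc <- g$feature_config; mc <- g$model_config
    tag <- paste0(mc$name, "+", fc$method)
    key <- paste(fc$method, fc$dim, sep = "_")
    if (is.null(feature_cache[[key]])) {
      t0 <- proc.time()[["elapsed"]]
      feature_cache[[key]] <- fit_features(corp, fc)
      feature_time[[key]] <- proc.time()[["elapsed"]] - t0
    }
    feats <- feature_cache[[key]]
    v <- validate_pairing(mc$name, feats)
    if (!isTRUE(v)) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        combination = tag, status = "skipped", finding = v$message,
        feature_seconds = feature_time[[key]], iteration_seconds = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    traj <- simulate_screening(corp, fc, mc, priors, stop_rules, seed = seed,
                               train_every_n = train_every_n, features = feats)
    dt <- proc.time()[["elapsed"]] - t0
    trajectories[[tag]] <- traj
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      combination = tag, status = "ok", finding = "",
      feature_seconds = feature_time[[key]],
      iteration_seconds = dt / max(nrow(traj), 1L),
      stringsAsFactors = FALSE)
  }
  list(trajectories = trajectories, log = do.call(rbind, log_rows))
}
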