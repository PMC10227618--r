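oracle_config <- function(corp) {
  truth <- as.numeric(corp$label == "relevant")
  names(truth) <- corp$record_id
  model_config("oracle", list(truth = truth))
}

test_that("prior selection respects class counts, seeds and sweep mode", {
  g <- small_synth(seed = 2, n = 300, prevalence = 0.05) # 15 relevant
  corp <- g$corpus
  p1 <- select_priors(corp, 1, 10, seed = 4)
  expect_length(p1$relevant_ids, 1)
  expect_length(p1$irrelevant_ids, 10)
  expect_true(all(corp$label[match(p1$relevant_ids, corp$record_id)] == "relevant"))
  expect_identical(select_priors(corp, 1, 10, seed = 4), p1)

  p2 <- select_priors(corp, 10, 10, seed = 4)
  expect_length(c(p2$relevant_ids, p2$irrelevant_ids), 20)

  sweep <- sweep_priors(corp, n_irrelevant = 10, seed = 4)
  expect_length(sweep, 15)
  expect_setequal(vapply(sweep, function(p) p$relevant_ids, character(1)),
                  corp$record_id[corp$label == "relevant"])
  # the irrelevant set is held constant across runs
  expect_length(unique(lapply(sweep, function(p) p$irrelevant_ids)), 1)

  expect_error(select_priors(corp, 100, 10, seed = 1), "prior error")
})

test_that("the balancer oversamples relevant ids to the target ratio", {
  ids <- paste0("r", 1:11)
  labels <- c(TRUE, rep(FALSE, 10))
  bal <- balance_labels(ids, labels, "oversample_relevant", seed = 1)
  expect_equal(sum(bal == "r1"), 10)
  expect_equal(sum(bal != "r1"), 10)
  expect_setequal(unique(bal), ids)
  # identity strategy and balanced fixed point
  expect_identical(balance_labels(ids, labels, "none"), ids)
  even <- balance_labels(paste0("x", 1:10), rep(c(TRUE, FALSE), 5),
                         "oversample_relevant", seed = 1)
  expect_setequal(even, paste0("x", 1:10))
  expect_length(even, 10)
  expect_error(balance_labels(ids, rep(TRUE, 11)), "both classes")
})

test_that("an oracle scorer screens every relevant record before any irrelevant", {
  g <- small_synth(seed = 5, n = 200, prevalence = 0.1)
  corp <- g$corpus
  pri <- select_priors(corp, 1, 5, seed = 2)
  traj <- simulate_screening(corp, feature_config("tfidf"), oracle_config(corp),
                             pri, list(stop_rule("budget", n = 50)), seed = 3)
  n_rel <- length(attr(traj, "relevant_ids"))
  expect_equal(traj$label[seq_len(n_rel)], rep("relevant", n_rel))
  expect_equal(traj$label[(n_rel + 1):50], rep("irrelevant", 50 - n_rel))
  # ties among equal scores are broken by canonical corpus order
  rel_ids <- corp$record_id[corp$label == "relevant"]
  expect_equal(traj$record_id[seq_len(n_rel)],
               setdiff(rel_ids, pri$relevant_ids))
})

test_that("all_relevant_found terminates on the last undiscovered relevant record", {
  g <- small_synth(seed = 6, n = 200, prevalence = 0.1)
  corp <- g$corpus
  pri <- select_priors(corp, 1, 5, seed = 2)
  traj <- simulate_screening(corp, feature_config("tfidf"), oracle_config(corp),
                             pri, seed = 3)
  expect_equal(attr(traj, "termination"), "all_relevant_found")
  expect_equal(traj$label[nrow(traj)], "relevant")
  expect_equal(sum(traj$label == "relevant"), length(attr(traj, "relevant_ids")))
})

test_that("a pool-sized budget screens every non-prior record exactly once", {
  g <- small_synth(seed = 7, n = 80, prevalence = 0.1)
  corp <- g$corpus
  pri <- select_priors(corp, 1, 4, seed = 1)
  pool_n <- nrow(corp) - 5
  traj <- simulate_screening(corp, feature_config("tfidf"),
                             model_config("naive_bayes"), pri,
                             list(stop_rule("budget", n = pool_n)), seed = 2)
  expect_equal(nrow(traj), pool_n)
  expect_false(any(duplicated(traj$record_id)))
  expect_length(intersect(traj$record_id,
                          c(pri$relevant_ids, pri$irrelevant_ids)), 0)
  expect_equal(traj$step, seq_len(pool_n))
  # final recall is 1
  expect_equal(sum(traj$label == "relevant"),
               length(attr(traj, "relevant_ids")))
})

test_that("identical inputs and seed reproduce identical trajectories", {
  g <- small_synth(seed = 9, n = 150, prevalence = 0.08)
  pri <- select_priors(g$corpus, 1, 8, seed = 5)
  run <- function() simulate_screening(g$corpus, feature_config("tfidf"),
                                       model_config("random_forest"), pri,
                                       list(stop_rule("budget", n = 25)),
                                       seed = 17)
  expect_identical(as.data.frame(run()), as.data.frame(run()))
})

test_that("the consecutive-irrelevant trigger fires exactly at the brute-force step", {
  set.seed(31)
  for (i in 1:100) {
    labels <- runif(sample(5:60, 1)) < 0.25 # TRUE = relevant
    k <- sample(1:8, 1)
    got <- screensim:::first_consecutive_run(labels, k)
    # brute force: scan every position for a full window of irrelevant labels
    brute <- NA_integer_
    for (s in seq_along(labels)) {
      if (s >= k && all(!labels[(s - k + 1):s])) { brute <- s; break }
    }
    expect_identical(got, brute)
  }
})

test_that("run_switch hands over at the trigger and retains all labels", {
  g <- small_synth(seed = 12, n = 150, prevalence = 0.06)
  corp <- g$corpus
  pri <- select_priors(corp, 1, 6, seed = 3)
  pol <- switch_policy(
    stop_rule("consecutive_irrelevant", k = 3),
    from = list(feature_config = feature_config("tfidf"),
                model_config = oracle_config(corp)),
    to = list(feature_config = feature_config("tfidf"),
              model_config = model_config("naive_bayes")))
  traj <- run_switch(corp, pol, pri, list(stop_rule("budget", n = 40)), seed = 2)
  sw <- attr(traj, "switch_step")
  # oracle screens relevant first, then 3 consecutive irrelevant fire the trigger
  n_rel <- length(attr(traj, "relevant_ids"))
  expect_equal(sw, n_rel + 3L)
  expect_equal(unique(traj$model_tag[seq_len(sw)]), "oracle+tfidf")
  expect_equal(unique(traj$model_tag[(sw + 1):nrow(traj)]), "naive_bayes+tfidf")
  expect_false(any(duplicated(traj$record_id)))
  expect_equal(traj$step, seq_len(nrow(traj)))
})

test_that("switching to an identical model reproduces the unswitched run bit-for-bit", {
  g <- small_synth(seed = 13, n = 200, prevalence = 0.05)
  corp <- g$corpus
  pri <- select_priors(corp, 1, 8, seed = 6)
  budget <- list(stop_rule("budget", n = 60))
  for (nm in c("naive_bayes", "logistic_regression")) {
    plain <- simulate_screening(corp, feature_config("tfidf"),
                                model_config(nm), pri, budget, seed = 4)
    pol <- switch_policy(
      stop_rule("consecutive_irrelevant", k = 5),
      from = list(feature_config = feature_config("tfidf"),
                  model_config = model_config(nm)),
      to = list(feature_config = feature_config("tfidf"),
                model_config = model_config(nm)))
    switched <- run_switch(corp, pol, pri, budget, seed = 4)
    expect_identical(plain$record_id, switched$record_id, label = nm)
    expect_identical(plain$score, switched$score, label = nm)
    expect_identical(plain$label, switched$label, label = nm)
  }
})

test_that("an all_relevant_found trigger is a policy error", {
  expect_error(switch_policy(stop_rule("all_relevant_found"),
                             from = list(), to = list()),
               "policy error")
})

test_that("batch simulation skips invalid pairings and matches single runs", {
  g <- small_synth(seed = 15, n = 150, prevalence = 0.08)
  pri <- select_priors(g$corpus, 1, 6, seed = 2)
  budget <- list(stop_rule("budget", n = 20))
  grid <- list(
    list(feature_config = feature_config("tfidf"),
         model_config = model_config("naive_bayes")),
    list(feature_config = feature_config("doc_embedding"),
         model_config = model_config("naive_bayes")),
    list(feature_config = feature_config("tfidf"),
         model_config = model_config("nn_2_layer")),
    list(feature_config = feature_config("doc_embedding"),
         model_config = model_config("logistic_regression")))
  b <- batch_simulate(g$corpus, grid, pri, budget, seed = 8)
  expect_named(b$trajectories,
               c("naive_bayes+tfidf", "logistic_regression+doc_embedding"))
  expect_equal(b$log$status, c("ok", "skipped", "skipped", "ok"))
  expect_match(b$log$finding[2], "negative values")
  expect_match(b$log$finding[3], "too wide")

  single <- simulate_screening(g$corpus, feature_config("tfidf"),
                               model_config("naive_bayes"), pri, budget,
                               seed = 8)
  expect_identical(as.data.frame(b$trajectories[["naive_bayes+tfidf"]]),
                   as.data.frame(single))

  b2 <- batch_simulate(g$corpus, grid, pri, budget, seed = 8)
  expect_identical(lapply(b$trajectories, as.data.frame),
                   lapply(b2$trajectories, as.data.frame))
  expect_error(batch_simulate(g$corpus, list(), pri, budget, seed = 1),
               "empty grid")
})
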