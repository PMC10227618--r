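# a handmade trajectory over a virtual corpus: N non-prior records, given
# relevant positions; priors counted separately
fake_traj <- function(rel_positions, n_steps, corpus_size, n_priors = 0L,
                      extra_relevant = character(0), tag = "m") {
  labels <- ifelse(seq_len(n_steps) %in% rel_positions, "relevant", "irrelevant")
  ids <- sprintf("f%04d", seq_len(n_steps))
  df <- data.frame(step = seq_len(n_steps), record_id = ids, label = labels,
                   model_tag = tag, score = 1 - seq_len(n_steps) / n_steps,
                   stringsAsFactors = FALSE)
  screensim:::new_trajectory(
    df,
    priors = structure(list(relevant_ids = character(0),
                            irrelevant_ids = character(0), seed = 1L),
                       class = "prior_set"),
    corpus_size = corpus_size, n_priors = n_priors,
    relevant_ids = c(ids[labels == "relevant"], extra_relevant),
    switch_step = NA_integer_, termination = "budget", seed = 1L)
}

test_that("recall curves accumulate relevant finds and respect conservation", {
  traj <- fake_traj(1:10, 20, 120)
  rc <- recall_curve(traj)
  expect_equal(rc$n_relevant_found[10], 10)
  expect_equal(rc$n_relevant_found[20], 10)
  expect_true(all(diff(rc$n_relevant_found) >= 0))

  flat <- fake_traj(6:8, 10, 50)
  expect_equal(recall_curve(flat)$n_relevant_found[1:5], rep(0, 5))
  # conservation: final curve value + undiscovered = total non-prior relevant
  part <- fake_traj(c(2, 4), 10, 50, extra_relevant = c("u1", "u2"))
  expect_equal(recall_curve(part)$n_relevant_found[10] +
                 length(attr(time_to_discovery(part), "undiscovered")),
               length(attr(part, "relevant_ids")))
})

test_that("wss reproduces the closed-form oracle and worst-case values", {
  oracle <- fake_traj(1:10, 100, 100)
  expect_equal(as.numeric(wss(oracle, 0.95)), 0.85)
  expect_equal(attr(wss(oracle, 0.95), "s_star"), 10L)
  worst <- fake_traj(91:100, 100, 100)
  expect_equal(as.numeric(wss(worst, 0.95)), -0.05)
  # logical-vector interface agrees
  rel <- c(rep(TRUE, 10), rep(FALSE, 90))
  expect_equal(as.numeric(wss(rel, 0.95, total_records = 100)), 0.85)
  # level not reached is flagged, not fabricated
  short <- fake_traj(1:5, 8, 100, extra_relevant = paste0("u", 1:5))
  expect_true(is.na(wss(short, 0.95)))
  expect_equal(attr(wss(short, 0.95), "reason"), "level_not_reached")
  expect_error(wss(oracle, 1.5), "level must be")
})

test_that("wss stays inside its bounds for random trajectories", {
  # bounds: the worst ranking puts the level-reaching step at N, giving
  # -(1 - level); the perfect ranking attains it at ceil(level * R), the
  # closed-form maximum
  set.seed(77)
  n <- 60; r <- 6; level <- 0.95
  best <- (1 - ceiling(level * r) / n) - (1 - level)
  for (i in 1:50) {
    traj <- fake_traj(sample.int(n, r), n, n)
    v <- as.numeric(wss(traj, level))
    expect_gte(v, -(1 - level))
    expect_lte(v, best)
  }
  oracle <- fake_traj(seq_len(r), n, n)
  expect_equal(as.numeric(wss(oracle, level)), best)
})

test_that("monte-carlo wss over random permutations matches the exact expectation", {
  # independent oracle: E[WSS@95] for N=100, R=10 equals 7/220 because recall
  # 0.95 needs all 10 relevant, so s* is the max of 10 positions drawn
  # without replacement: E[s*] = 10 * 101 / 11
  exact <- 1 - (10 * 101 / 11) / 100 - 0.05
  set.seed(123)
  vals <- replicate(10000, {
    rel <- logical(100)
    rel[sample.int(100, 10)] <- TRUE
    as.numeric(wss(rel, 0.95, total_records = 100))
  })
  expect_lt(abs(mean(vals) - exact), 0.005)
})

test_that("time to discovery averages over runs and excludes prior runs", {
  a <- fake_traj(c(7), 10, 50)
  expect_equal(time_to_discovery(a)$td, 7)
  # same record discovered at different steps in two runs
  mk <- function(step_of_x) {
    df <- data.frame(step = 1:15,
                     record_id = c(sprintf("o%02d", 1:(step_of_x - 1)), "x",
                                   sprintf("p%02d", (step_of_x + 1):15)),
                     label = ifelse(1:15 == step_of_x, "relevant", "irrelevant"),
                     model_tag = "m", score = 0, stringsAsFactors = FALSE)
    screensim:::new_trajectory(df, priors = structure(
      list(relevant_ids = character(0), irrelevant_ids = character(0),
           seed = 1L), class = "prior_set"),
      corpus_size = 50, n_priors = 0L, relevant_ids = "x",
      switch_step = NA_integer_, termination = "budget", seed = 1L)
  }
  td <- time_to_discovery(list(mk(7), mk(13)))
  expect_equal(td$td[td$record_id == "x"], 10)
  expect_equal(td$n_runs[td$record_id == "x"], 2)
  expect_equal(as.numeric(atd(td)), 10)

  # run where the record is a prior contributes nothing
  prior_run <- screensim:::new_trajectory(
    data.frame(step = 1:3, record_id = c("a", "b", "c"),
               label = "irrelevant", model_tag = "m", score = 0,
               stringsAsFactors = FALSE),
    priors = structure(list(relevant_ids = "x", irrelevant_ids = character(0),
                            seed = 1L), class = "prior_set"),
    corpus_size = 50, n_priors = 1L, relevant_ids = character(0),
    switch_step = NA_integer_, termination = "budget", seed = 1L)
  td2 <- time_to_discovery(list(mk(3), prior_run))
  expect_equal(td2$td[td2$record_id == "x"], 3)
  expect_equal(td2$n_runs[td2$record_id == "x"], 1)
})

test_that("rrf counts relevant records up to the percentage cut", {
  traj <- fake_traj(c(2, 4, 6, 8, 10), 50, 1000)
  expect_equal(as.numeric(rrf(traj, 0.01, 1000)), 5) # cut = 10
  expect_equal(as.numeric(rrf(traj, 0.005, 1000)), 2) # cut = 5
  # truncated trajectories are flagged
  r <- rrf(traj, 0.2, 1000)
  expect_true(attr(r, "truncated"))
  expect_equal(as.numeric(r), 5)
  # monotone in percent; saturation at full screening
  full <- fake_traj(c(3, 20, 40), 50, 50)
  vals <- vapply(c(0.1, 0.4, 0.8, 1), function(p)
    as.numeric(rrf(full, p, 50)), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[4], 3)
  expect_error(rrf(traj, 0), "percent must be")
})

test_that("rrf on a switched trajectory spans pre- and post-switch steps", {
  df <- data.frame(step = 1:10,
                   record_id = sprintf("s%02d", 1:10),
                   label = c("relevant", "relevant", rep("irrelevant", 3),
                             "relevant", "relevant", "relevant",
                             "irrelevant", "irrelevant"),
                   model_tag = c(rep("nb+tfidf", 5), rep("lr+emb", 5)),
                   score = 0, stringsAsFactors = FALSE)
  traj <- screensim:::new_trajectory(df, priors = structure(
    list(relevant_ids = character(0), irrelevant_ids = character(0),
         seed = 1L), class = "prior_set"),
    corpus_size = 500, n_priors = 0L,
    relevant_ids = df$record_id[df$label == "relevant"],
    switch_step = 5L, termination = "budget", seed = 1L)
  expect_equal(as.numeric(rrf(traj, 0.02, 500)), 5) # 2 pre + 3 post switch
})

test_that("rank cohesion matrices are symmetric with unit diagonal", {
  t1 <- fake_traj(c(1, 3, 5, 7), 20, 100)
  expect_equal(unname(rank_cohesion(list(a = t1, b = t1))["a", "b"]), 1)
  # exactly reversed discovery order
  rev_df <- as.data.frame(t1)
  rel_ids <- rev_df$record_id[rev_df$label == "relevant"]
  rev_df$record_id[rev_df$label == "relevant"] <- rev(rel_ids)
  t2 <- screensim:::new_trajectory(rev_df, priors = attr(t1, "priors"),
                                   corpus_size = 100, n_priors = 0L,
                                   relevant_ids = rel_ids,
                                   switch_step = NA_integer_,
                                   termination = "budget", seed = 1L)
  expect_equal(unname(rank_cohesion(list(a = t1, b = t2))["a", "b"]), -1)

  t3 <- fake_traj(c(2, 3, 9, 11), 20, 100)
  m <- rank_cohesion(list(x = t1, y = t2, z = t3))
  expect_equal(dim(m), c(3, 3))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_true(all(m >= -1 & m <= 1, na.rm = TRUE))

  # fewer than two common relevant records leaves the entry undefined
  t4 <- fake_traj(1, 4, 100)
  expect_true(is.na(rank_cohesion(list(t1, t4))[1, 2]))
  expect_error(rank_cohesion(list(t1)), "at least two")
})

test_that("corpus fraction reproduces the printed one-decimal percentages", {
  expect_equal(corpus_fraction(587, 46376), 1.3)
  expect_equal(corpus_fraction(0, 500), 0)
  expect_equal(corpus_fraction(500, 500), 100)
  expect_error(corpus_fraction(5, 0), "total_records")
  expect_error(corpus_fraction(10, 5), "cannot exceed")
})

test_that("metrics reports assemble every statistic with convention echo", {
  traj <- fake_traj(1:5, 30, 200)
  rep <- metrics_report(traj, wss_levels = c(0.8, 0.95),
                        rrf_percents = c(0.05, 0.1), total_records = 200)
  expect_named(rep$wss, c("wss@80%", "wss@95%"))
  expect_named(rep$rrf, c("rrf@5%", "rrf@10%"))
  expect_equal(as.numeric(rep$rrf[["rrf@5%"]]), 5)
  expect_equal(nrow(rep$td), 5)
  expect_match(rep$conventions$priors, "excluded")
})

test_that("trajectory logs round-trip through structured text", {
  g <- small_synth(seed = 3, n = 100, prevalence = 0.08)
  pri <- select_priors(g$corpus, 1, 5, seed = 1)
  traj <- simulate_screening(g$corpus, feature_config("tfidf"),
                             model_config("naive_bayes"), pri,
                             list(stop_rule("budget", n = 15)), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_identical(as.data.frame(traj), as.data.frame(back))
  expect_identical(attr(traj, "relevant_ids"), attr(back, "relevant_ids"))
  expect_identical(attr(traj, "corpus_size"), attr(back, "corpus_size"))
  expect_identical(attr(traj, "termination"), attr(back, "termination"))
  # metrics computed from the log equal metrics from the in-memory object
  expect_equal(as.numeric(wss(back, 0.5)), as.numeric(wss(traj, 0.5)))
})
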