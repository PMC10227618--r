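# evaluation statistics over screening trajectories

traj_relevant <- function(traj) traj$label == "relevant"

#' Recall curve of a trajectory
#'
#' Cumulative count of relevant records among screening steps 1..s. Priors
#' are excluded from both axes: step 1 is the first screened record, and
#' prior relevant records are not counted as found.
#'
#' @param traj a `trajectory`.
#' @return data.frame with `n_screened` and `n_relevant_found`.
#' @export
recall_curve <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  data.frame(n_screened = traj$step,
             n_relevant_found = cumsum(traj_relevant(traj)))
}

#' Work saved over sampling at a recall level
#'
#' WSS@level is the fraction of screening effort saved relative to random
#' screening at the point where `level` of the relevant records have been
#' found: with `s*` the first step at which recall reaches `level`,
#' `wss = (1 - s*/N) - (1 - level)`. Conventions (echoed in the result):
#' priors are excluded from both the pool size `N` and the recall
#' denominator, and the recall threshold is met at the first step with
#' recall >= level.
#'
#' @param x a `trajectory`, or a logical vector giving the true labels of a
#'   screening order (`TRUE` = relevant).
#' @param level recall level in (0, 1\].
#' @param total_records non-prior pool size `N`; defaults to the
#'   trajectory's corpus size minus its priors (required for vector input).
#' @param n_relevant_total non-prior relevant count (recall denominator);
#'   defaults to the trajectory's, or to `sum(x)` for vector input.
#' @return the WSS value, with attributes `s_star`, `level`, `conventions`;
#'   `NA` with attribute `reason = "level_not_reached"` when the trajectory
#'   stopped before reaching the level.
#' @export
wss <- function(x, level = 0.95, total_records = NULL, n_relevant_total = NULL) {
  assert_that(level > 0 && level <= 1, "level must be in (0, 1]")
  if (inherits(x, "trajectory")) {
    rel <- traj_relevant(x)
    total_records <- total_records %||%
      (attr(x, "corpus_size") - attr(x, "n_priors"))
    n_relevant_total <- n_relevant_total %||% length(attr(x, "relevant_ids"))
  } else {
    rel <- as.logical(x)
    assert_that(!is.null(total_records), "total_records is required for vector input")
    n_relevant_total <- n_relevant_total %||% sum(rel)
  }
  found <- cumsum(rel)
  s_star <- match(TRUE, found / n_relevant_total >= level)
  if (is.na(s_star)) {
    return(structure(NA_real_, reason = "level_not_reached", level = level))
  }
  structure((1 - s_star / total_records) - (1 - level),
            s_star = s_star, level = level,
            conventions = "priors excluded from N and recall denominator; threshold at first step with recall >= level")
}

#' Time to discovery per relevant record
#'
#' TD of a relevant record is the 1-based screening step at which it was
#' screened. For a set of runs, per-record TDs are averaged over the runs
#' in which the record was discovered and not a prior; records never
#' discovered in any run are reported as undiscovered rather than imputed.
#'
#' @param x a `trajectory` or a list of trajectories over the same corpus.
#' @return data.frame with `record_id`, `td` (mean over defining runs) and
#'   `n_runs`; attribute `undiscovered` lists relevant record ids with no
#'   defined TD in any run.
#' @export
time_to_discovery <- function(x) {
  trajs <- if (inherits(x, "trajectory")) list(x) else x
  stopifnot(all(vapply(trajs, inherits, logical(1), "trajectory")))
  all_rel <- unique(unlist(lapply(trajs, function(t)
    union(attr(t, "relevant_ids"),
          attr(t, "priors")$relevant_ids))))
  acc <- list()
  for (t in trajs) {
    rel_steps <- t[traj_relevant(t), c("record_id", "step")]
    acc[[length(acc) + 1L]] <- rel_steps
  }
  acc <- do.call(rbind, acc)
  if (is.null(acc) || nrow(acc) == 0L) {
    out <- data.frame(record_id = character(), td = numeric(),
                      n_runs = integer())
    attr(out, "undiscovered") <- all_rel
    return(out)
  }
  agg <- stats::aggregate(step ~ record_id, data = acc, FUN = mean)
  cnt <- stats::aggregate(step ~ record_id, data = acc, FUN = length)
  out <- data.frame(record_id = agg$record_id, td = agg$step,
                    n_runs = cnt$step, stringsAsFactors = FALSE)
  out <- out[order(out$td), ]
  rownames(out) <- NULL
  attr(out, "undiscovered") <- setdiff(all_rel, out$record_id)
  out
}

#' Average time to discovery
#'
#' @param x a `trajectory`, a list of trajectories, or a
#'   [time_to_discovery()] result.
#' @return mean TD over relevant records with a defined TD; attribute
#'   `undiscovered` flags relevant records never discovered (they are not
#'   imputed into the mean).
#' @export
atd <- function(x) {
  td <- if (is.data.frame(x)) x else time_to_discovery(x)
  structure(mean(td$td), undiscovered = attr(td, "undiscovered"))
}

#' Relevant records found after screening a fraction of the corpus
#'
#' RRF@percent is the number of relevant records among the first
#' `floor(percent * total_records)` screening steps. For switched runs the
#' count spans the whole trajectory, including records screened before the
#' switch. A trajectory shorter than the cut is counted over its available
#' steps and flagged as truncated.
#'
#' @param traj a `trajectory`.
#' @param percent fraction of the corpus in (0, 1\].
#' @param total_records corpus size the percentage refers to; defaults to
#'   the trajectory's corpus size.
#' @return integer count with attributes `cut` and `truncated`.
#' @export
rrf <- function(traj, percent, total_records = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  assert_that(percent > 0 && percent <= 1, "percent must be in (0, 1]")
  total_records <- total_records %||% attr(traj, "corpus_size")
  cut <- floor(percent * total_records)
  avail <- min(cut, nrow(traj))
  structure(sum(traj_relevant(traj)[seq_len(avail)]),
            cut = cut, truncated = cut > nrow(traj))
}

#' Rank-order cohesion matrix
#'
#' For each pair of runs, the Spearman correlation between the discovery
#' ranks of the relevant records discovered in both. Quantifies how similar
#' the discovery order of relevant records is across model configurations.
#'
#' @param trajs named list of >= 2 trajectories over the same corpus and
#'   priors.
#' @return square symmetric matrix with unit diagonal, `NA` entries where
#'   fewer than 2 common discovered relevant records exist.
#' @export
rank_cohesion <- function(trajs) {
  assert_that(length(trajs) >= 2, "need at least two trajectories")
  stopifnot(all(vapply(trajs, inherits, logical(1), "trajectory")))
  tags <- names(trajs) %||% paste0("run", seq_along(trajs))
  ranks <- lapply(trajs, function(t) {
    rel <- t[traj_relevant(t), ]
    stats::setNames(rank(rel$step), rel$record_id)
  })
  m <- length(trajs)
  out <- matrix(NA_real_, m, m, dimnames = list(tags, tags))
  diag(out) <- 1
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      common <- intersect(names(ranks[[i]]), names(ranks[[j]]))
      if (length(common) >= 2L) {
        out[i, j] <- out[j, i] <- stats::cor(ranks[[i]][common],
                                             ranks[[j]][common],
                                             method = "spearman")
      }
    }
  }
  out
}

#' Fraction of the corpus screened, as a percentage
#'
#' @param n_screened screened record count.
#' @param total_records corpus size (> 0).
#' @return `100 * n_screened / total_records`, rounded to one decimal.
#' @export
corpus_fraction <- function(n_screened, total_records) {
  assert_that(is_count(total_records, 1), "total_records must be positive")
  assert_that(n_screened <= total_records,
              "n_screened cannot exceed total_records")
  round(100 * n_screened / total_records, 1)
}

#' Assemble a metrics report for a trajectory
#'
#' @param traj a `trajectory`.
#' @param wss_levels recall levels for [wss()].
#' @param rrf_percents corpus fractions for [rrf()].
#' @param total_records corpus size for the RRF cuts (default: the
#'   trajectory's).
#' @return list of class `metrics_report` with the recall curve, WSS map,
#'   TD table, ATD, RRF map and the convention echo.
#' @export
metrics_report <- function(traj, wss_levels = c(0.95),
                           rrf_percents = c(0.01, 0.02),
                           total_records = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  wss_map <- lapply(wss_levels, function(l) wss(traj, l))
  names(wss_map) <- paste0("wss@", format(100 * wss_levels, trim = TRUE), "%")
  td <- time_to_discovery(traj)
  rrf_map <- lapply(rrf_percents, function(p)
    rrf(traj, p, total_records = total_records))
  names(rrf_map) <- paste0("rrf@", format(100 * rrf_percents, trim = TRUE), "%")
  structure(list(
    recall_curve = recall_curve(traj),
    wss = wss_map,
    td = td,
    atd = atd(td),
    rrf = rrf_map,
    conventions = list(
      priors = "excluded from pool size, recall denominator and step axis",
      recall_threshold = "first step with recall >= level",
      undiscovered = "reported, never imputed"
    )
  ), class = "metrics_report")
}

#' Write a trajectory log
#'
#' Structured text: a run-metadata header (`# key: json` lines) followed by
#' one CSV row per step. This format is the contract consumed by the
#' evaluation functions via [read_trajectory()].
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  meta <- list(corpus_size = attr(traj, "corpus_size"),
               n_priors = attr(traj, "n_priors"),
               relevant_ids = attr(traj, "relevant_ids"),
               prior_relevant_ids = attr(traj, "priors")$relevant_ids,
               prior_irrelevant_ids = attr(traj, "priors")$irrelevant_ids,
               prior_seed = attr(traj, "priors")$seed,
               switch_step = attr(traj, "switch_step"),
               termination = attr(traj, "termination"),
               seed = attr(traj, "seed"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k,
                       jsonlite::toJSON(meta[[k]], auto_unbox = TRUE,
                                        null = "null", na = "null")), con)
  }
  df <- as.data.frame(traj)
  df$score <- sprintf("%.17g", df$score) # lossless double round-trip
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory log
#'
#' @param path file written by [write_trajectory()].
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^# ", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^# ([a-z_]+): (.*)$", ln))[[1]]
    meta[[m[2]]] <- jsonlite::fromJSON(m[3])
  }
  df <- utils::read.csv(textConnection(paste(lines[-hdr], collapse = "\n")),
                        stringsAsFactors = FALSE)
  new_trajectory(df,
                 priors = structure(list(
                   relevant_ids = meta$prior_relevant_ids,
                   irrelevant_ids = meta$prior_irrelevant_ids,
                   seed = meta$prior_seed), class = "prior_set"),
                 corpus_size = meta$corpus_size, n_priors = meta$n_priors,
                 relevant_ids = meta$relevant_ids,
                 switch_step = meta$switch_step %||% NA_integer_,
                 termination = meta$termination, seed = meta$seed)
}
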