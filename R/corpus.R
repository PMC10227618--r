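# corpus container and delimited-text / RIS input-output

LABEL_LEVELS <- c("relevant", "irrelevant", "unknown")

#' Construct a screening corpus
#'
#' A corpus is the unit of screening: an ordered collection of records, each
#' with a title, an abstract (possibly empty), a three-state relevance label
#' and an optional DOI. Record order on construction is the canonical corpus
#' order used downstream for tie-breaking.
#'
#' @param records data.frame with columns `record_id`, `title`, `abstract`,
#'   `label` (one of `"relevant"`, `"irrelevant"`, `"unknown"`), and
#'   optionally `doi`.
#' @param provenance free-text note on where the records came from.
#' @return an object of class `corpus` (a data.frame).
#' @export
corpus <- function(records, provenance = "") {
  stopifnot(is.data.frame(records))
  need <- c("record_id", "title", "abstract", "label")
  miss <- setdiff(need, names(records))
  assert_that(length(miss) == 0L,
              paste0("corpus records lack column(s): ", paste(miss, collapse = ", ")))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$record_id <- as.character(records$record_id)
  records$title <- as.character(records$title)
  records$abstract <- ifelse(is.na(records$abstract), "", as.character(records$abstract))
  records$label <- as.character(records$label)
  if (is.null(records$doi)) records$doi <- rep(NA_character_, nrow(records))
  records$doi <- normalize_doi(records$doi)
  bad <- setdiff(unique(records$label), LABEL_LEVELS)
  assert_that(length(bad) == 0L,
              paste0("invalid label value(s): ", paste(bad, collapse = ", ")))
  dup <- records$record_id[duplicated(records$record_id)]
  assert_that(length(dup) == 0L,
              paste0("duplicate record_id(s): ", paste(unique(dup), collapse = ", ")))
  records <- records[, c("record_id", "title", "abstract", "label", "doi")]
  rownames(records) <- NULL
  structure(records, provenance = provenance, class = c("corpus", "data.frame"))
}

#' @export
print.corpus <- function(x, ...) {
  d <- describe_corpus(x)
  cat(sprintf("<corpus> %d records, %d relevant (%s%%)\n", d$n_records,
              d$n_relevant,
              ifelse(is.na(d$prevalence_percent), "NA",
                     format(round(d$prevalence_percent, 4)))))
  invisible(x)
}

is_relevant <- function(x) x$label == "relevant"

# strip resolver prefixes, lowercase; empty/NA stay NA
normalize_doi <- function(doi) {
  doi <- tolower(trimws(as.character(doi)))
  doi <- sub("^https?://(dx\\.)?doi\\.org/", "", doi)
  doi <- sub("^doi:\\s*", "", doi)
  doi[!nzchar(doi) | is.na(doi)] <- NA_character_
  doi
}

# lowercase, strip all non-alphanumeric, collapse whitespace
normalize_title <- function(title) {
  t <- tolower(as.character(title))
  t <- gsub("[^a-z0-9]+", " ", t)
  trimws(gsub(" +", " ", t))
}

map_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "included", "include", "relevant", "yes", "true")] <- "relevant"
  out[x %in% c("0", "excluded", "exclude", "irrelevant", "no", "false")] <- "irrelevant"
  out[is.na(x) | !nzchar(x) | x %in% c("unknown", "na")] <- "unknown"
  bad <- is.na(out)
  assert_that(!any(bad),
              paste0("unmappable label value(s): ",
                     paste(unique(x[bad]), collapse = ", ")))
  out
}

#' Read a labeled screening corpus
#'
#' Reads delimited text (`csv`/`tsv`; UTF-8, header row) or an RIS reference
#' file into a [corpus()]. Label strings `1/0`, `included/excluded`,
#' `relevant/irrelevant` (and empty for unknown) are mapped onto the
#' three-state label. Missing abstracts become empty text and are counted in
#' the load report attached as attribute `"load_report"`.
#'
#' @param path file to read.
#' @param format `"csv"`, `"tsv"` or `"ris"`; default guessed from the
#'   file extension.
#' @param columns named list mapping the roles `title`, `abstract`, `label`,
#'   and optionally `id`, `doi`, onto header names in the delimited file.
#' @return a `corpus`; attribute `"load_report"` holds
#'   `n_missing_abstract` and the source path.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "tsv", "ris"),
                        columns = list(title = "title", abstract = "abstract",
                                       label = "label_included")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ris = "ris", tsv = "tsv", txt = "tsv", "csv")
  }
  assert_that(file.exists(path), paste0("cannot read file: ", path))
  if (format == "ris") return(read_corpus_ris(path))

  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fill = TRUE, encoding = "UTF-8",
                          check.names = FALSE, colClasses = "character")
  pick <- function(role, fallbacks) {
    cand <- c(columns[[role]], fallbacks)
    cand[cand %in% names(df)][1]
  }
  title_col <- pick("title", "title")
  abstract_col <- pick("abstract", "abstract")
  label_col <- pick("label", c("label_included", "label", "included", "relevant"))
  if (is.na(label_col)) {
    stop("no mappable label column; found headers: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  assert_that(!is.na(title_col),
              paste0("no mappable title column; found headers: ",
                     paste(names(df), collapse = ", ")))
  id_col <- pick("id", c("record_id", "id"))
  doi_col <- pick("doi", "doi")

  n <- nrow(df)
  ids <- if (!is.na(id_col)) as.character(df[[id_col]]) else sprintf("rec_%06d", seq_len(n))
  abstract <- if (!is.na(abstract_col)) df[[abstract_col]] else rep("", n)
  missing_abs <- sum(is.na(abstract) | !nzchar(trimws(abstract)))
  out <- corpus(data.frame(
    record_id = ids,
    title = df[[title_col]],
    abstract = ifelse(is.na(abstract), "", abstract),
    label = map_label(df[[label_col]]),
    doi = if (!is.na(doi_col)) df[[doi_col]] else NA_character_,
    stringsAsFactors = FALSE
  ), provenance = path)
  attr(out, "load_report") <- list(path = path, n_records = n,
                                   n_missing_abstract = missing_abs)
  out
}

#' Write a corpus to disk
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p), ...)`
#' reproduces titles, abstracts and labels field-for-field. RIS output writes
#' one reference per record with TY/TI/AB/DO/LB/ER tags (LB carries the
#' relevance label).
#'
#' @param x a `corpus`.
#' @param path output file.
#' @param format `"csv"`, `"tsv"` or `"ris"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("csv", "tsv", "ris")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "corpus"))
  if (format == "ris") {
    write_corpus_ris(x, path)
    return(invisible(path))
  }
  df <- data.frame(record_id = x$record_id, title = x$title,
                   abstract = x$abstract, label_included = x$label,
                   doi = x$doi, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

read_corpus_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list(); cur <- list(); n_missing <- 0L
  flush <- function(cur) {
    if (length(cur) == 0L) return(NULL)
    data.frame(record_id = cur$ID %||% NA_character_,
               title = cur$TI %||% "",
               abstract = cur$AB %||% "",
               label = map_label(cur$LB %||% ""),
               doi = cur$DO %||% NA_character_,
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (grepl("^ER  -", ln)) {
      rec <- flush(cur)
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
      cur <- list()
    } else if (grepl("^[A-Z][A-Z0-9]  - ", ln)) {
      tag <- substr(ln, 1, 2)
      val <- sub("^..  - ", "", ln)
      cur[[tag]] <- val
    }
  }
  rec <- flush(cur)
  if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  df <- do.call(rbind, recs)
  if (is.null(df)) {
    df <- data.frame(record_id = character(), title = character(),
                     abstract = character(), label = character(),
                     doi = character(), stringsAsFactors = FALSE)
  }
  need_id <- is.na(df$record_id)
  df$record_id[need_id] <- sprintf("rec_%06d", which(need_id))
  out <- corpus(df, provenance = path)
  attr(out, "load_report") <- list(path = path, n_records = nrow(df),
                                   n_missing_abstract = sum(!nzchar(df$abstract)))
  out
}

write_corpus_ris <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(c(
      "TY  - JOUR",
      paste0("ID  - ", x$record_id[i]),
      paste0("TI  - ", x$title[i]),
      paste0("AB  - ", x$abstract[i]),
      if (!is.na(x$doi[i])) paste0("DO  - ", x$doi[i]),
      paste0("LB  - ", x$label[i]),
      "ER  - ",
      ""
    ), con)
  }
  invisible(path)
}

#' Deduplicate a corpus
#'
#' Records sharing a non-empty normalised DOI, or sharing a normalised title
#' (lowercased, punctuation and whitespace collapsed), are merged. The
#' retained record is the first in corpus order; within a merged group a
#' relevant label wins over irrelevant (and either wins over unknown), so a
#' merge never discards an inclusion decision.
#'
#' @param x a `corpus`.
#' @return list with elements `corpus` (deduplicated) and `report`, the
#'   latter holding `n_input`, `n_output`, `merged_groups` (retained id
#'   first) and `rule_hit` (`"doi"` or `"normalized_title"` per group).
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "corpus"))
  n <- nrow(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  rule <- rep(NA_character_, n) # rule that first linked record i into its group

  link <- function(key, rule_name) {
    ok <- !is.na(key) & nzchar(key)
    groups <- split(which(ok), key[ok])
    for (g in groups) {
      if (length(g) < 2L) next
      root <- find(g[1])
      for (i in g[-1]) {
        ri <- find(i)
        if (ri != root) {
          keep <- min(root, ri); drop <- max(root, ri)
          parent[drop] <<- keep
          if (is.na(rule[drop])) rule[drop] <<- rule_name
          root <- keep
        }
      }
    }
  }
  link(x$doi, "doi")
  link(normalize_title(x$title), "normalized_title")

  root <- vapply(seq_len(n), find, integer(1))
  keep_idx <- sort(unique(root))
  merged_groups <- list(); rule_hit <- character(0)
  labels <- x$label
  for (r in keep_idx) {
    members <- which(root == r)
    if (length(members) > 1L) {
      merged_groups[[length(merged_groups) + 1L]] <- x$record_id[members]
      rules <- unique(stats::na.omit(rule[members]))
      rule_hit <- c(rule_hit, if ("doi" %in% rules) "doi" else "normalized_title")
      grp_labels <- labels[members]
      labels[r] <- if ("relevant" %in% grp_labels) "relevant"
                   else if ("irrelevant" %in% grp_labels) "irrelevant" else "unknown"
    }
  }
  out <- x[keep_idx, , drop = FALSE]
  out$label <- labels[keep_idx]
  out <- corpus(out, provenance = attr(x, "provenance"))
  report <- list(n_input = n, n_output = nrow(out),
                 merged_groups = merged_groups, rule_hit = rule_hit)
  stopifnot(report$n_output +
              sum(vapply(merged_groups, length, integer(1)) - 1L) == n)
  list(corpus = out, report = report)
}

#' Corpus descriptives
#'
#' @param x a `corpus`.
#' @return list with `n_records`, `n_relevant`, `prevalence_percent`
#'   (100 * n_relevant / n_records; `NA` for an empty corpus) and
#'   `mean_abstract_words`, the mean whitespace-token count over non-empty
#'   abstracts.
#' @export
describe_corpus <- function(x) {
  stopifnot(inherits(x, "corpus"))
  n <- nrow(x)
  n_rel <- sum(is_relevant(x))
  toks <- tokenize_text(x$abstract)
  lens <- vapply(toks, length, integer(1))
  nonempty <- lens > 0L
  list(
    n_records = n,
    n_relevant = n_rel,
    prevalence_percent = if (n == 0L) NA_real_ else 100 * n_rel / n,
    mean_abstract_words = if (any(nonempty)) mean(lens[nonempty]) else NA_real_
  )
}
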