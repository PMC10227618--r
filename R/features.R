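# feature extraction: sparse term weighting, dense paragraph embeddings,
# precomputed embeddings, and classifier-feature compatibility rules

#' Feature-extraction configuration
#'
#' @param method one of `"tfidf"`, `"doc_embedding"`, `"wide_doc_embedding"`,
#'   `"precomputed_dense"`. The two embedding methods differ only in their
#'   default width: 40 for `doc_embedding`, 120 for `wide_doc_embedding`.
#' @param dim embedding width; ignored for tf-idf.
#' @param tfidf_params list of `max_features` (`NULL` for no cap),
#'   `ngram` (only unigrams supported) and `stopwords` (remove English
#'   stopwords, default `TRUE`).
#' @param seed integer, echoed into the matrix for provenance (the built-in
#'   extractors are deterministic).
#' @return object of class `feature_config`.
#' @export
feature_config <- function(method = c("tfidf", "doc_embedding",
                                      "wide_doc_embedding", "precomputed_dense"),
                           dim = NULL,
                           tfidf_params = list(max_features = NULL,
                                               stopwords = TRUE),
                           seed = 1L) {
  method <- match.arg(method)
  if (is.null(dim)) {
    dim <- switch(method, doc_embedding = 40L, wide_doc_embedding = 120L, 0L)
  }
  assert_that(method == "tfidf" || method == "precomputed_dense" || dim > 0,
              "dim must be positive")
  structure(list(method = method, dim = as.integer(dim),
                 tfidf_params = tfidf_params, seed = as.integer(seed)),
            class = "feature_config")
}

new_feature_matrix <- function(values, width_class, config, record_ids) {
  nonneg <- if (inherits(values, "sparseMatrix")) all(values@x >= 0) else all(values >= 0)
  structure(list(values = values, nonnegative = nonneg,
                 width_class = width_class, config = config,
                 record_ids = record_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s, %s, %s)\n",
              nrow(x$values), ncol(x$values), x$config$method, x$width_class,
              if (x$nonnegative) "nonnegative" else "signed"))
  invisible(x)
}

#' Subset a feature matrix by record ids
#'
#' @param features a `feature_matrix`.
#' @param ids record ids (a multiset: repeated ids give repeated rows, as
#'   produced by the training-set balancer).
#' @return a `feature_matrix` restricted to `ids`, in their order.
#' @export
subset_features <- function(features, ids) {
  idx <- match(ids, features$record_ids)
  assert_that(!anyNA(idx), "unknown record id(s) in subset")
  out <- features
  out$values <- features$values[idx, , drop = FALSE]
  out$record_ids <- ids
  out
}

corpus_texts <- function(corp) paste(corp$title, corp$abstract, sep = "   ")

# sparse document-term count matrix under the package tokenizer
doc_term_counts <- function(corp, stopwords = TRUE, max_features = NULL) {
  toks <- tokenize_text(corpus_texts(corp), remove_stopwords = stopwords)
  lens <- vapply(toks, length, integer(1))
  assert_that(any(lens > 0L), "all documents are empty after tokenization")
  flat <- unlist(toks, use.names = FALSE)
  doc <- rep.int(seq_along(toks), lens)
  vocab <- sort(unique(flat))
  if (!is.null(max_features) && length(vocab) > max_features) {
    df_count <- table(factor(unlist(lapply(toks, unique), use.names = FALSE),
                             levels = vocab))
    keep <- names(sort(df_count, decreasing = TRUE))[seq_len(max_features)]
    vocab <- sort(keep)
    in_vocab <- flat %in% vocab
    flat <- flat[in_vocab]; doc <- doc[in_vocab]
  }
  j <- match(flat, vocab)
  X <- Matrix::sparseMatrix(i = doc, j = j, x = 1,
                            dims = c(length(toks), length(vocab)),
                            dimnames = list(NULL, vocab))
  X
}

#' Fit tf-idf features
#'
#' Standard smoothed tf-idf over the concatenated title and abstract:
#' raw term counts weighted by `idf = log((1 + n) / (1 + df)) + 1`, rows
#' L2-normalised. Deterministic; the resulting matrix is nonnegative and
#' wide-sparse.
#'
#' @param corp a `corpus`.
#' @param config a [feature_config()] with method `"tfidf"`.
#' @return a `feature_matrix`.
#' @export
fit_tfidf <- function(corp, config = feature_config("tfidf")) {
  stopifnot(inherits(corp, "corpus"))
  assert_that(nrow(corp) > 0, "corpus is empty")
  p <- config$tfidf_params
  X <- doc_term_counts(corp, stopwords = isTRUE(p$stopwords %||% TRUE),
                       max_features = p$max_features)
  n <- nrow(X)
  df_count <- Matrix::colSums(X > 0)
  idf <- log((1 + n) / (1 + df_count)) + 1
  X <- X %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(X^2))
  norms[norms == 0] <- 1
  X <- Matrix::Diagonal(x = 1 / norms) %*% X
  X <- methods::as(X, "CsparseMatrix")
  colnames(X) <- names(df_count)
  new_feature_matrix(X, "wide_sparse", config, corp$record_id)
}

#' Fit a dense paragraph embedding
#'
#' Trains a count-based paragraph-embedding model on the corpus: the
#' positive pointwise-mutual-information document-term matrix is factorised
#' by truncated SVD and each document is represented by its `dim` leading
#' left-singular coordinates (scaled by the singular values). This spectral
#' factorisation is the closed-form counterpart of skip-gram-style embedding
#' training; it is deterministic (component signs are fixed so the
#' largest-magnitude loading of each component is positive), so identical
#' corpora give identical matrices regardless of seed.
#'
#' @param corp a `corpus` of at least 10 records.
#' @param config a [feature_config()] with method `"doc_embedding"` (default
#'   width 40) or `"wide_doc_embedding"` (default width 120).
#' @return a `feature_matrix` with `width_class = "narrow_dense"`; entries
#'   may be negative.
#' @export
fit_doc_embedding <- function(corp, config = feature_config("doc_embedding")) {
  stopifnot(inherits(corp, "corpus"))
  assert_that(nrow(corp) >= 10,
              "corpus too small for embedding training (minimum 10 records)")
  dim <- config$dim
  C <- doc_term_counts(corp, stopwords = TRUE)
  # drop hapax terms: they carry no co-occurrence signal
  keep <- Matrix::colSums(C) >= 2
  if (sum(keep) >= dim) C <- C[, keep, drop = FALSE]
  total <- sum(C)
  pr <- Matrix::rowSums(C) / total
  pc <- Matrix::colSums(C) / total
  P <- methods::as(C, "TsparseMatrix")
  val <- log(pmax(P@x / total, .Machine$double.xmin) /
               (pr[P@i + 1L] * pc[P@j + 1L]))
  val <- pmax(val, 0) # positive PMI
  P <- Matrix::sparseMatrix(i = P@i + 1L, j = P@j + 1L, x = val,
                            dims = dim(C))
  k <- min(dim, nrow(P) - 1L, ncol(P) - 1L)
  if (ncol(P) <= nrow(P)) {
    G <- as.matrix(Matrix::crossprod(P))
    eg <- eigen(G, symmetric = TRUE)
    W <- eg$vectors[, seq_len(k), drop = FALSE]
    D <- as.matrix(P %*% W)
  } else {
    G <- as.matrix(Matrix::tcrossprod(P))
    eg <- eigen(G, symmetric = TRUE)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    D <- U %*% diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  }
  # fix sign convention per component
  for (jj in seq_len(ncol(D))) {
    m <- which.max(abs(D[, jj]))
    if (D[m, jj] < 0) D[, jj] <- -D[, jj]
  }
  if (ncol(D) < dim) { # degenerate corpora: pad to the requested width
    D <- cbind(D, matrix(0, nrow(D), dim - ncol(D)))
  }
  colnames(D) <- sprintf("e%03d", seq_len(ncol(D)))
  new_feature_matrix(D, "narrow_dense", config, corp$record_id)
}

#' Wrap precomputed dense embeddings
#'
#' Reads externally produced sentence-embedding vectors (for example from a
#' transformer sentence encoder) from delimited text whose first column is
#' the record id, and wraps them as narrow-dense features aligned with the
#' corpus.
#'
#' @param path delimited text file (comma or tab), header row, first column
#'   `record_id`; or a numeric matrix with rownames set to record ids.
#' @param corp the `corpus` the rows must align with.
#' @return a `feature_matrix` with `width_class = "narrow_dense"`.
#' @export
load_precomputed_dense <- function(path, corp) {
  stopifnot(inherits(corp, "corpus"))
  if (is.matrix(path)) {
    m <- path
    ids <- rownames(m) %||% stop("matrix input needs record ids as rownames")
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
  }
  if (nrow(m) != nrow(corp)) {
    stop(sprintf("row count %d does not match corpus size %d",
                 nrow(m), nrow(corp)), call. = FALSE)
  }
  mism <- which(ids != corp$record_id)
  if (length(mism) > 0L) {
    stop(sprintf("record id mismatch at row %d: got '%s', expected '%s'",
                 mism[1], ids[mism[1]], corp$record_id[mism[1]]), call. = FALSE)
  }
  rownames(m) <- NULL
  cfg <- feature_config("precomputed_dense", dim = ncol(m))
  new_feature_matrix(m, "narrow_dense", cfg, corp$record_id)
}

#' Fit features from a configuration
#'
#' Dispatcher over [fit_tfidf()] and [fit_doc_embedding()];
#' `"precomputed_dense"` configurations must be materialised through
#' [load_precomputed_dense()] and cannot be fitted.
#'
#' @param corp a `corpus`.
#' @param config a [feature_config()].
#' @return a `feature_matrix`.
#' @export
fit_features <- function(corp, config) {
  switch(config$method,
    tfidf = fit_tfidf(corp, config),
    doc_embedding = fit_doc_embedding(corp, config),
    wide_doc_embedding = fit_doc_embedding(corp, config),
    precomputed_dense = stop("precomputed_dense features must be loaded with load_precomputed_dense()",
                             call. = FALSE)
  )
}

#' Check classifier-feature compatibility
#'
#' Enforces the model-feature exclusion rules: multinomial naive Bayes
#' cannot handle matrices containing negative values, and the neural
#' classifiers (2-layer network and the deep separable-convolution network)
#' require narrow dense inputs because wide sparse term matrices are not a
#' realistic network input.
#'
#' @param classifier_name a registered classifier name (see
#'   [classifier_names()]).
#' @param features a `feature_matrix`.
#' @return `TRUE` (invisibly) when the pair is compatible; otherwise a list
#'   of class `pairing_finding` with elements `rule` and `message`.
#' @export
validate_pairing <- function(classifier_name, features) {
  assert_that(classifier_name %in% classifier_names(),
              paste0("unknown classifier: ", classifier_name))
  stopifnot(inherits(features, "feature_matrix"))
  if (classifier_name == "naive_bayes" && !features$nonnegative) {
    return(structure(list(rule = "negative_values",
                          message = "naive_bayes cannot handle matrices containing negative values"),
                     class = "pairing_finding"))
  }
  if (classifier_name %in% c("nn_2_layer", "cnn_17") &&
      features$width_class != "narrow_dense") {
    return(structure(list(rule = "too_wide",
                          message = paste0(classifier_name,
                                           " requires narrow dense features; the matrix is too wide for the network input")),
                     class = "pairing_finding"))
  }
  invisible(TRUE)
}

pairing_ok <- function(classifier_name, features) {
  isTRUE(validate_pairing(classifier_name, features))
}

assert_pairing <- function(classifier_name, features) {
  v <- validate_pairing(classifier_name, features)
  if (!isTRUE(v)) stop("incompatible pairing: ", v$message, call. = FALSE)
  invisible(TRUE)
}
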