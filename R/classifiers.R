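# classifier registry behind one train/score contract

#' Registered classifier names
#'
#' The registry covers multinomial naive Bayes, ridge logistic regression,
#' a linear support vector machine, a probability random forest, a 2-layer
#' dense network, the 17-layer separable-convolution network, and an
#' `oracle` test double whose scores are the true labels (used to verify
#' engine mechanics independently of any trained model).
#'
#' @return character vector of names accepted by [model_config()].
#' @export
classifier_names <- function() {
  c("naive_bayes", "logistic_regression", "svm", "random_forest",
    "nn_2_layer", "cnn_17", "oracle")
}

#' Classifier configuration
#'
#' @param name a registered classifier name, see [classifier_names()].
#' @param hyperparams named list of overrides. Recognised entries:
#'   `alpha` (naive Bayes Laplace smoothing, default 1), `lambda` (ridge
#'   penalty for logistic regression, default 1e-3), `cost` and `kernel`
#'   (SVM, defaults 1 and `"linear"`), `num_trees` (random forest, default
#'   100), `hidden_units` (2-layer network, default 128), `batch_size` and
#'   `lr` (neural trainers), `cnn` (a [cnn_architecture()]), and `truth`
#'   (oracle scores, named by record id).
#' @param seed integer used by stochastic trainers.
#' @return object of class `model_config`.
#' @export
model_config <- function(name, hyperparams = list(), seed = 1L) {
  assert_that(name %in% classifier_names(),
              paste0("unknown classifier: ", name))
  structure(list(name = name, hyperparams = hyperparams,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Separable-convolution network architecture
#'
#' Describes the deep text-ranking network: three blocks of two separable
#' 1-D convolutions (kernel sizes 5 and 3, ReLU) followed by max-pooling and
#' dropout, then flatten, dropout, and two dense layers ending in a
#' single-unit sigmoid relevance-probability output. The default totals 17
#' layers counted as every layer in the stack after the input (the final
#' dense unit, which carries the sigmoid output, is one of the two trailing
#' dense layers). Class weighting is disabled by construction: imbalance is
#' handled upstream by the training-set balancer, never by per-class loss
#' weights.
#'
#' @param conv_filters filters per separable convolution (default 256).
#' @param kernel_sizes integer pair, kernels of the two convolutions in each
#'   block (default 5 and 3).
#' @param n_blocks number of conv blocks (default 3).
#' @param dropout_conv dropout rate inside each conv block.
#' @param dropout_dense dropout rate around the dense head.
#' @param dense_units width of the first trailing dense layer.
#' @param n_hidden_layers declared layer total; the derived count must match.
#' @return object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(conv_filters = 256L, kernel_sizes = c(5L, 3L),
                             n_blocks = 3L, dropout_conv = 0.2,
                             dropout_dense = 0.5, dense_units = 64L,
                             n_hidden_layers = 17L) {
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_sizes = as.integer(kernel_sizes),
                 n_blocks = as.integer(n_blocks),
                 dropout_conv = dropout_conv, dropout_dense = dropout_dense,
                 dense_units = as.integer(dense_units),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 class_weighting = FALSE),
            class = "cnn_architecture")
}

cnn_layers <- function(arch) {
  layers <- list()
  for (b in seq_len(arch$n_blocks)) {
    for (k in arch$kernel_sizes) {
      layers <- c(layers, list(list(type = "sepconv",
                                    filters = arch$conv_filters, kernel = k)))
    }
    layers <- c(layers, list(list(type = "maxpool"),
                             list(type = "dropout", rate = arch$dropout_conv)))
  }
  c(layers, list(
    list(type = "flatten"),
    list(type = "dropout", rate = arch$dropout_dense),
    list(type = "dense", units = arch$dense_units, activation = "relu"),
    list(type = "dropout", rate = arch$dropout_dense),
    list(type = "dense", units = 1L, activation = "sigmoid")
  ))
}

#' Build the CNN layer manifest
#'
#' Lays out the network of a [cnn_architecture()] for a given input width
#' and returns an ordered manifest of every layer with its output shape and
#' parameter count. The derived layer count must equal the declared
#' `n_hidden_layers` of the architecture.
#'
#' @param arch a [cnn_architecture()]; default [cnn_architecture()].
#' @param input_len input sequence length (the embedding width the network
#'   is paired with; default 120, the wide document embedding).
#' @return data.frame manifest (one row per layer: name, type, settings,
#'   output shape, parameter count) with attributes `n_hidden_layers`,
#'   `n_parameters`, `class_weighting`.
#' @export
build_cnn <- function(arch = cnn_architecture(), input_len = 120L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  layers <- cnn_layers(arch)
  derived <- length(layers)
  if (derived != arch$n_hidden_layers) {
    stop(sprintf("architecture error: derived layer count %d != declared %d",
                 derived, arch$n_hidden_layers), call. = FALSE)
  }
  net <- nn_build(layers, as.integer(input_len))
  rows <- lapply(seq_along(net$layers), function(i) {
    ly <- net$layers[[i]]
    sh <- ly$out_shape
    flattened <- !is.na(sh$flat) # flat width is set from the flatten layer on
    shape_txt <- if (flattened) sprintf("(%d)", sh$flat)
      else sprintf("(%d, %d)", sh$len, sh$ch)
    npar <- if (is.null(net$params[[i]])) 0L else
      sum(vapply(net$params[[i]], length, integer(1)))
    settings <- switch(ly$type,
      sepconv = sprintf("filters=%d, kernel=%d, activation=relu",
                        ly$filters, ly$kernel),
      dropout = sprintf("rate=%g", ly$rate),
      dense = sprintf("units=%d, activation=%s", ly$units, ly$activation),
      maxpool = "pool=2",
      "")
    data.frame(layer = sprintf("%02d_%s", i, ly$type), type = ly$type,
               settings = settings, output_shape = shape_txt,
               n_parameters = npar, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  structure(manifest,
            n_hidden_layers = derived,
            n_parameters = sum(manifest$n_parameters),
            class_weighting = arch$class_weighting,
            class = c("cnn_manifest", "data.frame"))
}

as_dense <- function(features) {
  if (inherits(features$values, "sparseMatrix")) as.matrix(features$values)
  else features$values
}

#' Train a classifier
#'
#' Trains `config$name` on the given (already labeled, already balanced)
#' rows. Neural trainers honour the early-stopping `rule` and record the
#' epochs run and final loss; shallow trainers ignore it. All trainers are
#' deterministic given the seed and single-threaded execution.
#'
#' @param config a [model_config()].
#' @param features a `feature_matrix` restricted to the labeled rows (see
#'   [subset_features()]).
#' @param labels logical or 0/1 vector, `TRUE`/1 = relevant.
#' @param rule an [early_stop_rule()] for neural trainers, or `NULL` for the
#'   default.
#' @return object of class `fitted_model`.
#' @export
train_model <- function(config, features, labels, rule = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(features, "feature_matrix"))
  assert_pairing(config$name, features)
  y <- as.integer(as.logical(labels))
  assert_that(length(y) == nrow(features$values),
              "labels length must match feature rows")
  if (config$name != "oracle" && length(unique(y)) < 2L) {
    stop("training error: labels contain a single class", call. = FALSE)
  }
  hp <- config$hyperparams
  rule <- rule %||% early_stop_rule()
  fit <- switch(config$name,
    naive_bayes = {
      X <- features$values
      alpha <- hp$alpha %||% 1
      cs1 <- Matrix::colSums(X[y == 1L, , drop = FALSE])
      cs0 <- Matrix::colSums(X[y == 0L, , drop = FALSE])
      list(log_prior = log(c(mean(y == 0L), mean(y == 1L))),
           log_lik0 = log((cs0 + alpha) / (sum(cs0) + alpha * ncol(X))),
           log_lik1 = log((cs1 + alpha) / (sum(cs1) + alpha * ncol(X))))
    },
    logistic_regression = {
      lam <- hp$lambda %||% 1e-3
      # tiny class counts are routine in early loop iterations; glmnet's
      # small-sample warning is expected there
      suppressWarnings(
        glmnet::glmnet(features$values, y, family = "binomial", alpha = 0,
                       lambda = c(25, 5, 1) * lam, standardize = FALSE))
    },
    svm = {
      e1071::svm(as_dense(features), factor(y, levels = c(0, 1)),
                 kernel = hp$kernel %||% "linear", cost = hp$cost %||% 1,
                 scale = FALSE)
    },
    random_forest = {
      ranger::ranger(x = as_dense(features),
                     y = factor(y, levels = c(0, 1)),
                     probability = TRUE,
                     num.trees = hp$num_trees %||% 100L,
                     seed = config$seed, num.threads = 1L)
    },
    nn_2_layer = {
      units <- hp$hidden_units %||% 128L
      layers <- list(
        list(type = "flatten"),
        list(type = "dense", units = units, activation = "relu"),
        list(type = "dense", units = units, activation = "relu"),
        list(type = "dense", units = 1L, activation = "sigmoid")
      )
      nn_train(layers, as_dense(features), y, rule = rule, seed = config$seed,
               batch_size = hp$batch_size %||% 32L, lr = hp$lr %||% 1e-3)
    },
    cnn_17 = {
      arch <- hp$cnn %||% cnn_architecture()
      nn_train(cnn_layers(arch), as_dense(features), y, rule = rule,
               seed = config$seed, batch_size = hp$batch_size %||% 32L,
               lr = hp$lr %||% 1e-3)
    },
    oracle = {
      assert_that(!is.null(hp$truth),
                  "oracle classifier needs hyperparams$truth (scores named by record id)")
      list(truth = hp$truth)
    }
  )
  meta <- if (config$name %in% c("nn_2_layer", "cnn_17")) {
    list(epochs_run = fit$epochs_run, final_loss = fit$history[fit$epochs_run])
  } else list()
  structure(list(config = config, fit = fit,
                 width = ncol(features$values),
                 training_meta = meta),
            class = "fitted_model")
}

#' Score records for relevance
#'
#' @param model a `fitted_model`.
#' @param features a `feature_matrix` with the same width as the training
#'   features.
#' @return numeric vector of relevance scores in \[0, 1\], named by record
#'   id, one per feature row. Scores order the screening queue; only the
#'   naive Bayes, logistic and neural scores are probabilities.
#' @export
predict_relevance <- function(model, features) {
  stopifnot(inherits(model, "fitted_model"), inherits(features, "feature_matrix"))
  if (model$config$name != "oracle" && ncol(features$values) != model$width) {
    stop(sprintf("scoring error: feature width %d does not match training width %d",
                 ncol(features$values), model$width), call. = FALSE)
  }
  f <- model$fit
  s <- switch(model$config$name,
    naive_bayes = {
      d <- as.numeric(features$values %*% (f$log_lik1 - f$log_lik0)) +
        (f$log_prior[2] - f$log_prior[1])
      stats::plogis(d)
    },
    logistic_regression = {
      lam <- model$config$hyperparams$lambda %||% 1e-3
      as.numeric(stats::predict(f, features$values, s = lam,
                                type = "response", exact = FALSE))
    },
    svm = {
      pr <- stats::predict(f, as_dense(features), decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      d <- dv[, 1]
      # decision values are oriented toward the class named first
      if (!grepl("^1", colnames(dv)[1])) d <- -d
      stats::plogis(d)
    },
    random_forest = {
      p <- stats::predict(f, data = as_dense(features),
                          num.threads = 1L)$predictions
      p[, "1"]
    },
    nn_2_layer = nn_scores(f, as_dense(features)),
    cnn_17 = nn_scores(f, as_dense(features)),
    oracle = {
      truth <- f$truth
      assert_that(all(features$record_ids %in% names(truth)),
                  "oracle truth does not cover all scored records")
      as.numeric(truth[features$record_ids])
    }
  )
  s <- pmin(pmax(as.numeric(s), 0), 1)
  names(s) <- features$record_ids
  s
}
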