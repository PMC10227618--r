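# minimal neural-network engine: 1-D separable convolutions, max-pooling,
# dropout, dense layers, binary cross-entropy, Adam, loss-delta early stop.
# Arrays are (batch, length, channels), column-major, so matrix(x, B*L, C)
# collapses batch and position for the pointwise/dense matrix products.

#' Early-stopping rule on the training-loss delta
#'
#' Training stops once the most recent `patience` consecutive
#' epoch-to-epoch loss improvements are all below `min_delta`, or when
#' `max_epochs` epochs have run, whichever comes first. The rule compensates
#' for the fluctuating training-set size of an active-learning loop, where
#' no fixed epoch count suits every iteration.
#'
#' @param min_delta nonnegative loss-improvement threshold.
#' @param patience number of consecutive sub-threshold improvements required.
#' @param max_epochs hard epoch cap.
#' @return object of class `early_stop_rule`.
#' @export
early_stop_rule <- function(min_delta = 1e-3, patience = 2L, max_epochs = 50L) {
  assert_that(min_delta >= 0, "min_delta must be nonnegative")
  assert_that(is_count(patience, 1), "patience must be >= 1")
  assert_that(is_count(max_epochs, patience), "max_epochs must be >= patience")
  structure(list(min_delta = min_delta, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs)),
            class = "early_stop_rule")
}

#' Evaluate the early-stopping rule on a loss history
#'
#' @param loss_history numeric vector of per-epoch losses (oldest first).
#' @param rule an [early_stop_rule()].
#' @return `TRUE` iff training should stop after the last recorded epoch.
#' @export
should_stop <- function(loss_history, rule) {
  assert_that(length(loss_history) >= 1, "loss_history is empty")
  n <- length(loss_history)
  if (n >= rule$max_epochs) return(TRUE)
  if (n < rule$patience + 1L) return(FALSE)
  deltas <- -diff(loss_history) # positive = improvement
  recent <- deltas[(n - rule$patience):(n - 1L)]
  all(recent < rule$min_delta)
}

nn_glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# build parameter tensors and per-layer output shapes for a layer stack
nn_build <- function(layers, input_len) {
  shape <- list(len = input_len, ch = 1L, flat = NA_integer_)
  params <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "sepconv") {
      k <- ly$kernel; cin <- shape$ch; f <- ly$filters
      assert_that(shape$len >= k,
                  sprintf("sequence length %d shorter than kernel %d at layer %d",
                          shape$len, k, i))
      params[[i]] <- list(
        Wd = matrix(nn_glorot(k, k, k * cin), k, cin),
        Wp = matrix(nn_glorot(cin, f, cin * f), cin, f),
        b = numeric(f)
      )
      shape$len <- shape$len - k + 1L
      shape$ch <- f
    } else if (ly$type == "maxpool") {
      assert_that(shape$len >= 2L, sprintf("cannot pool length %d at layer %d",
                                           shape$len, i))
      shape$len <- shape$len %/% 2L
    } else if (ly$type == "flatten") {
      shape$flat <- shape$len * shape$ch
    } else if (ly$type == "dense") {
      din <- if (!is.na(shape$flat)) shape$flat else shape$len * shape$ch
      if (is.na(shape$flat)) shape$flat <- din
      params[[i]] <- list(
        W = matrix(nn_glorot(din, ly$units, din * ly$units), din, ly$units),
        b = numeric(ly$units)
      )
      shape$flat <- ly$units
    } else if (ly$type != "dropout") {
      stop("unknown layer type: ", ly$type, call. = FALSE)
    }
    layers[[i]]$out_shape <- shape
  }
  list(layers = layers, params = params)
}

nn_forward <- function(net, x, training = FALSE) {
  # x: (B, L) matrix -> (B, L, 1) array
  B <- nrow(x)
  cur <- array(x, c(B, ncol(x), 1L))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]; pr <- net$params[[i]]
    if (ly$type == "sepconv") {
      d <- dim(cur); L <- d[2]; C <- d[3]; k <- nrow(pr$Wd)
      Lo <- L - k + 1L
      z <- array(0, c(B, Lo, C))
      for (j in seq_len(k)) {
        z <- z + sweep(cur[, j:(j + Lo - 1L), , drop = FALSE], 3L, pr$Wd[j, ], `*`)
      }
      zm <- matrix(z, B * Lo, C)
      ym <- sweep(zm %*% pr$Wp, 2L, pr$b, `+`)
      mask <- ym > 0
      ym[!mask] <- 0
      caches[[i]] <- list(x = cur, z = zm, mask = mask, Lo = Lo)
      cur <- array(ym, c(B, Lo, ncol(pr$Wp)))
    } else if (ly$type == "maxpool") {
      d <- dim(cur); Lo <- d[2] %/% 2L
      i1 <- seq(1L, 2L * Lo, by = 2L); i2 <- i1 + 1L
      x1 <- cur[, i1, , drop = FALSE]; x2 <- cur[, i2, , drop = FALSE]
      take1 <- x1 >= x2
      out <- x2; out[take1] <- x1[take1]
      caches[[i]] <- list(take1 = take1, in_len = d[2])
      cur <- out
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        keep <- 1 - ly$rate
        mask <- (stats::runif(length(cur)) < keep) / keep
        dim(mask) <- dim(cur)
        caches[[i]] <- mask
        cur <- cur * mask
      }
    } else if (ly$type == "flatten") {
      d <- dim(cur)
      caches[[i]] <- d
      cur <- matrix(cur, B, d[2] * d[3])
    } else if (ly$type == "dense") {
      a <- sweep(cur %*% pr$W, 2L, pr$b, `+`)
      if (identical(ly$activation, "relu")) {
        mask <- a > 0; a[!mask] <- 0
      } else if (identical(ly$activation, "sigmoid")) {
        a <- stats::plogis(a); mask <- NULL
      } else mask <- NULL
      caches[[i]] <- list(x = cur, mask = mask, out = a)
      cur <- a
    }
  }
  list(out = cur, caches = caches)
}

# d_out: gradient wrt network output (B x 1, before-activation handled by caller
# for the final sigmoid: pass (p - y)/B and flag final_sigmoid)
nn_backward <- function(net, fwd, d_out, final_logit_grad = TRUE) {
  grads <- vector("list", length(net$layers))
  cur <- d_out
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]; pr <- net$params[[i]]; ca <- fwd$caches[[i]]
    if (ly$type == "dense") {
      if (identical(ly$activation, "sigmoid")) {
        # caller supplies gradient wrt the logit for the final layer;
        # otherwise apply sigmoid derivative
        if (!(final_logit_grad && i == length(net$layers))) {
          cur <- cur * ca$out * (1 - ca$out)
        }
      } else if (identical(ly$activation, "relu")) {
        cur[!ca$mask] <- 0
      }
      grads[[i]] <- list(W = crossprod(ca$x, cur), b = colSums(cur))
      cur <- cur %*% t(pr$W)
    } else if (ly$type == "flatten") {
      cur <- array(cur, ca)
    } else if (ly$type == "dropout") {
      if (!is.null(ca)) cur <- cur * ca
    } else if (ly$type == "maxpool") {
      d <- dim(cur); B <- d[1]; Lo <- d[2]; C <- d[3]
      dx <- array(0, c(B, ca$in_len, C))
      i1 <- seq(1L, 2L * Lo, by = 2L); i2 <- i1 + 1L
      g1 <- cur; g1[!ca$take1] <- 0
      g2 <- cur; g2[ca$take1] <- 0
      dx[, i1, ] <- g1
      dx[, i2, ] <- g2
      cur <- dx
    } else if (ly$type == "sepconv") {
      d <- dim(cur); B <- d[1]; Lo <- d[2]; Fh <- d[3]
      dym <- matrix(cur, B * Lo, Fh)
      dym[!ca$mask] <- 0
      db <- colSums(dym)
      dWp <- crossprod(ca$z, dym)
      dzm <- dym %*% t(pr$Wp)
      C <- ncol(dzm)
      dz <- array(dzm, c(B, Lo, C))
      k <- nrow(pr$Wd)
      dWd <- matrix(0, k, C)
      dx <- array(0, dim(ca$x))
      for (j in seq_len(k)) {
        xs <- ca$x[, j:(j + Lo - 1L), , drop = FALSE]
        dWd[j, ] <- colSums(matrix(xs * dz, B * Lo, C))
        dx[, j:(j + Lo - 1L), ] <- dx[, j:(j + Lo - 1L), , drop = FALSE] +
          sweep(dz, 3L, pr$Wd[j, ], `*`)
      }
      grads[[i]] <- list(Wd = dWd, Wp = dWp, b = db)
      cur <- dx
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(m = lapply(p, function(w) w * 0), v = lapply(p, function(w) w * 0))
  })
}

adam_step <- function(params, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state[[i]]$m[[nm]] <- beta1 * state[[i]]$m[[nm]] + (1 - beta1) * g
      state[[i]]$v[[nm]] <- beta2 * state[[i]]$v[[nm]] + (1 - beta2) * g^2
      mhat <- state[[i]]$m[[nm]] / (1 - beta1^t)
      vhat <- state[[i]]$v[[nm]] / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# train a layer stack on a dense (n x len) matrix with binary labels.
# No class weighting: imbalance handling is the caller's (balancer's) job.
nn_train <- function(layers, x, y, rule = early_stop_rule(), seed = 1L,
                     batch_size = 32L, lr = 1e-3) {
  set_seed_stable(seed)
  net <- nn_build(layers, ncol(x))
  state <- adam_init(net$params)
  n <- nrow(x); t <- 0L
  history <- numeric(0)
  repeat {
    idx <- sample.int(n)
    epoch_losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1L, n)]
      xb <- x[bi, , drop = FALSE]; yb <- y[bi]
      fwd <- nn_forward(net, xb, training = TRUE)
      p <- as.numeric(fwd$out)
      epoch_losses <- c(epoch_losses, bce_loss(p, yb))
      d_out <- matrix((p - yb) / length(yb), ncol = 1L)
      grads <- nn_backward(net, fwd, d_out)
      t <- t + 1L
      upd <- adam_step(net$params, grads, state, t, lr = lr)
      net$params <- upd$params; state <- upd$state
    }
    history <- c(history, mean(epoch_losses))
    if (should_stop(history, rule)) break
  }
  list(net = net, history = history, epochs_run = length(history))
}

nn_scores <- function(fit, x, batch_size = 256L) {
  n <- nrow(x)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    out[bi] <- as.numeric(nn_forward(fit$net, x[bi, , drop = FALSE],
                                     training = FALSE)$out)
  }
  out
}
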