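## Minibatch Adam trainer for small dense and recurrent networks.
## Training contract shared by target models and probes: binary
## cross-entropy loss, Adam (beta1 0.9, beta2 0.999, eps 1e-8) at a fixed
## learning rate, fixed batch size, and the parameter set with the best
## validation loss retained.

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Dense net: 0 hidden layers = logistic regression, 1 hidden ReLU layer
## otherwise. X is already standardized. Returns best-on-validation params.
fit_dense <- function(X, y, Xval, yval, hidden, epochs, batch_size, lr, seed) {
  p <- ncol(X); N <- nrow(X)
  with_seed(seed, {
    ## hidden weights: He init (breaks symmetry for ReLU); output layer:
    ## zero init -- the sigmoid readout is convex in it, so the learned
    ## direction is data-driven from the first step
    params <- if (hidden > 0) {
      list(W1 = matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden),
           b1 = numeric(hidden),
           W2 = matrix(0, hidden, 1),
           b2 = 0)
    } else {
      list(W2 = matrix(0, p, 1), b2 = 0)
    }
    st <- adam_new(params)
    best <- list(loss = Inf, params = params)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      for (b0 in seq(1L, N, by = batch_size)) {
        idx <- ord[b0:min(N, b0 + batch_size - 1L)]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        m <- length(idx)
        if (hidden > 0) {
          Z1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
          H <- pmax(Z1, 0)
          s <- sigmoid(as.vector(H %*% params$W2) + params$b2)
          dz2 <- matrix((s - yb) / m, m, 1)
          dH <- dz2 %*% t(params$W2)
          dZ1 <- dH * (Z1 > 0)
          grads <- list(W1 = crossprod(Xb, dZ1), b1 = colSums(dZ1),
                        W2 = crossprod(H, dz2), b2 = sum(dz2))
        } else {
          s <- sigmoid(as.vector(Xb %*% params$W2) + params$b2)
          dz <- matrix((s - yb) / m, m, 1)
          grads <- list(W2 = crossprod(Xb, dz), b2 = sum(dz))
        }
        upd <- adam_step(params, grads, st, lr)
        params <- upd$params; st <- upd$state
      }
      pv <- dense_forward(params, Xval, hidden)$score
      history[ep] <- bce_loss(pv, yval)
      if (history[ep] < best$loss) best <- list(loss = history[ep], params = params)
    }
    list(params = best$params, val_loss = best$loss, history = history)
  })
}

dense_forward <- function(params, X, hidden) {
  if (hidden > 0) {
    H <- pmax(sweep(X %*% params$W1, 2, params$b1, "+"), 0)
    list(score = sigmoid(as.vector(H %*% params$W2) + params$b2), embed = H)
  } else {
    list(score = sigmoid(as.vector(X %*% params$W2) + params$b2), embed = X)
  }
}

## Elman recurrent net: H_t = tanh(X_t Wx + H_{t-1} Wh + bh); the last
## hidden state is the penultimate embedding. Xarr is N x F x T.
fit_rnn <- function(Xarr, y, Xval, yval, hidden, epochs, batch_size, lr, seed) {
  Fd <- dim(Xarr)[2]; Td <- dim(Xarr)[3]; N <- dim(Xarr)[1]
  with_seed(seed, {
    params <- list(
      Wx = matrix(stats::rnorm(Fd * hidden, 0, sqrt(1 / Fd)), Fd, hidden),
      Wh = matrix(stats::rnorm(hidden * hidden, 0, 0.5 * sqrt(1 / hidden)), hidden, hidden),
      bh = numeric(hidden),
      W2 = matrix(0, hidden, 1),
      b2 = 0)
    st <- adam_new(params)
    best <- list(loss = Inf, params = params)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      for (b0 in seq(1L, N, by = batch_size)) {
        idx <- ord[b0:min(N, b0 + batch_size - 1L)]
        m <- length(idx); yb <- y[idx]
        Hs <- vector("list", Td + 1L)
        Hs[[1]] <- matrix(0, m, hidden)
        for (t in seq_len(Td)) {
          Xt <- Xarr[idx, , t, drop = FALSE]; dim(Xt) <- c(m, Fd)
          Hs[[t + 1L]] <- tanh(Xt %*% params$Wx + Hs[[t]] %*% params$Wh +
                                 matrix(params$bh, m, hidden, byrow = TRUE))
        }
        s <- sigmoid(as.vector(Hs[[Td + 1L]] %*% params$W2) + params$b2)
        dz2 <- matrix((s - yb) / m, m, 1)
        grads <- list(Wx = params$Wx * 0, Wh = params$Wh * 0, bh = params$bh * 0,
                      W2 = crossprod(Hs[[Td + 1L]], dz2), b2 = sum(dz2))
        dH <- dz2 %*% t(params$W2)
        for (t in rev(seq_len(Td))) {
          dZ <- dH * (1 - Hs[[t + 1L]]^2)
          Xt <- Xarr[idx, , t, drop = FALSE]; dim(Xt) <- c(m, Fd)
          grads$Wx <- grads$Wx + crossprod(Xt, dZ)
          grads$Wh <- grads$Wh + crossprod(Hs[[t]], dZ)
          grads$bh <- grads$bh + colSums(dZ)
          dH <- dZ %*% t(params$Wh)
        }
        upd <- adam_step(params, grads, st, lr)
        params <- upd$params; st <- upd$state
      }
      pv <- rnn_forward(params, Xval)$score
      history[ep] <- bce_loss(pv, yval)
      if (history[ep] < best$loss) best <- list(loss = history[ep], params = params)
    }
    list(params = best$params, val_loss = best$loss, history = history)
  })
}

rnn_forward <- function(params, Xarr) {
  N <- dim(Xarr)[1]; Fd <- dim(Xarr)[2]; Td <- dim(Xarr)[3]
  hidden <- ncol(params$Wx)
  H <- matrix(0, N, hidden)
  for (t in seq_len(Td)) {
    Xt <- Xarr[, , t, drop = FALSE]; dim(Xt) <- c(N, Fd)
    H <- tanh(Xt %*% params$Wx + H %*% params$Wh +
                matrix(params$bh, N, hidden, byrow = TRUE))
  }
  list(score = sigmoid(as.vector(H %*% params$W2) + params$b2), embed = H)
}

cohort_flat_matrix <- function(ds) {
  t(vapply(ds$examples, function(e) as.vector(t(e$values)),
           numeric(nrow(ds$examples[[1]]$values) * ncol(ds$examples[[1]]$values))))
}

cohort_array <- function(ds) {
  Fd <- nrow(ds$examples[[1]]$values); Td <- ncol(ds$examples[[1]]$values)
  arr <- array(0, c(length(ds$examples), Fd, Td))
  for (i in seq_along(ds$examples)) arr[i, , ] <- ds$examples[[i]]$values
  arr
}

#' Train a target-task model exposing a penultimate embedding
#'
#' Fits a small binary classifier on the cohort's training split with
#' binary cross-entropy loss and the Adam optimizer at learning rate 0.001
#' and batch size 64; the parameter set with the lowest validation loss
#' across epochs is retained. Three desk-scale architectures are provided:
#' `"mlp"` (one 64-unit ReLU hidden layer on the flattened `F*T` input;
#' embedding dimension 64), `"linear"` (logistic regression; the
#' standardized input itself is the penultimate representation), and
#' `"recurrent"` (32-unit Elman network over the `T` time steps; embedding
#' is the final hidden state). Inputs are standardized per dimension using
#' training-split statistics.
#'
#' @param ds A `cohort`.
#' @param arch `"mlp"`, `"linear"`, or `"recurrent"`.
#' @param seed Integer seed controlling initialization and batch order.
#' @param epochs Training epochs, default 20.
#' @param hidden Hidden width for `"mlp"` (default 64) and `"recurrent"`
#'   (default 32 when `arch = "recurrent"` and `hidden` is left at 64).
#' @param batch_size,lr Optimizer contract; defaults 64 and 0.001.
#' @return An object of class `embedding_model` with accessors
#'   [predict_score()] and [embed()].
#' @export
train_target_model <- function(ds, arch = c("mlp", "linear", "recurrent"),
                               seed = 1, epochs = 20, hidden = 64,
                               batch_size = 64, lr = 0.001) {
  arch <- match.arg(arch)
  stopifnot(inherits(ds, "cohort"))
  tr <- ds$split == "train"; va <- ds$split == "validation"
  if (!any(tr) || !any(va)) {
    abort_enctsf("cohort needs non-empty train and validation splits",
                 "enctsf_training_error")
  }
  ytr <- ds$task_labels[tr]
  if (length(unique(ytr)) < 2) {
    abort_enctsf("training labels contain a single class; cannot fit a classifier",
                 "enctsf_training_error")
  }
  if (arch == "recurrent") {
    if (hidden == 64) hidden <- 32
    arr <- cohort_array(ds)
    mu <- apply(arr[tr, , , drop = FALSE], 2, mean)
    sdv <- apply(arr[tr, , , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    arr <- sweep(sweep(arr, 2, mu, "-"), 2, sdv, "/")
    fit <- fit_rnn(arr[tr, , , drop = FALSE], ytr, arr[va, , , drop = FALSE],
                   ds$task_labels[va], hidden, epochs, batch_size, lr, seed)
    d <- hidden
  } else {
    X <- cohort_flat_matrix(ds)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
    h <- if (arch == "mlp") hidden else 0L
    fit <- fit_dense(X[tr, , drop = FALSE], ytr, X[va, , drop = FALSE],
                     ds$task_labels[va], h, epochs, batch_size, lr, seed)
    d <- if (arch == "mlp") hidden else ncol(X)
  }
  structure(list(arch = arch, params = fit$params, mu = mu, sd = sdv,
                 hidden = if (arch == "mlp") hidden else if (arch == "recurrent") hidden else 0L,
                 dim_embed = d, seed = as.integer(seed),
                 val_loss = fit$val_loss, history = fit$history),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model: arch '%s', embedding dim %d, best val loss %.4f>\n",
              x$arch, x$dim_embed, x$val_loss))
  invisible(x)
}

model_forward <- function(model, ds) {
  if (model$arch == "recurrent") {
    arr <- cohort_array(ds)
    arr <- sweep(sweep(arr, 2, model$mu, "-"), 2, model$sd, "/")
    rnn_forward(model$params, arr)
  } else {
    X <- cohort_flat_matrix(ds)
    X <- sweep(sweep(X, 2, model$mu, "-"), 2, model$sd, "/")
    dense_forward(model$params, X, if (model$arch == "mlp") model$hidden else 0L)
  }
}

#' Predicted task scores
#'
#' @param model An `embedding_model`.
#' @param ds A `cohort` to score.
#' @return Numeric vector of scores in `[0, 1]`, one per example.
#' @export
predict_score <- function(model, ds) UseMethod("predict_score")

#' @export
predict_score.embedding_model <- function(model, ds) model_forward(model, ds)$score

#' Penultimate-layer embeddings
#'
#' @param model An `embedding_model`.
#' @param ds A `cohort` to embed.
#' @return Numeric matrix, one row per example, `model$dim_embed` columns.
#' @export
embed <- function(model, ds) UseMethod("embed")

#' @export
embed.embedding_model <- function(model, ds) model_forward(model, ds)$embed
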