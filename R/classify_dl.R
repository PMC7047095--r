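# Fully connected classifier with a forward pass transparent enough for
# DeepLIFT attribution.
#
# The architecture follows the study design this package implements: three
# hidden ReLU layers of 1000, 250 and 250 units with dropout 0.5/0.4/0.4,
# a softmax output, cross-entropy loss (binary for two classes, categorical
# otherwise), Adam with its canonical defaults, 50 epochs, batch size 30.
# The net is hand-rolled on base matrix algebra so every pre-activation is
# available to the attribution code and training is bit-deterministic
# under a seed.

#' Build an untrained dense network
#'
#' Weights are initialized with the Glorot/Xavier scaled-uniform scheme,
#' `U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out)))`, biases at
#' zero, all drawn from `seed`. ReLU activates the hidden layers (inputs
#' are already in \[0,1\], where ReLU is the identity) and softmax the
#' output; `hidden = integer(0)` yields plain multinomial logistic
#' regression.
#'
#' @param n_inputs number of input features.
#' @param n_classes number of output classes (>= 2).
#' @param hidden integer vector of hidden layer widths.
#' @param dropout per-hidden-layer dropout rates (same length as `hidden`).
#' @param class_labels optional character vector of class names (length
#'   `n_classes`); integer codes 0..K-1 otherwise.
#' @param seed integer seed for the initialization.
#' @return object of class `dense_net`: list of layers (`W` is
#'   fan_in x fan_out, `b` length fan_out, `activation` tag), dropout
#'   rates, and the class-label encoding table.
#' @export
build_network <- function(n_inputs, n_classes, hidden = c(1000L, 250L, 250L),
                          dropout = c(0.5, 0.4, 0.4), class_labels = NULL,
                          seed = 1L) {
  stopifnot(n_inputs >= 1L, n_classes >= 2L)
  if (length(hidden) != length(dropout)) {
    stop("hidden and dropout must have equal length", call. = FALSE)
  }
  if (length(dropout) && any(dropout < 0 | dropout >= 1)) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(class_labels)) class_labels <- as.character(seq_len(n_classes) - 1L)
  stopifnot(length(class_labels) == n_classes, !anyDuplicated(class_labels))
  dims <- c(n_inputs, hidden, n_classes)
  layers <- with_seed(seed, lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = numeric(fan_out),
         activation = if (l == length(dims) - 1L) "softmax" else "relu")
  }))
  structure(list(layers = layers, dropout = dropout, n_inputs = n_inputs,
                 n_classes = n_classes, classes = class_labels,
                 history = NULL, seed = seed),
            class = "dense_net")
}

#' @export
print.dense_net <- function(x, ...) {
  dims <- c(x$n_inputs, vapply(x$layers, function(l) ncol(l$W), integer(1)))
  cat(sprintf("dense_net: %s, dropout (%s), %d classes%s\n",
              paste(dims, collapse = " -> "),
              paste(x$dropout, collapse = ", "), x$n_classes,
              if (is.null(x$history)) " [untrained]" else
                sprintf(" [trained %d epochs, final loss %.4f]",
                        length(x$history$loss), utils::tail(x$history$loss, 1))))
  invisible(x)
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass with optional layer traces
#'
#' Runs the network without dropout. With `keep_layers = TRUE` it also
#' returns every layer's pre-activations and activations — the contract the
#' attribution module relies on. Pre-softmax output scores are returned as
#' the last pre-activation.
#'
#' @param model a `dense_net`.
#' @param x samples x features matrix (or a single feature vector).
#' @param keep_layers return per-layer traces.
#' @return list with `prob` (samples x classes), `logit` (pre-softmax), and
#'   when requested `pre`/`act` lists per layer.
#' @export
dense_forward <- function(model, x, keep_layers = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_inputs) {
    stop(sprintf("input has %d features, model expects %d", ncol(x), model$n_inputs),
         call. = FALSE)
  }
  a <- x
  pre <- act <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    a <- if (ly$activation == "relu") pmax(z, 0) else z
    if (keep_layers) { pre[[l]] <- z; act[[l]] <- a }
  }
  prob <- .softmax_rows(a)
  out <- list(prob = prob, logit = a)
  if (keep_layers) { out$pre <- pre; out$act <- act }
  out
}

#' Train a dense network
#'
#' Minimizes cross-entropy (binary form when the model has two classes,
#' categorical otherwise; both reduce to the same softmax gradient) with
#' Adam (step size 0.001, beta1 0.9, beta2 0.999, eps 1e-8). Inverted
#' dropout is active during training only; batch order and dropout masks
#' are drawn from `seed`, so training is deterministic.
#'
#' @param model an untrained or trained `dense_net`.
#' @param x samples x features matrix scaled to \[0,1\].
#' @param y class label vector (matched against `model$classes`).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 30).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param seed seed for shuffling and dropout.
#' @param verbose print per-epoch loss.
#' @return the trained `dense_net`, with `history$loss` per epoch.
#' @export
train_network <- function(model, x, y, epochs = 50L, batch_size = 30L,
                          lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "dense_net"), epochs >= 1L, batch_size >= 1L)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)", call. = FALSE)
  yi <- match(as.character(y), model$classes)
  if (anyNA(yi)) {
    stop("label(s) outside the model's class set: ",
         paste(unique(y[is.na(yi)]), collapse = ", "), call. = FALSE)
  }
  n <- nrow(x); K <- model$n_classes; L <- length(model$layers)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1
  mW <- lapply(model$layers, function(l) array(0, dim(l$W)))
  vW <- lapply(model$layers, function(l) array(0, dim(l$W)))
  mB <- lapply(model$layers, function(l) numeric(length(l$b)))
  vB <- lapply(model$layers, function(l) numeric(length(l$b)))
  step <- 0L
  loss_hist <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        nb <- length(idx)
        a <- x[idx, , drop = FALSE]
        acts <- vector("list", L + 1L); acts[[1L]] <- a
        pres <- vector("list", L)
        masks <- vector("list", L)
        for (l in seq_len(L)) {
          ly <- model$layers[[l]]
          z <- sweep(acts[[l]] %*% ly$W, 2, ly$b, "+")
          pres[[l]] <- z
          h <- if (ly$activation == "relu") pmax(z, 0) else z
          if (ly$activation == "relu" && model$dropout[l] > 0) {
            keep <- 1 - model$dropout[l]
            msk <- matrix(stats::runif(length(h)) < keep, nrow(h), ncol(h)) / keep
            h <- h * msk
            masks[[l]] <- msk
          }
          acts[[l + 1L]] <- h
        }
        p <- .softmax_rows(acts[[L + 1L]])
        yb <- Y[idx, , drop = FALSE]
        ep_loss <- ep_loss - sum(yb * log(pmax(p, 1e-12)))
        dZ <- (p - yb) / nb
        step <- step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], dZ)
          gB <- colSums(dZ)
          if (l > 1L) {
            dA <- tcrossprod(dZ, model$layers[[l]]$W)
            if (!is.null(masks[[l - 1L]])) dA <- dA * masks[[l - 1L]]
            dZ <- dA * (pres[[l - 1L]] > 0)
          }
          # Adam update
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW * gW
          mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
          vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB * gB
          bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
          model$layers[[l]]$W <- model$layers[[l]]$W -
            lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps)
          model$layers[[l]]$b <- model$layers[[l]]$b -
            lr * (mB[[l]] / bc1) / (sqrt(vB[[l]] / bc2) + eps)
        }
        if (!is.finite(ep_loss)) {
          stop(sprintf("non-finite training loss at epoch %d; inputs scaled to [0,1]?", ep),
               call. = FALSE)
        }
      }
      loss_hist[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, loss_hist[ep]))
    }
  })
  model$history <- list(
    loss = loss_hist,
    loss_type = if (K == 2L) "binary_cross_entropy" else "categorical_cross_entropy",
    epochs = epochs, batch_size = batch_size,
    optimizer = list(name = "adam", lr = lr, beta1 = beta1, beta2 = beta2, eps = eps),
    seed = seed)
  model
}

#' Class-probability predictions
#'
#' Dropout is disabled; rows sum to one.
#'
#' @param object a `dense_net`.
#' @param x samples x features matrix.
#' @return samples x classes probability matrix.
#' @export
predict_proba <- function(object, x) {
  p <- dense_forward(object, x)$prob
  colnames(p) <- object$classes
  p
}

#' Predict class labels from a dense network
#'
#' @param object a `dense_net`.
#' @param x samples x features matrix.
#' @param type `"class"` for labels (argmax, lowest index on ties) or
#'   `"prob"` for the probability matrix.
#' @param ... unused.
#' @return character labels or probability matrix.
#' @export
predict.dense_net <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, x)
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Save / load a dense network
#'
#' The on-disk layout is a single RDS file holding the plain-list model
#' (layer weight matrices and biases, activation tags, dropout rates and
#' the class-label encoding), so it can be reloaded by the explanation and
#' command-line code.
#'
#' @param model a `dense_net`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
save_dense_net <- function(model, path) {
  stopifnot(inherits(model, "dense_net"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_dense_net
#' @export
load_dense_net <- function(path) {
  structure(readRDS(path), class = "dense_net")
}
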