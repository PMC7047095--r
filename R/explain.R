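# DeepLIFT (Rescale rule) attribution for the dense network, class-average
# D1 marker scores, top-N marker lists, D2 pairwise orderings and the
# ablation-until-flip stability/similarity analyses.
#
# Attribution targets the pre-softmax outputs, where the summation-to-delta
# conservation property is exact for a piecewise-linear ReLU network.

#' DeepLIFT attribution scores
#'
#' Backpropagates contribution multipliers from the pre-softmax outputs to
#' the inputs. Linear layers propagate multipliers through the transposed
#' weights; ReLU units use the Rescale rule, multiplier =
#' delta-activation / delta-pre-activation relative to the reference when
#' `|delta-pre| > eps`, else the ReLU subgradient at the reference. The
#' score of input j for class k on sample i is
#' `C[i,j,k] = m(j,k) * (x_ij - ref_j)`, and for every sample and class the
#' scores sum to the output's difference from its reference value.
#'
#' @param model a trained `dense_net`.
#' @param x samples x features matrix (model input space).
#' @param reference the neutral input; default the zero vector.
#' @param eps threshold for the near-linear ReLU branch.
#' @return object of class `deeplift_scores`: array `C` (samples x
#'   features x classes), `reference`, `ref_logit` (pre-softmax output at
#'   the reference) and `logit` (per-sample pre-softmax outputs).
#' @export
deeplift_attribute <- function(model, x, reference = NULL, eps = 1e-7) {
  stopifnot(inherits(model, "dense_net"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(reference)) reference <- numeric(model$n_inputs)
  stopifnot(length(reference) == model$n_inputs)
  n <- nrow(x); p <- model$n_inputs; K <- model$n_classes
  L <- length(model$layers)
  fwd_ref <- dense_forward(model, reference, keep_layers = TRUE)
  fwd_x <- dense_forward(model, x, keep_layers = TRUE)
  C <- array(0, dim = c(n, p, K),
             dimnames = list(rownames(x), colnames(x), model$classes))
  for (i in seq_len(n)) {
    m <- diag(K)  # multipliers of the pre-softmax outputs w.r.t. themselves
    for (l in rev(seq_len(L))) {
      m <- model$layers[[l]]$W %*% m  # onto activations of layer l-1
      if (l > 1L) {
        dz <- fwd_x$pre[[l - 1L]][i, ] - fwd_ref$pre[[l - 1L]][1, ]
        da <- fwd_x$act[[l - 1L]][i, ] - fwd_ref$act[[l - 1L]][1, ]
        r <- ifelse(abs(dz) > eps, da / dz,
                    as.numeric(fwd_ref$pre[[l - 1L]][1, ] > 0))
        m <- m * r
      }
    }
    C[i, , ] <- m * (x[i, ] - reference)
  }
  structure(list(C = C, reference = reference,
                 ref_logit = fwd_ref$logit[1, ], logit = fwd_x$logit,
                 classes = model$classes),
            class = "deeplift_scores")
}

#' @export
print.deeplift_scores <- function(x, ...) {
  d <- dim(x$C)
  cat(sprintf("deeplift_scores: %d samples x %d features x %d classes\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Class-average difference scores (D1)
#'
#' For every feature j and class k, the mean over the class's samples of
#' the own-class score minus the average score over the other classes:
#' `D1[j,k] = mean_{i: y_i = k} ( C[i,j,k] - mean_{k' != k} C[i,j,k'] )`.
#' Classes without samples get an `NA` column.
#'
#' @param scores a [deeplift_attribute()] result.
#' @param y class labels aligned with the score rows.
#' @return features x classes matrix of D1 scores.
#' @export
class_average_scores <- function(scores, y) {
  stopifnot(inherits(scores, "deeplift_scores"))
  C <- scores$C
  y <- as.character(y)
  stopifnot(length(y) == dim(C)[1])
  bad <- setdiff(unique(y), scores$classes)
  if (length(bad)) stop("label(s) outside the model's classes: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  K <- dim(C)[3]
  D1 <- matrix(NA_real_, dim(C)[2], K, dimnames = list(dimnames(C)[[2]], scores$classes))
  for (k in seq_len(K)) {
    idx <- which(y == scores$classes[k])
    if (!length(idx)) next
    own <- C[idx, , k, drop = FALSE]
    others <- apply(C[idx, , -k, drop = FALSE], c(1, 2), mean)
    diff <- matrix(own, length(idx), dim(C)[2]) - others
    D1[, k] <- colMeans(diff)
  }
  D1
}

#' Top-N features per class by D1 score
#'
#' @param D1 features x classes D1 matrix (rownames = feature ids).
#' @param n how many features per class (default 300); ties break by
#'   feature order.
#' @return named list, per class an ordered character vector of feature
#'   ids of length `min(n, p)`.
#' @export
top_n_features <- function(D1, n = 300L) {
  stopifnot(n >= 1L, !is.null(rownames(D1)))
  out <- lapply(seq_len(ncol(D1)), function(k) {
    d <- D1[, k]
    if (all(is.na(d))) return(character(0))
    ord <- order(-d, seq_along(d))
    rownames(D1)[ord[seq_len(min(n, length(d)))]]
  })
  stats::setNames(out, colnames(D1))
}

#' Mean expression of top-ranked features per class
#'
#' The tabular analogue of a marker heatmap: for every class and every
#' feature in any class's top list, the mean scaled expression over that
#' class's samples.
#'
#' @param top_lists a [top_n_features()] result.
#' @param x samples x features scaled expression matrix.
#' @param y class labels aligned with rows of `x`.
#' @return data.frame with columns `class`, `feature_id`, `mean_expression`.
#' @export
topn_expression_summary <- function(top_lists, x, y) {
  feats <- unique(unlist(top_lists, use.names = FALSE))
  miss <- setdiff(feats, colnames(x))
  if (length(miss)) stop("feature(s) absent from x: ", paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  y <- as.character(y)
  do.call(rbind, lapply(sort(unique(y)), function(cl) {
    idx <- which(y == cl)
    data.frame(class = cl, feature_id = feats,
               mean_expression = colMeans(x[idx, feats, drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Pairwise score differences (D2) for one sample
#'
#' `D2[i,j,k'] = C[i,j,k] - C[i,j,k']` for the sample's class k and a rival
#' class k', sorted descending so the features most responsible for
#' preferring k over k' come first (ties by feature order).
#'
#' @param scores a [deeplift_attribute()] result.
#' @param i sample index.
#' @param k the sample's class label.
#' @param k_prime the rival class label (different from `k`).
#' @return data.frame with columns `feature_id`, `d2`, ordered descending.
#' @export
pairwise_differences <- function(scores, i, k, k_prime) {
  stopifnot(inherits(scores, "deeplift_scores"))
  if (identical(k, k_prime)) stop("k_prime must differ from k", call. = FALSE)
  ki <- match(as.character(k), scores$classes)
  kpi <- match(as.character(k_prime), scores$classes)
  if (is.na(ki) || is.na(kpi)) stop("unknown class label", call. = FALSE)
  d2 <- scores$C[i, , ki] - scores$C[i, , kpi]
  ord <- order(-d2, seq_along(d2))
  data.frame(feature_id = dimnames(scores$C)[[2]][ord], d2 = d2[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Zero features in order until the prediction flips
#'
#' Sets features to the reference value (zero in model-input space) one at
#' a time in the given order, re-running the forward pass after each step.
#' Similarity mode stops when the prediction becomes `to`; stability mode
#' (`to = NULL`) stops when it leaves `from`. Only features with strictly
#' positive D2 argue for `from`, so the caller-supplied `ordering` should
#' be truncated there; if no flip occurs within the ordering the run is
#' censored at its length.
#'
#' @param model a trained `dense_net`.
#' @param x a single input vector (model feature space, named like the
#'   model inputs).
#' @param ordering character vector of feature ids to zero, in order.
#' @param from the class the model currently predicts for `x`.
#' @param to rival class for similarity mode, or `NULL` for stability mode.
#' @param reference reference value vector (default zeros).
#' @return list with `steps` (features zeroed when stopping), `flipped`
#'   (logical), `censored` (logical) and `final_class`.
#' @export
ablate_until_flip <- function(model, x, ordering, from, to = NULL, reference = NULL) {
  stopifnot(inherits(model, "dense_net"))
  nm <- names(x)
  if (length(x) != model$n_inputs) stop("input length does not match the model", call. = FALSE)
  if (is.null(reference)) reference <- numeric(model$n_inputs)
  xv <- matrix(as.numeric(x), nrow = 1L)
  colnames(xv) <- model_input_names(model, nm)
  cur <- predict(model, xv)
  if (!identical(cur, as.character(from))) {
    stop("model does not predict '", from, "' for this sample (got '", cur, "')",
         call. = FALSE)
  }
  pos <- match(ordering, colnames(xv))
  if (anyNA(pos)) stop("ordering contains unknown feature id(s)", call. = FALSE)
  for (s in seq_along(pos)) {
    xv[1, pos[s]] <- reference[pos[s]]
    pred <- predict(model, xv)
    hit <- if (is.null(to)) !identical(pred, as.character(from))
           else identical(pred, as.character(to))
    if (hit) {
      return(list(steps = s, flipped = TRUE, censored = FALSE, final_class = pred))
    }
  }
  list(steps = length(pos), flipped = FALSE, censored = TRUE, final_class = cur)
}

# feature names for a bare vector: prefer supplied names, else synthesize
model_input_names <- function(model, nm) {
  if (!is.null(nm) && length(nm) == model$n_inputs) nm
  else sprintf("f%d", seq_len(model$n_inputs))
}

#' Class stability and similarity matrices
#'
#' For every ordered class pair (k, k') the similarity entry is the mean,
#' over correctly predicted samples of class k, of the number of features
#' that must be zeroed — in decreasing D2(k, k') order, positive D2 only —
#' before the prediction becomes k'. The stability entry of class k is the
#' mean per-sample minimum over rival orderings of the steps until the
#' prediction leaves k. Censored runs (no flip within the positive-D2
#' prefix) are excluded from the means and counted.
#'
#' @param model a trained `dense_net`.
#' @param x samples x features scaled matrix.
#' @param y class labels aligned with rows of `x`.
#' @param scores a [deeplift_attribute()] result for `x` (computed if
#'   missing).
#' @return object of class `stability_report`: `similarity` (K x K, NA
#'   diagonal), `stability` (length K), `censored` counts, `n_samples`
#'   used per class and the per-sample step logs.
#' @export
stability_similarity <- function(model, x, y, scores = NULL) {
  stopifnot(inherits(model, "dense_net"))
  if (is.null(scores)) scores <- deeplift_attribute(model, x)
  y <- as.character(y)
  classes <- model$classes
  K <- length(classes)
  pred <- predict(model, x)
  similarity <- matrix(NA_real_, K, K, dimnames = list(from = classes, to = classes))
  stability <- stats::setNames(rep(NA_real_, K), classes)
  cens_sim <- matrix(0L, K, K, dimnames = dimnames(similarity))
  cens_stab <- stats::setNames(integer(K), classes)
  n_used <- stats::setNames(integer(K), classes)
  logs <- list()
  for (k in seq_len(K)) {
    idx <- which(y == classes[k] & pred == classes[k])
    n_used[k] <- length(idx)
    if (!length(idx)) next
    sim_steps <- matrix(NA_real_, length(idx), K)
    stab_steps <- matrix(NA_real_, length(idx), K)  # leave-k steps per rival ordering
    for (a in seq_along(idx)) {
      i <- idx[a]
      for (kp in seq_len(K)) {
        if (kp == k) next
        d2 <- pairwise_differences(scores, i, classes[k], classes[kp])
        ordering <- d2$feature_id[d2$d2 > 0]
        if (!length(ordering)) next
        sim <- ablate_until_flip(model, x[i, ], ordering, classes[k],
                                 to = classes[kp])
        if (sim$flipped) sim_steps[a, kp] <- sim$steps
        stab <- ablate_until_flip(model, x[i, ], ordering, classes[k], to = NULL)
        if (stab$flipped) stab_steps[a, kp] <- stab$steps
      }
      logs[[length(logs) + 1L]] <- list(sample = i, class = classes[k],
                                        similarity = sim_steps[a, ],
                                        stability = stab_steps[a, ])
    }
    for (kp in seq_len(K)) {
      if (kp == k) next
      v <- sim_steps[, kp]
      cens_sim[k, kp] <- sum(is.na(v))
      if (any(!is.na(v))) similarity[k, kp] <- mean(v, na.rm = TRUE)
    }
    per_sample_min <- apply(stab_steps, 1, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    cens_stab[k] <- sum(is.na(per_sample_min))
    if (any(!is.na(per_sample_min))) stability[k] <- mean(per_sample_min, na.rm = TRUE)
  }
  structure(list(similarity = similarity, stability = stability,
                 censored_similarity = cens_sim, censored_stability = cens_stab,
                 n_samples = n_used, logs = logs,
                 stability_rule = "min-over-rival-orderings"),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report\n  stability (mean steps to leave class):\n")
  print(round(x$stability, 2))
  cat("  similarity (mean steps k -> k'):\n")
  print(round(x$similarity, 2))
  invisible(x)
}

#' Per-sample score table
#'
#' @param scores a [deeplift_attribute()] result.
#' @param i sample index.
#' @return features x classes matrix of scores for sample `i`.
#' @export
per_sample_scores <- function(scores, i) {
  stopifnot(inherits(scores, "deeplift_scores"))
  m <- scores$C[i, , ]
  dimnames(m) <- list(dimnames(scores$C)[[2]], scores$classes)
  m
}

#' Export explanation tables as TSV
#'
#' Writes the D1 matrix, per-class top-N lists (class, rank, feature_id,
#' d1), and — when a stability report is given — the similarity and
#' stability tables.
#'
#' @param D1 features x classes D1 matrix.
#' @param top_lists a [top_n_features()] result.
#' @param dir output directory.
#' @param stability optional `stability_report`.
#' @return invisibly, the directory.
#' @export
write_explanation <- function(D1, top_lists, dir, stability = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(D1, file.path(dir, "d1_scores.tsv"))
  top_df <- do.call(rbind, lapply(names(top_lists), function(cl) {
    ids <- top_lists[[cl]]
    if (!length(ids)) return(NULL)
    data.frame(class = cl, rank = seq_along(ids), feature_id = ids,
               d1 = D1[ids, cl], row.names = NULL, stringsAsFactors = FALSE)
  }))
  data.table::fwrite(top_df, file.path(dir, "top_features.tsv"), sep = "\t", quote = FALSE)
  if (!is.null(stability)) {
    write_matrix_tsv(stability$similarity, file.path(dir, "similarity.tsv"),
                     id_col = "from_class")
    df <- data.frame(class = names(stability$stability),
                     mean_steps = as.numeric(stability$stability),
                     censored = as.integer(stability$censored_stability),
                     n_samples = as.integer(stability$n_samples))
    data.table::fwrite(df, file.path(dir, "stability.tsv"), sep = "\t", quote = FALSE)
  }
  invisible(dir)
}
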