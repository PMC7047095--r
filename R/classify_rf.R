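# Two-stage random-forest classifier.
#
# Stage 1 grows 100 trees on all features and ranks them by Gini
# importance (mean decrease in Gini impurity over trees); the top 1000
# enter stage 2, a 500-tree forest. mtry = floor(sqrt(p)) at both stages.
# Before each stage every class is downsampled, without replacement, to
# the size of the smallest class; the two stages draw their downsamples
# independently from the seed stream.

.downsample_classes <- function(y) {
  tab <- table(y)
  m <- min(tab)
  idx <- unlist(lapply(names(tab), function(cl) {
    pool <- which(y == cl)
    if (length(pool) == m) pool else sample(pool, m)
  }), use.names = FALSE)
  sort(idx)
}

.fit_forest <- function(x, y_int, n_classes, ntree, mtry) {
  n <- nrow(x)
  boot <- matrix(sample.int(n, n * ntree, replace = TRUE), nrow = n, ncol = ntree) - 1L
  seeds <- sample.int(.Machine$integer.max, ntree)
  fit <- rf_fit_cpp(x, y_int, n_classes, ntree, mtry, boot, seeds)
  fit$mtry <- mtry
  fit$ntree <- ntree
  fit
}

#' Fit the two-stage random forest
#'
#' @param x samples x features numeric matrix with column names.
#' @param y class label vector (>= 2 classes, each with >= 2 samples).
#' @param seed integer seed driving downsampling, bootstraps and per-node
#'   feature subsampling.
#' @param n_select number of stage-1 features passed to stage 2 (default
#'   1000; all features when p < n_select).
#' @param ntree_stage1,ntree_stage2 ensemble sizes (defaults 100 and 500).
#' @return object of class `two_stage_rf` with the stage-1 importance
#'   vector, `selected_features`, both forests and the class encoding.
#' @export
two_stage_fit <- function(x, y, seed = 1L, n_select = 1000L,
                          ntree_stage1 = 100L, ntree_stage2 = 500L) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  tab <- table(y)
  if (any(tab < 2L)) {
    stop("class(es) with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "),
         "; run filter_small_classes first", call. = FALSE)
  }
  y_int <- match(y, classes) - 1L
  p <- ncol(x)
  mtry1 <- max(1L, as.integer(floor(sqrt(p))))
  with_seed(seed, {
    idx1 <- .downsample_classes(y)
    stage1 <- .fit_forest(x[idx1, , drop = FALSE], y_int[idx1], length(classes),
                          ntree_stage1, mtry1)
    importance <- as.numeric(stage1$importance)
    names(importance) <- colnames(x)
    n_keep <- min(n_select, p)
    sel <- order(-importance, seq_len(p))[seq_len(n_keep)]
    sel <- sort(sel)  # preserve original feature order in the stage-2 matrix
    selected <- colnames(x)[sel]
    mtry2 <- max(1L, as.integer(floor(sqrt(n_keep))))
    idx2 <- .downsample_classes(y)
    stage2 <- .fit_forest(x[idx2, sel, drop = FALSE], y_int[idx2],
                          length(classes), ntree_stage2, mtry2)
    structure(list(importance = importance, selected_features = selected,
                   stage1 = stage1, stage2 = stage2, classes = classes,
                   n_select = n_keep, seed = seed,
                   downsampled_n = list(stage1 = as.integer(table(y[idx1])),
                                        stage2 = as.integer(table(y[idx2])))),
              class = "two_stage_rf")
  })
}

#' @export
print.two_stage_rf <- function(x, ...) {
  cat(sprintf("two_stage_rf: %d-tree stage 1 on %d features -> top %d -> %d-tree stage 2; %d classes\n",
              x$stage1$ntree, length(x$importance), x$n_select,
              x$stage2$ntree, length(x$classes)))
  invisible(x)
}

#' Predict from a two-stage forest
#'
#' Majority vote over the stage-2 ensemble; vote fractions sum to one and
#' ties break to the lowest class index.
#'
#' @param object a `two_stage_rf`.
#' @param x samples x features matrix containing all selected features
#'   (matched by column name).
#' @param type `"class"` or `"vote"` (per-class vote fractions).
#' @param ... unused.
#' @return character labels or a samples x classes vote-fraction matrix.
#' @export
predict.two_stage_rf <- function(object, x, type = c("class", "vote"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x))
  miss <- setdiff(object$selected_features, colnames(x))
  if (length(miss)) {
    stop("input is missing selected feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5), call. = FALSE)
  }
  xs <- x[, object$selected_features, drop = FALSE]
  votes <- rf_votes_cpp(object$stage2$trees, xs, length(object$classes))
  colnames(votes) <- object$classes
  rownames(votes) <- rownames(x)
  if (type == "vote") return(votes)
  object$classes[max.col(votes, ties.method = "first")]
}

#' Save / load a two-stage forest
#'
#' Stores the plain-list model (stage-1 importances, selected feature ids,
#' both tree ensembles and the class encoding) as RDS.
#'
#' @param model a `two_stage_rf`.
#' @param path file path.
#' @export
save_two_stage_rf <- function(model, path) {
  stopifnot(inherits(model, "two_stage_rf"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_two_stage_rf
#' @export
load_two_stage_rf <- function(path) {
  structure(readRDS(path), class = "two_stage_rf")
}
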