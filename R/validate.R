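# Validation harness: stratified fivefold CV, one-dataset-out splits with
# the class-retention constraint, and the reported metrics (accuracy,
# per-class precision, confusion matrices).

#' Stratified k-fold split plans
#'
#' Shuffles each class independently and deals its members round-robin to
#' the folds, so per-class counts across folds differ by at most one and
#' every sample tests exactly once.
#'
#' @param y class label vector.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param sample_ids optional ids; indices are used otherwise.
#' @return list of split plans, each a list with `name`, `fold`, `train`,
#'   `test` (sample ids).
#' @export
stratified_kfold <- function(y, k = 5L, seed = 1L, sample_ids = NULL) {
  y <- as.character(y)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(y))
  stopifnot(length(sample_ids) == length(y), !anyDuplicated(sample_ids))
  tab <- table(y)
  if (any(tab < k)) {
    stop("class(es) smaller than k = ", k, ": ",
         paste(names(tab)[tab < k], collapse = ", "),
         "; run filter_small_classes first", call. = FALSE)
  }
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cl in names(tab)) {
      pool <- which(y == cl)
      pool <- pool[sample.int(length(pool))]
      fold_of[pool] <- rep_len(seq_len(k), length(pool))
    }
  })
  lapply(seq_len(k), function(f) {
    list(name = sprintf("fold_%d", f), fold = f,
         train = sample_ids[fold_of != f],
         test = sample_ids[fold_of == f])
  })
}

#' One-dataset-out split plans
#'
#' One plan per eligible dataset: a dataset is eligible iff every target
#' class present in it also occurs in at least one other dataset, so the
#' held-out classes remain represented in training.
#'
#' @param metadata data.frame with `sample_id`, `dataset_id` and the target
#'   column.
#' @param target name of the annotation column being predicted.
#' @return list of split plans (`name`, `dataset`, `train`, `test`).
#' @export
one_dataset_out_splits <- function(metadata, target = "tissue") {
  stopifnot(all(c("sample_id", "dataset_id", target) %in% colnames(metadata)))
  ds <- unique(metadata$dataset_id)
  if (length(ds) < 2L) stop("need at least 2 datasets", call. = FALSE)
  cls_of <- split(as.character(metadata[[target]]), metadata$dataset_id)
  plans <- list()
  for (d in ds) {
    held_classes <- unique(cls_of[[d]])
    other_classes <- unique(unlist(cls_of[setdiff(ds, d)], use.names = FALSE))
    if (!all(held_classes %in% other_classes)) next
    test <- metadata$dataset_id == d
    plans[[length(plans) + 1L]] <- list(
      name = sprintf("odo_%s", d), dataset = d,
      train = metadata$sample_id[!test],
      test = metadata$sample_id[test])
  }
  if (!length(plans)) {
    stop("no dataset is eligible for one-dataset-out validation", call. = FALSE)
  }
  plans
}

#' Evaluate predictions against truth
#'
#' @param predicted,truth equal-length label vectors.
#' @param classes the full class set (rows/columns of the confusion matrix).
#' @return object of class `eval_report`: `accuracy`, `precision` (named,
#'   `NA` for classes never predicted), `confusion` (true x predicted
#'   counts) and `n_test`.
#' @export
evaluate_predictions <- function(predicted, truth, classes = sort(unique(c(predicted, truth)))) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.character(predicted); truth <- as.character(truth)
  bad <- setdiff(unique(c(predicted, truth)), classes)
  if (length(bad)) stop("label(s) outside the class set: ", paste(bad, collapse = ", "), call. = FALSE)
  confusion <- table(factor(truth, levels = classes),
                     factor(predicted, levels = classes), dnn = c("true", "predicted"))
  confusion <- unclass(confusion)
  n_pred <- colSums(confusion)
  precision <- ifelse(n_pred > 0, diag(confusion) / n_pred, NA_real_)
  names(precision) <- classes
  structure(list(accuracy = sum(diag(confusion)) / length(truth),
                 precision = precision, confusion = confusion,
                 n_test = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.3f on %d samples\n", x$accuracy, x$n_test))
  print(round(x$precision, 3))
  invisible(x)
}

#' Aggregate split reports
#'
#' The headline number is the unweighted mean of per-split accuracies (one
#' average per held-out fold/dataset); a sample-size-weighted mean is also
#' returned.
#'
#' @param reports list of [evaluate_predictions()] results.
#' @return list with `mean_accuracy`, `weighted_accuracy`, `per_split`
#'   (data.frame) and the summed confusion matrix.
#' @export
aggregate_reports <- function(reports) {
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  n <- vapply(reports, function(r) r$n_test, numeric(1))
  nm <- names(reports)
  if (is.null(nm)) nm <- sprintf("split_%d", seq_along(reports))
  conf <- Reduce(`+`, lapply(reports, function(r) r$confusion))
  list(mean_accuracy = mean(acc),
       weighted_accuracy = sum(acc * n) / sum(n),
       per_split = data.frame(split = nm, accuracy = acc, n_test = n,
                              stringsAsFactors = FALSE),
       confusion = conf)
}

#' Run a model over a list of split plans
#'
#' The work-horse behind the fivefold-CV and one-dataset-out experiments.
#' For every split it fits the MinMax scaler (on the training rows by
#' default, or on the full matrix with `scaler_scope = "global"`, the
#' paper-faithful variant), scales both sides with clipping, trains the
#' requested model and evaluates on the held-out rows.
#'
#' @param x samples x features matrix (RPM-normalized, zero-filtered,
#'   unscaled), rownames = sample ids.
#' @param y named or aligned class label vector.
#' @param splits list of split plans from [stratified_kfold()] or
#'   [one_dataset_out_splits()].
#' @param model `"dl"` or `"rf"`.
#' @param seed base seed; split s uses `seed + s`.
#' @param scaler_scope `"train"` (no leakage) or `"global"`.
#' @param dl_args extra arguments to [train_network()] /
#'   [build_network()] (e.g. `hidden`, `dropout`, `epochs`).
#' @param rf_args extra arguments to [two_stage_fit()].
#' @return list with the [aggregate_reports()] summary, per-split reports
#'   and per-split predictions.
#' @export
run_model_validation <- function(x, y, splits, model = c("dl", "rf"), seed = 1L,
                                 scaler_scope = c("train", "global"),
                                 dl_args = list(), rf_args = list()) {
  model <- match.arg(model)
  scaler_scope <- match.arg(scaler_scope)
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  y <- stats::setNames(as.character(y), rownames(x))
  classes <- sort(unique(y))
  reports <- list(); predictions <- list()
  global_params <- if (scaler_scope == "global") minmax_fit(x) else NULL
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    leak <- intersect(sp$train, sp$test)
    if (length(leak)) stop("split '", sp$name, "' leaks sample(s): ",
                           paste(utils::head(leak, 3), collapse = ", "), call. = FALSE)
    xtr <- x[sp$train, , drop = FALSE]; xte <- x[sp$test, , drop = FALSE]
    params <- if (is.null(global_params)) minmax_fit(xtr) else global_params
    xtr <- minmax_transform(xtr, params)
    xte <- minmax_transform(xte, params)
    ytr <- y[sp$train]; yte <- y[sp$test]
    split_seed <- as.integer(seed) + s
    if (model == "dl") {
      net <- do.call(build_network, c(list(n_inputs = ncol(x),
                                           n_classes = length(classes),
                                           class_labels = classes,
                                           seed = split_seed),
                                      dl_args[intersect(names(dl_args),
                                                        c("hidden", "dropout"))]))
      net <- do.call(train_network, c(list(model = net, x = xtr, y = ytr,
                                           seed = split_seed),
                                      dl_args[intersect(names(dl_args),
                                                        c("epochs", "batch_size", "lr"))]))
      pred <- predict(net, xte)
    } else {
      fit <- do.call(two_stage_fit, c(list(x = xtr, y = ytr, seed = split_seed), rf_args))
      pred <- predict(fit, xte)
    }
    reports[[sp$name]] <- evaluate_predictions(pred, yte, classes)
    predictions[[sp$name]] <- stats::setNames(pred, sp$test)
  }
  c(aggregate_reports(reports), list(reports = reports, predictions = predictions))
}

#' Write evaluation reports as TSV
#'
#' Writes one row per split plus an aggregate row, and one confusion
#' matrix TSV per split.
#'
#' @param result a [run_model_validation()] result.
#' @param dir output directory.
#' @return invisibly, the summary file path.
#' @export
write_eval_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_path <- file.path(dir, "evaluation.tsv")
  df <- result$per_split
  df <- rbind(df, data.frame(split = "mean", accuracy = result$mean_accuracy,
                             n_test = sum(df$n_test)))
  data.table::fwrite(df, summary_path, sep = "\t", quote = FALSE)
  for (nm in names(result$reports)) {
    write_matrix_tsv(result$reports[[nm]]$confusion,
                     file.path(dir, sprintf("confusion_%s.tsv", nm)),
                     id_col = "true_class")
  }
  invisible(summary_path)
}
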