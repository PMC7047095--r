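test_that("stratified folds partition samples with per-class balance within 1", {
  y <- c(rep("A", 10), rep("B", 5))
  ids <- sprintf("s%02d", seq_along(y))
  folds <- stratified_kfold(y, k = 5, seed = 1, sample_ids = ids)
  test_sets <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(test_sets), ids)
  expect_identical(sum(lengths(test_sets)), length(ids))  # pairwise disjoint
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    yt <- y[match(f$test, ids)]
    expect_identical(sum(yt == "A"), 2L)  # 10 / 5
    expect_identical(sum(yt == "B"), 1L)  # 5 / 5
  }

  # counting oracle on a random label vector
  set.seed(2)
  y2 <- sample(c("u", "v", "w"), 47, replace = TRUE, prob = c(.5, .3, .2))
  y2 <- c(y2, rep(c("u", "v", "w"), 5))  # ensure every class >= k
  folds2 <- stratified_kfold(y2, k = 5, seed = 3)
  for (cl in unique(y2)) {
    per_fold <- vapply(folds2, function(f) sum(y2[as.integer(f$test)] == cl), integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1L)
    expect_identical(sum(per_fold), sum(y2 == cl))
  }
  expect_error(stratified_kfold(c("A", "A", "B"), k = 5), "smaller than k")
})

test_that("one-dataset-out keeps held-out classes represented in training", {
  md <- data.frame(sample_id = sprintf("s%d", 1:6),
                   dataset_id = rep(c("A", "B", "C"), each = 2),
                   tissue = c("T1", "T1", "T1", "T1", "T2", "T2"))
  plans <- one_dataset_out_splits(md, "tissue")
  expect_setequal(vapply(plans, `[[`, "", "dataset"), c("A", "B"))  # C is T2's only dataset

  md$tissue <- rep(c("T1", "T2"), 3)  # every class in all three datasets
  plans2 <- one_dataset_out_splits(md, "tissue")
  expect_length(plans2, 3)

  # oracle re-check of the retention predicate on a simulated cohort
  co <- small_cohort()
  plans3 <- one_dataset_out_splits(co$metadata, "tissue")
  for (d in unique(co$metadata$dataset_id)) {
    held <- unique(co$metadata$tissue[co$metadata$dataset_id == d])
    rest <- unique(co$metadata$tissue[co$metadata$dataset_id != d])
    eligible <- all(held %in% rest)
    expect_identical(d %in% vapply(plans3, `[[`, "", "dataset"), eligible)
  }
  # leak-freedom: no test sample or test dataset in training
  for (p in plans3) {
    expect_length(intersect(p$train, p$test), 0)
    train_ds <- unique(co$metadata$dataset_id[co$metadata$sample_id %in% p$train])
    expect_false(p$dataset %in% train_ds)
  }
})

test_that("evaluation metrics match their definitions", {
  perfect <- evaluate_predictions(c("a", "b", "a"), c("a", "b", "a"))
  expect_identical(perfect$accuracy, 1)
  expect_identical(diag(perfect$confusion), c(a = 2L, b = 1L))

  const <- evaluate_predictions(rep("x", 4), c("x", "x", "y", "y"),
                                classes = c("x", "y"))
  expect_identical(const$accuracy, 0.5)
  expect_identical(const$precision[["x"]], 0.5)
  expect_true(is.na(const$precision[["y"]]))
  expect_identical(sum(const$confusion), const$n_test)

  set.seed(4)
  pred <- sample(letters[1:3], 60, replace = TRUE)
  truth <- sample(letters[1:3], 60, replace = TRUE)
  r <- evaluate_predictions(pred, truth, letters[1:3])
  expect_identical(r$accuracy, mean(pred == truth))  # hand-counted agreement
  for (i in letters[1:3]) for (j in letters[1:3]) {
    expect_identical(r$confusion[i, j], sum(truth == i & pred == j))
  }
  expect_error(evaluate_predictions(c("a", "z"), c("a", "a"), c("a", "b")), "z")
})

test_that("aggregation averages per-split accuracies unweighted", {
  r1 <- evaluate_predictions(c("a", "a"), c("a", "b"), c("a", "b"))      # 0.5
  r2 <- evaluate_predictions(rep("a", 4), rep("a", 4), c("a", "b"))      # 1.0
  agg <- aggregate_reports(list(s1 = r1, s2 = r2))
  expect_identical(agg$mean_accuracy, 0.75)
  expect_identical(agg$weighted_accuracy, (0.5 * 2 + 1 * 4) / 6)
  expect_identical(sum(agg$confusion), 6L)
})

test_that("a memorizing 1-NN scores perfectly under CV on duplicated points", {
  # harness sanity check: every test point has an exact duplicate in training
  base <- matrix(runif(30), 10, 3)
  x <- rbind(base, base, base, base, base)
  rownames(x) <- sprintf("s%02d", 1:50)
  y <- rep(rep(c("p", "q"), each = 5), 5)
  folds <- stratified_kfold(y, k = 5, seed = 9, sample_ids = rownames(x))
  acc <- vapply(folds, function(f) {
    pred <- vapply(f$test, function(s) {
      d <- colSums((t(x[f$train, ]) - x[s, ])^2)
      y[match(f$train[which.min(d)], rownames(x))]
    }, "")
    mean(pred == y[match(f$test, rownames(x))])
  }, numeric(1))
  expect_identical(mean(acc), 1)
})

test_that("run_model_validation trains and evaluates over splits without leakage", {
  co <- small_cohort()
  d <- cohort_xy(co)
  folds <- stratified_kfold(d$y, k = 3, seed = 2, sample_ids = rownames(d$x))
  res <- run_model_validation(d$x, d$y, folds, model = "rf", seed = 1,
                              rf_args = list(ntree_stage1 = 40, ntree_stage2 = 60))
  expect_length(res$reports, 3)
  expect_gte(res$mean_accuracy, 0.9)  # learnable cohort
  expect_setequal(unlist(lapply(res$predictions, names)), rownames(d$x))

  dl <- run_model_validation(d$x, d$y, folds[1], model = "dl", seed = 1,
                             dl_args = list(hidden = c(64L), dropout = 0.3,
                                            epochs = 40))
  expect_gte(dl$mean_accuracy, 0.9)

  dir <- withr::local_tempdir()
  write_eval_report(res, dir)
  tsv <- read.delim(file.path(dir, "evaluation.tsv"))
  expect_identical(tsv$split[nrow(tsv)], "mean")
  expect_equal(tsv$accuracy[nrow(tsv)], res$mean_accuracy, tolerance = 1e-12)
})
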