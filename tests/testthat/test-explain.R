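test_that("linear model attribution equals weight times input", {
  net <- build_network(2, 2, hidden = integer(0), dropout = numeric(0),
                       class_labels = c("k0", "k1"), seed = 1)
  net$layers[[1]]$W <- cbind(c(2, -1), c(0.5, 3))
  net$layers[[1]]$b <- c(0.1, -0.2)
  x <- matrix(c(3, 1), 1, 2, dimnames = list("s1", c("fa", "fb")))
  sc <- deeplift_attribute(net, x)
  expect_equal(sc$C[1, , "k0"], c(fa = 6, fb = -1))
  expect_equal(sc$C[1, , "k1"], c(fa = 1.5, fb = 3))
  # input equal to the reference: all scores exactly zero
  zero <- deeplift_attribute(net, matrix(0, 1, 2))
  expect_identical(max(abs(zero$C)), 0)
})

test_that("summation-to-delta holds through ReLU layers (forward-pass oracle)", {
  net <- random_network(7, 3, hidden = c(12, 6), seed = 31)
  set.seed(32)
  x <- matrix(runif(140, -1, 1), 20, 7)
  sc <- deeplift_attribute(net, x)
  delta_fwd <- sweep(dense_forward(net, x)$logit, 2, sc$ref_logit)
  delta_attr <- apply(sc$C, c(1, 3), sum)
  expect_equal(delta_attr, delta_fwd, tolerance = 1e-5, ignore_attr = TRUE)
  # non-zero reference too
  ref <- runif(7)
  sc2 <- deeplift_attribute(net, x, reference = ref)
  delta_fwd2 <- sweep(dense_forward(net, x)$logit, 2, sc2$ref_logit)
  expect_equal(apply(sc2$C, c(1, 3), sum), delta_fwd2,
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("D1 matches the brute-force double loop", {
  net <- random_network(5, 3, hidden = 8L, seed = 41)
  set.seed(42)
  x <- matrix(runif(60), 12, 5, dimnames = list(NULL, sprintf("f%d", 1:5)))
  y <- rep(net$classes, each = 4)
  sc <- deeplift_attribute(net, x)
  D1 <- class_average_scores(sc, y)
  K <- 3
  for (k in seq_len(K)) {
    for (j in 1:5) {
      idx <- which(y == net$classes[k])
      vals <- vapply(idx, function(i) {
        sc$C[i, j, k] - mean(sc$C[i, j, setdiff(seq_len(K), k)])
      }, numeric(1))
      expect_equal(D1[j, k], mean(vals), tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # K = 2 with a single sample collapses to the score difference
  net2 <- random_network(4, 2, hidden = 6L, seed = 43)
  x1 <- matrix(runif(4), 1, 4, dimnames = list(NULL, sprintf("g%d", 1:4)))
  sc2 <- deeplift_attribute(net2, x1)
  D12 <- class_average_scores(sc2, net2$classes[1])
  expect_equal(D12[, 1], sc2$C[1, , 1] - sc2$C[1, , 2], ignore_attr = TRUE)
  # identical scores across classes give D1 == 0
  sc2$C[, , 2] <- sc2$C[, , 1]
  expect_equal(unname(class_average_scores(sc2, net2$classes[1])[, 1]),
               rep(0, 4))
})

test_that("top-N ranking is descending with feature-order tie-breaks", {
  D1 <- matrix(c(0.2, 0.9, 0.9, -1, 0, 1, 0, 0), 4, 2,
               dimnames = list(sprintf("f%d", 1:4), c("a", "b")))
  top <- top_n_features(D1, 3)
  expect_identical(top$a, c("f2", "f3", "f1"))   # tie f2/f3 -> feature order
  expect_identical(top$b, c("f2", "f1", "f3"))   # one-hot ranks first
  expect_identical(top_n_features(D1, 99)$a, c("f2", "f3", "f1", "f4"))
})

test_that("top-N expression summary equals brute-force group means", {
  set.seed(5)
  x <- matrix(runif(40), 8, 5, dimnames = list(sprintf("s%d", 1:8), sprintf("f%d", 1:5)))
  y <- rep(c("a", "b"), each = 4)
  top <- list(a = c("f3", "f1"), b = c("f2"))
  tab <- topn_expression_summary(top, x, y)
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$mean_expression[r],
                 mean(x[y == tab$class[r], tab$feature_id[r]]))
  }
  one <- topn_expression_summary(list(a = "f1"), x[1, , drop = FALSE], "a")
  expect_identical(one$mean_expression, unname(x[1, "f1"]))
})

test_that("D2 orderings sort score differences descending", {
  net <- random_network(6, 3, hidden = 5L, seed = 51)
  x <- matrix(runif(6), 1, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
  sc <- deeplift_attribute(net, x)
  d2 <- pairwise_differences(sc, 1, net$classes[1], net$classes[2])
  brute <- sc$C[1, , 1] - sc$C[1, , 2]
  expect_equal(d2$d2, unname(sort(brute, decreasing = TRUE)))
  expect_identical(d2$feature_id, names(brute)[order(-brute, seq_along(brute))])
  expect_error(pairwise_differences(sc, 1, "a", "a"), "differ")
  # equal columns: all-zero differences, order = feature order
  sc$C[1, , 2] <- sc$C[1, , 1]
  d2z <- pairwise_differences(sc, 1, net$classes[1], net$classes[2])
  expect_identical(d2z$feature_id, sprintf("f%d", 1:6))
  expect_identical(unique(d2z$d2), 0)
})

test_that("ablation flips a single-feature-driven linear model in one step", {
  net <- build_network(3, 2, hidden = integer(0), dropout = numeric(0),
                       class_labels = c("neg", "pos"), seed = 1)
  net$layers[[1]]$W <- cbind(c(0, 1, 1), c(10, 0, 0))  # f1 alone decides "pos"
  net$layers[[1]]$b <- c(0, 0)
  x <- c(f1 = 1, f2 = 0.5, f3 = 0.5)
  expect_identical(predict(net, matrix(x, 1, 3)), "pos")
  res <- ablate_until_flip(net, x, c("f1", "f2", "f3"), from = "pos", to = "neg")
  expect_identical(res$steps, 1L)
  expect_true(res$flipped)
  # model not predicting `from` is rejected per the precondition
  expect_error(ablate_until_flip(net, x, "f1", from = "neg"), "does not predict")
  # no flip within the ordering: censored at the cap
  res2 <- ablate_until_flip(net, x, c("f2", "f3"), from = "pos", to = "neg")
  expect_true(res2$censored)
  expect_identical(res2$steps, 2L)
})

test_that("stability and similarity matrices match a brute-force re-run", {
  co <- generate_cohort(sim_config(n_classes = 3, datasets_per_class = 2,
                                   samples_per_dataset = 5, n_srna = 20,
                                   n_contaminant = 0, markers_per_class = 4,
                                   marker_log2fc = 4, zero_inflation = 0,
                                   sex_effect_features = 0,
                                   age_effect_features = 0, seed = 61))
  d <- cohort_xy(co)
  xs <- minmax_transform(d$x, minmax_fit(d$x))
  net <- build_network(ncol(xs), 3, hidden = 16L, dropout = 0.2,
                       class_labels = sort(unique(d$y)), seed = 1)
  net <- train_network(net, xs, d$y, epochs = 40, batch_size = 8, seed = 1)
  sc <- deeplift_attribute(net, xs)
  rep_ <- stability_similarity(net, xs, d$y, sc)
  K <- 3

  # independent oracle: naive forward pass + order-then-zero loop
  naive_predict <- function(v) {
    a <- matrix(v, 1)
    for (l in net$layers) {
      a <- a %*% l$W + matrix(l$b, 1, length(l$b))
      if (l$activation == "relu") a <- pmax(a, 0)
    }
    net$classes[which.max(a)]
  }
  pred <- vapply(seq_len(nrow(xs)), function(i) naive_predict(xs[i, ]), "")
  sim_o <- matrix(NA_real_, K, K)
  stab_o <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    idx <- which(d$y == net$classes[k] & pred == net$classes[k])
    expect_identical(length(idx), as.integer(rep_$n_samples[k]))
    sim_steps <- matrix(NA_real_, length(idx), K)
    stab_min <- rep(NA_real_, length(idx))
    for (a in seq_along(idx)) {
      i <- idx[a]
      leave_steps <- rep(NA_real_, K)
      for (kp in seq_len(K)) {
        if (kp == k) next
        dd <- sc$C[i, , k] - sc$C[i, , kp]
        ord <- names(dd)[order(-dd, seq_along(dd))]
        ord <- ord[dd[ord] > 0]
        v <- xs[i, ]
        for (s in seq_along(ord)) {
          v[ord[s]] <- 0
          p <- naive_predict(v)
          if (is.na(sim_steps[a, kp]) && p == net$classes[kp]) sim_steps[a, kp] <- s
          if (is.na(leave_steps[kp]) && p != net$classes[k]) leave_steps[kp] <- s
          if (!is.na(sim_steps[a, kp]) && !is.na(leave_steps[kp])) break
        }
      }
      stab_min[a] <- if (all(is.na(leave_steps))) NA_real_ else min(leave_steps, na.rm = TRUE)
    }
    for (kp in setdiff(seq_len(K), k)) {
      if (any(!is.na(sim_steps[, kp]))) sim_o[k, kp] <- mean(sim_steps[, kp], na.rm = TRUE)
    }
    if (any(!is.na(stab_min))) stab_o[k] <- mean(stab_min, na.rm = TRUE)
  }
  expect_equal(unname(rep_$similarity), sim_o)
  expect_equal(unname(rep_$stability), stab_o)

  # stability can only be reached sooner than any targeted flip (per sample)
  for (lg in rep_$logs) {
    if (all(is.na(lg$similarity))) next
    expect_lte(min(lg$stability, na.rm = TRUE), min(lg$similarity, na.rm = TRUE))
  }
  # 3-class shape: NA diagonal, stability entries per class
  expect_true(all(is.na(diag(rep_$similarity))))
  expect_length(rep_$stability, 3)
})

test_that("score tables round-trip through TSV at full precision", {
  net <- random_network(8, 3, hidden = 6L, seed = 71)
  x <- matrix(runif(16), 2, 8, dimnames = list(c("s1", "s2"), sprintf("f%d", 1:8)))
  sc <- deeplift_attribute(net, x)
  tab <- per_sample_scores(sc, 2)
  expect_identical(dim(tab), c(8L, 3L))
  expect_identical(tab["f3", 2], sc$C[2, "f3", 2])
  dir <- withr::local_tempdir()
  srnaugment:::write_matrix_tsv(tab, file.path(dir, "scores.tsv"))
  back <- read.delim(file.path(dir, "scores.tsv"), check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), tab, tolerance = 1e-12, ignore_attr = TRUE)
})
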