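# Shared fixtures, generated in code. The small cohort backs most unit
# tests; the full-size acceptance cohort (2000 sRNAs, 3 datasets/class,
# 30 samples/dataset) is built lazily and cached for the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(seed = 7) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_classes = 3, datasets_per_class = 2,
                      samples_per_dataset = 12, n_srna = 300,
                      n_contaminant = 100, markers_per_class = 8,
                      marker_log2fc = 3, seed = seed)
    .fixture_env[[key]] <- generate_cohort(cfg)
  }
  .fixture_env[[key]]
}

acceptance_cohort <- function(null = FALSE) {
  key <- if (null) "acc_null" else "acc"
  if (is.null(.fixture_env[[key]])) {
    cfg <- if (null) {
      sim_config(marker_log2fc = 0, batch_sd = 0, sex_log2fc = 0,
                 age_slope = 0, seed = 202L)
    } else {
      sim_config(seed = 101L)  # defaults: 3 classes, 3 ds/class, 30/ds, 2000 sRNA, 20 markers, lfc 3
    }
    .fixture_env[[key]] <- generate_cohort(cfg)
  }
  .fixture_env[[key]]
}

# cohort -> samples x features sRNA matrix plus aligned labels
cohort_xy <- function(cohort, feature_set = "srna") {
  x <- prepare_features(cohort$counts, cohort$feature_kind, feature_set)
  y <- stats::setNames(cohort$metadata$tissue, cohort$metadata$sample_id)[rownames(x)]
  list(x = x, y = y)
}

# small random trained-ish network with arbitrary weights, for attribution tests
random_network <- function(n_inputs, n_classes, hidden, seed) {
  net <- build_network(n_inputs, n_classes, hidden = hidden,
                       dropout = rep(0, length(hidden)), seed = seed)
  # make biases non-zero so references have non-trivial activations
  set.seed(seed + 1)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$b <- stats::rnorm(length(net$layers[[l]]$b), 0, 0.3)
  }
  net
}
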