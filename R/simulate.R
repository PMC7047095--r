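# Synthetic sRNA cohort generator.
#
# Emulates the statistical structure of a multi-dataset small RNA-seq
# compendium: negative-binomial counts, per-class planted marker sRNAs,
# per-dataset multiplicative batch shifts, weak sex and age effects planted
# in both the sRNA and the contaminant feature blocks, per-sample library
# sizes, and independent zero inflation.

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. Defaults
#' describe a cohort that is learnable by the downstream classifiers while
#' still exercising the zero-fraction filter: strong tissue markers
#' (`marker_log2fc = 3`), moderate dataset batch effects
#' (`batch_sd = 0.2` on the natural-log scale), and mild zero inflation.
#'
#' @param n_classes number of tissue classes.
#' @param datasets_per_class datasets (studies) per class; each simulated
#'   dataset contains samples of a single class.
#' @param samples_per_dataset samples per dataset.
#' @param n_srna number of sRNA features.
#' @param n_contaminant number of contaminant (viral/bacterial) features.
#' @param markers_per_class sRNA markers planted per class (disjoint across
#'   classes).
#' @param marker_log2fc log2 fold change of a marker in its own class.
#' @param dispersion negative-binomial overdispersion; the NB size parameter
#'   is `1/dispersion`.
#' @param batch_sd standard deviation of the per-dataset log-normal
#'   multiplicative batch shift (natural log scale); 0 disables batch effects.
#' @param zero_inflation probability that any count is independently zeroed.
#' @param sex_effect_features number of features carrying a sex effect,
#'   split evenly between the sRNA and contaminant blocks.
#' @param sex_log2fc log2 fold change applied to sex-effect features in males.
#' @param age_range numeric length-2, sample ages drawn uniformly (years).
#' @param age_effect_features number of features carrying an age trend,
#'   split evenly between blocks.
#' @param age_slope per-year slope on the natural-log scale applied to
#'   age-effect features, centred at the midpoint of `age_range`.
#' @param library_size_range numeric length-2, per-sample library sizes
#'   drawn uniformly.
#' @param seed integer; all randomness flows from this single seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_classes = 3L,
                       datasets_per_class = 3L,
                       samples_per_dataset = 30L,
                       n_srna = 2000L,
                       n_contaminant = 500L,
                       markers_per_class = 20L,
                       marker_log2fc = 3,
                       dispersion = 0.3,
                       batch_sd = 0.2,
                       zero_inflation = 0.1,
                       sex_effect_features = 30L,
                       sex_log2fc = 1,
                       age_range = c(20, 90),
                       age_effect_features = 30L,
                       age_slope = 0.02,
                       library_size_range = c(5e5, 2e6),
                       seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes),
    datasets_per_class = as.integer(datasets_per_class),
    samples_per_dataset = as.integer(samples_per_dataset),
    n_srna = as.integer(n_srna),
    n_contaminant = as.integer(n_contaminant),
    markers_per_class = as.integer(markers_per_class),
    marker_log2fc = as.numeric(marker_log2fc),
    dispersion = as.numeric(dispersion),
    batch_sd = as.numeric(batch_sd),
    zero_inflation = as.numeric(zero_inflation),
    sex_effect_features = as.integer(sex_effect_features),
    sex_log2fc = as.numeric(sex_log2fc),
    age_range = as.numeric(age_range),
    age_effect_features = as.integer(age_effect_features),
    age_slope = as.numeric(age_slope),
    library_size_range = as.numeric(library_size_range),
    seed = as.integer(seed)
  )
  check_field(cfg$n_classes >= 1L, "n_classes", "must be >= 1")
  check_field(cfg$datasets_per_class >= 1L, "datasets_per_class", "must be >= 1")
  check_field(cfg$samples_per_dataset >= 1L, "samples_per_dataset", "must be >= 1")
  check_field(cfg$n_srna >= 1L, "n_srna", "must be >= 1")
  check_field(cfg$n_contaminant >= 0L, "n_contaminant", "must be >= 0")
  check_field(cfg$markers_per_class >= 0L, "markers_per_class", "must be >= 0")
  check_field(cfg$markers_per_class * cfg$n_classes <= cfg$n_srna,
              "markers_per_class", "requires markers_per_class * n_classes <= n_srna")
  check_field(cfg$dispersion > 0, "dispersion", "must be > 0")
  check_field(cfg$batch_sd >= 0, "batch_sd", "must be >= 0")
  check_field(cfg$zero_inflation >= 0 && cfg$zero_inflation <= 1,
              "zero_inflation", "must be in [0, 1]")
  check_field(cfg$sex_effect_features >= 0L, "sex_effect_features", "must be >= 0")
  check_field(cfg$age_effect_features >= 0L, "age_effect_features", "must be >= 0")
  check_field(length(cfg$age_range) == 2L && cfg$age_range[1] <= cfg$age_range[2] &&
                cfg$age_range[1] >= 0, "age_range", "must be an increasing pair of non-negative years")
  check_field(length(cfg$library_size_range) == 2L && all(cfg$library_size_range > 0) &&
                cfg$library_size_range[1] <= cfg$library_size_range[2],
              "library_size_range", "must be an increasing pair of positive sizes")
  check_field(cfg$sex_effect_features <= cfg$n_srna + cfg$n_contaminant,
              "sex_effect_features", "exceeds total feature count")
  check_field(cfg$age_effect_features <= cfg$n_srna + cfg$n_contaminant,
              "age_effect_features", "exceeds total feature count")
  structure(cfg, class = "sim_config")
}

# split a requested number of effect features between the two blocks,
# avoiding the planted marker rows, sRNA half first
.pick_effect_features <- function(n_wanted, n_srna, n_contaminant, exclude_srna) {
  if (n_wanted == 0L) return(integer(0))
  n_srna_half <- ceiling(n_wanted / 2)
  n_cont_half <- n_wanted - n_srna_half
  if (n_contaminant == 0L) {
    n_srna_half <- n_wanted
    n_cont_half <- 0L
  }
  srna_pool <- setdiff(seq_len(n_srna), exclude_srna)
  ids <- sample(srna_pool, min(n_srna_half, length(srna_pool)))
  if (n_cont_half > 0L) {
    ids <- c(ids, n_srna + sample.int(n_contaminant, min(n_cont_half, n_contaminant)))
  }
  sort(ids)
}

#' Generate a synthetic sRNA cohort
#'
#' Draws a features-by-samples count matrix, sample metadata and the ground
#' truth of all planted effects. Counts for feature f in sample s are
#' `NB(mean = mu_fs, size = 1/dispersion)` where `mu_fs` is the feature's
#' baseline relative abundance (log-normal across features) modulated by the
#' class-marker fold change, the sample's dataset batch shift, sex and age
#' effects, and rescaled so that the expected column total equals the
#' sample's library size; entries are then zeroed independently with
#' probability `zero_inflation`. Identical configurations (including the
#' seed) give bit-identical cohorts.
#'
#' @param config a [sim_config()].
#' @return a list of class `srn_cohort` with elements
#'   \describe{
#'     \item{counts}{integer matrix, features x samples, with dimnames.}
#'     \item{feature_kind}{character vector (`"srna"`/`"contaminant"`) per feature.}
#'     \item{metadata}{data.frame with sample_id, dataset_id, tissue, sex, age.}
#'     \item{truth}{ground truth: marker_ids_by_class, sex_feature_ids,
#'       age_feature_ids, dataset_batch_shifts.}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  p <- cfg$n_srna + cfg$n_contaminant
  feature_ids <- c(sprintf("srna_%05d", seq_len(cfg$n_srna)),
                   if (cfg$n_contaminant > 0L) sprintf("contam_%05d", seq_len(cfg$n_contaminant)))
  feature_kind <- c(rep("srna", cfg$n_srna), rep("contaminant", cfg$n_contaminant))

  classes <- sprintf("tissue_%d", seq_len(cfg$n_classes))

  # baseline relative abundances (arbitrary units, log-normal across features)
  baseline <- stats::rlnorm(p, meanlog = log(20), sdlog = 1)

  # planted effects
  n_mark <- cfg$markers_per_class * cfg$n_classes
  marker_idx <- if (n_mark > 0L) sample.int(cfg$n_srna, n_mark) else integer(0)
  mpc <- cfg$markers_per_class
  marker_by_class <- lapply(seq_len(cfg$n_classes), function(k) {
    if (mpc == 0L) integer(0) else marker_idx[((k - 1L) * mpc + 1L):(k * mpc)]
  })
  sex_idx <- .pick_effect_features(cfg$sex_effect_features, cfg$n_srna, cfg$n_contaminant, marker_idx)
  age_idx <- .pick_effect_features(cfg$age_effect_features, cfg$n_srna, cfg$n_contaminant,
                                   c(marker_idx, sex_idx[sex_idx <= cfg$n_srna]))

  # datasets: each dataset carries one class
  dataset_ids <- as.vector(t(outer(seq_len(cfg$n_classes), seq_len(cfg$datasets_per_class),
                                   function(k, r) sprintf("ds_%d_%d", k, r))))
  dataset_class <- rep(classes, each = cfg$datasets_per_class)
  batch_shift <- stats::rnorm(length(dataset_ids), 0, cfg$batch_sd)
  names(batch_shift) <- dataset_ids

  n <- length(dataset_ids) * cfg$samples_per_dataset
  sample_ids <- sprintf("s%04d", seq_len(n))
  samp_dataset <- rep(dataset_ids, each = cfg$samples_per_dataset)
  samp_class <- rep(dataset_class, each = cfg$samples_per_dataset)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  lib_size <- stats::runif(n, cfg$library_size_range[1], cfg$library_size_range[2])
  age_mid <- mean(cfg$age_range)

  log_base <- log(baseline)
  counts <- matrix(0L, nrow = p, ncol = n, dimnames = list(feature_ids, sample_ids))
  for (s in seq_len(n)) {
    lmu <- log_base
    k <- match(samp_class[s], classes)
    mk <- marker_by_class[[k]]
    if (length(mk)) lmu[mk] <- lmu[mk] + cfg$marker_log2fc * log(2)
    if (sex[s] == "male" && length(sex_idx)) {
      lmu[sex_idx] <- lmu[sex_idx] + cfg$sex_log2fc * log(2)
    }
    if (length(age_idx)) {
      lmu[age_idx] <- lmu[age_idx] + cfg$age_slope * (age[s] - age_mid)
    }
    lmu <- lmu + batch_shift[samp_dataset[s]]
    mu <- exp(lmu)
    mu <- mu / sum(mu) * lib_size[s]
    x <- stats::rnbinom(p, mu = mu, size = 1 / cfg$dispersion)
    if (cfg$zero_inflation > 0) {
      x[stats::runif(p) < cfg$zero_inflation] <- 0L
    }
    counts[, s] <- x
  }

  metadata <- data.frame(
    sample_id = sample_ids,
    dataset_id = samp_dataset,
    tissue = samp_class,
    sex = sex,
    age = age,
    stringsAsFactors = FALSE
  )
  truth <- list(
    marker_ids_by_class = stats::setNames(
      lapply(marker_by_class, function(i) feature_ids[i]), classes),
    sex_feature_ids = feature_ids[sex_idx],
    age_feature_ids = feature_ids[age_idx],
    dataset_batch_shifts = as.list(batch_shift)
  )
  structure(list(counts = counts, feature_kind = feature_kind,
                 metadata = metadata, truth = truth, config = cfg),
            class = "srn_cohort")
}

#' @export
print.srn_cohort <- function(x, ...) {
  cat(sprintf("srn_cohort: %d features (%d sRNA, %d contaminant) x %d samples, %d classes, %d datasets\n",
              nrow(x$counts), sum(x$feature_kind == "srna"),
              sum(x$feature_kind == "contaminant"), ncol(x$counts),
              length(unique(x$metadata$tissue)), length(unique(x$metadata$dataset_id))))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `counts.tsv` (feature_id, feature_kind, one column per sample),
#' `metadata.tsv` (sample_id, dataset_id, tissue, sex, age) and
#' `truth.json` (ground-truth planted effects) into `dir`.
#'
#' @param cohort an `srn_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "srn_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  truth_path <- file.path(dir, "truth.json")
  df <- data.table::data.table(feature_id = rownames(cohort$counts),
                               feature_kind = cohort$feature_kind)
  df <- cbind(df, data.table::as.data.table(cohort$counts))
  data.table::fwrite(df, counts_path, sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$metadata, meta_path, sep = "\t", quote = FALSE)
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(counts = counts_path, metadata = meta_path, truth = truth_path))
}
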