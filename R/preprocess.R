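# Count-matrix I/O, normalization, filtering, tissue grouping and age binning.
#
# The fixed preprocessing order is: RPM -> zero-fraction filter -> feature
# block selection -> MinMax scaling. RPM rescales columns only, so it never
# creates or destroys zeros and commutes with the zero filter.

#' Read a features-by-samples count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds feature ids, an
#' optional `feature_kind` second column (`srna`/`contaminant`; defaults to
#' `srna` when absent) and one numeric column per sample.
#'
#' @param path path to the TSV.
#' @return list with `counts` (numeric matrix, features x samples),
#'   `feature_kind` (character vector).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  if (ncol(dt) < 2L) stop("count file needs a feature id column plus sample columns", call. = FALSE)
  feature_ids <- as.character(dt[[1]])
  has_kind <- ncol(dt) >= 2L && colnames(dt)[2] == "feature_kind"
  kind <- if (has_kind) as.character(dt[[2]]) else rep("srna", nrow(dt))
  first_sample <- if (has_kind) 3L else 2L
  if (first_sample > ncol(dt)) stop("count file has no sample columns", call. = FALSE)
  sample_ids <- colnames(dt)[first_sample:ncol(dt)]
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature id(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(unique(kind), c("srna", "contaminant"))
  if (length(bad_kind)) stop("unknown feature_kind value(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  vals <- as.matrix(dt[, first_sample:ncol(dt), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(dt)[first_sample:ncol(dt)][!vapply(
      dt[first_sample:ncol(dt)], is.numeric, logical(1))]
    stop("non-numeric values in sample column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("non-finite values in count matrix", call. = FALSE)
  }
  if (any(vals < 0)) {
    ij <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 feature_ids[ij[1]], sample_ids[ij[2]]), call. = FALSE)
  }
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(feature_ids, sample_ids)
  list(counts = vals, feature_kind = kind)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id` and `dataset_id`; `tissue`, `sex`, `age`
#' optional (missing values allowed within them).
#'
#' @param path path to the TSV.
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample_id", "dataset_id")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id(s): ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "), call. = FALSE)
  }
  if ("age" %in% colnames(md)) {
    ok <- is.na(md$age) | (md$age >= 0 & md$age <= 120)
    if (!all(ok)) stop("age out of [0, 120] for sample(s): ",
                       paste(md$sample_id[!ok], collapse = ", "), call. = FALSE)
  }
  md
}

#' Reads-per-million normalization
#'
#' Scales every sample column so its total is one million.
#'
#' @param counts numeric matrix, features x samples.
#' @return matrix of the same shape with columns summing to 1e6.
#' @export
rpm_normalize <- function(counts) {
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, 1e6 / cs, "*")
}

#' Remove features with too many zeros
#'
#' A feature is retained iff its fraction of exactly-zero entries is at most
#' `max_zero_frac` (strictly greater fractions are removed; exactly 30%
#' zeros is retained at the default threshold).
#'
#' @param counts numeric matrix, features x samples.
#' @param max_zero_frac maximum tolerated zero fraction (default 0.30).
#' @return list with `counts` (filtered matrix, original feature order) and
#'   `retained` (character vector of retained feature ids).
#' @export
filter_zero_features <- function(counts, max_zero_frac = 0.30) {
  zf <- rowMeans(counts == 0)
  keep <- zf <= max_zero_frac
  if (!any(keep)) warning("zero-fraction filter removed every feature")
  list(counts = counts[keep, , drop = FALSE], retained = rownames(counts)[keep])
}

#' Fit a per-feature MinMax scaler
#'
#' @param x numeric matrix, samples x features (the fitting set).
#' @return object of class `minmax_params` holding per-feature min and max.
#' @export
minmax_fit <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 feature_ids = colnames(x)),
            class = "minmax_params")
}

#' Apply a fitted MinMax scaler
#'
#' Maps each feature affinely so the fitted min/max go to 0/1; constant
#' features map to 0; values outside the fitted range (unseen data) are
#' clipped to \[0, 1\].
#'
#' @param x numeric matrix, samples x features.
#' @param params a [minmax_fit()] result.
#' @return scaled matrix in \[0, 1\].
#' @export
minmax_transform <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  if (!identical(colnames(x), params$feature_ids)) {
    stop("feature set of input does not match the fitted scaler", call. = FALSE)
  }
  rng <- params$max - params$min
  rng[rng == 0] <- Inf  # constant features -> 0
  out <- sweep(sweep(x, 2, params$min, "-"), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Packaged tissue-to-group ontology map
#'
#' The flat BRENDA-tissue-ontology-derived merge table shipped with the
#' package (e.g. blood plasma -> blood_group, motor cortex -> brain_group).
#'
#' @return data.frame with columns `tissue` and `group`.
#' @export
default_ontology_map <- function() {
  path <- system.file("extdata", "tissue_ontology_map.tsv", package = "srnaugment",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Merge tissue labels into ontology groups
#'
#' Replaces each sample's tissue by its group; matching is case-insensitive
#' after whitespace trimming. Labels absent from the map pass through
#' unchanged with a warning.
#'
#' @param metadata data.frame with a `tissue` column.
#' @param ontology_map data.frame with columns `tissue`, `group`; defaults
#'   to [default_ontology_map()].
#' @return metadata with grouped `tissue`.
#' @export
group_tissues <- function(metadata, ontology_map = default_ontology_map()) {
  stopifnot("tissue" %in% colnames(metadata))
  key <- tolower(trimws(ontology_map$tissue))
  if (anyDuplicated(key)) stop("ontology map has duplicated tissue labels", call. = FALSE)
  idx <- match(tolower(trimws(metadata$tissue)), key)
  unmapped <- unique(metadata$tissue[is.na(idx) & !is.na(metadata$tissue)])
  if (length(unmapped)) {
    warning("tissue label(s) not in ontology map, passed through: ",
            paste(unmapped, collapse = ", "))
  }
  hit <- !is.na(idx)
  metadata$tissue[hit] <- ontology_map$group[idx[hit]]
  metadata
}

#' Age-interval presets
#'
#' Interval edges for the 2-, 3- and 4-class age binning schemes:
#' \[0;65\](65;110\]; \[0;45\](45;70\](70;110\]; \[0;30\](30;60\](60;80\](80;110\].
#'
#' @param k number of intervals (2, 3 or 4).
#' @return numeric vector of interval edges.
#' @export
age_bin_presets <- function(k) {
  switch(as.character(k),
         "2" = c(0, 65, 110),
         "3" = c(0, 45, 70, 110),
         "4" = c(0, 30, 60, 80, 110),
         stop("k must be 2, 3 or 4", call. = FALSE))
}

#' Bin ages into interval classes
#'
#' The first interval is closed at both ends, subsequent intervals are
#' left-open right-closed, so with edges `c(0, 65, 110)` an age of exactly
#' 65 falls in class 0 and 66 in class 1.
#'
#' @param age numeric vector of ages in years (no missing values).
#' @param boundaries strictly increasing interval edges; defaults to the
#'   two-interval preset.
#' @return integer vector of 0-based class codes with a `labels` attribute
#'   naming the intervals.
#' @export
bin_ages <- function(age, boundaries = age_bin_presets(2)) {
  stopifnot(length(boundaries) >= 2L, all(diff(boundaries) > 0))
  if (anyNA(age)) stop("missing age(s) at position(s): ",
                       paste(which(is.na(age)), collapse = ", "), call. = FALSE)
  out_of_range <- age < boundaries[1] | age > boundaries[length(boundaries)]
  if (any(out_of_range)) {
    stop("age(s) outside the binning range at position(s): ",
         paste(which(out_of_range), collapse = ", "), call. = FALSE)
  }
  # (edge_i, edge_{i+1}] everywhere, then pull the closed left end of bin 1 in
  code <- findInterval(age, boundaries, left.open = TRUE, rightmost.closed = FALSE)
  code[age == boundaries[1]] <- 1L
  labels <- c(sprintf("[%g;%g]", boundaries[1], boundaries[2]),
              if (length(boundaries) > 2L)
                sprintf("(%g;%g]", boundaries[-c(1, length(boundaries))], boundaries[-(1:2)]))
  structure(as.integer(code - 1L), labels = labels)
}

#' Drop samples belonging to small classes
#'
#' Removes all samples of classes with fewer than `min_samples` members.
#'
#' @param y class label vector.
#' @param min_samples minimum class size (paper presets: 9 or 15).
#' @param x optional samples-x-features matrix filtered alongside `y`.
#' @return list with `y`, `keep` (logical index) and, when given, `x`.
#' @export
filter_small_classes <- function(y, min_samples, x = NULL) {
  stopifnot(min_samples >= 1)
  tab <- table(y)
  ok_classes <- names(tab)[tab >= min_samples]
  if (length(ok_classes) < 2L) {
    stop("fewer than 2 classes survive the min_samples = ", min_samples,
         " filter", call. = FALSE)
  }
  keep <- y %in% ok_classes
  out <- list(y = y[keep], keep = keep)
  if (!is.null(x)) out$x <- x[keep, , drop = FALSE]
  out
}

#' Select a feature block
#'
#' @param counts features x samples matrix.
#' @param feature_kind per-feature kind vector aligned with `counts` rows.
#' @param feature_set `"srna"`, `"contaminant"` or `"both"`.
#' @return the row-subset matrix.
#' @export
select_feature_set <- function(counts, feature_kind,
                               feature_set = c("both", "srna", "contaminant")) {
  feature_set <- match.arg(feature_set)
  stopifnot(length(feature_kind) == nrow(counts))
  if (feature_set == "both") return(counts)
  counts[feature_kind == feature_set, , drop = FALSE]
}

#' Standard preprocessing chain (unscaled)
#'
#' Applies RPM normalization, the zero-fraction filter and feature-block
#' selection, and transposes to the samples-x-features orientation the
#' classifiers expect. MinMax scaling is left to the validation harness so
#' it can be fitted per training split (or globally with the
#' paper-faithful switch).
#'
#' @param counts features x samples count matrix.
#' @param feature_kind per-feature kind vector.
#' @param feature_set which block to keep.
#' @param max_zero_frac zero-filter threshold.
#' @return samples x features numeric matrix.
#' @export
prepare_features <- function(counts, feature_kind,
                             feature_set = c("both", "srna", "contaminant"),
                             max_zero_frac = 0.30) {
  feature_set <- match.arg(feature_set)
  m <- rpm_normalize(counts)
  kept <- filter_zero_features(m, max_zero_frac)
  kind <- feature_kind[match(kept$retained, rownames(counts))]
  m <- select_feature_set(kept$counts, kind, feature_set)
  t(m)
}
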