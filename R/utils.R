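# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stopifnot-style check with a named-field message, used by config validators
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

# Write a numeric matrix as TSV with an id first column; full precision.
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.table::data.table(id = rownames(m))
  data.table::setnames(df, "id", id_col)
  df <- cbind(df, data.table::as.data.table(m))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
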