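# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#'
#' All generators in the package route their randomness through this helper so
#' that identical arguments and seed give bit-identical output while leaving
#' the global RNG state untouched.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop("invalid-argument: ", sprintf(...), call. = FALSE)
}

#' Check that a count matrix is well formed
#' @noRd
check_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_invalid("%s must be a numeric matrix", what)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop_invalid("%s must have at least one gene and one sample", what)
  if (anyNA(counts) || any(counts < 0))
    stop_invalid("%s must be non-negative with no missing values", what)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_invalid("%s must carry unique row names (gene ids)", what)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop_invalid("%s must carry unique column names (sample ids)", what)
  invisible(counts)
}

#' Check a sample design data frame against a count matrix
#' @noRd
check_design <- function(design, counts = NULL,
                         need = c("genotype", "sex", "replicate")) {
  if (!is.data.frame(design))
    stop_invalid("design must be a data frame")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols))
    stop_invalid("design lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!is.null(counts)) {
    if (ncol(counts) != nrow(design))
      stop_invalid("design has %d rows but counts has %d samples",
                   nrow(design), ncol(counts))
    if (!is.null(design$sample_id) &&
        !identical(as.character(design$sample_id), colnames(counts)))
      stop_invalid("design sample_id does not match count matrix columns")
  }
  invisible(design)
}

as_factor_cols <- function(design, cols = c("genotype", "sex", "replicate")) {
  for (cl in intersect(cols, names(design)))
    if (!is.factor(design[[cl]])) design[[cl]] <- factor(design[[cl]])
  design
}
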