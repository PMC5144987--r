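# Tab-separated I/O for the package's tabular formats.

#' Write a count (or normalized) matrix as TSV
#'
#' First column `gene_id`, then one column per sample.
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts_tsv()]
#' @param path Input path.
#' @param integer Coerce to integer storage (default TRUE for raw counts).
#' @export
read_counts_tsv <- function(path, integer = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (integer) storage.mode(m) <- "integer"
  m
}

#' Write a sample design as TSV
#' @param design Data frame from [generate_design()].
#' @param path Output path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample design TSV
#'
#' Restores `genotype`, `sex`, `replicate` as factors and `infected` as
#' logical.
#' @param path Input path.
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d <- as_factor_cols(d)
  if (!is.null(d$infected)) d$infected <- as.logical(d$infected)
  d
}

#' Write the planted truth of a simulation as a long TSV
#'
#' One row per gene, term and level combination with a non-zero coefficient,
#' plus per-gene `baseline` and `dispersion` rows.
#' @param truth A `"synthetic_truth"` object.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  rows <- list(
    data.frame(gene_id = truth$gene_ids, term = "baseline", level = "",
               value = truth$baseline, stringsAsFactors = FALSE),
    data.frame(gene_id = truth$gene_ids, term = "dispersion", level = "",
               value = truth$dispersion, stringsAsFactors = FALSE))
  for (term in names(truth$coefficients)) {
    A <- truth$coefficients[[term]]
    M <- matrix(A, length(truth$gene_ids))
    lev_grid <- do.call(expand.grid, c(dimnames(A)[-1L],
                                       list(stringsAsFactors = FALSE)))
    lev_names <- apply(lev_grid, 1L, paste, collapse = ":")
    nz <- which(M != 0, arr.ind = TRUE)
    if (nrow(nz))
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = truth$gene_ids[nz[, 1L]], term = term,
                   level = lev_names[nz[, 2L]], value = M[nz],
                   stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a line-level covariate TSV (columns genotype, value)
#' @param path Input path.
#' @export
read_covariate_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genotype", "value") %in% names(d)))
    stop_invalid("covariate file needs columns genotype, value")
  d
}
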