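# Median-of-ratios normalization, empirical low-expression threshold
# derivation from intergenic vs genic count distributions, and expression
# filtering.

#' Median-of-ratios size factors
#'
#' For each sample k, the size factor is the median over reference genes of
#' `counts[i, k] / geomean_i`, where `geomean_i` is the geometric mean of gene
#' i across samples. Only genes with a strictly positive count in every
#' sample enter the median (the standard convention: a zero anywhere makes
#' the geometric mean, and hence the ratio, undefined on the log scale).
#'
#' @param counts Non-negative count matrix, genes x samples, with dimnames.
#' @return Named positive numeric vector of per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 40, 20, 40, 80), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' estimate_size_factors(m)  # c(A = 1/sqrt(2), B = sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  check_count_matrix(counts)
  eligible <- rowSums(counts > 0) == ncol(counts)
  if (!any(eligible))
    stop("normalization impossible: no gene has strictly positive counts ",
         "in every sample, so no median-of-ratios reference exists",
         call. = FALSE)
  lc <- log(counts[eligible, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(lc, 2L, function(col) exp(stats::median(col - loggeo)))
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param counts Count matrix, genes x samples.
#' @param size_factors Positive vector, one per sample; computed with
#'   [estimate_size_factors()] when omitted.
#' @return Matrix of normalized values with the size factors attached as
#'   attribute `"size_factors"`; gene ids and order are preserved.
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  check_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (length(size_factors) != ncol(counts))
    stop_invalid("length(size_factors) = %d but counts has %d samples",
                 length(size_factors), ncol(counts))
  if (any(size_factors <= 0) || anyNA(size_factors))
    stop_invalid("size factors must be strictly positive")
  norm <- sweep(counts, 2L, size_factors, "/")
  attr(norm, "size_factors") <- stats::setNames(size_factors, colnames(counts))
  norm
}

#' The published default low-expression threshold
#'
#' Empirical threshold (in normalized read counts) below which a gene is
#' treated as unexpressed when no intergenic count table is available to
#' derive a dataset-specific value.
#' @return The constant 3.486.
#' @export
default_expression_threshold <- function() 3.486

#' Derive a low-expression threshold from genic vs intergenic counts
#'
#' Kernel-density estimates (Gaussian kernel, Silverman bandwidth, common
#' 512-point grid) are computed for the log-scale per-gene and per-region
#' mean normalized counts. The threshold is the smallest grid value above the
#' intergenic mode at which the genic density exceeds the intergenic density
#' — the crossing of the background and signal distributions.
#'
#' @param genic Normalized genic matrix (genes x samples).
#' @param intergenic Normalized intergenic matrix on the same samples.
#' @param eps Offset added before taking logs (default 1e-8).
#' @param n_grid Number of density grid points (default 512).
#' @return The threshold on the normalized-count scale, with attributes
#'   `log_crossing`, `grid_step`, and the two log-scale modes.
#' @export
derive_threshold <- function(genic, intergenic, eps = 1e-8, n_grid = 512L) {
  if (!is.matrix(genic) || !is.matrix(intergenic) ||
      nrow(genic) < 2L || nrow(intergenic) < 2L)
    stop_invalid("genic and intergenic must be non-empty matrices")
  if (ncol(genic) != ncol(intergenic))
    stop_invalid("genic and intergenic must cover the same samples")
  lg <- log(rowMeans(genic) + eps)
  li <- log(rowMeans(intergenic) + eps)
  rng <- range(c(lg, li))
  dg <- stats::density(lg, bw = "nrd0", n = n_grid, from = rng[1], to = rng[2])
  di <- stats::density(li, bw = "nrd0", n = n_grid, from = rng[1], to = rng[2])
  grid <- dg$x
  mode_i <- grid[which.max(di$y)]
  mode_g <- grid[which.max(dg$y)]
  cand <- which(grid > mode_i & dg$y > di$y)
  if (!length(cand))
    stop(sprintf(paste0("no density crossing: genic density never exceeds the ",
                        "intergenic density above the intergenic mode ",
                        "(log-scale modes: intergenic %.4f, genic %.4f)"),
                 mode_i, mode_g), call. = FALSE)
  # refine the first sign change by linear interpolation of the density
  # difference between the bracketing grid points
  j <- min(cand)
  xc <- grid[j]
  if (j > 1L) {
    d0 <- dg$y[j - 1L] - di$y[j - 1L]
    d1 <- dg$y[j] - di$y[j]
    if (d0 < 0 && d1 > d0)
      xc <- grid[j - 1L] + (grid[j] - grid[j - 1L]) * (-d0) / (d1 - d0)
  }
  structure(exp(xc), log_crossing = xc,
            grid_step = diff(grid[1:2]),
            mode_intergenic = mode_i, mode_genic = mode_g)
}

#' Remove unexpressed genes
#'
#' First drops genes whose values are zero in all samples, then genes whose
#' normalized values fall below the threshold in ALL samples. A gene above
#' the threshold in even one fly is kept.
#'
#' @param norm Normalized matrix (genes x samples).
#' @param threshold Positive expression threshold; defaults to the published
#'   constant [default_expression_threshold()].
#' @return List with `matrix` (the retained rows, size-factor attribute
#'   preserved) and `report`, a `"filter_report"` whose counts partition the
#'   input: `n_input_genes = n_all_zero + n_below_threshold + n_expressed`.
#' @export
filter_expressed <- function(norm, threshold = default_expression_threshold()) {
  if (!is.matrix(norm) || nrow(norm) < 1L)
    stop_invalid("norm must be a non-empty matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_invalid("threshold must be a single positive number")
  mx <- apply(norm, 1L, max)
  all_zero <- mx == 0
  below <- !all_zero & mx < threshold
  keep <- mx >= threshold
  if (!any(keep))
    stop("all genes filtered: no gene reaches the expression threshold ",
         threshold, " in any sample", call. = FALSE)
  report <- structure(list(n_input_genes = nrow(norm),
                           n_all_zero = sum(all_zero),
                           n_below_threshold = sum(below),
                           n_expressed = sum(keep),
                           threshold = threshold),
                      class = "filter_report")
  out <- norm[keep, , drop = FALSE]
  attr(out, "size_factors") <- attr(norm, "size_factors")
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("expression filter (threshold %.4g): %d genes in; ",
                     "%d all-zero, %d below threshold in every sample, ",
                     "%d expressed\n"),
              x$threshold, x$n_input_genes, x$n_all_zero,
              x$n_below_threshold, x$n_expressed))
  invisible(x)
}
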