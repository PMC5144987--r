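# Screens attributing individual-level expression differences to known
# line-level covariates: Wolbachia infection status, residual heterozygosity,
# and total rRNA level.

#' Per-gene NB GLM screen for infection status
#'
#' Fits `log(mu_ik) = b0 + I` (I = infection status) against the
#' intercept-only model with a one-degree-of-freedom likelihood-ratio test
#' per gene, BH-FDR across genes. Infection is a line-level covariate: the
#' model deliberately carries no genotype term, so p-values are
#' anti-conservative whenever genotype effects exist (documented contract of
#' the published model, asserted by a property test).
#'
#' @param counts Count matrix (genes x samples).
#' @param design Sample design with a logical/two-level `infected` column.
#' @param size_factors Per-sample size factors; computed when omitted.
#' @param cr_adjust Passed to the dispersion estimator.
#' @return Data frame: `gene_id`, `screen = "infection"`, `statistic`, `df`,
#'   `p_value`, `fdr`.
#' @export
infection_test <- function(counts, design, size_factors = NULL,
                           cr_adjust = TRUE) {
  check_count_matrix(counts)
  design <- check_design(design, counts, need = "infected")
  inf <- factor(design$infected)
  if (nlevels(droplevels(inf)) < 2L)
    stop_invalid("both infection classes must be present")
  sf <- size_factors %||% estimate_size_factors(counts)
  offset <- log(sf)
  X1 <- stats::model.matrix(~ inf)
  X0 <- X1[, 1L, drop = FALSE]
  rows <- lapply(rownames(counts), function(gene) {
    y <- counts[gene, ]
    if (all(y == 0))
      return(data.frame(gene_id = gene, screen = "infection",
                        statistic = NA_real_, df = NA_integer_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    phi <- .estimate_phi(y, X1, offset, cells = inf, cr_adjust = cr_adjust)
    f1 <- .nb_fit(y, X1, offset, phi)
    f0 <- .nb_fit(y, X0, offset, phi)
    stat <- max(0, f0$deviance - f1$deviance)
    df <- f1$rank - f0$rank
    p <- if (df < 1L || stat <= 0) 1
         else stats::pchisq(stat, df, lower.tail = FALSE)
    data.frame(gene_id = gene, screen = "infection", statistic = stat,
               df = as.integer(df), p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Per-gene, per-genotype SD of normalized expression
#'
#' The sample SD pooled over all of a genotype's flies (both sexes, all
#' replicates) — the line-level variability that is correlated with residual
#' heterozygosity or rRNA level.
#'
#' @param norm Normalized matrix (genes x samples).
#' @param design Sample design with a `genotype` factor.
#' @return Matrix genes x genotypes of SDs; genotypes with fewer than 2 flies
#'   give NA (flagged with a warning).
#' @export
line_sd <- function(norm, design) {
  design <- as_factor_cols(check_design(design, norm, need = "genotype"))
  geno <- droplevels(design$genotype)
  out <- vapply(levels(geno), function(g) {
    idx <- which(geno == g)
    if (length(idx) < 2L) return(rep(NA_real_, nrow(norm)))
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    sqrt(rowSums((sub - m)^2) / (length(idx) - 1L))
  }, numeric(nrow(norm)))
  out <- matrix(out, nrow = nrow(norm),
                dimnames = list(rownames(norm), levels(geno)))
  if (anyNA(out))
    warning("singleton genotype(s): SD undefined (NA)", call. = FALSE)
  out
}

#' Correlate per-line expression SD with a line-level covariate
#'
#' Per gene, the Spearman correlation between the per-genotype SDs and the
#' covariate (residual heterozygosity percentage, total rRNA level, ...).
#' The p-value is exact (permutation null) when n <= 8 without ties, and the
#' t-approximation otherwise; BH-FDR across genes.
#'
#' @param line_sd_table Matrix from [line_sd()] (genes x genotypes).
#' @param covariate Data frame with columns `genotype`, `value`, one row per
#'   genotype, or a named numeric vector.
#' @param screen Label recorded in the output (e.g. `"heterozygosity"`).
#' @return Data frame: `gene_id`, `screen`, `statistic` (Spearman rho),
#'   `p_value`, `fdr`.
#' @export
covariate_correlation <- function(line_sd_table, covariate,
                                  screen = "covariate") {
  if (is.data.frame(covariate)) {
    if (!all(c("genotype", "value") %in% names(covariate)))
      stop_invalid("covariate data frame needs columns genotype, value")
    covariate <- stats::setNames(covariate$value,
                                 as.character(covariate$genotype))
  }
  common <- intersect(colnames(line_sd_table), names(covariate))
  if (length(common) < 4L)
    stop_invalid("need >= 4 genotypes with both SD and covariate defined")
  x <- covariate[common]
  if (stats::sd(x) == 0)
    stop("undefined correlation: covariate is constant across lines",
         call. = FALSE)
  sds <- line_sd_table[, common, drop = FALSE]
  rows <- lapply(rownames(sds), function(gene) {
    y <- sds[gene, ]
    ok <- !is.na(y)
    if (sum(ok) < 4L || stats::sd(y[ok]) == 0)
      return(data.frame(gene_id = gene, screen = screen,
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    n <- sum(ok)
    no_ties <- !anyDuplicated(y[ok]) && !anyDuplicated(x[ok])
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = n <= 8L && no_ties))
    data.frame(gene_id = gene, screen = screen,
               statistic = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
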