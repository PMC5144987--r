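# Per-gene negative-binomial GLM fitting, dispersion estimation, and the
# nested likelihood-ratio ladder over Genotype, Replicate, Sex and their
# interactions.
#
# Count model: x_ik ~ NB(mu_ik, sigma2_ik) with sigma2_ik = mu_ik + phi *
# mu_ik^2 (phi = 0 recovers the Poisson), log link, log size-factor offsets.
# Each term of log(mu) = b0 + S + G + R + G:R + G:S + R:S + G:R:S is tested
# by the deviance difference between a full and a reduced model of the
# ladder, with one dispersion per gene estimated under the fullest model and
# held fixed across all nested fits (required for deviance differences to be
# a valid likelihood-ratio statistic).

.TERM_MODEL_VARS <- c(G = "genotype", R = "replicate", S = "sex")

.term_to_model <- function(term) {
  paste(.TERM_MODEL_VARS[strsplit(term, ":", fixed = TRUE)[[1L]]],
        collapse = ":")
}

.term_set_formula <- function(term_set) {
  if (!all(term_set %in% .TERMS))
    stop_invalid("unknown term(s): %s",
                 paste(setdiff(term_set, .TERMS), collapse = ", "))
  rhs <- if (length(term_set)) vapply(term_set, .term_to_model, "") else "1"
  stats::reformulate(rhs)
}

# The model ladder: main effects are tested by single-term deletion from
# Model 1 (S + G + R); interactions by consecutive expansion up to the full
# three-way model.
.LADDER <- list(
  m1_noS = c("G", "R"),
  m1_noG = c("S", "R"),
  m1_noR = c("S", "G"),
  m1     = c("S", "G", "R"),
  m2a    = c("S", "G", "R", "G:R"),
  m2b    = c("S", "G", "R", "G:R", "G:S"),
  m2     = c("S", "G", "R", "G:R", "G:S", "R:S"),
  m3     = c("S", "G", "R", "G:R", "G:S", "R:S", "G:R:S")
)
.LADDER_TESTS <- list(
  "G"     = c(full = "m1",  reduced = "m1_noG"),
  "R"     = c(full = "m1",  reduced = "m1_noR"),
  "S"     = c(full = "m1",  reduced = "m1_noS"),
  "G:R"   = c(full = "m2a", reduced = "m1"),
  "G:S"   = c(full = "m2b", reduced = "m2a"),
  "R:S"   = c(full = "m2",  reduced = "m2b"),
  "G:R:S" = c(full = "m3",  reduced = "m2")
)

# Low-level IRLS fit at fixed dispersion. phi = 0 is the Poisson limit.
.nb_fit <- function(y, X, offset, phi, start = NULL) {
  fam <- if (phi > 0) MASS::negative.binomial(theta = 1 / phi)
         else stats::poisson()
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = fam, offset = offset, start = start,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  list(coefficients = fit$coefficients,
       fitted = fit$fitted.values,
       deviance = fit$deviance,
       rank = fit$rank,
       converged = fit$converged)
}

.nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi > 0) sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  else sum(stats::dpois(y, mu, log = TRUE))
}

# Dispersion by maximizing the (optionally Cox-Reid adjusted) profile
# likelihood in log(phi); golden-section search over a wide interval with a
# warm-started inner IRLS. The Cox-Reid term -0.5 * logdet(X' W X) corrects
# the downward bias of the plain profile MLE when the mean model uses many
# parameters. Falls back to the pooled method-of-moments estimate if the
# inner fits fail; returns 0 for under-dispersed data.
.estimate_phi <- function(y, X, offset, cells = NULL, cr_adjust = TRUE,
                          max_phi = 25) {
  if (all(y == 0))
    stop("degenerate gene: all counts are zero; filter before fitting",
         call. = FALSE)
  z <- y / exp(offset)
  phi_mom <- {
    if (!is.null(cells)) {
      m <- tapply(z, cells, mean)
      v <- tapply(z, cells, stats::var)
      n <- tapply(z, cells, length)
      ok <- !is.na(v) & n >= 2
      if (any(ok)) max(0, sum(n[ok] * (v[ok] - m[ok])) / sum(n[ok] * m[ok]^2))
      else max(0, (stats::var(z) - mean(z)) / mean(z)^2)
    } else max(0, (stats::var(z) - mean(z)) / mean(z)^2)
  }
  last_start <- NULL
  obj <- function(lp) {
    phi <- exp(lp)
    f <- .nb_fit(y, X, offset, phi, start = last_start)
    cf <- f$coefficients
    if (!anyNA(cf)) last_start <<- cf
    ll <- .nb_loglik(y, f$fitted, phi)
    if (cr_adjust) {
      keep <- !is.na(cf)
      w <- f$fitted / (1 + phi * f$fitted)
      XtWX <- crossprod(X[, keep, drop = FALSE] * sqrt(w))
      ld <- determinant(XtWX, logarithm = TRUE)$modulus
      ll <- ll - 0.5 * as.numeric(ld)
    }
    ll
  }
  phi_hat <- tryCatch({
    opt <- stats::optimize(obj, c(log(1e-6), log(max_phi)),
                           maximum = TRUE, tol = 1e-2)
    exp(opt$maximum)
  }, error = function(e) phi_mom)
  if (phi_hat < 1e-4) phi_hat <- 0
  phi_hat
}

#' Estimate a per-gene NB dispersion
#'
#' Maximizes the Cox-Reid adjusted NB profile likelihood in the dispersion
#' under the fullest model used for the gene, with a pooled within-cell
#' method-of-moments estimate `max(0, (s^2 - m) / m^2)` as fallback when the
#' likelihood fit fails. Under-dispersed data return 0 (the Poisson limit).
#'
#' @param counts_row Integer counts for one gene across samples.
#' @param design Sample design data frame with the factors named by
#'   `term_set`.
#' @param term_set Terms of the fullest model (default the full three-way
#'   model).
#' @param size_factors Per-sample size factors (default all 1).
#' @param cr_adjust Apply the Cox-Reid adjustment (default TRUE); set FALSE
#'   for the plain profile MLE.
#' @param max_dispersion Upper search bound.
#' @return A single dispersion value `phi >= 0`.
#' @export
estimate_dispersion <- function(counts_row, design,
                                term_set = .TERMS,
                                size_factors = NULL,
                                cr_adjust = TRUE, max_dispersion = 25) {
  design <- as_factor_cols(check_design(design,
    need = unique(unlist(.TERM_FACTORS[term_set]))))
  y <- as.numeric(counts_row)
  if (length(y) != nrow(design))
    stop_invalid("counts_row length %d does not match design rows %d",
                 length(y), nrow(design))
  if (length(y) < 2L) stop_invalid("at least 2 samples are required")
  sf <- size_factors %||% rep(1, length(y))
  X <- stats::model.matrix(.term_set_formula(term_set), design)
  vars <- unique(unlist(.TERM_FACTORS[term_set]))
  cells <- interaction(design[vars], drop = TRUE)
  .estimate_phi(y, X, log(sf), cells = cells, cr_adjust = cr_adjust,
                max_phi = max_dispersion)
}

#' Fit a negative-binomial GLM for one gene at fixed dispersion
#'
#' Log-link NB regression with log size-factor offsets, fitted by iteratively
#' reweighted least squares (relative deviance change < 1e-8, at most 100
#' iterations). The deviance is `2 * (loglik(saturated) - loglik(fitted))` at
#' the supplied dispersion. Aliased columns of a rank-deficient design are
#' dropped (with a warning); non-convergence is flagged, not an error.
#'
#' @param counts_row Counts for one gene.
#' @param design Sample design data frame.
#' @param term_set Character vector of model terms among `"G"`, `"R"`, `"S"`,
#'   `"G:R"`, `"G:S"`, `"R:S"`, `"G:R:S"` (empty = intercept only).
#' @param size_factors Per-sample size factors (default all 1).
#' @param dispersion Fixed `phi >= 0`; 0 fits a Poisson GLM.
#' @param gene_id Optional label carried into the result.
#' @return A `"gene_fit"` list: `gene_id`, `term_set`, `coefficients`,
#'   `fitted_means`, `deviance`, `dispersion`, `rank`, `converged`.
#' @examples
#' d <- data.frame(g = 1:4)
#' fit_nb_glm(c(3, 5, 7, 9), d, character(0))$fitted_means  # all 6
#' @export
fit_nb_glm <- function(counts_row, design, term_set = c("S", "G", "R"),
                       size_factors = NULL, dispersion = 0,
                       gene_id = NA_character_) {
  y <- as.numeric(counts_row)
  if (length(y) != nrow(design))
    stop_invalid("counts_row length does not match design rows")
  if (dispersion < 0) stop_invalid("dispersion must be >= 0")
  sf <- size_factors %||% rep(1, length(y))
  if (any(sf <= 0)) stop_invalid("size factors must be positive")
  design <- as_factor_cols(as.data.frame(design))
  X <- stats::model.matrix(.term_set_formula(term_set), design)
  f <- .nb_fit(y, X, log(sf), dispersion)
  if (anyNA(f$coefficients))
    warning("rank-deficient design: aliased coefficients dropped",
            call. = FALSE)
  structure(list(gene_id = gene_id, term_set = term_set,
                 coefficients = f$coefficients,
                 fitted_means = f$fitted,
                 deviance = f$deviance,
                 dispersion = dispersion,
                 rank = f$rank,
                 converged = f$converged),
            class = "gene_fit")
}

#' Likelihood-ratio test of two nested gene fits
#'
#' The statistic is the deviance of the reduced model minus the deviance of
#' the full model (clamped at 0 against convergence noise), valid because
#' both fits share the same dispersion; the p-value is the upper chi-square
#' tail with degrees of freedom equal to the rank difference.
#'
#' @param full,reduced `"gene_fit"` objects with `reduced$term_set` a subset
#'   of `full$term_set` and identical dispersion.
#' @param term Optional term label for the output row.
#' @return One-row data frame: `gene_id`, `term`, `lrt_stat`, `df`, `p_value`.
#' @export
lrt_term <- function(full, reduced, term = NA_character_) {
  if (!inherits(full, "gene_fit") || !inherits(reduced, "gene_fit"))
    stop_invalid("full and reduced must be gene_fit objects")
  if (!all(reduced$term_set %in% full$term_set))
    stop_invalid("models are not nested: reduced term set is not a subset")
  if (!isTRUE(all.equal(full$dispersion, reduced$dispersion)))
    stop_invalid("full and reduced must be fitted with the same dispersion")
  stat <- max(0, reduced$deviance - full$deviance)
  if (stat < 1e-8) stat <- max(0, stat)  # clamp convergence noise
  df <- full$rank - reduced$rank
  p <- if (df < 1L || stat <= 0) 1
       else stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(gene_id = full$gene_id, term = term, lrt_stat = stat,
             df = as.integer(df), p_value = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, take running minima of
#' `p(i) * m / i` from the largest rank down, restore input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted values in `[0, 1]`, monotone in the input.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) stop_invalid("p_values must be non-empty")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full likelihood-ratio ladder over all seven design terms
#'
#' Per gene, the dispersion is estimated once under the full three-way model
#' and reused for every nested comparison. Main effects are tested by
#' single-term deletion from Model 1 (`S + G + R`); `G:R` by Model 2(a) vs
#' Model 1; `G:S` by 2(b) vs 2(a); `R:S` by Model 2 vs 2(b); and `G:R:S` by
#' the full three-way model vs Model 2. FDR is adjusted per term across
#' genes. Genes with all-zero counts yield NA rows (with a warning) rather
#' than aborting the run.
#'
#' @param counts Count matrix (genes x samples).
#' @param design Sample design with `genotype`, `sex`, `replicate` factors of
#'   at least 2 levels each.
#' @param size_factors Per-sample size factors; computed from `counts` when
#'   omitted.
#' @param cr_adjust Passed to the dispersion estimator.
#' @param verbose Emit a progress message every 200 genes.
#' @return Data frame with 7 rows per gene: `gene_id`, `term`, `lrt_stat`,
#'   `df`, `p_value`, `fdr` (BH within term), plus a per-gene `dispersion`
#'   column.
#' @export
test_all_terms <- function(counts, design, size_factors = NULL,
                           cr_adjust = TRUE, verbose = FALSE) {
  check_count_matrix(counts)
  design <- as_factor_cols(check_design(design, counts))
  for (f in c("genotype", "sex", "replicate"))
    if (nlevels(droplevels(design[[f]])) < 2L)
      stop_invalid("factor %s needs at least 2 observed levels", f)
  design <- droplevels(design)
  sf <- size_factors %||% estimate_size_factors(counts)
  if (length(sf) != ncol(counts))
    stop_invalid("size_factors length does not match samples")
  offset <- log(sf)
  Xs <- lapply(.LADDER, function(ts)
    stats::model.matrix(.term_set_formula(ts), design))
  cells <- interaction(design$genotype, design$sex, design$replicate,
                       drop = TRUE)
  genes <- rownames(counts)
  n_terms <- length(.LADDER_TESTS)
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    y <- counts[i, ]
    if (all(y == 0)) {
      res[[i]] <- data.frame(gene_id = genes[i], term = names(.LADDER_TESTS),
                             lrt_stat = NA_real_, df = NA_integer_,
                             p_value = NA_real_, dispersion = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    phi <- .estimate_phi(y, Xs$m3, offset, cells = cells,
                         cr_adjust = cr_adjust)
    fits <- lapply(Xs, function(X) .nb_fit(y, X, offset, phi))
    rows <- lapply(names(.LADDER_TESTS), function(term) {
      pair <- .LADDER_TESTS[[term]]
      fu <- fits[[pair[["full"]]]]
      rd <- fits[[pair[["reduced"]]]]
      stat <- max(0, rd$deviance - fu$deviance)
      df <- fu$rank - rd$rank
      p <- if (df < 1L || stat <= 0) 1
           else stats::pchisq(stat, df, lower.tail = FALSE)
      data.frame(gene_id = genes[i], term = term, lrt_stat = stat,
                 df = as.integer(df), p_value = p, dispersion = phi,
                 stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
    if (verbose && i %% 200L == 0L)
      message(sprintf("[de-test] %d/%d genes", i, length(genes)))
  }
  out <- do.call(rbind, res)
  if (anyNA(out$p_value))
    warning(sum(is.na(out$p_value)) / n_terms,
            " all-zero gene(s) skipped (NA rows); filter before testing",
            call. = FALSE)
  out$term <- factor(out$term, levels = names(.LADDER_TESTS))
  out$fdr <- stats::ave(out$p_value, out$term,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}
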