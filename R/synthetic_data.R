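# Synthetic count data with the statistical structure the analysis assumes:
# a balanced genotype x sex x replicate design of individually sequenced
# flies, NB-distributed counts with gene-specific dispersion, per-sample size
# factors, planted mean effects for any of the seven design terms, and
# planted genotype/sex-dependent extra within-cell variance (CV_E signal).

.TERMS <- c("G", "R", "S", "G:R", "G:S", "R:S", "G:R:S")
.TERM_FACTORS <- list(
  "G" = "genotype", "R" = "replicate", "S" = "sex",
  "G:R" = c("genotype", "replicate"), "G:S" = c("genotype", "sex"),
  "R:S" = c("replicate", "sex"),
  "G:R:S" = c("genotype", "replicate", "sex")
)

#' Generate a balanced individual-fly sample design
#'
#' Builds the factorial layout of the study the package emulates: every
#' genotype is reared in each replicate environment, and a fixed number of
#' individual flies of each sex is sampled from every genotype x sex x
#' replicate cell. Wolbachia infection status is a line-level property: a
#' seeded random subset of genotypes is flagged infected, and the flag is
#' constant within genotype.
#'
#' @param n_genotypes Number of inbred genotypes (lines). Default 16.
#' @param n_replicates Number of replicate environments. Default 3.
#' @param n_flies_per_cell Individual flies per genotype x sex x replicate
#'   cell. Default 8, so the default design has `16 * 3 * 2 * 8 = 768` rows.
#' @param infected_fraction Fraction of genotypes carrying the endosymbiont;
#'   `round(infected_fraction * n_genotypes)` genotypes are flagged. Default
#'   9/16.
#' @param seed Integer seed; identical arguments and seed give identical
#'   tables.
#' @param dropout_rate Optional probability that an individual fly is lost to
#'   quality control. The study design is balanced before QC; a small random
#'   dropout emulates post-QC attrition. Must leave every cell non-empty.
#' @return A data frame with columns `sample_id`, `genotype`, `sex`,
#'   `replicate`, `fly_index`, `infected`; the factor columns carry the full
#'   level sets.
#' @examples
#' d <- generate_design(4, 2, 3, infected_fraction = 0.5, seed = 1)
#' nrow(d)  # 4 * 2 * 2 * 3 = 48
#' @export
generate_design <- function(n_genotypes = 16L, n_replicates = 3L,
                            n_flies_per_cell = 8L, infected_fraction = 9 / 16,
                            seed = 1L, dropout_rate = 0) {
  if (any(c(n_genotypes, n_replicates, n_flies_per_cell) < 1))
    stop_invalid("design dimensions must all be >= 1")
  if (infected_fraction < 0 || infected_fraction > 1)
    stop_invalid("infected_fraction must lie in [0, 1]")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("dropout_rate must lie in [0, 1)")
  geno <- sprintf("G%02d", seq_len(n_genotypes))
  repl <- sprintf("R%d", seq_len(n_replicates))
  sexes <- c("F", "M")
  grid <- expand.grid(fly_index = seq_len(n_flies_per_cell),
                      replicate = repl, sex = sexes, genotype = geno,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "sex", "replicate", "fly_index")]
  n_inf <- round(infected_fraction * n_genotypes)
  design <- with_seed(seed, {
    inf_geno <- if (n_inf > 0) sort(sample(geno, n_inf)) else character(0)
    keep <- if (dropout_rate > 0) stats::runif(nrow(grid)) >= dropout_rate
            else rep(TRUE, nrow(grid))
    d <- grid[keep, , drop = FALSE]
    d$infected <- d$genotype %in% inf_geno
    d
  })
  cells <- interaction(design$genotype, design$sex, design$replicate)
  if (nlevels(droplevels(cells)) < n_genotypes * 2L * n_replicates)
    stop("dropout emptied at least one genotype/sex/replicate cell; ",
         "lower dropout_rate", call. = FALSE)
  design$genotype <- factor(design$genotype, levels = geno)
  design$sex <- factor(design$sex, levels = sexes)
  design$replicate <- factor(design$replicate, levels = repl)
  design$sample_id <- sprintf("%s_%s_%s_f%d", design$genotype, design$sex,
                              design$replicate, design$fly_index)
  rownames(design) <- NULL
  design[, c("sample_id", "genotype", "sex", "replicate", "fly_index",
             "infected")]
}

# ANOVA-style effect: remove every lower-order margin of a (gene x levels...)
# array so coefficients sum to zero over each factor index.
.expand_margin <- function(m, d, margins) {
  other <- setdiff(seq_along(d), margins)
  a <- array(m, c(d[margins], d[other]))
  aperm(a, order(c(margins, other)))
}

.anova_effect <- function(A) {
  d <- dim(A)
  fac_dims <- seq_along(d)[-1L]
  k <- length(fac_dims)
  subsets <- list(integer(0))
  for (f in fac_dims)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))
  out <- array(0, d)
  for (T in subsets) {
    sgn <- (-1)^(k - length(T))
    m <- apply(A, c(1L, T), mean)
    out <- out + sgn * .expand_margin(m, d, c(1L, T))
  }
  dimnames(out) <- dimnames(A)
  out
}

#' Generate per-gene ground truth for the count simulator
#'
#' Draws, for each gene, a baseline log mean, a dispersion, sum-to-zero
#' log-scale effect coefficients for a requested fraction of genes per design
#' term, and an optional per-(genotype, sex) variance-inflation factor that
#' plants genotype- or genotype-by-sex-dependent microenvironmental
#' variability (differential CV_E) without touching the mean model.
#'
#' For each term, exactly `round(prop * n_genes)` genes receive non-zero
#' coefficients; coefficients are drawn i.i.d. normal(0, effect_sd^2) and then
#' centred so every factor margin sums to zero, which makes the baseline the
#' grand log-mean. Inactive coefficients are exactly zero.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_genotypes,n_replicates Factor sizes; must match the design the
#'   truth will be paired with.
#' @param prop_active Named proportions in `[0, 1]` for any of `"G"`, `"R"`,
#'   `"S"`, `"G:R"`, `"G:S"`, `"R:S"`, `"G:R:S"`; unnamed terms default to 0.
#' @param effect_sd SD of the log-scale effect draws (e.g. `log(1.5)` plants
#'   typical 1.5-fold effects).
#' @param dispersion_range Interval from which gene dispersions are drawn
#'   uniformly; variance = mu + phi * mu^2.
#' @param baseline_log_mean,baseline_log_sd Normal parameters of the per-gene
#'   baseline log mean (defaults centre genes near 100 counts with a
#'   realistic bulk RNA-seq spread).
#' @param cve_prop_genotype Fraction of genes whose dispersion is inflated in
#'   a random half of the genotypes (both sexes) — genotype-dependent CV_E.
#' @param cve_prop_genotype_sex Fraction of genes inflated in a random half of
#'   the genotypes in one random sex — genotype-by-sex-dependent CV_E.
#' @param cve_multiplier Multiplier (>= 1) applied to the dispersion of
#'   affected (genotype, sex) combinations.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_truth"`: a list with `gene_ids`,
#'   `baseline`, `dispersion`, `coefficients` (one array per term, gene-major),
#'   `cve_multiplier` (gene x genotype x sex array) and `active` (per-term
#'   gene index vectors).
#' @export
generate_truth <- function(n_genes,
                           n_genotypes = 16L, n_replicates = 3L,
                           prop_active = c(G = 0),
                           effect_sd = 0.25,
                           dispersion_range = c(0.05, 1),
                           baseline_log_mean = log(100), baseline_log_sd = 1,
                           cve_prop_genotype = 0, cve_prop_genotype_sex = 0,
                           cve_multiplier = 2,
                           seed = 1L) {
  if (length(n_genes) != 1L || n_genes < 1)
    stop_invalid("n_genes must be a positive integer (empty gene set)")
  props <- stats::setNames(numeric(length(.TERMS)), .TERMS)
  if (length(prop_active)) {
    if (is.null(names(prop_active)) ||
        !all(names(prop_active) %in% .TERMS))
      stop_invalid("prop_active must be named with terms among: %s",
                   paste(.TERMS, collapse = ", "))
    props[names(prop_active)] <- prop_active
  }
  if (any(props < 0 | props > 1))
    stop_invalid("prop_active values must lie in [0, 1]")
  if (length(dispersion_range) != 2L || any(dispersion_range < 0) ||
      diff(dispersion_range) < 0)
    stop_invalid("dispersion_range must be an interval within [0, Inf)")
  if (effect_sd <= 0) stop_invalid("effect_sd must be positive")
  if (cve_multiplier < 1) stop_invalid("cve_multiplier must be >= 1")

  geno <- sprintf("G%02d", seq_len(n_genotypes))
  repl <- sprintf("R%d", seq_len(n_replicates))
  sexes <- c("F", "M")
  lev <- list(genotype = geno, replicate = repl, sex = sexes)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))

  with_seed(seed, {
    baseline <- stats::rnorm(n_genes, baseline_log_mean, baseline_log_sd)
    dispersion <- stats::runif(n_genes, dispersion_range[1], dispersion_range[2])
    coefficients <- list()
    active <- list()
    for (term in .TERMS) {
      facs <- .TERM_FACTORS[[term]]
      dims <- c(n_genes, lengths(lev[facs]))
      A <- array(0, dims,
                 dimnames = c(list(gene_ids), unname(lev[facs])))
      n_act <- round(props[[term]] * n_genes)
      idx <- if (n_act > 0) sort(sample.int(n_genes, n_act)) else integer(0)
      if (length(idx)) {
        draw <- array(0, dims)
        nlev <- prod(dims[-1L])
        raw <- matrix(stats::rnorm(length(idx) * nlev, 0, effect_sd),
                      length(idx), nlev)
        sub <- array(0, c(length(idx), dims[-1L]))
        sub[] <- raw
        sub <- .anova_effect(sub)
        # place centred rows back; index gene-major slices
        A_flat <- matrix(A, n_genes, nlev)
        A_flat[idx, ] <- matrix(sub, length(idx), nlev)
        A[] <- A_flat
      }
      coefficients[[term]] <- A
      active[[term]] <- idx
    }
    cvem <- array(1, c(n_genes, n_genotypes, 2L),
                  dimnames = list(gene_ids, geno, sexes))
    n_g <- round(cve_prop_genotype * n_genes)
    cve_g_idx <- if (n_g > 0) sort(sample.int(n_genes, n_g)) else integer(0)
    for (i in cve_g_idx) {
      gg <- sample.int(n_genotypes, max(1L, n_genotypes %/% 2L))
      cvem[i, gg, ] <- cve_multiplier
    }
    n_gs <- round(cve_prop_genotype_sex * n_genes)
    pool <- setdiff(seq_len(n_genes), cve_g_idx)
    cve_gs_idx <- if (n_gs > 0) sort(sample(pool, min(n_gs, length(pool))))
                  else integer(0)
    for (i in cve_gs_idx) {
      gg <- sample.int(n_genotypes, max(1L, n_genotypes %/% 2L))
      sx <- sample.int(2L, 1L)
      cvem[i, gg, sx] <- cve_multiplier
    }
    structure(list(gene_ids = gene_ids, baseline = baseline,
                   dispersion = dispersion, coefficients = coefficients,
                   cve_multiplier = cvem,
                   active = active,
                   levels = lev, effect_sd = effect_sd,
                   cve_value = cve_multiplier,
                   cve_genes = list(G = cve_g_idx, `G:S` = cve_gs_idx)),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes, %d genotypes x %d replicates x 2 sexes\n",
              length(x$gene_ids), length(x$levels$genotype),
              length(x$levels$replicate)))
  act <- vapply(x$active, length, integer(1))
  cat("active genes per term:",
      paste(sprintf("%s=%d", names(act), act), collapse = ", "), "\n")
  invisible(x)
}

# Column index of a flattened interaction array for each sample.
.flat_index <- function(truth, term, design) {
  facs <- .TERM_FACTORS[[term]]
  idx <- lapply(facs, function(f)
    as.integer(factor(as.character(design[[f]]), levels = truth$levels[[f]])))
  sizes <- lengths(truth$levels[facs])
  out <- idx[[1L]]
  if (length(idx) > 1L) out <- out + (idx[[2L]] - 1L) * sizes[1L]
  if (length(idx) > 2L) out <- out + (idx[[3L]] - 1L) * sizes[1L] * sizes[2L]
  out
}

#' Simulate a negative-binomial count matrix from a design and truth
#'
#' For sample k with size factor s_k, counts of gene i are NB draws with mean
#' `s_k * exp(eta_ik)` (eta assembled from the truth's baseline and term
#' coefficients) and variance `mean + phi_eff * mean^2`, where
#' `phi_eff = phi * cve_multiplier` for the sample's (genotype, sex). A zero
#' effective dispersion degenerates to Poisson draws. Size factors are drawn
#' log-uniformly from `size_factor_range` and rescaled to geometric mean 1,
#' mirroring the identifiability convention of median-of-ratios
#' normalization.
#'
#' @param design Output of [generate_design()] (or a compatible data frame).
#' @param truth Output of [generate_truth()].
#' @param size_factor_range Positive interval for the log-uniform size-factor
#'   draws.
#' @param seed Integer seed.
#' @return Integer count matrix (genes x samples) with gene ids as row names
#'   and sample ids as column names; the generating size factors are attached
#'   as attribute `"true_size_factors"`.
#' @export
simulate_counts <- function(design, truth, size_factor_range = c(0.7, 1.4),
                            seed = 1L) {
  check_design(design)
  if (!inherits(truth, "synthetic_truth"))
    stop_invalid("truth must come from generate_truth()")
  if (nrow(design) < 1L) stop_invalid("design is empty")
  if (length(size_factor_range) != 2L || any(size_factor_range <= 0))
    stop_invalid("size_factor_range must be a positive interval")
  for (f in c("genotype", "replicate", "sex"))
    if (!all(as.character(design[[f]]) %in% truth$levels[[f]]))
      stop_invalid("design %s levels not covered by truth (dimension mismatch)", f)

  n_genes <- length(truth$gene_ids)
  n_samp <- nrow(design)
  eta <- matrix(truth$baseline, n_genes, n_samp)
  for (term in .TERMS) {
    A <- truth$coefficients[[term]]
    M <- matrix(A, n_genes)
    eta <- eta + M[, .flat_index(truth, term, design), drop = FALSE]
  }
  g_idx <- as.integer(factor(as.character(design$genotype),
                             levels = truth$levels$genotype))
  s_idx <- as.integer(factor(as.character(design$sex),
                             levels = truth$levels$sex))
  cvem <- matrix(truth$cve_multiplier, n_genes)
  phi_eff <- truth$dispersion * cvem[, g_idx + (s_idx - 1L) *
                                       length(truth$levels$genotype),
                                     drop = FALSE]

  with_seed(seed, {
    sf <- exp(stats::runif(n_samp, log(size_factor_range[1]),
                           log(size_factor_range[2])))
    sf <- sf / exp(mean(log(sf)))
    mu <- sweep(exp(eta), 2L, sf, "*")
    counts <- matrix(0, n_genes, n_samp)
    over <- phi_eff > 0
    if (any(over))
      counts[over] <- stats::rnbinom(sum(over), mu = mu[over],
                                     size = 1 / phi_eff[over])
    if (any(!over))
      counts[!over] <- stats::rpois(sum(!over), mu[!over])
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(truth$gene_ids,
                             as.character(design$sample_id %||%
                                            seq_len(n_samp)))
    attr(counts, "true_size_factors") <- stats::setNames(sf, colnames(counts))
    counts
  })
}

#' Simulate a low-count intergenic background matrix
#'
#' Intergenic regions carry only background reads; their per-region means are
#' drawn log-normally around `low_mean` so that, after normalization, the
#' genic and intergenic log-density curves cross at a recoverable point (the
#' empirical expression threshold).
#'
#' @param n_regions Number of intergenic regions (>= 1).
#' @param design Sample design (only its row count and sample ids are used).
#' @param low_mean Background mean count; 0 gives an all-zero matrix.
#' @param dispersion NB dispersion of the background draws.
#' @param mean_log_sd Log-scale SD of the per-region means.
#' @param seed Integer seed.
#' @return Integer matrix (regions x samples).
#' @export
simulate_intergenic_counts <- function(n_regions, design, low_mean = 1,
                                       dispersion = 0.5, mean_log_sd = 0.6,
                                       seed = 1L) {
  if (n_regions < 1) stop_invalid("n_regions must be >= 1")
  if (low_mean < 0) stop_invalid("low_mean must be non-negative")
  n_samp <- nrow(design)
  ids <- sprintf("ig%05d", seq_len(n_regions))
  samp <- as.character(design$sample_id %||% seq_len(n_samp))
  if (low_mean == 0) {
    m <- matrix(0L, n_regions, n_samp, dimnames = list(ids, samp))
    return(m)
  }
  with_seed(seed, {
    region_mu <- stats::rlnorm(n_regions, log(low_mean), mean_log_sd)
    mu <- matrix(region_mu, n_regions, n_samp)
    counts <- if (dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
    m <- matrix(as.integer(counts), n_regions, n_samp,
                dimnames = list(ids, samp))
    m
  })
}
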