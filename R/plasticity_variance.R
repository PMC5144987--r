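# Heterogeneity-of-variance testing, CV_E computation and its ANOVA,
# balanced-design variance components, and broad-sense heritability.
#
# CV_E = 100 * sd / mean within each genotype x sex x replicate cell is the
# quantitative measure of microenvironmental plasticity: variation among
# genetically identical flies in a nominally common environment.

#' Levene / Brown-Forsythe heterogeneity-of-variance test
#'
#' One-way ANOVA F on the absolute deviations `Z = |y - center_j|` from the
#' group centre: `center = "mean"` gives Levene's test, `center = "median"`
#' the Brown-Forsythe variant.
#'
#' @param values Numeric vector.
#' @param group_labels Grouping with at least 2 groups of at least 2
#'   observations.
#' @param center `"mean"` or `"median"`.
#' @return List: `statistic` (F), `df1`, `df2`, `p_value`, `center`.
#' @examples
#' levene_test(c(1, 3, 2, 0, 8, 4), rep(c("a", "b"), each = 3))$statistic
#' # 72/34, the hand-computed ANOVA on absolute deviations
#' @export
levene_test <- function(values, group_labels, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- droplevels(factor(group_labels))
  if (nlevels(g) < 2L) stop_invalid("need at least 2 groups")
  if (any(table(g) < 2L)) stop_invalid("every group needs >= 2 observations")
  if (length(values) != length(g)) stop_invalid("values/group length mismatch")
  ctr <- if (center == "mean") tapply(values, g, mean)
         else tapply(values, g, stats::median)
  z <- abs(values - ctr[as.integer(g)])
  if (stats::var(z) == 0)
    stop("undefined statistic: absolute deviations are constant across all ",
         "groups", call. = FALSE)
  a <- stats::anova(stats::lm(z ~ g))
  list(statistic = a$`F value`[1L], df1 = a$Df[1L], df2 = a$Df[2L],
       p_value = a$`Pr(>F)`[1L], center = center)
}

#' Per-gene heterogeneity-of-variance screen
#'
#' Applies [levene_test()] gene by gene across the given grouping (default:
#' the genotype x sex x replicate cells, i.e. variance heterogeneity among
#' individual flies within cells), with BH-FDR across genes.
#'
#' @param norm Normalized matrix (genes x samples).
#' @param design Sample design.
#' @param center `"mean"` (Levene) or `"median"` (Brown-Forsythe).
#' @param groups Optional explicit grouping vector; defaults to the
#'   genotype x sex x replicate interaction.
#' @return Data frame: `gene_id`, `statistic`, `df1`, `df2`, `p_value`,
#'   `fdr`; genes with undefined statistics carry NA.
#' @export
hov_test <- function(norm, design, center = c("mean", "median"),
                     groups = NULL) {
  center <- match.arg(center)
  design <- as_factor_cols(check_design(design, norm))
  g <- groups %||% interaction(design$genotype, design$sex, design$replicate,
                               drop = TRUE)
  rows <- lapply(rownames(norm), function(gene) {
    r <- tryCatch(levene_test(norm[gene, ], g, center),
                  error = function(e) NULL)
    data.frame(gene_id = gene,
               statistic = r$statistic %||% NA_real_,
               df1 = r$df1 %||% NA_integer_, df2 = r$df2 %||% NA_integer_,
               p_value = r$p_value %||% NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Coefficient of environmental variation
#'
#' `100 * sd / mean` with the sample (n-1) SD; the within-cell measure of
#' expression plasticity.
#'
#' @param values Numeric vector with `n >= 2` and positive mean.
#' @return Non-negative percentage.
#' @examples
#' cve(c(8, 12))  # 28.284
#' @export
cve <- function(values) {
  if (length(values) < 2L)
    stop("insufficient data: CV_E needs at least 2 observations",
         call. = FALSE)
  m <- mean(values)
  if (m <= 0)
    stop("undefined CV_E: cell mean must be positive", call. = FALSE)
  100 * stats::sd(values) / m
}

#' CV_E for every gene and genotype x sex x replicate cell
#'
#' @param norm Normalized matrix (genes x samples).
#' @param design Sample design.
#' @return Long data frame with one row per gene and cell: `gene_id`,
#'   `genotype`, `sex`, `replicate`, `n`, `mean`, `sd`, `cve`, `defined`.
#'   Cells where CV_E is undefined (mean <= 0 or n < 2) are flagged
#'   `defined = FALSE` with NA `cve`, never fabricated.
#' @export
cve_table <- function(norm, design) {
  design <- as_factor_cols(check_design(design, norm))
  cells <- interaction(design$genotype, design$sex, design$replicate,
                       drop = FALSE, sep = "\r")
  lv <- levels(cells)
  per_cell <- lapply(lv, function(cl) {
    idx <- which(cells == cl)
    parts <- strsplit(cl, "\r", fixed = TRUE)[[1L]]
    n <- length(idx)
    if (n == 0L) return(NULL)
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    s <- if (n >= 2L) sqrt(rowSums((sub - m)^2) / (n - 1)) else rep(NA_real_, nrow(norm))
    ok <- n >= 2L & m > 0
    data.frame(gene_id = rownames(norm), genotype = parts[1L],
               sex = parts[2L], replicate = parts[3L],
               n = n, mean = m, sd = s,
               cve = ifelse(ok, 100 * s / m, NA_real_),
               defined = ok, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, per_cell)
  out <- out[order(match(out$gene_id, rownames(norm))), ]
  out$genotype <- factor(out$genotype, levels = levels(design$genotype))
  out$sex <- factor(out$sex, levels = levels(design$sex))
  out$replicate <- factor(out$replicate, levels = levels(design$replicate))
  rownames(out) <- NULL
  out
}

# Type-II sums of squares for cve ~ sex + genotype + sex:genotype via nested
# least-squares fits (equal to Type I/III on the balanced design).
.cve_anova_one <- function(y, sex, genotype, Xcache = NULL) {
  rss <- function(X) {
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }
  X_full <- Xcache$full %||% stats::model.matrix(~ sex * genotype)
  X_sg <- Xcache$sg %||% stats::model.matrix(~ sex + genotype)
  X_s <- Xcache$s %||% stats::model.matrix(~ sex)
  X_g <- Xcache$g %||% stats::model.matrix(~ genotype)
  n <- length(y)
  df_res <- n - qr(X_full)$rank
  if (df_res < 1L) return(NULL)  # term inestimable: no replicate stratum
  rss_full <- rss(X_full); rss_sg <- rss(X_sg)
  ss <- c(S = rss(X_g) - rss_sg,
          G = rss(X_s) - rss_sg,
          `G:S` = rss_sg - rss_full)
  df <- c(S = nlevels(sex) - 1L, G = nlevels(genotype) - 1L,
          `G:S` = (nlevels(sex) - 1L) * (nlevels(genotype) - 1L))
  mse <- rss_full / df_res
  Fv <- ifelse(rep(mse, 3L) > 0, (ss / df) / mse,
               ifelse(ss <= 1e-12, 0, Inf))
  pv <- ifelse(Fv == 0, 1, stats::pf(Fv, df, df_res, lower.tail = FALSE))
  data.frame(term = names(ss), F = unname(Fv), df1 = unname(df),
             df2 = df_res, p_value = unname(pv), stringsAsFactors = FALSE)
}

#' ANOVA of CV_E as a trait: Y = mu + S + G + G:S + e
#'
#' Replicate-level CV_E values are the observations, so the residual stratum
#' is replicate-within-genotype-by-sex and the genotype-by-sex term is
#' estimable. Type-II sums of squares are used (identical to Type I/III on
#' the balanced design). FDR is adjusted per term across genes.
#'
#' @param cve_tab Output of [cve_table()]; undefined cells are excluded.
#' @return Data frame: `gene_id`, `term` (`"G"`, `"S"`, `"G:S"`), `F`, `df1`,
#'   `df2`, `p_value`, `fdr`. Genes whose defined cells leave a term
#'   inestimable are flagged with NA rows.
#' @export
cve_anova <- function(cve_tab) {
  need <- c("gene_id", "genotype", "sex", "cve", "defined")
  if (!all(need %in% names(cve_tab)))
    stop_invalid("cve_tab must come from cve_table()")
  genes <- unique(cve_tab$gene_id)
  complete <- all(cve_tab$defined)
  Xcache <- NULL
  if (complete) {
    first <- cve_tab[cve_tab$gene_id == genes[1L], ]
    Xcache <- list(full = stats::model.matrix(~ sex * genotype, first),
                   sg = stats::model.matrix(~ sex + genotype, first),
                   s = stats::model.matrix(~ sex, first),
                   g = stats::model.matrix(~ genotype, first))
  }
  rows <- lapply(genes, function(gene) {
    sub <- cve_tab[cve_tab$gene_id == gene & cve_tab$defined, ]
    r <- if (nrow(sub) && nlevels(droplevels(sub$genotype)) >= 2L &&
             nlevels(droplevels(sub$sex)) >= 2L)
      .cve_anova_one(sub$cve, droplevels(sub$sex), droplevels(sub$genotype),
                     if (complete) Xcache else NULL)
    else NULL
    if (is.null(r))
      r <- data.frame(term = c("S", "G", "G:S"), F = NA_real_,
                      df1 = NA_integer_, df2 = NA_integer_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    cbind(gene_id = gene, r)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::ave(out$p_value, out$term,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}

# General EMS solver for balanced crossed designs with random
# genotype-containing terms. E[MS_t] = sigma_eps + sum over u >= t of
# m_u * sigma_u, with m_u the number of observations per cell of u
# (unrestricted mixed-model convention). Solved top-down on the raw scale,
# truncated to zero afterwards.
.ems_components <- function(y, facs) {
  facs <- lapply(facs, function(f) droplevels(factor(f)))
  present <- names(facs)[vapply(facs, nlevels, 1L) >= 2L]
  if (!"genotype" %in% present)
    stop_invalid("variance components need a genotype factor with >= 2 levels")
  dat <- as.data.frame(facs[present])
  dat$y <- y
  cells <- interaction(dat[present], drop = FALSE)
  tab <- table(cells)
  balanced <- length(unique(tab)) == 1L && all(tab > 0)
  if (!balanced)
    warning("unbalanced design: EMS coefficients use average cell sizes ",
            "(least-squares approximation)", call. = FALSE)
  form <- stats::reformulate(paste(present, collapse = " * "), response = "y")
  # only the sums of squares are used, so the F-test warnings that anova.lm
  # emits on degenerate (e.g. constant) input are irrelevant here
  a <- suppressWarnings(stats::anova(stats::lm(form, data = dat)))
  ms <- a$`Sum Sq` / a$Df
  names(ms) <- rownames(a)
  if (!"Residuals" %in% names(ms) || a["Residuals", "Df"] < 1L)
    stop_invalid("no residual degrees of freedom: need replication within cells")
  mse <- ms[["Residuals"]]
  N <- length(y)
  others <- setdiff(present, "genotype")
  subsets <- list(character(0))
  for (f in others) subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))
  rterms <- lapply(subsets, function(s) c("genotype", s))
  term_name <- function(tt) {
    cand <- rownames(a)
    hit <- cand[vapply(cand, function(nm)
      setequal(strsplit(nm, ":", fixed = TRUE)[[1L]], tt), logical(1))]
    if (!length(hit)) NA_character_ else hit[1L]
  }
  nm_map <- vapply(rterms, term_name, "")
  coef_m <- vapply(rterms, function(tt)
    N / prod(vapply(tt, function(f) nlevels(dat[[f]]), 1L)), 0)
  sizes <- lengths(rterms)
  ord <- order(sizes, decreasing = TRUE)
  raw <- numeric(length(rterms))
  for (k in ord) {
    tt <- rterms[[k]]
    covered <- which(vapply(rterms, function(u)
      length(u) > length(tt) && all(tt %in% u), logical(1)))
    raw[k] <- (ms[[nm_map[k]]] - mse -
                 sum(coef_m[covered] * raw[covered])) / coef_m[k]
  }
  short <- vapply(rterms, function(tt) {
    code <- unname(c(genotype = "G", replicate = "R", sex = "S")[tt])
    paste0("sigma_", paste(code[order(match(code, c("G", "R", "S")))],
                           collapse = ""))
  }, "")
  comp <- stats::setNames(pmax(raw, 0), short)
  list(components = comp, sigma_eps = mse, mean_squares = ms,
       balanced = balanced)
}

#' Variance components by expected mean squares
#'
#' Method-of-moments estimates from the expected mean squares of the
#' random-effects ANOVA on a balanced (or near-balanced) design; negative
#' solutions are truncated to 0.
#'
#' Two schemes mirror the two heritability estimators: `"expression"` treats
#' per-fly values (conventionally `log2(normalized + 1)`) with random G,
#' G:R, G:S, G:R:S and the within-cell residual; `"cve"` treats per-cell
#' CV_E values with random G and G:S, the replicate stratum serving as the
#' residual.
#'
#' @param values Numeric vector of observations for one gene.
#' @param design Data frame with `genotype` plus `replicate`/`sex` (scheme
#'   `"expression"`) or `genotype` plus `sex` (scheme `"cve"`), one row per
#'   observation.
#' @param scheme `"expression"` or `"cve"`.
#' @return A `"variance_components"` list: `scheme`, `components` (named
#'   vector of variances, e.g. `sigma_G`, `sigma_GR`, `sigma_GS`,
#'   `sigma_GRS`), `sigma_eps`, `mean_squares`, `balanced`.
#' @export
variance_components <- function(values, design, scheme = c("expression", "cve")) {
  scheme <- match.arg(scheme)
  design <- as.data.frame(design)
  facs <- if (scheme == "expression")
    list(genotype = design$genotype, replicate = design$replicate,
         sex = design$sex)
  else list(genotype = design$genotype, sex = design$sex)
  facs <- facs[!vapply(facs, is.null, logical(1))]
  if (length(values) != nrow(design))
    stop_invalid("values length does not match design rows")
  r <- .ems_components(values, facs)
  structure(list(scheme = scheme, components = r$components,
                 sigma_eps = r$sigma_eps, mean_squares = r$mean_squares,
                 balanced = r$balanced),
            class = "variance_components")
}

#' Broad-sense heritability from variance components
#'
#' Expression scheme:
#' `H2 = (sG + sGR + sGS + sGRS) / (sG + sGR + sGS + sGRS + s_eps)`;
#' CV_E scheme: `H2 = (sG + sGS) / (sG + sGS + s_eps)`. A 0/0 ratio is
#' defined as 0; the truncation of components keeps H2 in `[0, 1]`.
#'
#' @param vc A `"variance_components"` object.
#' @return List: `h2` in `[0, 1]` and `scheme`.
#' @export
heritability <- function(vc) {
  if (!inherits(vc, "variance_components"))
    stop_invalid("vc must come from variance_components()")
  genetic <- sum(vc$components)
  tot <- genetic + vc$sigma_eps
  h2 <- if (tot <= 0) 0 else genetic / tot
  list(h2 = min(1, max(0, h2)), scheme = vc$scheme)
}

#' Per-gene expression heritability table
#'
#' Computes variance components and H2 for each gene on
#' `log2(normalized + 1)` values (the variance-stabilized scale on which
#' variance components are conventionally taken).
#'
#' @param norm Normalized matrix (genes x samples).
#' @param design Sample design.
#' @return Data frame: `gene_id`, `h2`, the component estimates and
#'   `sigma_eps`.
#' @export
heritability_table <- function(norm, design) {
  design <- as_factor_cols(check_design(design, norm))
  vals <- log2(norm + 1)
  rows <- lapply(rownames(norm), function(gene) {
    vc <- variance_components(vals[gene, ], design, "expression")
    data.frame(gene_id = gene, h2 = heritability(vc)$h2,
               t(vc$components), sigma_eps = vc$sigma_eps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene CV_E heritability table
#'
#' @param cve_tab Output of [cve_table()]; per-gene CV_E values over the
#'   genotype x sex x replicate cells feed the CV_E-scheme variance
#'   components.
#' @return Data frame: `gene_id`, `h2`, `sigma_G`, `sigma_GS`, `sigma_eps`.
#' @export
cve_heritability_table <- function(cve_tab) {
  genes <- unique(cve_tab$gene_id)
  rows <- lapply(genes, function(gene) {
    sub <- cve_tab[cve_tab$gene_id == gene & cve_tab$defined, ]
    if (nrow(sub) < 4L || nlevels(droplevels(sub$genotype)) < 2L)
      return(data.frame(gene_id = gene, h2 = NA_real_, sigma_G = NA_real_,
                        sigma_GS = NA_real_, sigma_eps = NA_real_,
                        stringsAsFactors = FALSE))
    vc <- variance_components(sub$cve, sub[, c("genotype", "sex")], "cve")
    comp <- vc$components
    data.frame(gene_id = gene, h2 = heritability(vc)$h2,
               sigma_G = unname(comp["sigma_G"]),
               sigma_GS = if ("sigma_GS" %in% names(comp))
                 unname(comp["sigma_GS"]) else 0,
               sigma_eps = vc$sigma_eps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
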