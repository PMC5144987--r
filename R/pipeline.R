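# End-to-end orchestration: simulate or ingest -> normalize -> filter ->
# LRT ladder -> heterogeneity-of-variance -> CV_E / heritability ->
# clustering / enrichment -> covariate screens, under one configuration,
# with per-stage logging and a machine-readable summary.

#' Build and validate a pipeline configuration
#'
#' Exactly one of `counts` (with `design`) or `sim` must be supplied:
#' `counts`/`design`/`intergenic` may be file paths (TSV) or in-memory
#' objects; `sim` is a named list of arguments for [generate_design()],
#' [generate_truth()] and [simulate_counts()] (any of `n_genes`,
#' `n_genotypes`, `n_replicates`, `n_flies_per_cell`, `infected_fraction`,
#' `prop_active`, `effect_sd`, `dispersion_range`, `cve_prop_genotype`,
#' `cve_prop_genotype_sex`, `cve_multiplier`, `size_factor_range`,
#' `dropout_rate`, `intergenic_regions`). Validation reports every violated
#' field, not just the first.
#'
#' @param counts,design,intergenic Count matrix / design / intergenic matrix,
#'   or paths to their TSV files.
#' @param gene_sets Named list of gene sets or a GMT path (optional).
#' @param covariates Named list of covariate tables (or paths), e.g.
#'   `list(heterozygosity = ..., rrna = ...)` (optional).
#' @param sim Simulation parameter list (optional, exclusive with `counts`).
#' @param threshold Expression-threshold override; when NULL the threshold is
#'   derived from intergenic counts if present, else the published default.
#' @param alpha FDR significance level (default 0.05).
#' @param cluster_term Term whose significant genes are clustered (default
#'   `"G:R:S"`, the among-individual signature).
#' @param cluster_method Correlation for clustering, `"pearson"` or
#'   `"spearman"`.
#' @param beta_grid Adjacency-sharpening grid for [mmc_cluster()].
#' @param max_cluster_genes Cap on genes entering clustering (most
#'   significant first) to bound runtime.
#' @param seed Single integer driving all randomness.
#' @param output_dir Directory for stage outputs (optional; created).
#' @return A validated `"pipeline_config"` list.
#' @export
pipeline_config <- function(counts = NULL, design = NULL, intergenic = NULL,
                            gene_sets = NULL, covariates = NULL, sim = NULL,
                            threshold = NULL, alpha = 0.05,
                            cluster_term = "G:R:S",
                            cluster_method = "pearson",
                            beta_grid = seq(0.5, 12, length.out = 24L),
                            max_cluster_genes = 400L,
                            seed = 1L, output_dir = NULL) {
  problems <- character(0)
  if (is.null(counts) == is.null(sim))
    problems <- c(problems,
                  "exactly one of `counts` or `sim` must be provided")
  if (!is.null(counts) && is.null(design))
    problems <- c(problems, "`design` is required when `counts` is given")
  if (!is.null(alpha) && (alpha <= 0 || alpha >= 1))
    problems <- c(problems, "`alpha` must lie in (0, 1)")
  if (!is.null(threshold) && threshold <= 0)
    problems <- c(problems, "`threshold` must be positive")
  if (!cluster_term %in% .TERMS)
    problems <- c(problems, sprintf("`cluster_term` must be one of: %s",
                                    paste(.TERMS, collapse = ", ")))
  if (!cluster_method %in% c("pearson", "spearman"))
    problems <- c(problems, "`cluster_method` must be pearson or spearman")
  if (length(seed) != 1L || is.na(seed))
    problems <- c(problems, "`seed` must be a single integer")
  if (!is.null(sim) && !is.list(sim))
    problems <- c(problems, "`sim` must be a named list")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(counts = counts, design = design, intergenic = intergenic,
                 gene_sets = gene_sets, covariates = covariates, sim = sim,
                 threshold = threshold, alpha = alpha,
                 cluster_term = cluster_term,
                 cluster_method = cluster_method, beta_grid = beta_grid,
                 max_cluster_genes = max_cluster_genes,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  strip <- config[setdiff(names(config), "output_dir")]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(strip, digits.d = 15,
                                              vec.len = 1e6)), tf)
  unname(tools::md5sum(tf))
}

.stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1fs)", stage, sprintf(...),
                  as.numeric(proc.time()[3L] - t0)))
}

.load_or <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data acquisition (simulation or TSV
#' ingest), median-of-ratios normalization, expression filtering, the
#' seven-term NB likelihood-ratio ladder, Levene/Brown-Forsythe
#' heterogeneity-of-variance tests, the CV_E table and its ANOVA, expression
#' and CV_E heritability, male-bias contingency test, coexpression
#' clustering of the configured significant set (with optional gene-set
#' enrichment), and covariate screens. Any stage failure aborts with the
#' failing stage named. All randomness flows from `config$seed`; two runs
#' with identical config and seed produce byte-identical summaries.
#'
#' @param config A [pipeline_config()] object.
#' @return A `"run_summary"` list (also written as JSON plus per-stage TSVs
#'   to `config$output_dir` when set) with the per-stage gene counts, a
#'   Table-1-shaped per-term count matrix with the mean/CV_E overlap column,
#'   clustering and screen summaries, the software version, seed and a
#'   config hash. All stage result tables are attached in
#'   `attr(summary, "results")`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  t0 <- proc.time()[3L]
  stage <- "init"
  res <- list()
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- data -----------------------------------------------------------------
  dat <- run_stage("data", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      design <- generate_design(
        n_genotypes = sim$n_genotypes %||% 16L,
        n_replicates = sim$n_replicates %||% 3L,
        n_flies_per_cell = sim$n_flies_per_cell %||% 8L,
        infected_fraction = sim$infected_fraction %||% 9 / 16,
        seed = config$seed,
        dropout_rate = sim$dropout_rate %||% 0)
      truth <- generate_truth(
        n_genes = sim$n_genes %||% 500L,
        n_genotypes = sim$n_genotypes %||% 16L,
        n_replicates = sim$n_replicates %||% 3L,
        prop_active = sim$prop_active %||% c(G = 0),
        effect_sd = sim$effect_sd %||% 0.25,
        dispersion_range = sim$dispersion_range %||% c(0.05, 1),
        cve_prop_genotype = sim$cve_prop_genotype %||% 0,
        cve_prop_genotype_sex = sim$cve_prop_genotype_sex %||% 0,
        cve_multiplier = sim$cve_multiplier %||% 2,
        seed = config$seed + 1L)
      counts <- simulate_counts(design, truth,
                                size_factor_range =
                                  sim$size_factor_range %||% c(0.7, 1.4),
                                seed = config$seed + 2L)
      intergenic <- if (!is.null(sim$intergenic_regions))
        simulate_intergenic_counts(sim$intergenic_regions, design,
                                   seed = config$seed + 3L)
      list(counts = counts, design = design, truth = truth,
           intergenic = intergenic)
    } else {
      list(counts = .load_or(config$counts, read_counts_tsv),
           design = .load_or(config$design, read_design_tsv),
           truth = NULL,
           intergenic = .load_or(config$intergenic, read_counts_tsv))
    }
  })
  check_count_matrix(dat$counts)
  dat$design <- as_factor_cols(check_design(dat$design, dat$counts))
  .stage_log("data", t0, "%d genes x %d samples", nrow(dat$counts),
             ncol(dat$counts))

  # -- normalize ------------------------------------------------------------
  norm <- run_stage("normalize", {
    sf <- estimate_size_factors(dat$counts)
    normalize_counts(dat$counts, sf)
  })
  sf <- attr(norm, "size_factors")
  .stage_log("normalize", t0, "size factors in [%.3f, %.3f]",
             min(sf), max(sf))

  # -- filter ---------------------------------------------------------------
  filt <- run_stage("filter", {
    thr <- config$threshold
    if (is.null(thr) && !is.null(dat$intergenic)) {
      norm_ig <- sweep(dat$intergenic, 2L, sf, "/")
      thr <- as.numeric(derive_threshold(norm, norm_ig))
    }
    thr <- thr %||% default_expression_threshold()
    filter_expressed(norm, thr)
  })
  expressed <- filt$matrix
  .stage_log("filter", t0, "%d of %d genes expressed (threshold %.4g)",
             filt$report$n_expressed, filt$report$n_input_genes,
             filt$report$threshold)

  # -- differential expression ladder ---------------------------------------
  counts_expr <- dat$counts[rownames(expressed), , drop = FALSE]
  de <- run_stage("de-test", test_all_terms(counts_expr, dat$design, sf))
  de_sig <- tapply(de$fdr < config$alpha, de$term, sum, na.rm = TRUE)
  .stage_log("de-test", t0, "significant at FDR %.2g: %s", config$alpha,
             paste(sprintf("%s=%d", names(de_sig), de_sig), collapse = " "))

  # -- heterogeneity of variance --------------------------------------------
  hov <- run_stage("hov-test", {
    list(levene = hov_test(expressed, dat$design, center = "mean"),
         brown_forsythe = hov_test(expressed, dat$design, center = "median"))
  })
  .stage_log("hov-test", t0, "Levene significant: %d; Brown-Forsythe: %d",
             sum(hov$levene$fdr < config$alpha, na.rm = TRUE),
             sum(hov$brown_forsythe$fdr < config$alpha, na.rm = TRUE))

  # -- CV_E and its ANOVA ---------------------------------------------------
  cvetab <- run_stage("cve", cve_table(expressed, dat$design))
  cveaov <- run_stage("cve-anova", cve_anova(cvetab))
  .stage_log("cve-anova", t0, "genes with differential CV_E (G): %d",
             sum(cveaov$fdr[cveaov$term == "G"] < config$alpha, na.rm = TRUE))

  # -- heritability ---------------------------------------------------------
  h2_expr <- run_stage("heritability", heritability_table(expressed, dat$design))
  h2_cve <- run_stage("heritability", cve_heritability_table(cvetab))
  .stage_log("heritability", t0, "mean H2 expression %.3f, CV_E %.3f",
             mean(h2_expr$h2, na.rm = TRUE), mean(h2_cve$h2, na.rm = TRUE))

  # -- sex bias of the focus set --------------------------------------------
  focus_genes <- de$gene_id[de$term == config$cluster_term &
                              !is.na(de$fdr) & de$fdr < config$alpha]
  sex_bias <- run_stage("sex-bias", {
    mb <- male_biased_genes(expressed, dat$design)
    rest <- setdiff(rownames(expressed), focus_genes)
    if (length(focus_genes) && length(rest))
      sex_bias_fisher(sum(mb[focus_genes]), length(focus_genes),
                      sum(mb[rest]), length(rest))
    else NULL
  })

  # -- clustering -----------------------------------------------------------
  modules <- run_stage("cluster", {
    genes <- focus_genes
    if (length(genes) > config$max_cluster_genes) {
      sub <- de[de$term == config$cluster_term & de$gene_id %in% genes, ]
      genes <- sub$gene_id[order(sub$p_value)][seq_len(config$max_cluster_genes)]
    }
    if (length(genes) >= 3L) {
      cm <- correlation_matrix(expressed[genes, , drop = FALSE],
                               config$cluster_method)
      mmc_cluster(cm, config$beta_grid)
    } else NULL
  })
  if (!is.null(modules))
    .stage_log("cluster", t0, "%d modules, Q = %.3f (beta %.2f)",
               modules$n_modules, modules$modularity_q,
               modules$transform_parameter)

  # -- enrichment -----------------------------------------------------------
  enrichment <- run_stage("enrich", {
    gs <- .load_or(config$gene_sets, read_gmt)
    if (!is.null(gs) && !is.null(modules)) {
      universe <- rownames(expressed)
      do.call(rbind, lapply(sort(unique(modules$module)), function(mod) {
        mg <- names(modules$module)[modules$module == mod]
        cbind(module_label = mod,
              geneset_enrichment(mg, gs, universe))
      }))
    } else NULL
  })

  # -- covariate screens ----------------------------------------------------
  screens <- run_stage("screen", {
    out <- list()
    if (!is.null(dat$design$infected) &&
        nlevels(droplevels(factor(dat$design$infected))) == 2L)
      out$infection <- infection_test(counts_expr, dat$design, sf)
    if (!is.null(config$covariates)) {
      sds <- line_sd(expressed, dat$design)
      for (nm in names(config$covariates)) {
        cov <- .load_or(config$covariates[[nm]], read_covariate_tsv)
        out[[nm]] <- covariate_correlation(sds, cov, screen = nm)
      }
    }
    out
  })

  # -- summary --------------------------------------------------------------
  table1 <- summarize_table1(de, cveaov, config$alpha)
  screen_counts <- lapply(screens, function(s)
    sum(s$fdr < config$alpha, na.rm = TRUE))
  summary <- structure(list(
    package_version = as.character(utils::packageVersion("microplast")),
    seed = config$seed,
    config_hash = .config_hash(config),
    filter = unclass(filt$report),
    table1 = table1,
    hov_significant = list(
      levene = sum(hov$levene$fdr < config$alpha, na.rm = TRUE),
      brown_forsythe = sum(hov$brown_forsythe$fdr < config$alpha,
                           na.rm = TRUE)),
    heritability = list(
      mean_h2_expression = mean(h2_expr$h2, na.rm = TRUE),
      mean_h2_cve = mean(h2_cve$h2, na.rm = TRUE)),
    sex_bias = if (!is.null(sex_bias))
      list(odds_ratio = sex_bias$odds_ratio, p_value = sex_bias$p_value),
    clustering = if (!is.null(modules))
      list(n_genes = length(modules$gene_ids),
           n_modules = modules$n_modules,
           modularity_q = modules$modularity_q,
           beta = modules$transform_parameter),
    enrichment_hits = if (!is.null(enrichment))
      sum(enrichment$bonferroni_p < config$alpha),
    screen_significant = screen_counts,
    alpha = config$alpha), class = "run_summary")
  attr(summary, "results") <- list(
    design = dat$design, truth = dat$truth, size_factors = sf,
    filter_report = filt$report, de = de, hov = hov, cve_table = cvetab,
    cve_anova = cveaov, h2_expression = h2_expr, h2_cve = h2_cve,
    modules = modules, enrichment = enrichment, screens = screens,
    sex_bias = sex_bias)

  if (!is.null(config$output_dir)) {
    run_stage("write", .write_outputs(config$output_dir, dat, sf, filt, de,
                                      hov, cvetab, cveaov, h2_expr, h2_cve,
                                      modules, enrichment, screens, summary))
  }
  .stage_log("done", t0, "pipeline complete")
  summary
}

.write_outputs <- function(dir, dat, sf, filt, de, hov, cvetab, cveaov,
                           h2_expr, h2_cve, modules, enrichment, screens,
                           summary) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_counts_tsv(dat$counts, file.path(dir, "counts.tsv"))
  write_design_tsv(dat$design, file.path(dir, "design.tsv"))
  if (!is.null(dat$truth)) write_truth_tsv(dat$truth,
                                           file.path(dir, "truth.tsv"))
  wt(data.frame(sample_id = names(sf), size_factor = sf), "size_factors.tsv")
  wt(de, "term_tests.tsv")
  wt(hov$levene, "hov_levene.tsv")
  wt(hov$brown_forsythe, "hov_brown_forsythe.tsv")
  wt(cvetab, "cve_table.tsv")
  wt(cveaov, "cve_anova.tsv")
  wt(h2_expr, "heritability_expression.tsv")
  wt(h2_cve, "heritability_cve.tsv")
  if (!is.null(modules))
    wt(data.frame(gene_id = names(modules$module),
                  module = unname(modules$module)), "modules.tsv")
  if (!is.null(enrichment)) wt(enrichment, "enrichment.tsv")
  for (nm in names(screens)) wt(screens[[nm]], sprintf("screen_%s.tsv", nm))
  writeLines(summary_json(summary), file.path(dir, "run_summary.json"))
  invisible(dir)
}

#' Serialize a run summary as canonical JSON
#'
#' Fixed formatting (pretty, 10 significant digits, scalars unboxed) so that
#' identical runs produce byte-identical files.
#' @param summary A `"run_summary"` object.
#' @return A JSON character scalar.
#' @export
summary_json <- function(summary) {
  as.character(jsonlite::toJSON(unclass(summary), pretty = TRUE,
                                auto_unbox = TRUE, digits = 10,
                                dataframe = "columns", na = "null"))
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary (microplast ", x$package_version, ", seed ", x$seed,
      ")\n", sep = "")
  cat(sprintf("  expressed genes: %d of %d (threshold %.4g)\n",
              x$filter$n_expressed, x$filter$n_input_genes,
              x$filter$threshold))
  cat("  per-term significant gene counts (FDR <", x$alpha, "):\n")
  print(x$table1, row.names = FALSE)
  if (!is.null(x$clustering))
    cat(sprintf("  clustering: %d genes -> %d modules, Q = %.3f\n",
                x$clustering$n_genes, x$clustering$n_modules,
                x$clustering$modularity_q))
  invisible(x)
}

#' Per-term significant-gene counts with the mean/CV_E overlap
#'
#' The layout of the study's headline table: for each of the seven design
#' terms the number of genes differentially expressed at `fdr < alpha`; for
#' the CV_E ANOVA terms (G, S, G:S — the only terms of the CV_E model) the
#' number with differential CV_E, and the size of the intersection. Terms
#' absent from the CV_E model carry NA.
#'
#' @param term_tests Output of [test_all_terms()].
#' @param cve_tests Output of [cve_anova()].
#' @param alpha FDR threshold (default 0.05).
#' @return Data frame: `term`, `n_de`, `n_cve`, `n_overlap`.
#' @export
summarize_table1 <- function(term_tests, cve_tests, alpha = 0.05) {
  g_de <- unique(term_tests$gene_id)
  g_cve <- unique(cve_tests$gene_id)
  if (!setequal(g_de, g_cve))
    stop_invalid("term_tests and cve_tests cover different gene universes")
  rows <- lapply(.TERMS, function(term) {
    de_genes <- term_tests$gene_id[term_tests$term == term &
                                     !is.na(term_tests$fdr) &
                                     term_tests$fdr < alpha]
    if (term %in% c("G", "S", "G:S")) {
      cve_genes <- cve_tests$gene_id[cve_tests$term == term &
                                       !is.na(cve_tests$fdr) &
                                       cve_tests$fdr < alpha]
      data.frame(term = term, n_de = length(de_genes),
                 n_cve = length(cve_genes),
                 n_overlap = length(intersect(de_genes, cve_genes)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(term = term, n_de = length(de_genes), n_cve = NA_integer_,
                 n_overlap = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
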