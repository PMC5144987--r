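# Modularity-maximizing coexpression clustering of significant gene sets,
# connectivity-ordered module reporting, hypergeometric gene-set enrichment
# with Bonferroni control, and the male-bias contingency test.

#' Gene-gene correlation matrix
#'
#' @param norm_subset Normalized matrix (genes x samples), at least 2 genes
#'   and 3 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric genes x genes matrix with unit diagonal. Constant genes
#'   (undefined correlation) are excluded, with their ids recorded in
#'   attribute `"excluded"` and a warning.
#' @export
correlation_matrix <- function(norm_subset, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.matrix(norm_subset) || nrow(norm_subset) < 2L)
    stop_invalid("need at least 2 genes")
  if (ncol(norm_subset) < 3L)
    stop_invalid("need at least 3 samples for a correlation matrix")
  sds <- apply(norm_subset, 1L, stats::sd)
  excluded <- rownames(norm_subset)[sds == 0]
  if (length(excluded)) {
    warning(length(excluded), " constant gene(s) excluded from correlation",
            call. = FALSE)
    norm_subset <- norm_subset[sds > 0, , drop = FALSE]
    if (nrow(norm_subset) < 2L)
      stop_invalid("fewer than 2 non-constant genes remain")
  }
  cm <- stats::cor(t(norm_subset), method = method)
  diag(cm) <- 1
  attr(cm, "excluded") <- excluded
  cm
}

#' Weighted-graph modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)` with
#' `k_i = sum_j A_ij`, `2m = sum_ij A_ij`; self-loops are ignored (the
#' diagonal is zeroed). An all-zero adjacency has Q = 0 by convention.
#'
#' @param adjacency Non-negative symmetric matrix.
#' @param labels Community label per node.
#' @return Q in `[-1, 1]`.
#' @export
modularity <- function(adjacency, labels) {
  if (!is.matrix(adjacency) || any(adjacency < 0))
    stop_invalid("adjacency must be a non-negative matrix")
  if (length(labels) != nrow(adjacency))
    stop_invalid("labels length does not match adjacency dimension")
  A <- adjacency
  diag(A) <- 0
  m2 <- sum(A)
  if (m2 <= 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    q <- q + sum(A[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

# Deterministic greedy agglomerative modularity maximization. Communities
# are identified by their lexicographically smallest member id; ties in
# delta-Q are broken by that label pair, so the result is invariant to gene
# order up to relabeling.
.greedy_modularity <- function(A, ids) {
  n <- nrow(A)
  diag(A) <- 0
  m2 <- sum(A)
  if (m2 <= 0)
    return(list(labels = rep(1L, n), q = 0))
  ord <- order(ids)
  e <- A[ord, ord] / m2          # pairwise weight fractions
  a <- rowSums(e)                # degree fractions per community
  comm_label <- ids[ord]         # min member id per community
  members <- as.list(seq_len(n)) # indices into ord
  q <- -sum(a^2)                 # all singletons (diag zero)
  best_q <- q
  best_assign <- seq_len(n)
  assign <- seq_len(n)
  active <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    ee <- e[act, act, drop = FALSE]
    dq <- 2 * (ee - outer(a[act], a[act]))
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    mx <- max(dq)
    cand <- which(dq >= mx - 1e-12, arr.ind = TRUE)
    # tie-break: lexicographically smallest (label_i, label_j) pair
    li <- comm_label[act[cand[, 1L]]]
    lj <- comm_label[act[cand[, 2L]]]
    lo <- pmin(li, lj); hi <- pmax(li, lj)
    pick <- order(lo, hi)[1L]
    u <- act[cand[pick, 1L]]; v <- act[cand[pick, 2L]]
    if (comm_label[v] < comm_label[u]) { tmp <- u; u <- v; v <- tmp }
    # merge v into u
    q <- q + 2 * unname(e[u, v] - a[u] * a[v])
    e[u, ] <- e[u, ] + e[v, ]
    e[, u] <- e[, u] + e[, v]
    e[u, u] <- e[u, u]           # already includes both cross terms
    a[u] <- a[u] + a[v]
    members[[u]] <- c(members[[u]], members[[v]])
    members[[v]] <- integer(0)
    active[v] <- FALSE
    assign[members[[u]]] <- u
    if (q > best_q + 1e-12) {
      best_q <- q
      best_assign <- assign
    }
  }
  labels_ord <- match(best_assign, sort(unique(best_assign)))
  labels <- integer(n)
  labels[ord] <- labels_ord
  list(labels = labels, q = best_q)
}

#' Modularity-based coexpression clustering (MMC-style)
#'
#' Sharpens the absolute correlation into an adjacency `A = |cor|^beta`,
#' searches `beta` over a grid, and for each candidate runs deterministic
#' greedy agglomerative modularity maximization; the `beta` achieving the
#' highest modularity Q is selected (smallest beta on ties). Modules are
#' ordered by mean within-module edge weight (connectivity), descending, and
#' relabeled 1..K in that order.
#'
#' @param cor_mat Symmetric correlation matrix with unit diagonal (e.g. from
#'   [correlation_matrix()]).
#' @param beta_grid Candidate sharpening exponents (default 24 points from
#'   0.5 to 12).
#' @return A `"module_assignment"` list: `gene_ids`, `module` (integer per
#'   gene, named), `n_modules`, `modularity_q`, `transform_parameter` (the
#'   selected beta), `module_order` (mean within-module connectivity by
#'   module, descending).
#' @export
mmc_cluster <- function(cor_mat, beta_grid = seq(0.5, 12, length.out = 24L)) {
  if (!is.matrix(cor_mat) || nrow(cor_mat) != ncol(cor_mat))
    stop_invalid("cor_mat must be a square matrix")
  if (max(abs(cor_mat - t(cor_mat))) > 1e-8)
    stop_invalid("cor_mat must be symmetric")
  if (any(abs(diag(cor_mat) - 1) > 1e-8))
    stop_invalid("cor_mat must have unit diagonal")
  ids <- rownames(cor_mat) %||% sprintf("g%04d", seq_len(nrow(cor_mat)))
  base <- abs(cor_mat)
  best <- NULL
  for (beta in beta_grid) {
    A <- base^beta
    r <- .greedy_modularity(A, ids)
    if (is.null(best) || r$q > best$q + 1e-12) {
      best <- r
      best$beta <- beta
      best$A <- A
    }
  }
  A <- best$A
  diag(A) <- 0
  conn <- vapply(sort(unique(best$labels)), function(cl) {
    idx <- which(best$labels == cl)
    if (length(idx) < 2L) return(0)
    sum(A[idx, idx]) / (length(idx) * (length(idx) - 1L))
  }, 0)
  min_id <- vapply(sort(unique(best$labels)), function(cl)
    min(ids[best$labels == cl]), "")
  ord <- order(-conn, min_id)
  relabel <- match(best$labels, sort(unique(best$labels))[ord])
  structure(list(gene_ids = ids,
                 module = stats::setNames(relabel, ids),
                 n_modules = length(conn),
                 modularity_q = best$q,
                 transform_parameter = best$beta,
                 module_order = conn[ord]),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d genes in %d modules, Q = %.4f (beta = %.2f)\n",
              length(x$gene_ids), x$n_modules, x$modularity_q,
              x$transform_parameter))
  print(table(module = x$module))
  invisible(x)
}

#' Hypergeometric gene-set enrichment with Bonferroni control
#'
#' Upper-tail hypergeometric p for an overlap at least as large as observed,
#' with each set first intersected with the universe; the Bonferroni factor
#' is the number of sets tested.
#'
#' @param module_genes Character vector of genes in the module (must be a
#'   subset of the universe).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return Data frame: `set_name`, `k_in`, `K_set`, `n_module`, `N`,
#'   `p_value`, `bonferroni_p`.
#' @export
geneset_enrichment <- function(module_genes, gene_sets, universe) {
  if (!length(universe)) stop_invalid("empty universe")
  if (!length(module_genes)) stop_invalid("empty module")
  if (!all(module_genes %in% universe))
    stop_invalid("module_genes must be a subset of the universe")
  if (!length(gene_sets) || is.null(names(gene_sets)))
    stop_invalid("gene_sets must be a non-empty named list")
  N <- length(unique(universe))
  n <- length(unique(module_genes))
  m <- length(gene_sets)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(module_genes, set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k_in = k, K_set = K, n_module = n, N = N,
               p_value = p, bonferroni_p = min(1, p * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher's exact test of sex-biased expression in a focus gene set
#'
#' Two-sided exact test on the 2x2 table (focus vs rest) x (male-biased vs
#' not), with the conditional maximum-likelihood odds ratio.
#'
#' @param n_biased_in_focus,n_focus Male-biased count and size of the focus
#'   set.
#' @param n_biased_in_rest,n_rest Male-biased count and size of the
#'   remaining transcriptome.
#' @return List: `odds_ratio`, `p_value`, `table`.
#' @export
sex_bias_fisher <- function(n_biased_in_focus, n_focus,
                            n_biased_in_rest, n_rest) {
  vals <- c(n_biased_in_focus, n_focus, n_biased_in_rest, n_rest)
  if (any(vals < 0)) stop_invalid("cell counts must be non-negative")
  if (n_biased_in_focus > n_focus || n_biased_in_rest > n_rest)
    stop_invalid("biased counts cannot exceed group sizes")
  tab <- matrix(c(n_biased_in_focus, n_focus - n_biased_in_focus,
                  n_biased_in_rest, n_rest - n_biased_in_rest),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("focus", "rest"),
                                c("male_biased", "not_biased")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Flag male-biased genes
#'
#' A gene is male-biased when its mean normalized expression in males exceeds
#' that in females — the minimal operationalization of the term.
#'
#' @param norm Normalized matrix.
#' @param design Sample design with a `sex` factor using levels F/M.
#' @return Named logical vector per gene.
#' @export
male_biased_genes <- function(norm, design) {
  design <- as_factor_cols(check_design(design, norm, need = "sex"))
  male <- design$sex == "M"
  if (!any(male) || all(male))
    stop_invalid("both sexes must be present")
  rowMeans(norm[, male, drop = FALSE]) >
    rowMeans(norm[, !male, drop = FALSE])
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors with set descriptions in
#'   attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop_invalid("malformed GMT line(s): %s",
                 paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions (default `"na"`).
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(gene_sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(gene_sets), desc, gene_sets)
  writeLines(unname(lines), path)
  invisible(path)
}
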