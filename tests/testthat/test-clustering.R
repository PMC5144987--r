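# Correlation matrices, modularity clustering, enrichment, sex-bias test.

# Simulate a factor-model expression matrix with planted modules:
# within-module correlation ~ rho_w, between-module ~ rho_b.
planted_modules <- function(n_per_module, n_modules, n_samples,
                            rho_w = 0.8, rho_b = 0.1, seed = 1) {
  set.seed(seed)
  a2 <- rho_w - rho_b
  common <- rnorm(n_samples)
  mats <- lapply(seq_len(n_modules), function(m) {
    fac <- rnorm(n_samples)
    t(vapply(seq_len(n_per_module), function(i)
      sqrt(a2) * fac + sqrt(rho_b) * common +
        sqrt(1 - rho_w) * rnorm(n_samples), numeric(n_samples)))
  })
  x <- do.call(rbind, mats)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(ncol(x)))
  list(x = x, truth = rep(seq_len(n_modules), each = n_per_module))
}

test_that("correlation_matrix is symmetric with unit diagonal and excludes constants", {
  set.seed(2)
  x <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  x[2, ] <- -x[1, ]        # perfect anti-correlation
  cm <- correlation_matrix(x)
  expect_equal(diag(cm), setNames(rep(1, 5), rownames(x)))
  expect_equal(cm, t(cm))
  expect_equal(cm["g1", "g2"], -1)

  xc <- rbind(x, flat = rep(3, 30))
  expect_warning(cm2 <- correlation_matrix(xc), "constant")
  expect_false("flat" %in% rownames(cm2))
  expect_identical(attr(cm2, "excluded"), "flat")

  expect_error(correlation_matrix(x[, 1:2]), "at least 3 samples")

  # independent genes: mean off-diagonal within 3 SE of 0
  set.seed(3)
  xi <- matrix(rnorm(40 * 100), 40, 100,
               dimnames = list(sprintf("g%02d", 1:40), NULL))
  colnames(xi) <- sprintf("s%03d", 1:100)
  ci <- correlation_matrix(xi)
  off <- ci[upper.tri(ci)]
  expect_lt(abs(mean(off)), 3 / sqrt(99 * length(off)))
})

test_that("modularity matches closed forms on the canonical toys", {
  # single community -> 0
  A <- matrix(1, 4, 4); diag(A) <- 0
  expect_equal(modularity(A, rep(1, 4)), 0)

  # two disconnected equal cliques, correct labels -> exactly 1/2
  B <- matrix(0, 10, 10)
  B[1:5, 1:5] <- 1; B[6:10, 6:10] <- 1; diag(B) <- 0
  good <- rep(1:2, each = 5)
  expect_equal(modularity(B, good), 0.5, tolerance = 1e-12)

  # deliberately wrong labels score lower
  bad <- rep(1:2, times = 5)
  expect_lt(modularity(B, bad), modularity(B, good))

  expect_error(modularity(B, rep(1, 3)), "labels length")
})

test_that("mmc_cluster recovers perfect blocks deterministically and reports a verifiable Q", {
  n <- 10
  cm <- matrix(0, n, n)
  cm[1:5, 1:5] <- 1; cm[6:10, 6:10] <- 1
  diag(cm) <- 1
  rownames(cm) <- colnames(cm) <- sprintf("g%02d", 1:n)
  r <- mmc_cluster(cm)
  expect_equal(r$n_modules, 2)
  expect_equal(unname(r$module[1:5]), rep(r$module[[1]], 5))
  expect_equal(unname(r$module[6:10]), rep(r$module[[6]], 5))
  expect_equal(r$modularity_q, 0.5, tolerance = 1e-12)

  # reported Q equals an independent recomputation from adjacency + labels
  A <- abs(cm)^r$transform_parameter
  diag(A) <- 0
  expect_equal(modularity(A, r$module), r$modularity_q, tolerance = 1e-10)

  # all-zero off-diagonal: degenerate single module with Q = 0
  z <- diag(1, 4)
  rownames(z) <- colnames(z) <- paste0("g", 1:4)
  rz <- mmc_cluster(z)
  expect_equal(rz$n_modules, 1)
  expect_equal(rz$modularity_q, 0)
})

test_that("clustering is stable under gene-order permutation up to relabeling", {
  pm <- planted_modules(6, 3, 80, seed = 4)
  cm <- correlation_matrix(pm$x)
  r1 <- mmc_cluster(cm)
  set.seed(9)
  perm <- sample(nrow(cm))
  r2 <- mmc_cluster(cm[perm, perm])
  m2 <- r2$module[names(r1$module)]
  tab <- table(r1$module, m2)
  expect_equal(sum(tab > 0), length(unique(r1$module)))  # a bijection
  expect_equal(r1$modularity_q, r2$modularity_q, tolerance = 1e-12)
})

test_that("planted three-module structure is recovered with high agreement", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:5, function(s) {
    pm <- planted_modules(10, 3, 150, seed = s)
    r <- mmc_cluster(correlation_matrix(pm$x))
    mclust::adjustedRandIndex(r$module, pm$truth)
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("module ordering follows mean within-module connectivity", {
  # two blocks with different internal correlation strength
  cm <- matrix(0.05, 12, 12)
  cm[1:6, 1:6] <- 0.4
  cm[7:12, 7:12] <- 0.9
  diag(cm) <- 1
  rownames(cm) <- colnames(cm) <- sprintf("g%02d", 1:12)
  r <- mmc_cluster(cm)
  expect_equal(r$n_modules, 2)
  # module 1 must be the high-connectivity block (genes 7..12)
  expect_true(all(r$module[7:12] == 1))
  expect_true(all(diff(r$module_order) <= 0))
})

test_that("hypergeometric enrichment matches enumeration and behaves monotonically", {
  # module of 10, set of 10, all overlap, universe 100: the single most
  # extreme draw
  uni <- sprintf("u%03d", 1:100)
  mod <- uni[1:10]
  r <- geneset_enrichment(mod, list(hit = uni[1:10]), uni)
  expect_equal(r$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(r$k_in, 10)

  # zero overlap with a small set: upper tail from zero is total mass
  r0 <- geneset_enrichment(mod, list(miss = uni[90:95]), uni)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  # enumeration oracle on small universes
  set.seed(8)
  for (i in 1:20) {
    N <- sample(10:60, 1)
    uni <- sprintf("u%03d", 1:N)
    mod <- sample(uni, sample(2:min(8, N - 2), 1))
    set <- sample(uni, sample(2:min(10, N - 2), 1))
    r <- geneset_enrichment(mod, list(s = set), uni)
    expect_equal(r$p_value,
                 hyper_upper_bruteforce(r$k_in, r$K_set, N, r$n_module),
                 tolerance = 1e-10)
  }

  # growing the universe with irrelevant genes makes the overlap rarer
  uni_small <- sprintf("u%03d", 1:30)
  mod <- uni_small[1:5]; set <- uni_small[3:8]
  p_small <- geneset_enrichment(mod, list(s = set), uni_small)$p_value
  p_big <- geneset_enrichment(mod, list(s = set),
                              c(uni_small, sprintf("x%03d", 1:30)))$p_value
  expect_lt(p_big, p_small)

  # Bonferroni over the number of sets
  many <- lapply(1:5, function(i) sample(uni_small, 5))
  names(many) <- paste0("set", 1:5)
  rb <- geneset_enrichment(mod, many, uni_small)
  expect_equal(rb$bonferroni_p, pmin(1, rb$p_value * 5))

  expect_error(geneset_enrichment(character(0), many, uni_small),
               "empty module")
  expect_error(geneset_enrichment(c(mod, "zzz"), many, uni_small),
               "subset of the universe")
})

test_that("sex_bias_fisher matches enumeration with odds-ratio symmetry", {
  r <- sex_bias_fisher(5, 10, 5, 10)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-8)
  expect_equal(r$p_value, 1)

  r2 <- sex_bias_fisher(8, 10, 2, 10)
  expect_equal(r2$p_value, fisher_two_sided_bruteforce(8, 2, 2, 8),
               tolerance = 1e-10)

  # swapping rows inverts the odds ratio, p unchanged
  r3 <- sex_bias_fisher(2, 10, 8, 10)
  expect_equal(r3$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r3$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-6)

  # random small tables vs enumeration
  set.seed(10)
  for (i in 1:20) {
    nf <- sample(3:30, 1); nr <- sample(3:30, 1)
    a <- sample(0:nf, 1); c_ <- sample(0:nr, 1)
    r <- sex_bias_fisher(a, nf, c_, nr)
    expect_equal(r$p_value,
                 fisher_two_sided_bruteforce(a, nf - a, c_, nr - c_),
                 tolerance = 1e-8)
  }
  expect_error(sex_bias_fisher(-1, 5, 2, 5), "non-negative")
  expect_error(sex_bias_fisher(7, 5, 2, 5), "exceed")
})

test_that("male_biased_genes compares sex means", {
  d <- small_design()
  m <- matrix(1, 2, nrow(d), dimnames = list(c("up", "down"), d$sample_id))
  m["up", d$sex == "M"] <- 3
  m["down", d$sex == "F"] <- 3
  mb <- male_biased_genes(m, d)
  expect_true(mb[["up"]])
  expect_false(mb[["down"]])
})

test_that("GMT files round-trip and match the reference reader", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g9"))
  tf <- tempfile(fileext = ".gmt")
  write_gmt(sets, tf, descriptions = c("first", "second"))
  back <- read_gmt(tf)
  expect_equal(back, sets, ignore_attr = TRUE)
  expect_equal(unname(attr(back, "descriptions")), c("first", "second"))
  skip_if_not_installed("fgsea")
  ref <- fgsea::gmtPathways(tf)
  expect_equal(ref, sets, ignore_attr = TRUE)
})

test_that("the adjusted-Rand helper agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(ari(rep(1:2, 10), rep(1:2, 10)), 1)
})
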