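# CV_E, heterogeneity of variance, variance components, heritability.

test_that("levene_test reproduces the hand ANOVA on absolute deviations", {
  r <- levene_test(c(1, 3, 2, 0, 8, 4), rep(c("a", "b"), each = 3),
                   center = "mean")
  expect_equal(r$statistic, 72 / 34, tolerance = 1e-12)
  expect_equal(c(r$df1, r$df2), c(1, 4))

  # label exchangeability
  perm <- c(4, 2, 6, 1, 3, 5)
  r2 <- levene_test(c(1, 3, 2, 0, 8, 4)[perm],
                    rep(c("a", "b"), each = 3)[perm], center = "mean")
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)

  expect_error(levene_test(1:4, c("a", "a", "a", "a")), "at least 2 groups")
  expect_error(levene_test(rep(5, 6), rep(c("a", "b"), 3), "mean"),
               "undefined statistic")
})

test_that("levene_test agrees with the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(5)
  y <- c(rnorm(20, sd = 1), rnorm(20, sd = 3))
  g <- factor(rep(c("a", "b"), each = 20))
  for (ctr in c("mean", "median")) {
    ours <- levene_test(y, g, ctr)
    ref <- car::leveneTest(y, g, center = get(ctr))
    expect_equal(ours$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("levene type-I error is near nominal and centers mostly agree on symmetric data", {
  set.seed(6)
  n_sim <- 400
  rej <- agree <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    y <- rnorm(40)
    g <- factor(rep(c("a", "b"), each = 20))
    pm <- levene_test(y, g, "mean")$p_value
    pd <- levene_test(y, g, "median")$p_value
    rej[i] <- pm < 0.05
    agree[i] <- (pm < 0.05) == (pd < 0.05)
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
  expect_gte(mean(agree), 0.95)
})

test_that("cve computes 100*sd/mean with its documented edge cases", {
  expect_equal(cve(c(10, 10, 10, 10)), 0)
  expect_equal(cve(c(8, 12)), 100 * sqrt(8) / 10, tolerance = 1e-12)
  expect_equal(cve(c(8, 12)), 28.284, tolerance = 1e-3)
  x <- c(3, 9, 4, 8)
  expect_equal(cve(x * 17), cve(x), tolerance = 1e-12)
  expect_error(cve(c(5)), "insufficient data")
  expect_error(cve(c(-3, 1)), "undefined CV_E")
})

test_that("cve_table covers every cell, flags undefined cells, and responds to planted dispersion", {
  sd <- small_dataset(n_genes = 6, seed = 2)
  nm <- normalize_counts(sd$counts)
  tab <- cve_table(nm, sd$design)
  expect_equal(nrow(tab), 6 * 4 * 2 * 2)
  expect_true(all(tab$n == 4))
  expect_true(all(tab$defined))

  # all-equal matrix: every cve is 0
  flat <- matrix(5, 3, nrow(sd$design),
                 dimnames = list(paste0("g", 1:3), sd$design$sample_id))
  tf <- cve_table(flat, sd$design)
  expect_true(all(tf$cve == 0))

  # a zero-mean cell is flagged, not fabricated
  z <- flat
  z[1, sd$design$genotype == "G01" & sd$design$sex == "F" &
      sd$design$replicate == "R1"] <- 0
  tz <- cve_table(z, sd$design)
  bad <- tz[tz$gene_id == "g1" & tz$genotype == "G01" & tz$sex == "F" &
              tz$replicate == "R1", ]
  expect_false(bad$defined)
  expect_true(is.na(bad$cve))
})

test_that("doubling a genotype's dispersion raises its CV_E", {
  # planted genotype-specific variance inflation, many genes, one-sided check
  design <- generate_design(4, 3, 8, 0.5, seed = 3)
  truth <- generate_truth(60, n_genotypes = 4, n_replicates = 3,
                          dispersion_range = c(0.3, 0.3),
                          cve_prop_genotype = 1, cve_multiplier = 2, seed = 4)
  counts <- simulate_counts(design, truth, seed = 5)
  nm <- normalize_counts(counts)
  tab <- cve_table(nm, design)
  diffs <- vapply(seq_len(60), function(i) {
    gid <- truth$gene_ids[i]
    m <- truth$cve_multiplier[i, , 1]
    hot <- names(m)[m > 1]
    sub <- tab[tab$gene_id == gid, ]
    mean(sub$cve[sub$genotype %in% hot]) -
      mean(sub$cve[!sub$genotype %in% hot])
  }, 0)
  expect_gt(mean(diffs > 0), 0.9)
  expect_gt(t.test(diffs)$statistic, 2)
})

test_that("cve_anova detects planted genotype CV_E signal and respects balance symmetries", {
  # identical CV_E in all cells: F = 0, p = 1
  design <- small_design()
  flat <- matrix(5, 2, nrow(design),
                 dimnames = list(c("g1", "g2"), design$sample_id))
  tab <- cve_table(flat, design)
  aov0 <- cve_anova(tab)
  expect_true(all(aov0$F == 0))
  expect_true(all(aov0$p_value == 1))

  # swapping sex labels leaves the G statistic unchanged (orthogonality)
  sdat <- small_dataset(n_genes = 4, seed = 9)
  nm <- normalize_counts(sdat$counts)
  t1 <- cve_table(nm, sdat$design)
  d2 <- sdat$design
  d2$sex <- factor(ifelse(d2$sex == "F", "M", "F"), c("F", "M"))
  t2 <- cve_table(nm, d2)
  a1 <- cve_anova(t1); a2 <- cve_anova(t2)
  expect_equal(a1$F[a1$term == "G"], a2$F[a2$term == "G"], tolerance = 1e-8)
})

test_that("cve_anova agrees with car Type-II sums of squares", {
  skip_if_not_installed("car")
  sdat <- small_dataset(n_genes = 2, seed = 12)
  nm <- normalize_counts(sdat$counts)
  tab <- cve_table(nm, sdat$design)
  ours <- cve_anova(tab)
  for (g in unique(tab$gene_id)) {
    sub <- tab[tab$gene_id == g, ]
    ref <- car::Anova(lm(cve ~ sex * genotype, sub), type = 2)
    expect_equal(ours$F[ours$gene_id == g & ours$term == "G"],
                 ref["genotype", "F value"], tolerance = 1e-8)
    expect_equal(ours$F[ours$gene_id == g & ours$term == "G:S"],
                 ref["sex:genotype", "F value"], tolerance = 1e-8)
  }
})

test_that("EMS variance components solve the one-way and crossed toys", {
  # one-way balanced toy: E[MS_G] = s_e + n * s_G; constructed data with
  # MS_G = 11, MS_e = 1, n = 5 must return s_G = 2.
  g <- factor(rep(paste0("G", 1:4), each = 5))
  base <- c(2, -1, 0, -1, 0) * sqrt(4 / 6)   # per-group SS = 4 -> MSE = 1
  eff <- c(-1.5, -0.5, 0.5, 1.5)
  eff <- eff * sqrt(11 * 3 / (5 * sum(eff^2)))  # forces MS_G = 11
  y <- rep(eff, each = 5) + rep(base, 4)
  a <- anova(lm(y ~ g))
  ms_g <- a$`Sum Sq`[1] / a$Df[1]
  mse <- a$`Sum Sq`[2] / a$Df[2]
  expect_equal(c(ms_g, mse), c(11, 1), tolerance = 1e-10)
  vc <- variance_components(y, data.frame(genotype = g), "expression")
  expect_equal(unname(vc$components["sigma_G"]), 2, tolerance = 1e-10)
  expect_equal(unname(vc$components["sigma_G"]), (ms_g - mse) / 5,
               tolerance = 1e-10)

  # all-constant input: all components 0
  dsn <- small_design()
  vc0 <- variance_components(rep(4, nrow(dsn)), dsn, "expression")
  expect_true(all(vc0$components == 0))
  expect_equal(vc0$sigma_eps, 0)
})

test_that("EMS components match REML on balanced designs with interior estimates", {
  skip_if_not_installed("lme4")
  set.seed(31)
  dsn <- generate_design(8, 3, 6, 0.5, seed = 1)
  y <- rnorm(8, sd = 2)[as.integer(dsn$genotype)] +
    rnorm(16, sd = 1.5)[as.integer(interaction(dsn$genotype, dsn$sex))] +
    rnorm(24, sd = 1.2)[as.integer(interaction(dsn$genotype, dsn$replicate))] +
    rnorm(48, sd = 1)[as.integer(interaction(dsn$genotype, dsn$sex,
                                             dsn$replicate))] +
    rnorm(nrow(dsn), sd = 1)
  vc <- variance_components(y, dsn, "expression")
  fit <- lme4::lmer(y ~ sex * replicate + (1 | genotype) +
                      (1 | genotype:sex) + (1 | genotype:replicate) +
                      (1 | genotype:sex:replicate), data = dsn,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  vcr <- as.data.frame(lme4::VarCorr(fit))
  get <- function(nm) vcr$vcov[vcr$grp == nm]
  # REML equals the EMS ANOVA estimator on balanced data when interior
  expect_equal(unname(vc$components["sigma_G"]), get("genotype"),
               tolerance = 1e-4)
  expect_equal(unname(vc$components["sigma_GS"]), get("genotype:sex"),
               tolerance = 1e-4)
  expect_equal(vc$sigma_eps, vcr$vcov[vcr$grp == "Residual"],
               tolerance = 1e-3)
})

test_that("null genetic variance yields near-zero truncated components", {
  set.seed(33)
  dsn <- small_design()
  sg <- replicate(200, {
    vc <- variance_components(rnorm(nrow(dsn)), dsn, "expression")
    unname(vc$components["sigma_G"])
  })
  expect_gte(mean(sg == 0), 0.4)
  expect_lt(median(sg), 0.02)
})

test_that("heritability implements both formulas and stays within [0, 1]", {
  vc <- structure(list(scheme = "expression",
                       components = c(sigma_G = 1, sigma_GR = 0,
                                      sigma_GS = 0, sigma_GRS = 0),
                       sigma_eps = 1), class = "variance_components")
  expect_equal(heritability(vc)$h2, 0.5)
  vc$components[] <- 0
  expect_equal(heritability(vc)$h2, 0)
  vc$sigma_eps <- 0
  expect_equal(heritability(vc)$h2, 0)  # 0/0 -> 0

  # monotone in sigma_G
  h <- vapply(c(0.5, 1, 2, 4), function(sg) {
    vc$components["sigma_G"] <- sg
    vc$sigma_eps <- 1
    heritability(vc)$h2
  }, 0)
  expect_true(all(diff(h) > 0))
})

test_that("planted heritability is recovered on the paper-scale design", {
  set.seed(35)
  dsn <- generate_design(16, 3, 8, 0.5, seed = 1)
  h2_true <- 0.3
  n_genes <- 60
  est <- replicate(n_genes, {
    y <- rnorm(16, sd = sqrt(h2_true))[as.integer(dsn$genotype)] +
      rnorm(nrow(dsn), sd = sqrt(1 - h2_true))
    vc <- variance_components(y, dsn, "expression")
    heritability(vc)$h2
  })
  expect_true(all(est >= 0 & est <= 1))
  expect_lt(abs(mean(est) - h2_true), 0.05)
})

test_that("CV_E scale invariance propagates to the ANOVA and cve-scheme heritability", {
  sdat <- small_dataset(n_genes = 3, seed = 14)
  nm <- normalize_counts(sdat$counts)
  nm2 <- nm
  nm2[2, ] <- nm2[2, ] * 13   # rescale one gene
  t1 <- cve_table(nm, sdat$design)
  t2 <- cve_table(nm2, sdat$design)
  expect_equal(t1$cve, t2$cve, tolerance = 1e-10)
  a1 <- cve_anova(t1); a2 <- cve_anova(t2)
  expect_equal(a1$F, a2$F, tolerance = 1e-8)
  h1 <- cve_heritability_table(t1); h2 <- cve_heritability_table(t2)
  expect_equal(h1$h2, h2$h2, tolerance = 1e-8)
})
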