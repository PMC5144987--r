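# Shared fixtures: a small balanced design with simulated counts, sized for
# fast unit tests (4 genotypes x 2 replicates x 2 sexes x 4 flies).

small_design <- function(seed = 1) {
  generate_design(n_genotypes = 4, n_replicates = 2, n_flies_per_cell = 4,
                  infected_fraction = 0.5, seed = seed)
}

small_dataset <- function(n_genes = 30, prop_active = c(G = 0),
                          effect_sd = log(1.5),
                          dispersion_range = c(0.2, 0.5), seed = 1, ...) {
  design <- small_design(seed)
  truth <- generate_truth(n_genes, n_genotypes = 4, n_replicates = 2,
                          prop_active = prop_active, effect_sd = effect_sd,
                          dispersion_range = dispersion_range,
                          seed = seed + 1, ...)
  counts <- simulate_counts(design, truth, seed = seed + 2)
  list(design = design, truth = truth, counts = counts)
}

# Brute-force Benjamini-Hochberg step-up, directly from the definition:
# sort ascending, q(i) = min over j >= i of min(1, p(j) * m / j), restore
# input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  run <- 1
  for (i in m:1) {
    run <- min(run, ps[i] * m / i)
    adj[i] <- min(1, run)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Hypergeometric upper-tail P(X >= k) by direct enumeration with choose().
hyper_upper_bruteforce <- function(k, K, N, n) {
  tot <- choose(N, n)
  sum(vapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j), 0)) / tot
}

# Two-sided Fisher p by enumerating the hypergeometric support with choose().
fisher_two_sided_bruteforce <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Adjusted Rand index between two partitions (Hubert & Arabie).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  expected <- si * sj / sn
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
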