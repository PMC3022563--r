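# Shared fixtures and comparison helpers. All fixtures are generated in
# code (no data files); sizes are kept small so individual tests run in
# milliseconds.

# Random dataset under the package's own generative model.
rand_dataset <- function(seed, m = 15, n = 40, alphabet = "binary",
                         trait = c("binary", "quantitative"),
                         maf = c(0.15, 0.5), ld_rho = 0.3, planted = NULL) {
  trait <- match.arg(trait)
  cfg <- sim_config(m = m, n = n, alphabet = alphabet, maf_range = maf,
                    ld_rho = ld_rho, planted = planted, seed = seed)
  G <- generate_genotypes(cfg)
  y <- if (trait == "binary") plant_binary_trait(G, cfg)
       else plant_quantitative_trait(G, cfg)
  list(G = G, y = y, cfg = cfg)
}

# Canonical (anchor, partner) ordering for positional comparison: the
# ranked output order is only defined up to floating-point ties.
canon <- function(r) {
  d <- as.data.frame(r)
  d <- d[order(d$snp_a, d$snp_b), , drop = FALSE]
  rownames(d) <- NULL
  d
}

pair_key <- function(d) paste(d$snp_a, d$snp_b)

# A pruning threshold near the given quantile of the statistics but
# strictly between two attained values, so set comparisons at the
# threshold are not at the mercy of last-ulp differences.
choose_theta <- function(stats, frac = 0.6) {
  v <- sort(unique(stats[is.finite(stats)]))
  if (length(v) < 2L) return(if (length(v)) v[1] else 0)
  # merge ulp-level near-ties (same mathematical value, different summation
  # order) so the midpoint is well separated from every attained value
  keep <- c(TRUE, diff(v) > 1e-8 * pmax(1, abs(v[-1])))
  v <- v[keep]
  if (length(v) < 2L) return(v[1])
  i <- min(max(1L, ceiling(frac * length(v))), length(v) - 1L)
  (v[i] + v[i + 1L]) / 2
}

# Random 2 x k contingency table with positive margins.
rand_table <- function(k = sample(2:9, 1), lambda = 5) {
  repeat {
    cnt <- matrix(rpois(2L * k, lambda), nrow = 2L)
    keep <- colSums(cnt) > 0
    cnt <- cnt[, keep, drop = FALSE]
    if (ncol(cnt) >= 2L && all(rowSums(cnt) > 0)) {
      return(episcan:::new_contingency_table(cnt))
    }
  }
}

# Random consistent (counts, margins) pair drawn from an actual dataset,
# plus the true free-cell count.
rand_counts_margins <- function(n = sample(10:60, 1)) {
  repeat {
    Xi <- rbinom(n, 1, runif(1, 0.2, 0.8))
    Xj <- rbinom(n, 1, runif(1, 0.2, 0.8))
    yv <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(yv)) == 2L) break
  }
  list(counts = list(n_00 = sum(Xi == 0 & Xj == 0), n_01 = sum(Xi == 0 & Xj == 1),
                     n_10 = sum(Xi == 1 & Xj == 0), n_11 = sum(Xi == 1 & Xj == 1)),
       margins = list(c_i0 = sum(yv == 1 & Xi == 0), c_i1 = sum(yv == 1 & Xi == 1),
                      c_j0 = sum(yv == 1 & Xj == 0), c_j1 = sum(yv == 1 & Xj == 1)),
       t_true = sum(yv == 1 & Xi == 0 & Xj == 0),
       Xi = Xi, Xj = Xj, y = yv)
}

table_stat_fun_acc <- function(test) {
  switch(test, chi2 = chi_square, gtest = g_statistic, mi = mutual_information)
}

expect_same_scan <- function(a, b, tol = 1e-9) {
  ca <- canon(a); cb <- canon(b)
  expect_identical(pair_key(ca), pair_key(cb))
  expect_equal(ca$statistic, cb$statistic, tolerance = tol)
  expect_identical(ca$k, cb$k)
}
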