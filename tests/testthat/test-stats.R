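test_that("anova_f matches hand-computed and reference values", {
  # perfect separation: zero within-group variance
  a <- anova_f(c(1, 1, 3, 3), c("g1", "g1", "g2", "g2"))
  expect_equal(a$SS_between, 4)
  expect_equal(a$SS_within, 0)
  expect_identical(a$F, Inf)
  # hand-computed: groups {0,2} vs {1,3}
  b <- anova_f(c(0, 2, 1, 3), c(0, 0, 1, 1))
  expect_equal(b$SS_between, 1)
  expect_equal(b$SS_within, 4)
  expect_equal(b$F, 0.5)
  # equal group means
  c0 <- anova_f(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(c0$SS_between, 0)
  expect_identical(c0$F, 0)
  # reference oracle: stats::aov on a random instance
  set.seed(1)
  v <- rnorm(30)
  g <- sample(letters[1:3], 30, replace = TRUE)
  ref <- summary(stats::aov(v ~ factor(g)))[[1]]
  mine <- anova_f(v, g)
  expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(mine$SS_between, ref[["Sum Sq"]][1], tolerance = 1e-9)
  # errors
  expect_error(anova_f(1:4, rep("g", 4)), "monomorphic")
  expect_error(anova_f(1:3, c("a", "b", "c")), "residual degrees")
})

test_that("sum-of-squares decomposition holds on random instances", {
  set.seed(42)
  for (r in 1:300) {
    n <- sample(5:40, 1)
    v <- rnorm(n)
    g <- sample(seq_len(sample(2:4, 1)), n, replace = TRUE)
    if (length(unique(g)) < 2 || n <= length(unique(g))) next
    a <- anova_f(v, g)
    expect_lt(abs(a$SS_between + a$SS_within - a$SS_total),
              1e-9 * max(1, a$SS_total))
  }
})

test_that("joint group labels encode pairs and drop empty cells", {
  j <- joint_group_labels(c(0, 0, 1, 1), c(0, 1, 0, 1), card = 2)
  expect_identical(j$labels, c(0L, 1L, 2L, 3L))
  expect_identical(j$k, 4L)
  expect_identical(joint_group_labels(c(0, 0, 1, 1), c(0, 0, 1, 1), card = 2)$k, 2L)
  expect_identical(joint_group_labels(c(0, 0, 0, 0), c(0, 1, 0, 1), card = 2)$k, 2L)
})

test_that("contingency_table counts directly and is permutation-symmetric", {
  Xi <- c(0, 0, 1, 1); Xj <- c(0, 1, 0, 1); y <- c(1, 1, 0, 0)
  tb <- contingency_table(Xi, Xj, y, card = 2)
  expect_identical(unname(tb$col_margins), rep(1L, 4))
  expect_identical(tb$N, 4L)
  expect_identical(unname(tb$counts["case", ]), c(1L, 1L, 0L, 0L))
  perm <- c(3, 1, 4, 2)
  tb2 <- contingency_table(Xi[perm], Xj[perm], y[perm], card = 2)
  expect_identical(tb$counts, tb2$counts)
})

test_that("chi-square, G and MI match hand values and reference routines", {
  t22 <- episcan:::new_contingency_table(matrix(c(3, 1, 1, 3), 2))
  expect_equal(chi_square(t22), 2.0)
  expect_equal(g_statistic(t22), 12 * log(1.5) - 4 * log(2), tolerance = 1e-12)
  expect_equal(mutual_information(t22), (12 * log(1.5) - 4 * log(2)) / 16,
               tolerance = 1e-12)
  t10 <- episcan:::new_contingency_table(matrix(c(30, 10, 10, 30), 2))
  expect_equal(chi_square(t10), 20.0)
  ind <- episcan:::new_contingency_table(matrix(c(10, 10, 10, 10), 2))
  expect_equal(chi_square(ind), 0)
  expect_equal(g_statistic(ind), 0)
  expect_equal(mutual_information(ind), 0)
  # zero cell stays finite under 0*log(0) = 0
  z <- episcan:::new_contingency_table(matrix(c(2, 0, 0, 2), 2))
  expect_true(is.finite(g_statistic(z)))
  # reference: stats::chisq.test without continuity correction
  set.seed(7)
  for (r in 1:50) {
    tb <- rand_table()
    ref <- suppressWarnings(stats::chisq.test(tb$counts, correct = FALSE))
    expect_equal(chi_square(tb), unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("statistics are invariant to column reordering", {
  set.seed(11)
  for (r in 1:50) {
    tb <- rand_table()
    perm <- sample(ncol(tb$counts))
    tb2 <- episcan:::new_contingency_table(tb$counts[, perm])
    expect_equal(chi_square(tb), chi_square(tb2), tolerance = 1e-12)
    expect_equal(g_statistic(tb), g_statistic(tb2), tolerance = 1e-12)
    expect_equal(mutual_information(tb), mutual_information(tb2), tolerance = 1e-12)
  }
})

test_that("MI is bounded by min(log 2, log k)", {
  set.seed(13)
  for (r in 1:100) {
    tb <- rand_table()
    expect_lte(mutual_information(tb),
               min(log(2), log(ncol(tb$counts))) + 1e-12)
  }
})

test_that("brute_force_scan covers all pairs and handles degenerate SNPs", {
  d <- rand_dataset(3, m = 5, n = 20)
  b <- brute_force_scan(d$G, d$y, "chi2")
  expect_identical(nrow(b), 10L)
  # identical duplicated SNPs: pair statistic equals the single-locus value
  X <- rbind(d$G$codes, dup = d$G$codes[1, ])
  Gd <- genotype_matrix(X, snp_ids = c(rownames(d$G$codes), "dup"),
                        individual_ids = colnames(d$G$codes))
  bd <- canon(brute_force_scan(Gd, d$y, "chi2"))
  row <- bd[bd$snp_a == rownames(d$G$codes)[1] & bd$snp_b == "dup", ]
  single <- contingency_table(X[1, ], X[1, ], d$y$values, card = 2)
  expect_equal(row$statistic, chi_square(single), tolerance = 1e-9)
  # anova with a duplicated SNP: no extra split
  dq <- rand_dataset(4, m = 5, n = 20, trait = "quantitative")
  Xq <- rbind(dq$G$codes, dup = dq$G$codes[2, ])
  Gq <- genotype_matrix(Xq, snp_ids = c(rownames(dq$G$codes), "dup"),
                        individual_ids = colnames(dq$G$codes))
  bq <- canon(brute_force_scan(Gq, dq$y, "anova"))
  row2 <- bq[bq$snp_a == rownames(dq$G$codes)[2] & bq$snp_b == "dup", ]
  jl <- joint_group_labels(Xq[2, ], Xq[2, ], card = 2)
  expect_equal(row2$statistic, anova_f(dq$y$values, jl$labels)$F, tolerance = 1e-9)
  # engine/trait mismatch
  expect_error(brute_force_scan(d$G, d$y, "anova"), "quantitative")
})

test_that("brute_force_scan is invariant to SNP reordering up to relabeling", {
  d <- rand_dataset(5, m = 10, n = 30)
  b1 <- canon(brute_force_scan(d$G, d$y, "gtest"))
  set.seed(1); perm <- sample(10)
  G2 <- genotype_matrix(d$G$codes[perm, ], snp_ids = rownames(d$G$codes)[perm],
                        individual_ids = colnames(d$G$codes))
  b2 <- canon(brute_force_scan(G2, d$y, "gtest"))
  key1 <- apply(cbind(b1$snp_a, b1$snp_b), 1, function(z) paste(sort(z), collapse = "|"))
  key2 <- apply(cbind(b2$snp_a, b2$snp_b), 1, function(z) paste(sort(z), collapse = "|"))
  expect_equal(b1$statistic[order(key1)], b2$statistic[order(key2)], tolerance = 1e-9)
})
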