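test_that("anchor index groups partners by genotype-overlap counts", {
  X <- rbind(s1 = c(0L, 0L, 1L, 1L),
             s2 = c(0L, 1L, 0L, 1L),
             s3 = c(0L, 1L, 1L, 0L),
             s4 = c(0L, 0L, 1L, 1L))
  G <- genotype_matrix(X)
  idx <- build_anchor_index(G, 1)
  expect_identical(idx$n_A, 2L)
  expect_identical(idx$n_B, 2L)
  # s2 and s3 both have one 1 on each side of the anchor split -> same entry
  expect_setequal(idx$entries[["1,1"]], c(2L, 3L))
  # s4 identical to the anchor -> entry (0, n_B)
  expect_identical(idx$entries[["0,2"]], 4L)
  # every partner in exactly one entry; entry count bounded
  expect_identical(sort(unname(unlist(idx$entries))), 2:4)
  expect_lte(length(idx$entries), (idx$n_A + 1L) * (idx$n_B + 1L))
})

test_that("group prefix sums give extremal subset sums", {
  pre <- group_prefix_sums(c(0, 1, 2, 3), rep(TRUE, 4))
  expect_identical(pre$A$low, c(0, 0, 1, 3, 6))
  expect_identical(pre$A$high, c(0, 3, 5, 6, 6))
  # complementarity: low[r] + high[size - r] = total
  for (r in 0:4) expect_equal(pre$A$low[r + 1] + pre$A$high[4 - r + 1], 6)
  # constant values: low = high = r * c
  prec <- group_prefix_sums(rep(2.5, 5), rep(TRUE, 5))
  expect_equal(prec$A$low, 2.5 * 0:5)
  expect_equal(prec$A$high, 2.5 * 0:5)
  # empty group: length-1 prefix arrays
  pre0 <- group_prefix_sums(c(1, 2), c(TRUE, TRUE))
  expect_identical(pre0$B$low, 0)
})

test_that("delta_bound dominates the exact subset gain (brute-force subsets)", {
  # worked example: values {0,1,2,3}, subgroup size 2
  pre <- group_prefix_sums(c(0, 1, 2, 3), rep(TRUE, 4))
  db <- delta_bound(4, 2L, 6, pre$A$low, pre$A$high)
  expect_equal(db, 4) # max over T_1 in {1, 5} of (4 T_1 - 12)^2 / 16
  # equals the true max gain over all C(4,2) subsets
  gains <- combn(c(0, 1, 2, 3), 2, function(s) {
    T1 <- sum(s); (4 * T1 - 2 * 6)^2 / (4 * 2 * 2)
  })
  expect_equal(db, max(gains))
  expect_identical(delta_bound(4, 0L, 6, pre$A$low, pre$A$high), 0)
  expect_identical(delta_bound(4, 4L, 6, pre$A$low, pre$A$high), 0)
  expect_error(delta_bound(4, 5L, 6, pre$A$low, pre$A$high), "out of range")
  # constant group: bound vanishes for every split size
  prec <- group_prefix_sums(rep(1.5, 6), rep(TRUE, 6))
  for (r in 0:6) {
    expect_equal(delta_bound(6, r, 9, prec$A$low, prec$A$high), 0, tolerance = 1e-12)
  }
  # random groups: dominance over every exact subset sum
  set.seed(21)
  for (rep in 1:30) {
    ng <- sample(3:8, 1)
    v <- rnorm(ng)
    pre <- group_prefix_sums(v, rep(TRUE, ng))
    for (n1 in 1:(ng - 1)) {
      db <- delta_bound(ng, n1, sum(v), pre$A$low, pre$A$high)
      gains <- combn(v, n1, function(s) {
        (ng * sum(s) - n1 * sum(v))^2 / (ng * n1 * (ng - n1))
      })
      expect_gte(db + 1e-9, max(gains))
    }
  }
})

test_that("entry bounds dominate exact pair F over random data and permutations", {
  set.seed(31)
  checked <- 0L
  for (s in 1:6) {
    d <- rand_dataset(100 + s, m = 12, n = 30, trait = "quantitative")
    n <- 30
    vals <- d$y$values
    for (p in 1:4) {
      pv <- if (p == 1) vals else sample(vals)
      Tot <- sum(pv)
      ss_tot <- sum(pv^2) - Tot^2 / n
      for (i in 1:11) {
        idx <- build_anchor_index(d$G, i, partners = (i + 1L):12L)
        A <- d$G$codes[i, ] == 0L
        pre <- group_prefix_sums(pv, A)
        ssb1 <- if (idx$n_A > 0 && idx$n_B > 0) {
          min(max(pre$A$total^2 / idx$n_A + pre$B$total^2 / idx$n_B - Tot^2 / n, 0), ss_tot)
        } else 0
        eb <- entry_upper_bound(idx$n_A1, idx$n_B1, pre, ssb1, ss_tot, n)
        for (q in seq_along(idx$partners)) {
          j <- idx$partners[q]
          jl <- joint_group_labels(d$G$codes[i, ], d$G$codes[j, ], card = 2)
          Fx <- if (jl$k < 2 || n <= jl$k) 0 else anova_f(pv, jl$labels)$F
          expect_identical(jl$k, eb$k[q])
          if (is.infinite(Fx)) expect_identical(eb$bound[q], Inf)
          else expect_gte(eb$bound[q] + 1e-9 * max(1, Fx), Fx)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gte(checked, 1000L)
})

test_that("entry (0,0) bound collapses to the anchor's single-locus F", {
  d <- rand_dataset(7, m = 8, n = 25, trait = "quantitative")
  vals <- d$y$values
  n <- 25
  i <- 2L
  A <- d$G$codes[i, ] == 0L
  pre <- group_prefix_sums(vals, A)
  nA <- sum(A); nB <- n - nA
  Tot <- sum(vals)
  ss_tot <- sum(vals^2) - Tot^2 / n
  ssb1 <- pre$A$total^2 / nA + pre$B$total^2 / nB - Tot^2 / n
  eb <- entry_upper_bound(0L, 0L, pre, ssb1, ss_tot, n)
  single <- anova_f(vals, as.integer(A))
  expect_identical(eb$k, 2L)
  expect_equal(eb$bound, single$F, tolerance = 1e-9)
})

test_that("fastanova_scan equals the brute-force oracle at any threshold", {
  for (s in 1:8) {
    d <- rand_dataset(200 + s, m = 14, n = 35, trait = "quantitative",
                      ld_rho = if (s %% 2) 0 else 0.5)
    b <- canon(brute_force_scan(d$G, d$y, "anova"))
    # theta = 0: full equivalence
    expect_same_scan(brute_force_scan(d$G, d$y, "anova"),
                     fastanova_scan(d$G, d$y, theta = 0))
    # pruning threshold: exact filtered set
    th <- choose_theta(b$statistic)
    fa <- canon(fastanova_scan(d$G, d$y, theta = th))
    bf <- b[b$statistic >= th, , drop = FALSE]
    expect_identical(pair_key(fa), pair_key(bf))
    expect_equal(fa$statistic, bf$statistic, tolerance = 1e-9)
  }
})

test_that("fastanova at theta = Inf returns exactly the perfectly separating pairs", {
  # the trait is constant except on the joint cell (s1,s2) = (1,1); only
  # that pair carves every joint group pure
  X <- rbind(s1 = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
             s2 = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
             s3 = c(0L, 1L, 1L, 1L, 0L, 1L, 1L, 0L))
  G <- genotype_matrix(X)
  y <- phenotype_vector(c(1, 1, 1, 5, 1, 1, 1, 5), individual_ids = colnames(X),
                        kind = "quantitative")
  fa <- fastanova_scan(G, y, theta = Inf)
  expect_identical(nrow(fa), 1L)
  expect_identical(fa$statistic, Inf)
  expect_setequal(c(fa$snp_a, fa$snp_b), c("s1", "s2"))
  # and the oracle agrees
  b <- brute_force_scan(G, y, "anova")
  expect_identical(sum(is.infinite(b$statistic)), 1L)
})

test_that("anchor index is unchanged by phenotype permutation and pruning grows with theta", {
  d <- rand_dataset(17, m = 12, n = 30, trait = "quantitative")
  idx1 <- build_anchor_index(d$G, 3)
  yp <- permute_phenotype(d$y, sample(30))
  idx2 <- build_anchor_index(d$G, 3)
  expect_identical(idx1, idx2)
  b <- brute_force_scan(d$G, d$y, "anova")
  cand <- vapply(c(0, 1, 2, 4), function(th) {
    attr(fastanova_scan(d$G, d$y, theta = th), "n_candidates")
  }, numeric(1))
  expect_true(all(diff(cand) <= 0))
})
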