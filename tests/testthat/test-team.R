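test_that("hamming_distance counts differing individuals", {
  expect_identical(hamming_distance(c(0, 1, 2), c(0, 1, 2)), 0L)
  expect_identical(hamming_distance(c(0, 1, 0, 1), c(1, 0, 1, 0)), 4L)
  expect_identical(hamming_distance(c(0, 1, 2), c(0, 2, 2)), 1L)
  expect_error(hamming_distance(c(0, 1), c(0, 1, 1)), "length")
})

test_that("build_mst attains the optimal weight (independent igraph oracle)", {
  skip_if_not_installed("igraph")
  set.seed(61)
  for (s in 1:12) {
    m <- sample(3:25, 1)
    d <- rand_dataset(400 + s, m = m, n = sample(10:50, 1),
                      alphabet = sample(c("binary", "triallelic"), 1),
                      ld_rho = 0.5)
    tree <- build_mst(d$G)
    D <- matrix(0, m, m)
    for (i in 1:m) for (j in 1:m) D[i, j] <- sum(d$G$codes[i, ] != d$G$codes[j, ])
    # +1 offset: igraph drops zero-weight entries of an adjacency matrix
    g <- igraph::graph_from_adjacency_matrix(D + 1, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    oracle <- sum(igraph::E(igraph::mst(g))$weight) - (m - 1)
    expect_identical(tree$total_weight, as.integer(oracle))
    # edge weights match their difference lists
    for (v in 2:m) {
      e <- tree$edges[[v]]
      expect_identical(e$weight, hamming_distance(d$G$codes[e$u, ], d$G$codes[e$v, ]))
    }
  }
})

test_that("build_mst is deterministic and joins duplicate SNPs at weight 0", {
  d <- rand_dataset(63, m = 8, n = 25)
  X <- rbind(d$G$codes, dup1 = d$G$codes[3, ], dup2 = d$G$codes[3, ])
  G <- genotype_matrix(X, snp_ids = c(rownames(d$G$codes), "dup1", "dup2"),
                       individual_ids = colnames(d$G$codes))
  t1 <- build_mst(G)
  t2 <- build_mst(G)
  expect_identical(t1$parent, t2$parent)
  expect_identical(lapply(t1$edges[-1], `[[`, "ind"),
                   lapply(t2$edges[-1], `[[`, "ind"))
  w <- vapply(t1$edges[-1], `[[`, integer(1), "weight")
  expect_gte(sum(w == 0L), 2L)
  # two-SNP matrix: the single edge (1,2)
  G2 <- genotype_matrix(d$G$codes[1:2, ])
  t3 <- build_mst(G2)
  expect_identical(t3$parent, c(NA_integer_, 1L))
})

test_that("apply_diff touches only differing individuals and is an involution", {
  d <- rand_dataset(65, m = 6, n = 30, alphabet = "triallelic")
  tree <- build_mst(d$G)
  y01 <- as.integer(d$y$values)
  card <- 3L
  i <- 1L
  count_table <- function(partner) {
    tab <- array(0L, dim = c(card, card, 2L))
    tab[] <- tabulate(d$G$codes[i, ] + card * d$G$codes[partner, ] +
                        card^2 * y01 + 1L, nbins = 2L * card^2)
    tab
  }
  for (v in which(!is.na(tree$parent))) {
    e <- tree$edges[[v]]
    tab_u <- count_table(e$u)            # state before traversing edge (u, v)
    fwd <- apply_diff(tab_u, e, d$G$codes[i, ], y01, "forward")
    expect_identical(fwd, count_table(e$v))   # forward lands on the (i, v) table
    back <- apply_diff(fwd, e, d$G$codes[i, ], y01, "backward")
    expect_identical(back, tab_u)             # involution
    if (e$weight == 1L) {
      expect_identical(sum(abs(fwd - tab_u) > 0), 2L) # exactly two cells change
    }
    if (e$weight == 0L) expect_identical(fwd, tab_u)
    expect_identical(sum(fwd), sum(tab_u)) # mass preserved
  }
  # corrupted state is caught
  empty <- array(0L, dim = c(card, card, 2L))
  e1 <- tree$edges[[which(!is.na(tree$parent))[1]]]
  if (e1$weight > 0) {
    expect_error(apply_diff(empty, e1, d$G$codes[i, ], y01, "forward"),
                 "below zero")
  }
})

test_that("team_scan (both implementations) equals the brute-force oracle", {
  for (s in 1:6) {
    d <- rand_dataset(500 + s, m = 12, n = 60,
                      alphabet = if (s %% 2) "binary" else "triallelic",
                      ld_rho = 0.4)
    for (test in c("chi2", "gtest", "mi")) {
      b <- brute_force_scan(d$G, d$y, test)
      expect_same_scan(b, team_scan(d$G, d$y, test))
      expect_same_scan(b, team_scan(d$G, d$y, test, .impl = "r"))
    }
  }
})

test_that("maintained table equals direct counting at every traversal checkpoint", {
  d <- rand_dataset(71, m = 12, n = 40, alphabet = "triallelic", ld_rho = 0.5)
  card <- 3L
  y01 <- as.integer(d$y$values)
  seen <- 0L
  audit <- function(anchor, node, tab) {
    direct <- array(0L, dim = c(card, card, 2L))
    idx3 <- d$G$codes[anchor, ] + card * d$G$codes[node, ] + card^2 * y01 + 1L
    direct[] <- tabulate(idx3, nbins = 2L * card^2)
    expect_identical(tab, direct)
    seen <<- seen + 1L
  }
  team_scan(d$G, d$y, "chi2", .impl = "r", on_visit = audit)
  expect_gte(seen, 100L) # (m-1) anchors x (m-1) forward steps
})

test_that("traversal work equals n + 2 * tree weight per anchor", {
  d <- rand_dataset(73, m = 9, n = 50, ld_rho = 0.6)
  tree <- build_mst(d$G)
  r <- team_scan(d$G, d$y, "chi2", .impl = "r")
  m <- 9L
  expect_identical(attr(r, "touched"),
                   (m - 1L) * (50L + 2L * tree$total_weight))
})

test_that("all SNPs identical collapses every pair to the single-locus statistic", {
  base <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L)
  X <- rbind(s1 = base, s2 = base, s3 = base, s4 = base)
  G <- genotype_matrix(X)
  y <- phenotype_vector(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1), colnames(X))
  r <- team_scan(G, y, "chi2")
  single <- chi_square(contingency_table(base, base, y$values, card = 2))
  expect_identical(nrow(r), 6L)
  expect_equal(r$statistic, rep(single, 6), tolerance = 1e-12)
})

test_that("the spanning tree is identical before and after phenotype permutation", {
  d <- rand_dataset(75, m = 12, n = 30)
  t1 <- build_mst(d$G)
  invisible(permute_phenotype(d$y, sample(30)))
  t2 <- build_mst(d$G)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
})

test_that("team rejects a quantitative trait", {
  d <- rand_dataset(77, m = 6, n = 20, trait = "quantitative")
  expect_error(team_scan(d$G, d$y, "chi2"), "binary trait")
})
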