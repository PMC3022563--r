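#' One-way ANOVA decomposition over genotype groups
#'
#' Decomposes the total sum of squares of a quantitative trait over the
#' groups defined by `labels` and forms the F statistic
#' `F = (SS_between/(k-1)) / (SS_within/(n-k))` with `k` the number of
#' non-empty groups. Two degenerate conventions keep the maximum statistic
#' well defined under permutation: if `SS_within = 0` and `SS_between > 0`
#' (perfect separation) then `F = +Inf`; if `SS_between = 0` (all group
#' means equal) then `F = 0`.
#'
#' @param values numeric trait values.
#' @param labels group label per individual (any atomic type).
#' @return An object of class `anova_result`: list with `SS_between`,
#'   `SS_within`, `SS_total`, `k`, `F`.
#' @export
anova_f <- function(values, labels) {
  values <- as.numeric(values)
  if (length(values) != length(labels)) stop("length mismatch", call. = FALSE)
  n <- length(values)
  Tg <- rowsum(values, labels)           # group sums, sorted by label
  ng <- rowsum(rep(1, n), labels)
  k <- nrow(Tg)
  if (k < 2L) stop("monomorphic split: fewer than 2 genotype groups", call. = FALSE)
  if (n <= k) stop("no residual degrees of freedom (n <= k)", call. = FALSE)
  Tot <- sum(values)
  ss_total <- sum(values^2) - Tot^2 / n
  ss_between <- sum(Tg^2 / ng) - Tot^2 / n
  # guard tiny negative round-off
  ss_total <- max(ss_total, 0)
  ss_between <- min(max(ss_between, 0), ss_total)
  ss_within <- ss_total - ss_between
  tol <- 1e-12 * max(1, ss_total)
  F <- if (ss_between <= tol) {
    0
  } else if (ss_within <= tol) {
    Inf
  } else {
    (ss_between / (k - 1)) / (ss_within / (n - k))
  }
  structure(list(SS_between = ss_between, SS_within = ss_within,
                 SS_total = ss_total, k = k, F = F),
            class = "anova_result")
}

#' Joint genotype group labels of a SNP pair
#'
#' Encodes the pair genotype as `code_i * card + code_j` where `card` is
#' the alphabet size, so a binary pair has joint codes in `0..3` and a
#' triallelic pair in `0..8`. Only observed (non-empty) joint codes count
#' towards `k`.
#'
#' @param Xi,Xj integer genotype rows of equal length.
#' @param card alphabet cardinality (2 or 3).
#' @return List with `labels` (integer per individual) and `k` (number of
#'   distinct observed joint codes).
#' @export
joint_group_labels <- function(Xi, Xj, card = max(c(Xi, Xj)) + 1L) {
  if (length(Xi) != length(Xj)) stop("genotype rows differ in length", call. = FALSE)
  card <- max(2L, as.integer(card))
  labels <- as.integer(Xi) * card + as.integer(Xj)
  list(labels = labels, k = length(unique(labels)))
}

#' Two-locus contingency table for a binary trait
#'
#' Counts individuals by phenotype class (rows: case = 1, control = 0) and
#' joint genotype group (columns: non-empty joint codes, ascending).
#'
#' @param Xi,Xj integer genotype rows.
#' @param y a binary [phenotype_vector()] or a plain 0/1 vector aligned
#'   with the genotype columns.
#' @param card alphabet cardinality.
#' @return An object of class `contingency_table`: list with `counts`
#'   (2 x k integer matrix, row 1 = case), `codes` (joint codes per
#'   column), `N`, `row_margins`, `col_margins`.
#' @export
contingency_table <- function(Xi, Xj, y, card = max(c(Xi, Xj)) + 1L) {
  if (inherits(y, "phenotype_vector")) {
    if (y$kind != "binary") stop("contingency tables need a binary phenotype", call. = FALSE)
    y <- y$values
  }
  jl <- joint_group_labels(Xi, Xj, card)
  codes <- sort(unique(jl$labels))
  col <- match(jl$labels, codes)
  case <- tabulate(col[y == 1], nbins = length(codes))
  ctrl <- tabulate(col[y == 0], nbins = length(codes))
  counts <- rbind(case = case, control = ctrl)
  new_contingency_table(counts, codes)
}

new_contingency_table <- function(counts, codes = seq_len(ncol(counts)) - 1L) {
  counts <- matrix(as.integer(counts), nrow = 2L,
                   dimnames = list(c("case", "control"), NULL))
  structure(list(counts = counts, codes = as.integer(codes),
                 N = sum(counts),
                 row_margins = as.integer(rowSums(counts)),
                 col_margins = as.integer(colSums(counts))),
            class = "contingency_table")
}

check_row_margins <- function(t) {
  if (any(t$row_margins == 0)) {
    stop("single-class phenotype: a contingency-table row margin is zero",
         call. = FALSE)
  }
}

#' Pearson chi-square statistic of a 2 x k contingency table
#'
#' `sum((O - E)^2 / E)` with `E = row * col / N`. Empty genotype columns
#' must already have been dropped (as [contingency_table()] does), so every
#' expected count is positive.
#'
#' @param t a [contingency_table()].
#' @return Non-negative numeric.
#' @export
chi_square <- function(t) {
  check_row_margins(t)
  E <- outer(t$row_margins, t$col_margins) / t$N
  sum((t$counts - E)^2 / E)
}

#' G statistic (likelihood-ratio test) of a 2 x k contingency table
#'
#' `2 * sum(O * log(O / E))` in natural log, with the convention
#' `0 * log(0) = 0` so tables with empty cells stay finite.
#'
#' @param t a [contingency_table()].
#' @return Non-negative numeric.
#' @export
g_statistic <- function(t) {
  check_row_margins(t)
  E <- outer(t$row_margins, t$col_margins) / t$N
  O <- t$counts
  pos <- O > 0
  2 * sum(O[pos] * log(O[pos] / E[pos]))
}

#' Mutual information (in nats) of a 2 x k contingency table
#'
#' `sum(p * log(p / (p_row * p_col)))` with `p = O/N`; satisfies the
#' identity `G = 2 * N * MI`.
#'
#' @param t a [contingency_table()].
#' @return Non-negative numeric.
#' @export
mutual_information <- function(t) {
  check_row_margins(t)
  p <- t$counts / t$N
  pr <- t$row_margins / t$N
  pc <- t$col_margins / t$N
  pe <- outer(pr, pc)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / pe[pos]))
}

# statistic registry used by COE and TEAM -------------------------------------

table_stat_fun <- function(test) {
  switch(test,
         chi2 = chi_square,
         gtest = g_statistic,
         mi = mutual_information,
         stop("unknown contingency-table test: ", test, call. = FALSE))
}

test_code <- function(test) {
  match(test, c("chi2", "gtest", "mi")) - 1L
}

check_test_phenotype <- function(test, kind) {
  if (test == "anova" && kind != "quantitative") {
    stop("ANOVA test requires a quantitative phenotype", call. = FALSE)
  }
  if (test != "anova" && kind != "binary") {
    stop("test '", test, "' requires a binary phenotype", call. = FALSE)
  }
  invisible(TRUE)
}

#' Brute-force all-pairs two-locus scan (reference oracle)
#'
#' Computes the chosen statistic for every SNP pair `i < j` by direct
#' per-pair grouping, with no pruning and no incremental bookkeeping. Pairs
#' whose test is undefined (fewer than 2 joint groups, or no residual
#' degrees of freedom for ANOVA) are emitted with statistic 0 and their
#' `k` flagged, so all engines agree with the oracle on row counts.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype_vector()] (quantitative for `anova`, binary
#'   otherwise), aligned with `G`.
#' @param test `"anova"`, `"chi2"`, `"gtest"` or `"mi"`.
#' @return A [scan_result()] with all `m(m-1)/2` pairs.
#' @export
brute_force_scan <- function(G, y, test = c("anova", "chi2", "gtest", "mi")) {
  test <- match.arg(test)
  stopifnot(inherits(G, "genotype_matrix"), inherits(y, "phenotype_vector"))
  check_test_phenotype(test, y$kind)
  yv <- y$values
  m <- n_snps(G)
  n <- n_individuals(G)
  card <- alphabet_card(G)
  X <- G$codes
  ia <- ib <- integer(0)
  stat <- numeric(0)
  kk <- integer(0)
  for (i in seq_len(m - 1L)) {
    js <- (i + 1L):m
    # joint codes for all partners at once: card*Xi + Xj
    base <- matrix(card * X[i, ], nrow = length(js), ncol = n, byrow = TRUE)
    Jm <- base + X[js, , drop = FALSE]
    res <- pairwise_stats_from_joint(Jm, yv, card * card, test, n)
    ia <- c(ia, rep.int(i, length(js)))
    ib <- c(ib, js)
    stat <- c(stat, res$stat)
    kk <- c(kk, res$k)
  }
  scan_result(ia, ib, stat, kk, ids = snp_ids(G))
}

# Vectorized per-anchor statistics: Jm is (#partners x n) joint-code matrix,
# codes in 0..(ncell-1). Direct counting, independent of any scan engine.
pairwise_stats_from_joint <- function(Jm, yv, ncell, test, n) {
  np <- nrow(Jm)
  ng <- matrix(0, np, ncell)   # group sizes
  Tg <- matrix(0, np, ncell)   # group sums (anova) / case counts (tables)
  w <- if (test == "anova") yv else as.numeric(yv == 1)
  for (c in seq_len(ncell) - 1L) {
    Mc <- Jm == c
    ng[, c + 1L] <- rowSums(Mc)
    Tg[, c + 1L] <- Mc %*% w
  }
  k <- rowSums(ng > 0)
  if (test == "anova") {
    Tot <- sum(yv)
    ss_total <- sum(yv^2) - Tot^2 / n
    ratio <- Tg^2 / ng
    ratio[ng == 0] <- 0
    ss_b <- rowSums(ratio) - Tot^2 / n
    ss_b <- pmin(pmax(ss_b, 0), ss_total)
    ss_w <- ss_total - ss_b
    tol <- 1e-12 * max(1, ss_total)
    F <- (ss_b / pmax(k - 1, 1)) / (ss_w / pmax(n - k, 1))
    F[ss_b <= tol] <- 0
    F[ss_b > tol & ss_w <= tol] <- Inf
    undef <- k < 2 | n <= k
    F[undef] <- 0
    list(stat = F, k = k)
  } else {
    M1 <- sum(yv == 1)
    M0 <- n - M1
    O1 <- Tg
    O0 <- ng - O1
    E1 <- ng * (M1 / n)
    E0 <- ng * (M0 / n)
    occ <- ng > 0
    stat <- switch(test,
      chi2 = {
        d1 <- (O1 - E1)^2 / E1
        d0 <- (O0 - E0)^2 / E0
        d1[!occ] <- 0; d0[!occ] <- 0
        rowSums(d1) + rowSums(d0)
      },
      gtest = {
        t1 <- O1 * log(O1 / E1); t1[O1 == 0] <- 0
        t0 <- O0 * log(O0 / E0); t0[O0 == 0] <- 0
        2 * (rowSums(t1) + rowSums(t0))
      },
      mi = {
        p1 <- O1 / n; p0 <- O0 / n
        e1 <- (M1 / n) * (ng / n); e0 <- (M0 / n) * (ng / n)
        t1 <- p1 * log(p1 / e1); t1[O1 == 0] <- 0
        t0 <- p0 * log(p0 / e0); t0[O0 == 0] <- 0
        rowSums(t1) + rowSums(t0)
      })
    stat[k < 2] <- 0
    stat <- pmax(stat, 0)
    list(stat = stat, k = k)
  }
}
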