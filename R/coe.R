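#' Feasible interval of the free cell of a two-locus case/control table
#'
#' With binary genotypes and a binary trait, the 2 x 4 two-locus
#' contingency table is fully determined — given the joint genotype cell
#' sizes and the single-locus case margins — by a single free count
#' `t = #cases in joint cell (0,0)`. The set of tables consistent with the
#' margins is the integer interval `[L, U]`:
#' `L = max(0, c_i0 - n_01, c_j0 - n_10, c_j0 - c_i1)` and
#' `U = min(n_00, c_i0, c_j0, n_11 + c_j0 - c_i1)`. Any statistic convex in
#' `t` attains its maximum over this domain at `L` or `U`.
#'
#' @param counts list/vector with joint genotype cell sizes `n_00`, `n_01`,
#'   `n_10`, `n_11` (cells of `(Xi, Xj)`).
#' @param margins list/vector with single-locus case counts `c_i0`, `c_i1`
#'   (cases with `Xi = 0` / `Xi = 1`) and `c_j0`, `c_j1`.
#' @return List with integers `L` and `U`.
#' @export
feasible_interval <- function(counts, margins) {
  counts <- as.list(counts); margins <- as.list(margins)
  L <- max(0L,
           margins$c_i0 - counts$n_01,
           margins$c_j0 - counts$n_10,
           margins$c_j0 - margins$c_i1)
  U <- min(counts$n_00, margins$c_i0, margins$c_j0,
           counts$n_11 + margins$c_j0 - margins$c_i1)
  if (L > U) {
    stop("inconsistent margins: empty feasible interval (caller bug — ",
         "tables counted from data always admit their own t)", call. = FALSE)
  }
  list(L = as.integer(L), U = as.integer(U))
}

#' Materialize the two-locus table with a given free cell count
#'
#' Builds the full 2 x 4 case/control table whose case row is
#' `(t, c_i0 - t, c_j0 - t, c_i1 - c_j0 + t)` over the joint genotype cells
#' `(0,0), (0,1), (1,0), (1,1)`, control row = genotype cell sizes minus
#' the case row; empty genotype cells are dropped.
#'
#' @param t integer in the [feasible_interval()].
#' @param counts,margins as in [feasible_interval()].
#' @return A [contingency_table()].
#' @export
table_at <- function(t, counts, margins) {
  counts <- as.list(counts); margins <- as.list(margins)
  fi <- feasible_interval(counts, margins)
  if (t < fi$L || t > fi$U) {
    stop("t = ", t, " outside feasible interval [", fi$L, ", ", fi$U, "]",
         call. = FALSE)
  }
  ncell <- c(counts$n_00, counts$n_01, counts$n_10, counts$n_11)
  case <- c(t,
            margins$c_i0 - t,
            margins$c_j0 - t,
            margins$c_i1 - margins$c_j0 + t)
  ctrl <- ncell - case
  if (any(case < 0) || any(ctrl < 0)) {
    stop("negative cell in materialized table (inconsistent inputs)", call. = FALSE)
  }
  keep <- ncell > 0
  new_contingency_table(rbind(case[keep], ctrl[keep]),
                        codes = (0:3)[keep])
}

#' Convex upper bound on a two-locus statistic from table margins
#'
#' The chosen statistic, viewed as a function of the free cell count `t`,
#' is convex on the feasible interval, so its maximum over all tables
#' consistent with the margins is attained at an endpoint:
#' `max(stat(table_at(L)), stat(table_at(U)))`. The true table's `t` lies
#' in `[L, U]`, so this dominates the exact statistic of the pair.
#'
#' @param counts,margins as in [feasible_interval()].
#' @param test `"chi2"`, `"gtest"` or `"mi"`.
#' @return Numeric upper bound (0 for degenerate margins with no cases or
#'   no controls).
#' @export
convex_upper_bound <- function(counts, margins, test = c("chi2", "gtest", "mi")) {
  test <- match.arg(test)
  margins <- as.list(margins)
  counts <- as.list(counts)
  n <- counts$n_00 + counts$n_01 + counts$n_10 + counts$n_11
  M <- margins$c_i0 + margins$c_i1
  if (M == 0L || M == n) return(0)
  fi <- feasible_interval(counts, margins)
  f <- table_stat_fun(test)
  sL <- f(table_at(fi$L, counts, margins))
  if (fi$U == fi$L) return(sL)
  max(sL, f(table_at(fi$U, counts, margins)))
}

# Vectorized chi2/G/MI at a given case-row matrix; C (np x 4) case rows,
# Ncell (np x 4) genotype cell sizes, M1 total cases, n individuals.
coe_stat_rows <- function(C, Ncell, M1, n, test) {
  O1 <- C
  O0 <- Ncell - C
  occ <- Ncell > 0
  M0 <- n - M1
  E1 <- Ncell * (M1 / n)
  E0 <- Ncell * (M0 / n)
  switch(test,
    chi2 = {
      d1 <- (O1 - E1)^2 / E1; d0 <- (O0 - E0)^2 / E0
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
      e1 <- (M1 / n) * (Ncell / n); e0 <- (M0 / n) * (Ncell / n)
      t1 <- p1 * log(p1 / e1); t1[O1 == 0] <- 0
      t0 <- p0 * log(p0 / e0); t0[O0 == 0] <- 0
      rowSums(t1) + rowSums(t0)
    })
}

#' Exhaustive two-locus convex-statistic scan for binary trait and genotype
#'
#' Returns exactly the SNP pairs whose exact statistic is `>= theta`, with
#' exact values — identical to filtering [brute_force_scan()] at `theta`.
#' Per anchor SNP the genotype-only [build_anchor_index()] is reused (the
#' joint cell sizes are a bijection of the entry key given the anchor group
#' sizes); the per-SNP case margins are refreshed from the current
#' phenotype in O(m); and each pair's convex bound is evaluated at the two
#' endpoints of its feasible interval. Only candidates whose bound reaches
#' `theta` are tested exactly.
#'
#' @param G binary-alphabet [genotype_matrix()].
#' @param y binary [phenotype_vector()] aligned with `G`.
#' @param theta non-negative statistic threshold (0 returns all pairs).
#' @param test `"chi2"`, `"gtest"` or `"mi"`.
#' @param values optional raw 0/1 phenotype override (permutation driver).
#' @return A [scan_result()] restricted to pairs with statistic `>= theta`.
#' @export
coe_scan <- function(G, y, theta = 0, test = c("chi2", "gtest", "mi"),
                     values = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(G, "genotype_matrix"))
  if (G$alphabet != "binary") {
    stop("COE requires a binary genotype alphabet (use team for triallelic data)",
         call. = FALSE)
  }
  if (is.null(values)) {
    stopifnot(inherits(y, "phenotype_vector"))
    if (y$kind != "binary") {
      stop("COE requires a binary trait (use fastanova for quantitative traits)",
           call. = FALSE)
    }
    values <- y$values
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0) {
    stop("theta must be a single non-negative number", call. = FALSE)
  }
  m <- n_snps(G)
  n <- n_individuals(G)
  X <- G$codes
  case <- values == 1
  M1 <- sum(case)
  c1 <- as.integer(X %*% case)       # cases with X_j = 1, per SNP
  c0 <- M1 - c1
  ia <- ib <- integer(0)
  stat <- numeric(0)
  kk <- integer(0)
  n_candidates <- 0L
  for (i in seq_len(m - 1L)) {
    idx <- build_anchor_index(G, i, partners = (i + 1L):m)
    js <- idx$partners
    n_00 <- idx$n_A - idx$n_A1
    n_01 <- idx$n_A1
    n_10 <- idx$n_B - idx$n_B1
    n_11 <- idx$n_B1
    ci0 <- c0[i]; ci1 <- c1[i]
    cj0 <- c0[js]
    L <- pmax(0L, ci0 - n_01, cj0 - n_10, cj0 - ci1)
    U <- pmin(n_00, ci0, cj0, n_11 + cj0 - ci1)
    Ncell <- cbind(n_00, n_01, n_10, n_11)
    case_rows <- function(t) cbind(t, ci0 - t, cj0 - t, ci1 - cj0 + t)
    bound <- pmax(coe_stat_rows(case_rows(L), Ncell, M1, n, test),
                  coe_stat_rows(case_rows(U), Ncell, M1, n, test))
    k <- rowSums(Ncell > 0)
    bound[k < 2L] <- 0
    keep <- bound >= theta
    if (!any(keep)) next
    n_candidates <- n_candidates + sum(keep)
    for (j in js[keep]) {
      tab <- contingency_table(X[i, ], X[j, ], values, card = 2L)
      kj <- ncol(tab$counts)
      sj <- if (kj < 2L) 0 else table_stat_fun(test)(tab)
      if (sj >= theta) {
        ia <- c(ia, i); ib <- c(ib, j)
        stat <- c(stat, sj); kk <- c(kk, kj)
      }
    }
  }
  out <- scan_result(ia, ib, stat, kk, ids = snp_ids(G))
  attr(out, "n_candidates") <- n_candidates
  attr(out, "n_pairs") <- m * (m - 1L) / 2L
  out
}
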