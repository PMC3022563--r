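#' Build the per-anchor 2D index of partner SNPs
#'
#' For an anchor SNP `i` over a binary alphabet, every partner SNP `j` is
#' characterized by the pair of counts `(n_A1, n_B1)`: the number of
#' individuals with `Xi = 0 & Xj = 1` and with `Xi = 1 & Xj = 1`. Partners
#' sharing the same `(n_A1, n_B1)` occupy the same index entry, and every
#' quantity the scan's upper bound needs about a pair's genotype
#' configuration is a function of the entry alone. The index depends only
#' on genotypes, so it is built once per dataset and reused unchanged for
#' every phenotype permutation.
#'
#' @param G a binary-alphabet [genotype_matrix()].
#' @param i anchor SNP index (1-based).
#' @param partners integer vector of partner indices; default all `j != i`.
#' @return An object of class `anchor_index`: list with `anchor`, `n_A`,
#'   `n_B`, `partners`, `n_A1`, `n_B1` (parallel vectors) and `entries`
#'   (list mapping `"n_A1,n_B1"` keys to partner index vectors).
#' @export
build_anchor_index <- function(G, i, partners = setdiff(seq_len(n_snps(G)), i)) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (G$alphabet != "binary") {
    stop("anchor index requires a binary genotype alphabet", call. = FALSE)
  }
  X <- G$codes
  A <- X[i, ] == 0L
  n_A <- sum(A)
  n_B <- ncol(X) - n_A
  P <- X[partners, , drop = FALSE]
  n_A1 <- as.integer(rowSums(P[, A, drop = FALSE] == 1L))
  n_B1 <- as.integer(rowSums(P[, !A, drop = FALSE] == 1L))
  key <- paste(n_A1, n_B1, sep = ",")
  entries <- split(as.integer(partners), key)
  structure(list(anchor = as.integer(i), n_A = n_A, n_B = n_B,
                 partners = as.integer(partners),
                 n_A1 = n_A1, n_B1 = n_B1, entries = entries),
            class = "anchor_index")
}

#' Sorted prefix extrema of phenotype values within the anchor's groups
#'
#' For each side of the anchor split (group A: `Xi = 0`; group B:
#' `Xi = 1`), sorts the phenotype values and precomputes `low[r]` (sum of
#' the `r` smallest) and `high[r]` (sum of the `r` largest) for
#' `r = 0..group size`. Any subgroup of size `r` has its value sum inside
#' `[low[r], high[r]]`, which is what the scan's second bound term
#' maximizes over. These are the only permutation-dependent quantities of
#' the bound and cost O(n log n) per permutation.
#'
#' @param values numeric phenotype values aligned with the genotype columns.
#' @param membership logical vector, `TRUE` for group A (`Xi = 0`).
#' @return An object of class `group_prefix`: per side, `low`, `high`
#'   (length size+1) and the group total; plus the group sizes.
#' @export
group_prefix_sums <- function(values, membership) {
  one_side <- function(v) {
    s <- sort(v)
    list(low = c(0, cumsum(s)),
         high = c(0, cumsum(rev(s))),
         total = sum(v), size = length(v))
  }
  structure(list(A = one_side(values[membership]),
                 B = one_side(values[!membership])),
            class = "group_prefix")
}

#' Maximum between-group sum-of-squares gain from splitting one group
#'
#' Splitting a group of size `n_g` and value sum `T_g` into a subgroup of
#' size `n_1` with (unknown) sum `T_1` and its complement increases the
#' between-group sum of squares by `(n_g*T_1 - n_1*T_g)^2 /
#' (n_g*n_1*(n_g-n_1))` — a convex quadratic in `T_1`. Since the true
#' subgroup sum lies in `[low[n_1], high[n_1]]` (extremal subset sums), the
#' gain is bounded by its value at those two endpoints.
#'
#' @param n_g group size.
#' @param n_1 subgroup size, `0 <= n_1 <= n_g`.
#' @param T_g group value sum.
#' @param low,high prefix extremum vectors from [group_prefix_sums()].
#' @return Non-negative numeric upper bound on the gain (0 when the split
#'   is empty or total).
#' @export
delta_bound <- function(n_g, n_1, T_g, low, high) {
  if (any(n_1 < 0L) || any(n_1 > n_g)) {
    stop("subgroup size out of range", call. = FALSE)
  }
  out <- numeric(length(n_1))
  inner <- n_1 > 0L & n_1 < n_g
  if (any(inner)) {
    n1 <- n_1[inner]
    denom <- n_g * n1 * (n_g - n1)
    lo <- (n_g * low[n1 + 1L] - n1 * T_g)^2 / denom
    hi <- (n_g * high[n1 + 1L] - n1 * T_g)^2 / denom
    out[inner] <- pmax(lo, hi)
  }
  out
}

#' Upper bound on the two-locus F statistic for one index entry
#'
#' The bound on the pair's between-group sum of squares is the sum of two
#' terms: the anchor's single-SNP `SS_between` under the current (possibly
#' permuted) phenotype, plus the maximal split gains on the A and B sides
#' from [delta_bound()]. The entry fixes which joint-genotype cells are
#' occupied, hence the exact `k` used in the F bound. All pairs indexed by
#' the same entry share this bound.
#'
#' @param n_A1,n_B1 the entry key counts.
#' @param prefix a [group_prefix_sums()] object for the anchor split.
#' @param ss_b_single anchor's single-locus `SS_between` under the current
#'   phenotype.
#' @param ss_total total sum of squares of the phenotype.
#' @param n number of individuals.
#' @return List with `bound` (F upper bound, may be `Inf`) and `k`.
#' @export
entry_upper_bound <- function(n_A1, n_B1, prefix, ss_b_single, ss_total, n) {
  n_A <- prefix$A$size
  n_B <- prefix$B$size
  dA <- delta_bound(n_A, n_A1, prefix$A$total, prefix$A$low, prefix$A$high)
  dB <- delta_bound(n_B, n_B1, prefix$B$total, prefix$B$low, prefix$B$high)
  ub <- pmin(ss_b_single + dA + dB, ss_total)
  k <- (n_A1 > 0L) + (n_A1 < n_A) + (n_B1 > 0L) + (n_B1 < n_B)
  bound <- numeric(length(ub))
  ok <- k >= 2L & n > k
  tol <- 1e-12 * max(1, ss_total)
  infb <- ok & ub >= ss_total - tol
  finb <- ok & !infb
  bound[infb] <- Inf
  bound[finb] <- (ub[finb] / (k[finb] - 1)) /
    ((ss_total - ub[finb]) / (n - k[finb]))
  list(bound = bound, k = as.integer(k))
}

#' Exhaustive two-locus ANOVA scan with upper-bound pruning
#'
#' Returns exactly the SNP pairs whose exact two-locus F statistic is
#' `>= theta`, with exact values — identical to filtering
#' [brute_force_scan()] at `theta`, but typically after testing only a
#' small candidate fraction. Per anchor SNP, the single-locus ANOVA and
#' the [group_prefix_sums()] are computed, every index entry gets its
#' shared F upper bound, and the exact two-locus ANOVA runs only on
#' partners in entries whose bound reaches `theta`. Pairs with F exactly
#' equal to `theta` are included.
#'
#' @param G binary-alphabet [genotype_matrix()].
#' @param y quantitative [phenotype_vector()] aligned with `G`.
#' @param theta non-negative F threshold (0 returns all pairs).
#' @param values optional raw numeric phenotype override (used internally
#'   by the permutation driver to avoid re-validating).
#' @return A [scan_result()] restricted to pairs with `F >= theta`.
#' @export
fastanova_scan <- function(G, y, theta = 0, values = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (G$alphabet != "binary") {
    stop("FastANOVA requires a binary genotype alphabet (use team for triallelic data)",
         call. = FALSE)
  }
  if (is.null(values)) {
    stopifnot(inherits(y, "phenotype_vector"))
    if (y$kind != "quantitative") {
      stop("FastANOVA requires a quantitative trait (use coe or team for binary traits)",
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
  Tot <- sum(values)
  ss_total <- max(sum(values^2) - Tot^2 / n, 0)
  ia <- ib <- integer(0)
  stat <- numeric(0)
  kk <- integer(0)
  n_candidates <- 0L
  for (i in seq_len(m - 1L)) {
    idx <- build_anchor_index(G, i, partners = (i + 1L):m)
    A <- X[i, ] == 0L
    prefix <- group_prefix_sums(values, A)
    TA <- prefix$A$total
    ss_b_single <- 0
    if (idx$n_A > 0L && idx$n_B > 0L) {
      ss_b_single <- TA^2 / idx$n_A + (Tot - TA)^2 / idx$n_B - Tot^2 / n
      ss_b_single <- min(max(ss_b_single, 0), ss_total)
    }
    eb <- entry_upper_bound(idx$n_A1, idx$n_B1, prefix, ss_b_single,
                            ss_total, n)
    # a pair whose test is undefined scores 0 by convention; keep it iff theta <= 0
    keep <- eb$bound >= theta | (theta <= 0)
    if (!any(keep)) next
    js <- idx$partners[keep]
    n_candidates <- n_candidates + length(js)
    for (j in js) {
      jl <- joint_group_labels(X[i, ], X[j, ], card = 2L)
      if (jl$k < 2L || n <= jl$k) {
        Fj <- 0; kj <- jl$k
      } else {
        a <- anova_f(values, jl$labels)
        Fj <- a$F; kj <- a$k
      }
      if (Fj >= theta) {
        ia <- c(ia, i); ib <- c(ib, j)
        stat <- c(stat, Fj); kk <- c(kk, kj)
      }
    }
  }
  out <- scan_result(ia, ib, stat, kk, ids = snp_ids(G))
  attr(out, "n_candidates") <- n_candidates
  attr(out, "n_pairs") <- m * (m - 1L) / 2L
  out
}
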