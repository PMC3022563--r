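#' Hamming distance between two genotype rows
#'
#' Number of individuals at which the two SNPs carry different codes; the
#' edge weight of the SNP graph the spanning tree is built on, and exactly
#' the number of individuals an incremental table update must touch when
#' stepping between the two SNPs.
#'
#' @param Xu,Xv integer genotype rows of equal length.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(Xu, Xv) {
  if (length(Xu) != length(Xv)) stop("genotype rows differ in length", call. = FALSE)
  sum(Xu != Xv)
}

#' Minimum spanning tree of the SNPs under Hamming distance
#'
#' Prim's algorithm on the complete graph whose nodes are SNPs and whose
#' edge weights are pairwise Hamming distances, rooted at SNP 1.
#' Tie-breaking is deterministic: among equal-weight candidate edges the
#' one with the lexicographically smallest (min endpoint, max endpoint) is
#' chosen, so two builds on the same matrix give identical edge sets. Each
#' tree edge stores its difference list — the individuals at which the two
#' SNPs differ, with both codes — which is all an incremental traversal
#' needs. The tree depends only on genotypes and is reused unchanged for
#' every phenotype permutation.
#'
#' @param G a [genotype_matrix()].
#' @return An object of class `spanning_tree`: list with `m`, `root` (1),
#'   `parent` (parent node per non-root node, NA for root), `edges` (list
#'   per non-root node `v`: `u` = parent, `v`, `weight`, `ind`, `from`,
#'   `to` — difference list oriented parent to child), `children` (list of
#'   ascending child indices per node) and `total_weight`.
#' @export
build_mst <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$codes
  m <- nrow(X)
  card <- alphabet_card(G)
  agree <- matrix(0L, m, m)
  for (c in seq_len(card) - 1L) {
    Ic <- (X == c) * 1L
    agree <- agree + Ic %*% t(Ic)
  }
  D <- ncol(X) - agree
  intree <- rep(FALSE, m)
  intree[1L] <- TRUE
  # best known connection of each outside node to the tree
  best_w <- D[1L, ]
  best_u <- rep(1L, m)
  parent <- rep(NA_integer_, m)
  for (step in seq_len(m - 1L)) {
    cand <- which(!intree)
    # order candidate edges by (weight, min endpoint, max endpoint)
    ep_min <- pmin(best_u[cand], cand)
    ep_max <- pmax(best_u[cand], cand)
    pick <- cand[order(best_w[cand], ep_min, ep_max)][1L]
    intree[pick] <- TRUE
    parent[pick] <- best_u[pick]
    out <- which(!intree)
    if (length(out) > 0L) {
      w_new <- D[pick, out]
      better <- w_new < best_w[out]
      # equal weight: prefer the edge with smaller (min endpoint, max endpoint)
      tie <- w_new == best_w[out]
      if (any(tie)) {
        o <- out[tie]
        old_min <- pmin(best_u[o], o); old_max <- pmax(best_u[o], o)
        new_min <- pmin(pick, o); new_max <- pmax(pick, o)
        better[tie] <- (new_min < old_min) | (new_min == old_min & new_max < old_max)
      }
      upd <- out[better]
      best_w[upd] <- D[pick, upd]
      best_u[upd] <- pick
    }
  }
  edges <- vector("list", m)
  children <- rep(list(integer(0)), m)
  total <- 0L
  for (v in seq_len(m)[-1L]) {
    u <- parent[v]
    ind <- which(X[u, ] != X[v, ])
    edges[[v]] <- list(u = u, v = v, weight = length(ind),
                       ind = ind, from = X[u, ind], to = X[v, ind])
    children[[u]] <- sort(c(children[[u]], v))
    total <- total + length(ind)
  }
  structure(list(m = m, root = 1L, parent = parent, edges = edges,
                 children = children, total_weight = total),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("spanning_tree: ", x$m, " SNPs, total Hamming weight ",
      x$total_weight, "\n", sep = "")
  invisible(x)
}

# Depth-first tour of the tree as flat arrays for the traversal kernels.
# Each step moves the current node: forward steps descend a tree edge
# (applying its diff), backward steps return to the parent (reversed diff).
mst_tour <- function(tree) {
  node <- integer(0); fwd <- logical(0)
  ind <- from <- to <- list()
  walk <- function(u) {
    for (v in tree$children[[u]]) {
      e <- tree$edges[[v]]
      node <<- c(node, v); fwd <<- c(fwd, TRUE)
      ind[[length(ind) + 1L]] <<- e$ind
      from[[length(from) + 1L]] <<- e$from
      to[[length(to) + 1L]] <<- e$to
      walk(v)
      node <<- c(node, u); fwd <<- c(fwd, FALSE)
      ind[[length(ind) + 1L]] <<- e$ind
      from[[length(from) + 1L]] <<- e$to
      to[[length(to) + 1L]] <<- e$from
    }
  }
  walk(tree$root)
  lens <- lengths(ind)
  list(node = node, forward = fwd,
       off = c(0L, cumsum(lens)),
       ind = unlist(ind, use.names = FALSE) %||% integer(0),
       from = unlist(from, use.names = FALSE) %||% integer(0),
       to = unlist(to, use.names = FALSE) %||% integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an edge difference list to a joint-count table
#'
#' The maintained table for anchor `i` and current partner `u` is a
#' `card x card x 2` array of counts over (anchor code, partner code,
#' phenotype class). Stepping the partner from `u` to `v` only requires
#' moving the individuals at which `u` and `v` differ: each such
#' individual leaves cell `(Xi[s], from[s], y[s])` and enters
#' `(Xi[s], to[s], y[s])`. `direction = "backward"` undoes a forward
#' application exactly (involution).
#'
#' @param table numeric/integer `card x card x 2` array.
#' @param diff list with `ind` (individual indices), `from`, `to` (codes).
#' @param Xi anchor genotype row.
#' @param y 0/1 phenotype values.
#' @param direction `"forward"` or `"backward"`.
#' @return The updated table.
#' @export
apply_diff <- function(table, diff, Xi, y, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (length(diff$ind) == 0L) return(table)
  from <- diff$from; to <- diff$to
  if (direction == "backward") { tmp <- from; from <- diff$to; to <- diff$from }
  card <- dim(table)[1L]
  s <- diff$ind
  a <- Xi[s]
  cls <- y[s]
  dec <- a + card * from + card * card * cls + 1L
  inc <- a + card * to + card * card * cls + 1L
  for (q in seq_along(dec)) {
    table[dec[q]] <- table[dec[q]] - 1L
    if (table[dec[q]] < 0L) {
      stop("table cell decremented below zero: corrupted traversal state",
           call. = FALSE)
    }
    table[inc[q]] <- table[inc[q]] + 1L
  }
  table
}

table_to_contingency <- function(table, card) {
  # table: card x card x 2 array (anchor, partner, class 0/1)
  n1 <- as.vector(table[, , 2L])  # cases, joint code = anchor*card + partner
  n0 <- as.vector(table[, , 1L])
  # as.vector runs anchor fastest; joint code anchor*card+partner runs partner fastest
  ord <- order(rep(seq_len(card) - 1L, times = card) * card +
                 rep(seq_len(card) - 1L, each = card))
  n1 <- n1[ord]; n0 <- n0[ord]
  keep <- (n1 + n0) > 0
  new_contingency_table(rbind(n1[keep], n0[keep]),
                        codes = (seq_len(card * card) - 1L)[keep])
}

#' Exact all-pairs two-locus scan via incremental tree traversal
#'
#' For every anchor SNP `i`, the full joint-count table for the pair
#' (`i`, root) is built by one pass over the individuals; a depth-first
#' traversal of the minimum spanning tree then moves the partner SNP along
#' tree edges, updating the table through each edge's difference list
#' ([apply_diff()]) instead of rescanning all individuals, and emits the
#' exact statistic for every pair `(i, j)` with `j > i`. All
#' `m(m-1)/2` pairs are recorded — this is what makes permutation FDR
#' estimation possible in addition to FWER.
#'
#' @param G a [genotype_matrix()] (binary or triallelic).
#' @param y a binary [phenotype_vector()] aligned with `G`.
#' @param test `"chi2"`, `"gtest"` or `"mi"`.
#' @param tree optional prebuilt [build_mst()] result (reused across
#'   permutations by the permutation driver).
#' @param .impl `"cpp"` (default) or `"r"` — the pure-R traversal supports
#'   instrumentation and is otherwise identical.
#' @param on_visit optional callback `function(anchor, node, table)`
#'   invoked at every forward traversal step (R implementation only; used
#'   to audit the maintained table against direct counting).
#' @param values optional raw 0/1 phenotype override.
#' @return A [scan_result()] with all pairs; attribute `touched` (R
#'   implementation) counts individuals touched per anchor:
#'   `n + 2 * total tree weight`.
#' @export
team_scan <- function(G, y, test = c("chi2", "gtest", "mi"), tree = NULL,
                      .impl = c("cpp", "r"), on_visit = NULL, values = NULL) {
  test <- match.arg(test)
  .impl <- match.arg(.impl)
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(values)) {
    stopifnot(inherits(y, "phenotype_vector"))
    if (y$kind != "binary") {
      stop("TEAM requires a binary trait (use fastanova for quantitative traits)",
           call. = FALSE)
    }
    values <- y$values
  }
  if (is.null(tree)) tree <- build_mst(G)
  m <- n_snps(G)
  if (.impl == "cpp" && is.null(on_visit)) {
    res <- team_stats_matrix(G, tree, matrix(as.integer(values), ncol = 1L), test)
    pr <- pair_indices(m)
    out <- scan_result(pr$ia, pr$ib, res$stats[, 1L], res$k, ids = snp_ids(G))
    return(out)
  }
  team_scan_r(G, values, test, tree, on_visit)
}

pair_indices <- function(m) {
  ia <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  ib <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m), use.names = FALSE)
  list(ia = ia, ib = ib)
}

pair_row <- function(i, j, m) {
  # row of pair (i < j) in the canonical pair enumeration
  (i - 1L) * m - (i * (i - 1L)) %/% 2L + (j - i)
}

team_scan_r <- function(G, values, test, tree, on_visit = NULL) {
  m <- n_snps(G)
  n <- n_individuals(G)
  card <- alphabet_card(G)
  X <- G$codes
  y01 <- as.integer(values)
  tour <- mst_tour(tree)
  statf <- table_stat_fun(test)
  npairs <- (m * (m - 1L)) %/% 2L
  stat <- numeric(npairs)
  kvec <- integer(npairs)
  touched <- 0L
  for (i in seq_len(m - 1L)) {
    tab <- array(0L, dim = c(card, card, 2L))
    idx3 <- X[i, ] + card * X[tree$root, ] + card * card * y01 + 1L
    cnt <- tabulate(idx3, nbins = card * card * 2L)
    tab[] <- cnt
    touched <- touched + n
    if (tree$root > i) {
      ct <- table_to_contingency(tab, card)
      r <- pair_row(i, tree$root, m)
      kvec[r] <- ncol(ct$counts)
      stat[r] <- if (kvec[r] < 2L) 0 else statf(ct)
    }
    for (t in seq_along(tour$node)) {
      rng <- if (tour$off[t + 1L] > tour$off[t]) (tour$off[t] + 1L):tour$off[t + 1L] else integer(0)
      diff <- list(ind = tour$ind[rng], from = tour$from[rng], to = tour$to[rng])
      tab <- apply_diff(tab, diff, X[i, ], y01, "forward")
      touched <- touched + length(rng)
      v <- tour$node[t]
      if (tour$forward[t]) {
        if (!is.null(on_visit)) on_visit(i, v, tab)
        if (v > i) {
          ct <- table_to_contingency(tab, card)
          r <- pair_row(i, v, m)
          kvec[r] <- ncol(ct$counts)
          stat[r] <- if (kvec[r] < 2L) 0 else statf(ct)
        }
      }
    }
  }
  pr <- pair_indices(m)
  out <- scan_result(pr$ia, pr$ib, stat, kvec, ids = snp_ids(G))
  attr(out, "touched") <- touched
  out
}

# All-pairs statistics for K phenotype columns at once (C++ kernel).
# Y: n x K integer matrix of 0/1 phenotypes. Returns list(stats = npairs x K
# matrix in canonical pair order, k = npairs occupancy counts).
team_stats_matrix <- function(G, tree, Y, test) {
  tour <- mst_tour(tree)
  cpp_team_stats(G$codes, tour$node - 1L, as.integer(tour$forward),
                 tour$off, tour$ind - 1L, tour$from, tour$to,
                 Y, alphabet_card(G), test_code(test), tree$root - 1L)
}
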