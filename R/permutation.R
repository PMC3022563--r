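#' Build a reproducible phenotype permutation plan
#'
#' Draws `K` uniform random permutations of the individuals from a single
#' seeded generator, sequentially, so regeneration from `(n, K, seed)` is
#' bit-identical. Shuffling is across all individuals (exchangeability
#' under the global null); no stratification.
#'
#' @param n number of individuals.
#' @param K number of permutations.
#' @param seed integer RNG seed.
#' @return An object of class `permutation_plan`: list with `n`, `K`,
#'   `seed` and `perms` (`n x K` integer matrix, one permutation of
#'   `1..n` per column).
#' @export
permutation_plan <- function(n, K, seed) {
  stopifnot(n >= 2L, K >= 1L)
  if (is.na(seed)) stop("a seed is required (no silent nondeterminism)", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  perms <- vapply(seq_len(K), function(k) sample.int(n), integer(n))
  structure(list(n = as.integer(n), K = as.integer(K),
                 seed = as.integer(seed), perms = perms),
            class = "permutation_plan")
}

#' Reassign phenotype values to individuals under a permutation
#'
#' @param y a [phenotype_vector()].
#' @param perm integer permutation of `1..n`.
#' @return A [phenotype_vector()] with the same ids (in the same order)
#'   carrying the shuffled values; the multiset of values is preserved.
#' @export
permute_phenotype <- function(y, perm) {
  stopifnot(inherits(y, "phenotype_vector"))
  n <- length(y$values)
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    stop("perm must be a permutation of 1..n", call. = FALSE)
  }
  phenotype_vector(unname(y$values)[perm], individual_ids = names(y$values),
                   kind = y$kind)
}

#' Per-permutation maxima of the pair statistic (null distribution)
#'
#' Computes, for each permutation in the plan, the maximum two-locus
#' statistic over all SNP pairs — the basis for max-statistic FWER
#' control. The `team` and `brute` engines compute every maximum exactly.
#' The pruning engines (`fastanova`, `coe`) use a running threshold
#' protocol: the first `ceiling(alpha*(K+1))` permutations are computed
#' exactly; afterwards the threshold `theta` tracks the
#' `ceiling(alpha*(K+1))`-th largest exact maximum seen so far, and a
#' permutation whose pruned scan returns no pair `>= theta` is recorded as
#' *certified below* `theta` (its exact value cannot affect any null
#' quantile at or above `theta`, which is all FWER control at level
#' `alpha` needs).
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype_vector()] aligned with `G`.
#' @param plan a [permutation_plan()].
#' @param engine `"fastanova"`, `"coe"`, `"team"` or `"brute"`.
#' @param test statistic name (must match the engine/trait).
#' @param alpha FWER level driving the pruning threshold protocol.
#' @return An object of class `null_maxima`: list with `values` (length
#'   K; certified entries hold their certification threshold), `exact`
#'   (logical), `threshold` (certification threshold or `NA`), plus
#'   `K`, `alpha`, `engine`, `test`.
#' @export
permutation_maxima <- function(G, y, plan, engine = c("team", "fastanova", "coe", "brute"),
                               test = NULL, alpha = 0.05) {
  engine <- match.arg(engine)
  stopifnot(inherits(plan, "permutation_plan"),
            plan$n == n_individuals(G))
  if (is.null(test)) test <- if (y$kind == "quantitative") "anova" else "chi2"
  validate_engine(engine, test, y$kind, G$alphabet, fdr = FALSE)
  K <- plan$K
  vals <- unname(y$values)
  values <- numeric(K)
  exact <- rep(TRUE, K)
  threshold <- rep(NA_real_, K)
  if (engine == "team") {
    tree <- build_mst(G)
    Y <- matrix(as.integer(vals)[plan$perms], nrow = plan$n, ncol = K)
    values <- as.numeric(team_stats_matrix_max(G, tree, Y, test))
  } else if (engine == "brute") {
    for (k in seq_len(K)) {
      yp <- permute_phenotype(y, plan$perms[, k])
      values[k] <- max(brute_force_scan(G, yp, test)$statistic)
    }
  } else {
    E <- ceiling(alpha * (K + 1))
    exact_vals <- numeric(0)
    scan1 <- function(th, pv) {
      if (engine == "fastanova") fastanova_scan(G, NULL, theta = th, values = pv)
      else coe_scan(G, NULL, theta = th, test = test, values = pv)
    }
    for (k in seq_len(K)) {
      pv <- vals[plan$perms[, k]]
      th <- if (length(exact_vals) < E) 0 else sort(exact_vals, decreasing = TRUE)[E]
      r <- scan1(th, pv)
      if (nrow(r) > 0L) {
        values[k] <- max(r$statistic)
        exact_vals <- c(exact_vals, values[k])
      } else {
        # pruned scan certifies that the true maximum is below th
        values[k] <- th
        exact[k] <- FALSE
        threshold[k] <- th
      }
    }
  }
  structure(list(values = values, exact = exact, threshold = threshold,
                 K = K, alpha = alpha, engine = engine, test = test),
            class = "null_maxima")
}

team_stats_matrix_max <- function(G, tree, Y, test) {
  tour <- mst_tour(tree)
  cpp_team_maxima(G$codes, tour$node - 1L, as.integer(tour$forward),
                  tour$off, tour$ind - 1L, tour$from, tour$to,
                  Y, alphabet_card(G), test_code(test), tree$root - 1L)
}

#' Certified lower bound on statistics adjustable from a maxima object
#'
#' The largest certification threshold among non-exact entries; adjusted
#' p-values are available exactly for statistics strictly above it.
#'
#' @param maxima a `null_maxima` object.
#' @return Numeric (0 when every maximum is exact).
#' @export
exactness_floor <- function(maxima) {
  if (all(maxima$exact)) 0 else max(maxima$threshold, na.rm = TRUE)
}

#' FWER-adjusted permutation p-values for a scan result
#'
#' `p_adj(s) = (1 + #{k : max_k >= s}) / (K + 1)` — the add-one
#' finite-sample-valid permutation estimator of the probability that the
#' null maximum statistic reaches `s`. A pair is FWER-significant at level
#' `alpha` iff `p_adj <= alpha`. Requesting a p-value for a statistic at or
#' below a certification threshold of the maxima is an error (the exact
#' count is unknown there); the scan pipeline only adjusts pairs above the
#' [exactness_floor()].
#'
#' @param observed a [scan_result()].
#' @param maxima a `null_maxima` object from [permutation_maxima()].
#' @return `observed` with `significance` set to the adjusted p-values and
#'   `significance_kind = "fwer_adjusted_p"`.
#' @export
fwer_adjusted_pvalues <- function(observed, maxima) {
  stopifnot(inherits(observed, "scan_result"), inherits(maxima, "null_maxima"))
  s <- observed$statistic
  floorv <- exactness_floor(maxima)
  if (any(s < floorv) && !all(maxima$exact)) {
    stop("statistic at or below the certification threshold (",
         format(floorv), "); increase exactness threshold", call. = FALSE)
  }
  ex <- maxima$values[maxima$exact]
  cnt <- vapply(s, function(si) sum(ex >= si), numeric(1))
  observed$significance <- (1 + cnt) / (maxima$K + 1)
  observed$significance_kind <- rep("fwer_adjusted_p", nrow(observed))
  observed
}

#' Permutation-estimated FDR threshold and q-values
#'
#' For a rejection region `{statistic >= t}`,
#' `FDR_hat(t) = min(1, mean_k #{null stats in permutation k >= t} /
#' max(1, #{observed >= t}))`. The threshold `t*` is the smallest observed
#' statistic with `FDR_hat(t) <= q`; the q-value of a pair with statistic
#' `s` is `min over observed thresholds t <= s of FDR_hat(t)` (step-up
#' enforcement, making q-values monotone non-increasing in the statistic).
#' Requires all-pairs statistics, i.e. the `team` (or `brute`) engine.
#'
#' @param observed_stats numeric vector of all observed pair statistics.
#' @param null_stats numeric matrix of null pair statistics, one column
#'   per permutation (all pairs per column).
#' @param q target FDR in (0, 1).
#' @return List with `t_star` (`NA` if no threshold attains the target),
#'   `q_values` (aligned with `observed_stats`) and `fdr_hat` (per unique
#'   observed threshold, decreasing-threshold order).
#' @export
fdr_threshold <- function(observed_stats, null_stats, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop("q must be in (0, 1)", call. = FALSE)
  }
  K <- ncol(null_stats)
  nv <- sort(as.vector(null_stats))         # pooled null stats, ascending
  ts <- sort(unique(observed_stats))        # candidate thresholds, ascending
  ov <- sort(observed_stats)
  n_null_ge <- length(nv) - findInterval(ts, nv, left.open = TRUE)
  n_obs_ge <- length(ov) - findInterval(ts, ov, left.open = TRUE)
  fdr <- pmin(1, (n_null_ge / K) / pmax(1, n_obs_ge))
  qv_at_ts <- cummin(fdr)  # min FDR_hat over thresholds <= t, left to right
  pos <- findInterval(observed_stats, ts)
  q_values <- qv_at_ts[pos]
  ok <- which(fdr <= q)
  t_star <- if (length(ok) > 0L) ts[min(ok)] else NA_real_
  list(t_star = t_star, q_values = q_values,
       fdr_hat = data.frame(threshold = rev(ts), fdr_hat = rev(fdr)))
}
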