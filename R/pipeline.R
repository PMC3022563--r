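# Applicability matrix: which engine supports which trait kind, genotype
# alphabet, statistic and error-control type.
validate_engine <- function(engine, test, kind, alphabet, fdr = FALSE) {
  if (engine == "fastanova") {
    if (kind != "quantitative" || alphabet != "binary") {
      stop("FastANOVA requires a quantitative trait and binary genotype",
           call. = FALSE)
    }
    if (test != "anova") {
      stop("FastANOVA supports the ANOVA test only", call. = FALSE)
    }
  } else if (engine == "coe") {
    if (kind != "binary" || alphabet != "binary") {
      stop("COE requires a binary trait and binary genotype", call. = FALSE)
    }
    if (!test %in% c("chi2", "gtest", "mi")) {
      stop("COE supports the convex contingency-table tests chi2, gtest, mi",
           call. = FALSE)
    }
  } else if (engine == "team") {
    if (kind != "binary") {
      stop("TEAM requires a binary trait (any genotype alphabet)", call. = FALSE)
    }
    if (!test %in% c("chi2", "gtest", "mi")) {
      stop("TEAM supports the contingency-table tests chi2, gtest, mi",
           call. = FALSE)
    }
  } else if (engine == "brute") {
    check_test_phenotype(test, kind)
  } else {
    stop("unknown engine: ", engine, call. = FALSE)
  }
  if (fdr && !engine %in% c("team", "brute")) {
    stop("FDR control requires all-pairs statistics and is available for TEAM only ",
         "(FastANOVA and COE control FWER)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a full epistasis scan with permutation error control
#'
#' End-to-end driver: reads (or accepts) the genotype matrix and phenotype
#' vector, aligns samples by individual id, validates the engine /
#' trait / alphabet / error-type combination, runs the chosen scan engine
#' and the permutation procedure, and returns (optionally writes) the
#' significant SNP pairs with their significance levels.
#'
#' With `alpha` set, significance is the FWER-adjusted permutation p-value
#' of the maximum-statistic null distribution and pairs with
#' `p_adj <= alpha` are reported. With `fdr` set (TEAM or brute engines
#' only), significance is the permutation q-value and pairs with
#' `q <= fdr` are reported. Exactly one of `alpha`/`fdr` must be given.
#'
#' @param genotypes a [genotype_matrix()] or a genotype file path.
#' @param phenotype a [phenotype_vector()] or a phenotype file path.
#' @param engine `"fastanova"`, `"coe"`, `"team"`, or `"brute"` (the
#'   oracle pipeline; any setting).
#' @param test `"anova"`, `"chi2"`, `"gtest"` or `"mi"`; default `anova`
#'   for quantitative traits, `chi2` for binary.
#' @param alpha FWER level, or `NULL`.
#' @param fdr target FDR, or `NULL`.
#' @param K number of permutations.
#' @param seed integer RNG seed (required; permutations are the only
#'   source of randomness).
#' @param output optional results TSV path (written with `# key=value`
#'   metadata lines).
#' @param format genotype file format when `genotypes` is a path.
#' @param report `"significant"` (default) or `"all"` (all pairs;
#'   all-pairs engines only).
#' @param verbose log dataset dimensions, pruning rate and timing.
#' @return A [scan_result()] (invisibly if `output` is given) with
#'   attributes `n_pairs`, `engine`, `plan`.
#' @export
run_scan <- function(genotypes, phenotype,
                     engine = c("team", "fastanova", "coe", "brute"),
                     test = NULL, alpha = NULL, fdr = NULL,
                     K = 1000L, seed, output = NULL,
                     format = c("tsv", "plink_raw"),
                     report = c("significant", "all"),
                     verbose = FALSE) {
  engine <- match.arg(engine)
  report <- match.arg(report)
  t0 <- proc.time()[["elapsed"]]
  if (is.character(genotypes)) {
    genotypes <- read_genotypes(genotypes, format = match.arg(format))
  }
  if (is.character(phenotype)) phenotype <- read_phenotype(phenotype)
  al <- align_samples(genotypes, phenotype)
  G <- al$genotypes
  y <- al$phenotype
  if (is.null(test)) test <- if (y$kind == "quantitative") "anova" else "chi2"
  if (is.null(alpha) == is.null(fdr)) {
    stop("exactly one of alpha (FWER) or fdr (target FDR) must be set",
         call. = FALSE)
  }
  validate_engine(engine, test, y$kind, G$alphabet, fdr = !is.null(fdr))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  m <- n_snps(G)
  n <- n_individuals(G)
  if (engine %in% c("fastanova", "coe") && n > 100L && verbose) {
    message("note: ", engine, " targets small cohorts (< 100 individuals); n = ", n)
  }
  if (report == "all" && engine %in% c("fastanova", "coe")) {
    stop("report = 'all' needs all-pairs statistics; use the team or brute engine",
         call. = FALSE)
  }
  plan <- permutation_plan(n, K, seed)
  lvl <- if (is.null(alpha)) fdr else alpha
  pruned <- NA_real_

  if (!is.null(fdr)) {
    # all-pairs statistics observed and under every permutation
    if (engine == "team") {
      tree <- build_mst(G)
      obs <- team_scan(G, y, test, tree = tree)
      Y <- matrix(as.integer(unname(y$values))[plan$perms], nrow = n, ncol = K)
      null_stats <- team_stats_matrix(G, tree, Y, test)$stats
    } else {
      obs <- brute_force_scan(G, y, test)
      null_stats <- vapply(seq_len(K), function(k) {
        yp <- permute_phenotype(y, plan$perms[, k])
        sort_canonical(brute_force_scan(G, yp, test))$statistic
      }, numeric((m * (m - 1L)) %/% 2L))
    }
    fq <- fdr_threshold(obs$statistic, null_stats, q = fdr)
    obs$significance <- fq$q_values
    obs$significance_kind <- rep("fdr_q", nrow(obs))
    res <- if (report == "all") obs else obs[obs$significance <= fdr, , drop = FALSE]
    class(res) <- c("scan_result", "data.frame")
  } else {
    maxima <- permutation_maxima(G, y, plan, engine, test, alpha = alpha)
    if (engine == "team") {
      obs <- team_scan(G, y, test)
    } else if (engine == "brute") {
      obs <- brute_force_scan(G, y, test)
    } else {
      th <- exactness_floor(maxima)
      obs <- if (engine == "fastanova") {
        fastanova_scan(G, y, theta = th)
      } else {
        coe_scan(G, y, theta = th, test = test)
      }
      pruned <- 1 - attr(obs, "n_candidates") / attr(obs, "n_pairs")
    }
    if (engine %in% c("team", "brute")) {
      obs <- fwer_adjusted_pvalues(obs, maxima)
      res <- if (report == "all") obs else obs[obs$significance <= alpha, , drop = FALSE]
    } else {
      # every pair above the certification floor gets an exact p-value
      obs <- fwer_adjusted_pvalues(obs, maxima)
      res <- obs[obs$significance <= alpha, , drop = FALSE]
    }
    class(res) <- c("scan_result", "data.frame")
  }

  if (verbose) {
    message(sprintf(
      "engine=%s test=%s m=%d n=%d K=%d %s=%g pairs=%d reported=%d%s elapsed=%.2fs",
      engine, test, m, n, K, if (is.null(alpha)) "fdr" else "alpha", lvl,
      (m * (m - 1L)) %/% 2L, nrow(res),
      if (!is.na(pruned)) sprintf(" pruned=%.1f%%", 100 * pruned) else "",
      proc.time()[["elapsed"]] - t0))
  }
  attr(res, "n_pairs") <- (m * (m - 1L)) %/% 2L
  attr(res, "engine") <- engine
  attr(res, "plan") <- plan
  if (!is.null(output)) {
    meta <- list(engine = engine, test = test, K = K, seed = plan$seed)
    meta[[if (is.null(alpha)) "fdr" else "alpha"]] <- lvl
    write_results(res, output, meta = meta)
    return(invisible(res))
  }
  res
}

# Reorder a scan_result into canonical pair order (anchor, partner
# ascending) — used when comparing all-pairs vectors positionally.
sort_canonical <- function(r) {
  ord <- order(attr(r, "ia"), attr(r, "ib"))
  out <- r[ord, , drop = FALSE]
  attr(out, "ia") <- attr(r, "ia")[ord]
  attr(out, "ib") <- attr(r, "ib")[ord]
  class(out) <- c("scan_result", "data.frame")
  out
}
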