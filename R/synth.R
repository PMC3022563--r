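#' Simulation configuration for synthetic genotype/phenotype data
#'
#' Defines the generative model used throughout the test-bench: SNP 1 is
#' drawn i.i.d. per individual (binary: Bernoulli(maf); triallelic:
#' Hardy-Weinberg genotype frequencies from allele frequency maf); each
#' subsequent SNP copies its left neighbour's code per individual with
#' probability `ld_rho` and redraws otherwise, giving a Markov-chain form
#' of linkage disequilibrium under which expected Hamming distances (and
#' hence the spanning-tree structure) are analytically tractable. An
#' optional planted effect raises the trait only for individuals in one
#' joint-genotype cell of one SNP pair — pure epistasis with weak marginal
#' effects, the scenario single-locus prescreening misses.
#'
#' @param m,n numbers of SNPs and individuals.
#' @param alphabet `"binary"` or `"triallelic"`.
#' @param maf_range minor-allele-frequency range, drawn uniformly per SNP.
#' @param ld_rho neighbour-copy probability in `[0, 1)`.
#' @param planted optional list: `pair` (two SNP indices), `cell` (target
#'   joint codes, length 2), `effect_size`, `model` (`"quantitative"` or
#'   `"logistic"`).
#' @param noise_sigma residual standard deviation of the quantitative trait.
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 50L, n = 80L, alphabet = c("binary", "triallelic"),
                       maf_range = c(0.2, 0.5), ld_rho = 0,
                       planted = NULL, noise_sigma = 1, seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(m >= 2L, n >= 2L,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1, noise_sigma > 0)
  if (!is.null(planted)) {
    stopifnot(length(planted$pair) == 2L, planted$pair[1] != planted$pair[2],
              all(planted$pair >= 1L), all(planted$pair <= m),
              length(planted$cell) == 2L, is.finite(planted$effect_size))
    planted$model <- match.arg(planted$model, c("quantitative", "logistic"))
  }
  structure(list(m = as.integer(m), n = as.integer(n), alphabet = alphabet,
                 maf_range = as.numeric(maf_range), ld_rho = ld_rho,
                 planted = planted, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_snp <- function(n, maf, alphabet) {
  if (alphabet == "binary") {
    rbinom(n, 1L, maf)
  } else {
    # Hardy-Weinberg genotype frequencies from allele frequency maf
    rbinom(n, 2L, maf)
  }
}

#' Generate a genotype matrix under the simulation model
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] (`snp1..snpm` x `ind1..indn`).
#' @export
generate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  X <- matrix(0L, cfg$m, cfg$n)
  for (r in seq_len(cfg$m)) {
    maf <- runif(1, cfg$maf_range[1], cfg$maf_range[2])
    for (attempt in seq_len(100L)) {
      fresh <- draw_snp(cfg$n, maf, cfg$alphabet)
      if (r == 1L || cfg$ld_rho == 0) {
        row <- fresh
      } else {
        copy <- runif(cfg$n) < cfg$ld_rho
        row <- ifelse(copy, X[r - 1L, ], fresh)
      }
      if (length(unique(row)) > 1L) break
      if (attempt == 100L) {
        stop("SNP ", r, " monomorphic after 100 redraws; widen maf_range or increase n",
             call. = FALSE)
      }
    }
    X[r, ] <- as.integer(row)
  }
  genotype_matrix(X, snp_ids = paste0("snp", seq_len(cfg$m)),
                  individual_ids = paste0("ind", seq_len(cfg$n)),
                  alphabet = cfg$alphabet)
}

planted_indicator <- function(G, cfg) {
  p <- cfg$planted
  if (is.null(p)) return(rep(0, n_individuals(G)))
  as.numeric(G$codes[p$pair[1], ] == p$cell[1] & G$codes[p$pair[2], ] == p$cell[2])
}

#' Plant a quantitative trait with a single-cell epistatic effect
#'
#' `y_s = effect_size * 1[genotype of the planted pair hits the target
#' joint cell] + Normal(0, noise_sigma^2)`. With no planted effect the
#' trait is pure Gaussian noise (null dataset). The single-cell indicator
#' keeps the two SNPs' marginal effects weak relative to their joint
#' effect.
#'
#' @param G a [genotype_matrix()] from [generate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return A quantitative [phenotype_vector()].
#' @export
plant_quantitative_trait <- function(G, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ind <- planted_indicator(G, cfg)
  eff <- if (is.null(cfg$planted)) 0 else cfg$planted$effect_size
  y <- eff * ind + rnorm(n_individuals(G), 0, cfg$noise_sigma)
  phenotype_vector(y, individual_ids = individual_ids(G),
                   kind = "quantitative")
}

#' Plant a binary trait with a single-cell logistic epistatic effect
#'
#' `P(case) = logistic(beta0 + effect_size * 1[planted cell])` with
#' `beta0` solved so the expected case fraction is 0.5. Redraws (up to
#' 100 times) if a class comes out empty.
#'
#' @param G a [genotype_matrix()].
#' @param cfg the same [sim_config()].
#' @return A binary [phenotype_vector()].
#' @export
plant_binary_trait <- function(G, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ind <- planted_indicator(G, cfg)
  eff <- if (is.null(cfg$planted)) 0 else cfg$planted$effect_size
  f <- mean(ind)
  logistic <- function(x) 1 / (1 + exp(-x))
  beta0 <- if (eff == 0 || f %in% c(0, 1)) {
    -eff * f   # degenerate cases: center directly
  } else {
    uniroot(function(b) f * logistic(b + eff) + (1 - f) * logistic(b) - 0.5,
            interval = c(-abs(eff) - 10, abs(eff) + 10))$root
  }
  p <- logistic(beta0 + eff * ind)
  for (attempt in seq_len(100L)) {
    y <- rbinom(length(p), 1L, p)
    if (length(unique(y)) > 1L) break
    if (attempt == 100L) stop("binary trait degenerate after 100 redraws", call. = FALSE)
  }
  phenotype_vector(y, individual_ids = individual_ids(G), kind = "binary")
}

#' Generate and optionally write a full synthetic dataset
#'
#' Draws genotypes and a phenotype under `cfg` (quantitative or logistic
#' planted model, or a pure-null trait when nothing is planted). When
#' `dir` is given, writes the native genotype TSV, the phenotype TSV and a
#' JSON sidecar recording the full configuration — including the planted
#' truth — for downstream harnesses.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @param trait `"quantitative"`, `"binary"`, or `NULL` to follow the
#'   planted model (binary when nothing is planted and `trait` is `NULL`
#'   defaults to quantitative).
#' @return List with `genotypes`, `phenotype`, `config`, and (if written)
#'   `paths`.
#' @export
simulate_dataset <- function(cfg, dir = NULL, trait = NULL) {
  G <- generate_genotypes(cfg)  # seeds the RNG; trait draw continues the stream
  if (is.null(trait)) {
    trait <- if (!is.null(cfg$planted) && cfg$planted$model == "logistic") {
      "binary"
    } else {
      "quantitative"
    }
  }
  trait <- match.arg(trait, c("quantitative", "binary"))
  y <- if (trait == "quantitative") plant_quantitative_trait(G, cfg)
       else plant_binary_trait(G, cfg)
  out <- list(genotypes = G, phenotype = y, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gp <- file.path(dir, "genotypes.tsv")
    pp <- file.path(dir, "phenotype.tsv")
    jp <- file.path(dir, "config.json")
    write_genotypes(G, gp)
    write_phenotype(y, pp)
    jsonlite::write_json(unclass(cfg), jp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    out$paths <- list(genotypes = gp, phenotype = pp, config = jp)
  }
  out
}
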