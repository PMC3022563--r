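# episcan

Exhaustive two-locus epistasis scans for genome-wide association studies,
with permutation-based error control.

## The problem

Complex traits are rarely explained by single markers: a pair of SNPs can
carry strong joint association while each member's marginal effect is
weak — exactly the signal that single-locus tests and two-step
prescreening miss. Testing association for every SNP pair is
statistically straightforward but computationally brutal: `m` SNPs give
`m(m−1)/2` pairs, and permutation-based multiple-testing control
multiplies that by the number of permutations `K`. `episcan` implements
three exact scan engines that cut this cost without changing any answer,
for the three standard problem settings:

| Engine      | Trait        | Genotype codes | Error control | Statistic                 |
|-------------|--------------|----------------|---------------|---------------------------|
| `fastanova` | quantitative | binary {0,1}   | FWER          | two-locus ANOVA F         |
| `coe`       | binary       | binary {0,1}   | FWER          | chi-square, G-test, MI    |
| `team`      | binary       | any {0,1,2}    | FWER & FDR    | any contingency statistic |

All three are **exact**: a pruned scan returns precisely the pairs a
brute-force scan would return above a threshold, with the same
statistics. The package ships its own brute-force oracle
(`brute_force_scan()`) and the test suite holds every engine to it.

## The methods in one paragraph each

**FastANOVA** bounds the two-locus F statistic by a sum of two terms: the
anchor SNP's single-locus `SS_between`, plus the maximal split gain of
each anchor genotype group — a convex quadratic in the unknown subgroup
phenotype sum, maximized at extremal prefix sums of the sorted group
values. Partner SNPs are indexed per anchor by the pair of counts
`(n_A1, n_B1)` (partners with `Xj = 1` inside each anchor group); all
partners in an entry share one bound, the entry count is bounded by the
number of individuals, and the index is genotype-only, so it is built
once and reused across all permutations.

**COE** exploits convexity in the contingency table itself: with binary
trait and genotypes, fixing the joint genotype cell sizes and the
single-locus case margins leaves a single free cell `t`, feasible on an
integer interval `[L, U]`. Chi-square, G and mutual information are
convex in `t`, so each pair's statistic is bounded by its value at the
two endpoint tables — the vertices of the feasible polytope.

**TEAM** computes every pair's statistic exactly by incremental counting:
SNPs are nodes of a minimum spanning tree under Hamming distance, and a
depth-first traversal updates the pair's contingency table through each
edge's difference list (only the individuals where the two SNPs differ),
instead of rescanning all `n` individuals per pair. Recording all pairs
is what enables FDR estimation in addition to FWER control.

**Error control** is by phenotype permutation throughout (no asymptotic
p-values, no Bonferroni): FWER via the null distribution of the maximum
pair statistic with add-one adjusted p-values
`(1 + #{max_k ≥ s})/(K+1)`, and, for `team`, permutation-estimated FDR
with step-up q-values. For the pruning engines the per-permutation
maxima themselves are computed with a sound certify-below-threshold
protocol so that pruning survives the permutation loop.

## Worked example

Simulate a binary-trait dataset with a planted pure-epistasis effect
(only individuals with `snp5 = 1` **and** `snp21 = 1` get a log-odds
shift of 4), then scan it with the tree engine and 500 permutations:

```r
library(episcan)

cfg <- sim_config(m = 30, n = 100, alphabet = "binary",
                  maf_range = c(0.4, 0.5), seed = 42,
                  planted = list(pair = c(5, 21), cell = c(1, 1),
                                 effect_size = 4, model = "logistic"))
d <- simulate_dataset(cfg, dir = "example_data")

run_scan(d$paths$genotypes, d$paths$phenotype, engine = "team",
         alpha = 0.05, K = 500, seed = 7, verbose = TRUE)
#> engine=team test=chi2 m=30 n=100 K=500 alpha=0.05 pairs=435 reported=1 elapsed=2.62s
#> scan_result: 1 SNP pair(s)
#>  snp_a snp_b statistic k significance significance_kind
#>   snp5 snp21   24.4805 4  0.003992016   fwer_adjusted_p
```

The planted pair is the only one of the 435 to survive FWER control: its
chi-square statistic over the `k = 4` joint genotype groups is 24.48, and
in 500 phenotype permutations the genome-wide *maximum* statistic reached
24.48 only once — adjusted p-value `(1+1)/501 ≈ 0.004`. The same call
with `fdr = 0.1` instead of `alpha` reports the pair with a q-value of
0.002, the permutation-estimated false discovery rate at its threshold.

The same scan runs from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/episcan.R", package="episcan"))')" \
    team --genotypes example_data/genotypes.tsv \
         --phenotype example_data/phenotype.tsv \
         --alpha 0.05 --permutations 500 --seed 7 --output results.tsv
```

Subcommands `fastanova`, `coe`, `team`, `brute` and `simulate` mirror the
R functions; trait/genotype/error-type combinations outside the table
above are rejected with an explanatory message.

## Layout

- `R/` — data model and I/O, statistics and oracle, the three engines,
  permutation error control, simulator, pipeline.
- `src/` — C++ traversal kernel for the tree engine's permutation loop.
- `inst/cli/episcan.R` — command-line front end.
- `vignettes/epistasis-scans.Rmd` — models, bounds, protocols, design
  decisions, and what the simulator does and does not emulate.
- `tests/testthat/` — unit, property and acceptance suites.
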