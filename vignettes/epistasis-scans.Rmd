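---
title: "Exhaustive two-locus epistasis scans: models, bounds, and error control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive two-locus epistasis scans: models, bounds, and error control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcan)
```

## The problem

A genome-wide association study measures `m` SNPs on `n` individuals and a
phenotype — quantitative (an inbred-cross trait, an expression level) or
binary (case/control). Single-locus tests relate the phenotype to one SNP
at a time; epistasis detection relates it to *pairs* of SNPs, because a
pair can carry strong joint signal while each member's marginal effect is
negligible. An exhaustive two-locus scan evaluates all `m(m-1)/2` pairs,
and the multiple-testing burden is handled by permutation: the phenotype
values are shuffled across individuals and reassigned, the scan is
repeated, and the null distribution of the test statistic is estimated
from the shuffled replicates. With `K` permutations the work is
`(K+1) · m(m-1)/2` pair tests, which is what the three engines in this
package are designed to cut down — without changing any answer.

The engines' shared contract is **exactness**: a pruned scan must return
exactly the pairs a brute-force scan would return above a threshold, with
the same statistics. `brute_force_scan()` is the package's reference
implementation of that contract and every engine is tested against it.

## Statistics

For a quantitative trait, the two-locus test is the one-way ANOVA F
statistic over the joint genotype groups of a pair. Writing `T_g` and
`n_g` for the phenotype sum and size of group `g`,

* `SS_between = Σ_g T_g²/n_g − T²/n`, `SS_within = SS_total − SS_between`,
* `F = (SS_between/(k−1)) / (SS_within/(n−k))`, `k` = number of non-empty
  joint groups.

Two degenerate conventions make the maximum statistic well defined under
permutation: perfectly separating pairs (`SS_within = 0`,
`SS_between > 0`) score `F = +Inf`, and pairs with equal group means
score 0. Pairs whose test is undefined (`k < 2`, or `n ≤ k`) are emitted
with statistic 0 and their `k` flagged rather than dropped, so engines
and the oracle always agree on row counts.

For a binary trait, a pair defines a `2 × k` contingency table of
phenotype class by joint genotype group (empty groups dropped), and the
package implements three statistics on it: Pearson's chi-square, the
G statistic (likelihood ratio, natural log, `0·log 0 = 0`), and mutual
information in nats, which satisfies `G = 2·N·MI` (a tested identity).
No asymptotic p-values are computed anywhere: significance comes only
from permutation, which is also why degrees-of-freedom bookkeeping is
reduced to reporting `k` alongside each statistic.

## The FastANOVA engine: a sum-of-two-terms bound

For binary genotypes, fix an anchor SNP `i` with groups
`A = {Xi = 0}` and `B = {Xi = 1}`. A partner SNP `j` splits `A` into a
subgroup of size `n_A1` (those with `Xj = 1`) and its complement, and
likewise `B`. The pair's `SS_between` is the anchor's single-locus
`SS_between` plus the two split gains, and each gain is a convex
quadratic in the unknown subgroup phenotype sum `T_1`:

    gain = (n_g·T_1 − n_1·T_g)² / (n_g·n_1·(n_g − n_1))

Since `T_1` must be a sum of `n_1` of the group's values, it lies between
the sum of the `n_1` smallest and the `n_1` largest values — the prefix
extrema computed by `group_prefix_sums()` — and a convex function on an
interval is maximized at an endpoint. The bound on the pair's F is
therefore the anchor term plus two endpoint-maximized gains
(`delta_bound()`), converted to an F bound with the *exact* `k` of the
pair, which is determined by `(n_A1, n_B1)` occupancy alone.

The decisive structural fact is that `(n_A1, n_B1)` takes at most
`(n_A+1)(n_B+1)` values — bounded by the number of individuals, not the
number of SNPs — so partners are grouped into a 2-D index
(`build_anchor_index()`) whose entries share one bound each. The index
depends only on genotypes: it is built once and reused unchanged for
every permutation, while the permutation-dependent part (sorted prefix
sums per anchor) is O(n log n) per anchor per permutation. The scan
(`fastanova_scan()`) tests exactly the partners in entries whose bound
reaches the threshold; ties at the threshold are included.

The concrete algebra above is this package's own reconstruction of the
bound's published shape (single-locus term plus permutation-independent
genotype term); its correctness is enforced by two tested properties
rather than by derivation fidelity — soundness (no pair's exact F exceeds
its entry bound, checked over random data and permutations) and
completeness (scan output equals the filtered brute-force output,
exactly).

## The COE engine: convex statistics at polytope vertices

With binary genotypes *and* a binary trait, the two-locus table has four
genotype columns with fixed sizes `n_00, n_01, n_10, n_11` (derivable
from the same anchor index) and fixed single-locus case margins. Given
those margins the whole `2 × 4` table has a single free cell
`t = #cases in cell (0,0)`; the feasible set is the integer interval

    L = max(0, c_i0 − n_01, c_j0 − n_10, c_j0 − c_i1)
    U = min(n_00, c_i0, c_j0, n_11 + c_j0 − c_i1)

(`feasible_interval()`), and the true table's `t` always lies inside it.
Chi-square, G and MI are convex in `t` on this interval, so their maximum
over all margin-consistent tables is attained at `t = L` or `t = U`:
`convex_upper_bound()` evaluates the statistic at the two endpoint tables
and takes the larger. That maximum dominates the pair's exact statistic,
giving the pruning bound; the genotype-derived quantities are
permutation-invariant and the case margins refresh in O(m) per
permutation. Convexity is not proved in code — it is enforced
empirically by a grid-dominance property test (every interior integer `t`
is dominated by the endpoint maximum, over a thousand random
margin/count draws, for all three statistics), which would also catch a
user-registered statistic that is not actually convex.

Restricting this engine to the binary/binary setting keeps the vertex
set at two points; richer alphabets go to the tree engine below.

## The TEAM engine: incremental tables along a spanning tree

For human-style data (three genotype codes, larger `n`) the package
takes a different route: compute *every* pair's statistic exactly, but
cheaply. SNPs become nodes of a complete graph weighted by Hamming
distance (the number of individuals at which two SNPs differ), and a
minimum spanning tree is built once per dataset (`build_mst()`, Prim's
algorithm, deterministic tie-breaking by smallest endpoint pair, root at
SNP 1). Each tree edge stores its difference list: the individuals where
its endpoints differ, with both codes.

For each anchor `i`, the joint-count table of (`i`, root) is built by one
O(n) pass; a depth-first traversal then walks the partner SNP along tree
edges, and `apply_diff()` moves only the differing individuals between
cells — forward on entering an edge, backward (an exact involution) on
leaving. The maintained table is exact at every traversal point (audited
against direct counting in tests), and the work per anchor is
`n + 2 × (total tree weight)` individual touches, which is what linkage
disequilibrium buys: correlated neighbours give light edges. The
traversal is re-run per permutation with the same tree — the tree
depends only on genotypes. Because the engine records all `m(m-1)/2`
statistics rather than only threshold survivors, it supports
permutation FDR estimation in addition to FWER control.

"Difference between connected SNPs" is implemented as the
individual-level Hamming difference set, and the per-permutation
re-traversal keeps the traversal state independent across permutations;
both are this package's design choices, with exactness and all-pairs
recording as the tested contract. The hot loop (traversal across
permutation columns) is compiled C++; a pure-R traversal with an
audit callback (`team_scan(..., .impl = "r")`) is kept as the
instrumentable reference and tested to agree with it.

## Permutation error control

`permutation_plan()` draws `K` permutations sequentially from one seeded
generator, so `(n, K, seed)` regenerates the plan bit-identically; the
phenotype is shuffled across all individuals (exchangeability under the
global null; no stratification).

**FWER.** The null distribution of the *maximum* pair statistic yields
the add-one adjusted p-value `p_adj(s) = (1 + #{k: max_k ≥ s})/(K+1)`,
the standard finite-sample-valid permutation estimator; a pair is
reported at level `alpha` iff `p_adj ≤ alpha`. For the pruning engines,
computing every permutation's maximum exactly would forfeit the
pruning, so `permutation_maxima()` uses a threshold protocol: the first
`ceiling(alpha·(K+1))` permutations are computed exactly, after which the
threshold `theta` tracks the running `ceiling(alpha·(K+1))`-th largest
exact maximum; a permutation whose pruned scan returns nothing at
`theta` is recorded as *certified below* `theta`. Certified entries
cannot disturb any count `#{max_k ≥ s}` with `s > theta` — and every
pair that can be significant at level `alpha` has `s` above the final
`theta` — so the reported significant set is provably identical to the
all-exact computation (also verified in tests against the brute-force
pipeline). Requesting a p-value below the certification floor raises an
error rather than returning a wrong number.

**FDR** (all-pairs engine only). For a rejection region
`{statistic ≥ t}`, `FDR_hat(t) = min(1, mean_k #{null stats ≥ t} /
max(1, #{observed ≥ t}))`; `fdr_threshold()` returns the smallest
observed `t` with `FDR_hat(t) ≤ q` and per-pair q-values with step-up
enforcement (`q(s) = min over thresholds t ≤ s of FDR_hat(t)`), making
q-values monotone non-increasing in the statistic.

The output's `significance_kind` column records which of the two was
computed, since "significance level" alone would be ambiguous.

## The synthetic-data generator

`sim_config()` + `simulate_dataset()` define the package's test bench:

* **Genotypes.** SNP 1 is i.i.d. across individuals — binary:
  Bernoulli(maf); triallelic: Hardy–Weinberg genotype frequencies from
  allele frequency maf — with maf drawn per SNP from `maf_range`
  (default 0.2–0.5). Each later SNP copies its left neighbour per
  individual with probability `ld_rho`, else redraws: a Markov-chain
  form of LD chosen over haplotype-block models because expected
  Hamming distances (and hence spanning-tree behaviour) stay
  analytically tractable; monomorphic draws are rejected (≤100
  retries). Default sizes follow the engines' design regimes: `n = 80`
  binary (the small-cohort setting the bounds target) and hundreds of
  individuals for triallelic designs.
* **Phenotypes.** The planted interaction is a *single-cell indicator*:
  only individuals hitting one joint genotype cell of one pair get the
  effect — quantitative `y = effect·1[cell] + N(0, sigma²)` or logistic
  `P(case) = logistic(beta0 + effect·1[cell])` with `beta0` solved so
  the expected prevalence is 0.5. A single-cell effect (rather than a
  product term) is pure epistasis with weak marginals, exactly the
  signal single-locus prescreening misses. The default planted cell is
  the heterozygote-by-heterozygote cell `(1,1)` for triallelic designs:
  at maf 0.5 it covers ~25% of individuals, which keeps each SNP's
  marginal signal small relative to the joint signal while leaving the
  cell populated enough for contingency statistics to rank the pair
  first at moderate effect sizes — a double-homozygote cell `(2,2)`
  (frequency maf⁴) carries too few individuals for that at realistic
  `n`.

What the generator does *not* emulate: coalescent-realistic LD,
population structure, case–control ascertainment, genotyping error or
missingness. Passing tests therefore demonstrate algorithmic exactness
and calibration under exchangeable, complete data — not robustness to
confounding or to missing genotypes (which the readers reject by
design).

## Numerical and design choices

* Tiny negative round-off in sums of squares is clamped to zero, and
  `SS_between` is clamped to `SS_total`; `F = Inf` / `F = 0` conventions
  use a `1e-12`-relative tolerance on `SS_within` / `SS_between`.
* Thresholded scans include ties (`statistic ≥ theta`).
* Output rows sort by statistic descending, ties by pair index;
  statistics print with 10 significant digits and `+Inf` prints `inf`.
* Pair orientation is always (earlier index, later index); each
  unordered pair appears once.
* MST tie-breaks are lexicographic on (weight, min endpoint,
  max endpoint), so rebuilds are bit-identical — required for the
  "build once, reuse across permutations" contract.
* Missing genotypes are rejected with a count of offending cells, never
  imputed: imputation would silently change every downstream count.
* Binary phenotypes are 0 = control, 1 = case; genotype input formats
  are the SNP-major TSV (native) and PLINK `.raw` (transposed on read,
  its PHENOTYPE column ignored).

## Problem sizes used by the test bench

The test suite and the reproduction script exercise: oracle equivalence
on 100 random instances per engine (`m ≤ 50`, `n ≤ 60` for the two
bounded engines; `m ≤ 40`, `n ≤ 200` including triallelic for the tree
engine); bound soundness on >1000 (pair, permutation) draws per bound;
vertex dominance on 1000 random margin/count draws; FWER calibration on
500 null datasets (`m = 20`, `n = 50`, `K = 200`, `alpha = 0.05`,
binomial 95% acceptance band 0.031–0.069); and planted-effect recovery
on 100 replicates per trait model (quantitative: effect 2 sigma at
`n = 200`; logistic: effect 2.0 at `n = 500`, triallelic). These sizes
make the full property battery run in minutes on one core while keeping
every count large enough for the stated statistical bands.

## Known limitations

* The pruning engines cover exactly their design settings
  (quantitative/binary for the ANOVA bound, binary/binary for the convex
  bound); everything else routes to the tree engine, which is exact but
  prunes nothing.
* The per-permutation re-traversal of the spanning tree leaves some
  constant-factor speedup on the table compared with sharing table
  updates across permutations; the package trades that for stateless
  permutations and a simpler exactness argument.
* Covariates, stratified permutation schemes, dosage genotypes and
  missing data are out of scope.
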