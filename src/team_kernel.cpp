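#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Contingency statistic of the maintained joint-count table.
// tab has card*card cells, each with a control (cls 0) and case (cls 1)
// count; cells with zero total are skipped (already-dropped columns).
// test: 0 = chi-square, 1 = G, 2 = mutual information (nats).
static double table_stat(const int *tab, int ncell, double M1, double M0,
                         double n, int test) {
  double acc = 0.0;
  for (int c = 0; c < ncell; ++c) {
    double n0 = tab[2 * c];
    double n1 = tab[2 * c + 1];
    double ng = n0 + n1;
    if (ng <= 0.0) continue;
    double e1 = ng * M1 / n;
    double e0 = ng * M0 / n;
    switch (test) {
    case 0:
      acc += (n1 - e1) * (n1 - e1) / e1 + (n0 - e0) * (n0 - e0) / e0;
      break;
    case 1:
      if (n1 > 0.0) acc += n1 * std::log(n1 / e1);
      if (n0 > 0.0) acc += n0 * std::log(n0 / e0);
      break;
    default:
      if (n1 > 0.0) acc += (n1 / n) * std::log((n1 * n) / (ng * M1));
      if (n0 > 0.0) acc += (n0 / n) * std::log((n0 * n) / (ng * M0));
    }
  }
  if (test == 1) acc *= 2.0;
  return acc < 0.0 ? 0.0 : acc;
}

// Exact all-pairs two-locus statistics for K phenotype columns.
//
// X: m x n genotype codes. The partner SNP walks a depth-first tour of the
// minimum spanning tree; each tour step carries the difference list of the
// traversed edge (individual index, partner code before, partner code
// after), pre-oriented so every step is applied in the same way. For each
// anchor i the joint table of (i, root) is counted once, then only the
// differing individuals are touched per step. Statistics are emitted at
// forward steps entering a node j > i.
//
// Returns stats (npairs x K, canonical pair order: (1,2), (1,3), ...,
// (m-1,m)) and k (non-empty joint cell count per pair, phenotype-free).
// [[Rcpp::export]]
List cpp_team_stats(IntegerMatrix X, IntegerVector tour_node,
                    IntegerVector tour_forward, IntegerVector diff_off,
                    IntegerVector diff_ind, IntegerVector diff_from,
                    IntegerVector diff_to, IntegerMatrix Y, int card,
                    int test, int root) {
  const int m = X.nrow(), n = X.ncol(), K = Y.ncol();
  const int L = tour_node.size();
  const int ncell = card * card;
  const int npairs = m * (m - 1) / 2;
  NumericMatrix stats(npairs, K);
  IntegerVector kvec(npairs);
  std::vector<int> tab(2 * ncell);

  for (int kcol = 0; kcol < K; ++kcol) {
    const int *y = &Y(0, kcol);
    double M1 = 0.0;
    for (int s = 0; s < n; ++s) M1 += y[s];
    double M0 = n - M1;
    for (int i = 0; i < m - 1; ++i) {
      std::fill(tab.begin(), tab.end(), 0);
      for (int s = 0; s < n; ++s) {
        int cell = X(i, s) * card + X(root, s);
        ++tab[2 * cell + y[s]];
      }
      if (root > i) {
        int r = i * m - i * (i + 1) / 2 + (root - i - 1);
        stats(r, kcol) = table_stat(tab.data(), ncell, M1, M0, (double)n, test);
      }
      for (int t = 0; t < L; ++t) {
        for (int d = diff_off[t]; d < diff_off[t + 1]; ++d) {
          int s = diff_ind[d];
          int a = X(i, s);
          int cls = y[s];
          --tab[2 * (a * card + diff_from[d]) + cls];
          ++tab[2 * (a * card + diff_to[d]) + cls];
        }
        int v = tour_node[t];
        if (tour_forward[t] && v > i) {
          int r = i * m - i * (i + 1) / 2 + (v - i - 1);
          stats(r, kcol) = table_stat(tab.data(), ncell, M1, M0, (double)n, test);
          if (kcol == 0) {
            int occ = 0;
            for (int c = 0; c < ncell; ++c)
              if (tab[2 * c] + tab[2 * c + 1] > 0) ++occ;
            kvec[r] = occ;
            if (occ < 2) stats(r, kcol) = 0.0;
          } else if (kvec[r] < 2) {
            stats(r, kcol) = 0.0;
          }
        }
      }
      if (kcol == 0 && root > i) {
        // occupancy for the (i, root) pair, counted directly
        std::fill(tab.begin(), tab.end(), 0);
        for (int s = 0; s < n; ++s) ++tab[2 * (X(i, s) * card + X(root, s))];
        int occ = 0;
        for (int c = 0; c < ncell; ++c)
          if (tab[2 * c] + tab[2 * c + 1] > 0) ++occ;
        int r = i * m - i * (i + 1) / 2 + (root - i - 1);
        kvec[r] = occ;
        if (occ < 2)
          for (int kc = 0; kc <= kcol; ++kc) stats(r, kc) = 0.0;
      }
    }
  }
  // zero-out undefined pairs (k < 2) across all columns
  for (int r = 0; r < npairs; ++r)
    if (kvec[r] < 2)
      for (int kc = 0; kc < K; ++kc) stats(r, kc) = 0.0;
  return List::create(Named("stats") = stats, Named("k") = kvec);
}

// Per-permutation maxima of the all-pairs statistics (same arguments as
// cpp_team_stats); avoids materializing the full matrix when only the
// null maximum distribution is needed.
// [[Rcpp::export]]
NumericVector cpp_team_maxima(IntegerMatrix X, IntegerVector tour_node,
                              IntegerVector tour_forward, IntegerVector diff_off,
                              IntegerVector diff_ind, IntegerVector diff_from,
                              IntegerVector diff_to, IntegerMatrix Y, int card,
                              int test, int root) {
  const int m = X.nrow(), n = X.ncol(), K = Y.ncol();
  const int L = tour_node.size();
  const int ncell = card * card;
  NumericVector maxima(K);
  std::vector<int> tab(2 * ncell);
  for (int kcol = 0; kcol < K; ++kcol) {
    const int *y = &Y(0, kcol);
    double M1 = 0.0;
    for (int s = 0; s < n; ++s) M1 += y[s];
    double M0 = n - M1;
    double best = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      std::fill(tab.begin(), tab.end(), 0);
      for (int s = 0; s < n; ++s)
        ++tab[2 * (X(i, s) * card + X(root, s)) + y[s]];
      if (root > i) {
        double v0 = table_stat(tab.data(), ncell, M1, M0, (double)n, test);
        if (v0 > best) best = v0;
      }
      for (int t = 0; t < L; ++t) {
        for (int d = diff_off[t]; d < diff_off[t + 1]; ++d) {
          int s = diff_ind[d];
          int a = X(i, s);
          int cls = y[s];
          --tab[2 * (a * card + diff_from[d]) + cls];
          ++tab[2 * (a * card + diff_to[d]) + cls];
        }
        if (tour_forward[t] && tour_node[t] > i) {
          double v = table_stat(tab.data(), ncell, M1, M0, (double)n, test);
          if (v > best) best = v;
        }
      }
    }
    maxima[kcol] = best;
  }
  return maxima;
}
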