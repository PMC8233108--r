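// Two-phase Louvain maximization of resolution-scaled modularity
// Q(gamma) = (1/2m) sum_ij (A_ij - gamma k_i k_j / 2m) delta(c_i, c_j)
// on dense symmetric non-negative matrices, plus the z-scored Rand
// pair-counting statistic under the hypergeometric (fixed module sizes) null.
//
// Randomness is a local mt19937 stream seeded from the caller: results are
// bit-identical for identical (matrix, gamma, seed) and independent of R's
// global RNG state.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Fisher-Yates with an explicit modulo draw so the permutation sequence does
// not depend on the standard library's distribution implementation.
void shuffle_order(std::vector<int>& idx, std::mt19937& rng) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)(rng() % (uint32_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// One level of greedy local moves on an n x n dense matrix (column-major).
// comm is modified in place; returns true if any node moved.
bool local_moves(const std::vector<double>& A, int n, double gamma,
                 double total2m, std::vector<int>& comm, std::mt19937& rng) {
  std::vector<double> k(n, 0.0), stot(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += A[i + (size_t)n * j];
    k[i] = s;
  }
  for (int i = 0; i < n; ++i) stot[comm[i]] += k[i];

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> wi(n, 0.0); // weight from node i into each community

  bool any_move = false;
  bool improved = true;
  int pass = 0;
  while (improved && pass < 1000) {
    improved = false;
    ++pass;
    shuffle_order(order, rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int ci = comm[i];
      // links from i to each community (self edge excluded from gain terms)
      std::vector<int> seen;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double a = A[i + (size_t)n * j];
        if (a != 0.0) {
          int cj = comm[j];
          if (wi[cj] == 0.0) seen.push_back(cj);
          wi[cj] += a;
        }
      }
      // remove i from its community
      stot[ci] -= k[i];
      double gain_stay = wi[ci] - gamma * k[i] * stot[ci] / total2m;
      double best_gain = gain_stay;
      int best_c = ci;
      for (int s = 0; s < (int)seen.size(); ++s) {
        int c = seen[s];
        if (c == ci) continue;
        double g = wi[c] - gamma * k[i] * stot[c] / total2m;
        if (g > best_gain + 1e-12) { // strict improvement; ties keep current
          best_gain = g;
          best_c = c;
        }
      }
      if (best_c != ci) {
        comm[i] = best_c;
        improved = true;
        any_move = true;
      }
      stot[comm[i]] += k[i];
      for (int s = 0; s < (int)seen.size(); ++s) wi[seen[s]] = 0.0;
      wi[ci] = 0.0;
    }
  }
  return any_move;
}

void renumber(std::vector<int>& comm, int n, int& ncomm) {
  std::vector<int> map_(n, -1);
  ncomm = 0;
  for (int i = 0; i < n; ++i) {
    if (map_[comm[i]] < 0) map_[comm[i]] = ncomm++;
    comm[i] = map_[comm[i]];
  }
}

} // namespace

// [[Rcpp::export]]
IntegerVector louvain_cpp(NumericMatrix A, double gamma, int seed) {
  int n0 = A.nrow();
  if (n0 != A.ncol()) stop("matrix must be square");
  std::mt19937 rng((uint32_t)seed);

  std::vector<double> W(A.begin(), A.end());
  double total2m = 0.0;
  for (size_t t = 0; t < W.size(); ++t) {
    if (W[t] < 0) stop("weights must be non-negative");
    total2m += W[t];
  }
  if (total2m <= 0) stop("graph has no edges (total weight is zero)");

  int n = n0;
  std::vector<int> assign(n0); // original node -> current-level node
  for (int i = 0; i < n0; ++i) assign[i] = i;

  for (int level = 0; level < 1000; ++level) {
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    bool moved = local_moves(W, n, gamma, total2m, comm, rng);
    int ncomm;
    renumber(comm, n, ncomm);
    for (int i = 0; i < n0; ++i) assign[i] = comm[assign[i]];
    if (!moved || ncomm == n) break;
    // aggregate: B_cd = sum over i in c, j in d of W_ij (diagonal holds
    // intra-community weight, counted as in the flattened matrix)
    std::vector<double> B((size_t)ncomm * ncomm, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        B[comm[i] + (size_t)ncomm * comm[j]] += W[i + (size_t)n * j];
    W.swap(B);
    n = ncomm;
  }

  // contiguous 1-based labels in order of first appearance
  std::vector<int> map_(n0, -1);
  int next = 0;
  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) {
    if (map_[assign[i]] < 0) map_[assign[i]] = ++next;
    out[i] = map_[assign[i]];
  }
  return out;
}

namespace {

// z-scored Rand statistic of Traud, Kelsic, Mucha & Porter for two label
// vectors (values need not be contiguous; they are compacted here).
double zrand_core(const int* x, const int* y, int n) {
  if (n < 2) stop("need at least 2 nodes");
  std::vector<int> xl, yl;
  std::vector<int> xi(n), yi(n);
  for (int i = 0; i < n; ++i) {
    int a = -1;
    for (int t = 0; t < (int)xl.size(); ++t)
      if (xl[t] == x[i]) { a = t; break; }
    if (a < 0) { xl.push_back(x[i]); a = (int)xl.size() - 1; }
    xi[i] = a;
    int b = -1;
    for (int t = 0; t < (int)yl.size(); ++t)
      if (yl[t] == y[i]) { b = t; break; }
    if (b < 0) { yl.push_back(y[i]); b = (int)yl.size() - 1; }
    yi[i] = b;
  }
  int kx = (int)xl.size(), ky = (int)yl.size();
  std::vector<double> nij((size_t)kx * ky, 0.0), ni(kx, 0.0), nj(ky, 0.0);
  for (int i = 0; i < n; ++i) {
    nij[xi[i] + (size_t)kx * yi[i]] += 1.0;
    ni[xi[i]] += 1.0;
    nj[yi[i]] += 1.0;
  }
  double dn = n;
  double M = dn * (dn - 1.0) / 2.0;
  double M1 = 0.0, M2 = 0.0, wab = 0.0, ni3 = 0.0, nj3 = 0.0;
  for (int a = 0; a < kx; ++a) { M1 += ni[a] * (ni[a] - 1.0) / 2.0; ni3 += ni[a] * ni[a] * ni[a]; }
  for (int b = 0; b < ky; ++b) { M2 += nj[b] * (nj[b] - 1.0) / 2.0; nj3 += nj[b] * nj[b] * nj[b]; }
  for (size_t t = 0; t < nij.size(); ++t) wab += nij[t] * (nij[t] - 1.0) / 2.0;

  double muab = M1 * M2 / M;
  double C1 = dn * (dn * dn - 3.0 * dn - 2.0) - 8.0 * (dn + 1.0) * M1 + 4.0 * ni3;
  double C2 = dn * (dn * dn - 3.0 * dn - 2.0) - 8.0 * (dn + 1.0) * M2 + 4.0 * nj3;
  double a1 = 4.0 * M1 - 2.0 * M, a2 = 4.0 * M2 - 2.0 * M;
  double sig2 = M / 16.0
    - (a1 * a1) * (a2 * a2) / (256.0 * M * M)
    + C1 * C2 / (16.0 * dn * (dn - 1.0) * (dn - 2.0))
    + ((a1 * a1) - 4.0 * C1 - 4.0 * M) * ((a2 * a2) - 4.0 * C2 - 4.0 * M) /
      (64.0 * dn * (dn - 1.0) * (dn - 2.0) * (dn - 3.0));
  if (!(sig2 > 1e-12)) return 0.0; // degenerate partitions carry no signal
  return (wab - muab) / std::sqrt(sig2);
}

} // namespace

// [[Rcpp::export]]
double zrand_cpp(IntegerVector p1, IntegerVector p2) {
  if (p1.size() != p2.size()) stop("partitions must cover the same nodes");
  return zrand_core(&p1[0], &p2[0], p1.size());
}

// Mean z-Rand over the given (0-based) column pairs of a node x run matrix.
// [[Rcpp::export]]
double mean_pairwise_zrand_cpp(IntegerMatrix parts, IntegerMatrix pairs) {
  int n = parts.nrow();
  int np = pairs.nrow();
  if (np == 0) stop("no pairs given");
  std::vector<int> a(n), b(n);
  double acc = 0.0;
  for (int p = 0; p < np; ++p) {
    int ca = pairs(p, 0), cb = pairs(p, 1);
    for (int i = 0; i < n; ++i) { a[i] = parts(i, ca); b[i] = parts(i, cb); }
    acc += zrand_core(a.data(), b.data(), n);
  }
  return acc / np;
}

// Fraction of partitions in which each node pair is co-assigned.
// [[Rcpp::export]]
NumericMatrix agreement_cpp(IntegerMatrix parts) {
  int n = parts.nrow(), r = parts.ncol();
  NumericMatrix D(n, n);
  for (int c = 0; c < r; ++c)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (parts(i, c) == parts(j, c)) { D(i, j) += 1.0; }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      D(i, j) /= r;
      D(j, i) = D(i, j);
    }
  return D;
}
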