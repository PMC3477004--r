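#ifndef BGE_SCORER_H
#define BGE_SCORER_H

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

// Local BGe marginal-likelihood scores for one dataset under the
// Geiger-Heckerman Normal-Wishart parameterization (prior mean 0,
// T0 = t * I).  Records where a child is clamped by an intervention are
// dropped from that child's own local score only, so the posterior scatter
// matrix R is held per child whenever a mask is present.
struct BgeScorer {
  int n;            // number of nodes in the domain
  double am, aw, t; // alpha_mu, alpha_w, T0 scale
  std::vector<int> Ncs;              // effective record count per child
  std::vector<std::vector<double>> Rms; // per-child posterior matrix (n*n)
  bool shared;                       // no mask: all children share Rms[0]
  std::unordered_map<uint64_t, double> cache;

  void precompute(const Rcpp::NumericMatrix &X,
                  Rcpp::Nullable<Rcpp::LogicalMatrix> mask) {
    n = X.ncol();
    int N = X.nrow();
    shared = mask.isNull();
    Rcpp::LogicalMatrix mk;
    if (!shared) mk = Rcpp::LogicalMatrix(mask);
    int nR = shared ? 1 : n;
    Ncs.assign(n, 0);
    Rms.assign(nR, std::vector<double>());
    for (int c = 0; c < nR; ++c) {
      std::vector<int> rows;
      rows.reserve(N);
      for (int r = 0; r < N; ++r)
        if (shared || !mk(r, c)) rows.push_back(r);
      int Nc = (int)rows.size();
      if (shared)
        for (int cc = 0; cc < n; ++cc) Ncs[cc] = Nc;
      else
        Ncs[c] = Nc;
      std::vector<double> R(n * n, 0.0);
      std::vector<double> xbar(n, 0.0);
      if (Nc > 0) {
        for (int j = 0; j < n; ++j) {
          double s = 0;
          for (int r : rows) s += X(r, j);
          xbar[j] = s / Nc;
        }
        for (int r : rows)
          for (int a = 0; a < n; ++a) {
            double da = X(r, a) - xbar[a];
            for (int b = a; b < n; ++b)
              R[a * n + b] += da * (X(r, b) - xbar[b]);
          }
        double f = (double)Nc * am / (Nc + am); // prior mean is 0
        for (int a = 0; a < n; ++a)
          for (int b = a; b < n; ++b)
            R[a * n + b] += f * xbar[a] * xbar[b];
      }
      for (int a = 0; a < n; ++a) {
        R[a * n + a] += t;
        for (int b = a + 1; b < n; ++b) R[b * n + a] = R[a * n + b];
      }
      Rms[c] = std::move(R);
    }
  }

  // log det of the sub-matrix of R indexed by idx, via Cholesky
  double logdetSub(const std::vector<double> &R,
                   const std::vector<int> &idx) const {
    int k = (int)idx.size();
    if (k == 0) return 0.0;
    double L[64];
    for (int a = 0; a < k; ++a)
      for (int b = 0; b <= a; ++b)
        L[a * k + b] = R[idx[a] * n + idx[b]];
    double ld = 0.0;
    for (int a = 0; a < k; ++a) {
      for (int b = 0; b < a; ++b) {
        double s = L[a * k + b];
        for (int q = 0; q < b; ++q) s -= L[a * k + q] * L[b * k + q];
        L[a * k + b] = s / L[b * k + b];
      }
      double s = L[a * k + a];
      for (int q = 0; q < a; ++q) s -= L[a * k + q] * L[a * k + q];
      if (s <= 0.0)
        Rcpp::stop("singular posterior precision in BGe score "
                   "(degenerate data or improper prior scale)");
      L[a * k + a] = std::sqrt(s);
      ld += std::log(s);
    }
    return ld;
  }

  double localScore(int child, const std::vector<int> &parents) const {
    int Nc = Ncs[child];
    if (Nc == 0) return 0.0; // empty effective record set: unit evidence
    const std::vector<double> &R = Rms[shared ? 0 : child];
    int p = (int)parents.size();
    double l1 = logdetSub(R, parents);
    std::vector<int> fam(parents);
    fam.push_back(child);
    double l2 = logdetSub(R, fam);
    return 0.5 * (std::log(am) - std::log(Nc + am)) -
           0.5 * Nc * std::log(M_PI) +
           std::lgamma(0.5 * (Nc + aw - n + p + 1)) -
           std::lgamma(0.5 * (aw - n + p + 1)) +
           0.5 * (aw - n + 2 * p + 1) * std::log(t) -
           0.5 * (Nc + aw - n + p + 1) * l2 + 0.5 * (Nc + aw - n + p) * l1;
  }

  // cache key: child in high bits, parent-set bitmask in low bits (n <= 32)
  double localScoreCached(int child, const std::vector<int> &parents) {
    uint64_t key = ((uint64_t)child) << 32;
    for (int p : parents) key |= (1ull << p);
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    double v = localScore(child, parents);
    cache.emplace(key, v);
    return v;
  }
};

#endif
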