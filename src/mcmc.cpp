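#include <Rcpp.h>
#include <functional>
#include <algorithm>
#include "bn_core.h"
#include "bge_scorer.h"
using namespace Rcpp;

// reflect v into [lo, hi]
static double reflectInto(double v, double lo, double hi) {
  if (hi <= lo) return lo;
  double range = 2.0 * (hi - lo);
  v = (v - lo) - std::floor((v - lo) / range) * range;
  if (v < 0) v += range;
  if (v > hi - lo) v = range - v;
  return lo + v;
}

// Per-node energy spectra for the fan-in-restricted partition function:
// for node c, the energies eps(c, pi) = sum_{i != c} |B[i,c] - 1(i in pi)|
// over every parent set pi with |pi| <= fanIn.
static void epsSpectra(const NumericMatrix &B, int fanIn,
                       std::vector<std::vector<double>> &out) {
  int n = B.ncol();
  out.assign(n, std::vector<double>());
  for (int c = 0; c < n; ++c) {
    double base = 0.0;
    std::vector<double> delta; // energy change from including node i
    std::vector<int> others;
    for (int i = 0; i < n; ++i) {
      if (i == c) continue;
      base += std::fabs(B(i, c));
      delta.push_back(std::fabs(B(i, c) - 1.0) - std::fabs(B(i, c)));
      others.push_back(i);
    }
    int m = (int)others.size();
    std::vector<double> &vals = out[c];
    // enumerate subsets of size <= fanIn recursively
    std::vector<int> pick;
    std::function<void(int, double)> rec = [&](int start, double acc) {
      vals.push_back(base + acc);
      if ((int)pick.size() == fanIn) return;
      for (int q = start; q < m; ++q) {
        pick.push_back(q);
        rec(q + 1, acc + delta[q]);
        pick.pop_back();
      }
    };
    rec(0, 0.0);
  }
}

static double logSumExpNeg(const std::vector<double> &eps, double beta) {
  double mn = eps[0];
  for (double e : eps) mn = std::min(mn, e);
  double s = 0.0;
  for (double e : eps) s += std::exp(-beta * (e - mn));
  return -beta * mn + std::log(s);
}

// [[Rcpp::export]]
double log_partition_cpp(NumericMatrix B, double beta, int fan_in) {
  std::vector<std::vector<double>> eps;
  epsSpectra(B, fan_in, eps);
  double lz = 0.0;
  for (auto &v : eps) lz += logSumExpNeg(v, beta);
  return lz;
}

static double energyOf(const Adj &adj, int n, const NumericMatrix &B) {
  double e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) e += std::fabs(B(i, j) - (adj[i * n + j] ? 1.0 : 0.0));
  return e;
}

// Structure MCMC over DAGs (methods: 0 = BN, 1 = BN-I, 2 = BN-E).
// X is the standardized data matrix; mask marks clamped cells (BN-I);
// B is the belief matrix (BN-E).  Uses R's RNG: seed with set.seed().
// [[Rcpp::export]]
List run_mcmc_cpp(NumericMatrix X, Nullable<LogicalMatrix> mask, int method,
                  Nullable<NumericMatrix> Bopt, IntegerVector intervened0,
                  int n_steps, double burn_in_fraction, int fan_in,
                  double beta_max, double beta_step, int thin_store,
                  double am, double aw, double t, bool raw_dags) {
  int n = X.ncol();
  BgeScorer sc;
  sc.am = am;
  sc.aw = aw;
  sc.t = t;
  sc.precompute(X, mask);

  NumericMatrix B;
  std::vector<std::vector<double>> eps;
  if (method == 2) {
    B = NumericMatrix(Bopt);
    epsSpectra(B, fan_in, eps);
  }
  std::vector<int> intervened(intervened0.begin(), intervened0.end());

  Adj adj(n * n, 0);
  std::vector<std::vector<int>> parents(n);
  std::vector<double> local(n);
  double totalLogLik = 0.0;
  for (int c = 0; c < n; ++c) {
    local[c] = sc.localScoreCached(c, parents[c]);
    totalLogLik += local[c];
  }
  double beta = (method == 2) ? beta_max / 2.0 : 0.0;
  double curEnergy = (method == 2) ? energyOf(adj, n, B) : 0.0;
  double curLogZ = (method == 2) ? [&] {
    double lz = 0.0;
    for (auto &v : eps) lz += logSumExpNeg(v, beta);
    return lz;
  }() : 0.0;

  int burnIn = (int)std::floor(n_steps * burn_in_fraction);
  std::vector<double> dirAcc(n * n, 0.0), skelAcc(n * n, 0.0);
  std::vector<double> betaSamples;
  std::vector<double> logScores;
  std::vector<int> logScoreSteps;
  List snapshots;
  long nRetained = 0;
  // acceptance bookkeeping: add, delete, reverse, beta
  long prop[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};

  std::vector<int> cpdag; // status matrix of the current structure
  bool cpdagDirty = true;
  std::vector<Move> moves;

  for (int step = 1; step <= n_steps; ++step) {
    bool betaMove = (method == 2) && (step % 2 == 0);
    if (betaMove) {
      prop[3]++;
      double u = unif_rand();
      double bNew = reflectInto(beta + (2.0 * u - 1.0) * beta_step, 0.0,
                                beta_max);
      double lzNew = 0.0;
      for (auto &v : eps) lzNew += logSumExpNeg(v, bNew);
      double logA = -(bNew - beta) * curEnergy - (lzNew - curLogZ);
      if (logA >= 0.0 || std::log(unif_rand()) < logA) {
        beta = bNew;
        curLogZ = lzNew;
        acc[3]++;
      }
    } else {
      enumerateMoves(adj, n, fan_in, moves);
      int nOld = (int)moves.size();
      int pick = (int)std::floor(unif_rand() * nOld);
      if (pick >= nOld) pick = nOld - 1;
      Move mv = moves[pick];
      prop[mv.kind - 1]++;
      Adj adjNew(adj);
      if (mv.kind == 1) adjNew[mv.i * n + mv.j] = 1;
      else if (mv.kind == 2) adjNew[mv.i * n + mv.j] = 0;
      else { adjNew[mv.i * n + mv.j] = 0; adjNew[mv.j * n + mv.i] = 1; }
      int nNew = countMoves(adjNew, n, fan_in);
      // local scores of affected children
      double dScore = 0.0;
      std::vector<int> paJ(parents[mv.j]);
      std::vector<int> paI;
      if (mv.kind == 1) paJ.push_back(mv.i);
      else if (mv.kind == 2)
        paJ.erase(std::find(paJ.begin(), paJ.end(), mv.i));
      else {
        paJ.erase(std::find(paJ.begin(), paJ.end(), mv.i));
        paI = parents[mv.i];
        paI.push_back(mv.j);
      }
      double newLocJ = sc.localScoreCached(mv.j, paJ);
      dScore += newLocJ - local[mv.j];
      double newLocI = 0.0;
      if (mv.kind == 3) {
        newLocI = sc.localScoreCached(mv.i, paI);
        dScore += newLocI - local[mv.i];
      }
      double dPrior = 0.0, dE = 0.0;
      if (method == 2) {
        if (mv.kind == 1) dE = 1.0 - 2.0 * B(mv.i, mv.j);
        else if (mv.kind == 2) dE = 2.0 * B(mv.i, mv.j) - 1.0;
        else dE = (2.0 * B(mv.i, mv.j) - 1.0) + (1.0 - 2.0 * B(mv.j, mv.i));
        dPrior = -beta * dE; // partition function cancels across structures
      }
      double logA = dScore + dPrior + std::log((double)nOld) -
                    std::log((double)nNew);
      if (logA >= 0.0 || std::log(unif_rand()) < logA) {
        adj = adjNew;
        local[mv.j] = newLocJ;
        parents[mv.j] = paJ;
        if (mv.kind == 3) {
          local[mv.i] = newLocI;
          parents[mv.i] = paI;
        }
        totalLogLik += dScore;
        curEnergy += dE;
        acc[mv.kind - 1]++;
        cpdagDirty = true;
      }
    }

    if (step > burnIn) {
      nRetained++;
      if (raw_dags) {
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j)
            if (adj[i * n + j]) { dirAcc[i * n + j] += 1.0; }
      } else {
        if (cpdagDirty) {
          if (method == 1 && !intervened.empty())
            tsCpdagCore(adj, n, intervened, cpdag);
          else
            dagToCpdagCore(adj, n, cpdag);
          cpdagDirty = false;
        }
        // directed edge adds 1 to its direction; undirected (status 2 in
        // both cells) adds 1 to both directions: the DGE superposition rule
        for (int i = 0; i < n * n; ++i)
          if (cpdag[i]) dirAcc[i] += 1.0;
      }
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (adj[i * n + j]) { skelAcc[i * n + j] += 1.0; skelAcc[j * n + i] += 1.0; }
      if (method == 2) betaSamples.push_back(beta);
      if (step % thin_store == 0) {
        logScores.push_back(totalLogLik);
        logScoreSteps.push_back(step);
        LogicalMatrix snap(n, n);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j)
            snap(i, j) = adj[i * n + j] == 1;
        snapshots.push_back(snap);
      }
    }
  }

  NumericMatrix dirOut(n, n), skelOut(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      dirOut(i, j) = dirAcc[i * n + j];
      skelOut(i, j) = skelAcc[i * n + j];
    }
  LogicalMatrix finalAdj(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      finalAdj(i, j) = adj[i * n + j] == 1;
  return List::create(
      _["edgeCounts"] = dirOut, _["skelCounts"] = skelOut,
      _["nRetained"] = (double)nRetained,
      _["betaSamples"] = NumericVector(betaSamples.begin(), betaSamples.end()),
      _["logScores"] = NumericVector(logScores.begin(), logScores.end()),
      _["logScoreSteps"] = IntegerVector(logScoreSteps.begin(),
                                         logScoreSteps.end()),
      _["proposed"] = NumericVector::create(prop[0], prop[1], prop[2], prop[3]),
      _["accepted"] = NumericVector::create(acc[0], acc[1], acc[2], acc[3]),
      _["snapshots"] = snapshots, _["finalAdj"] = finalAdj,
      _["finalLogLik"] = totalLogLik);
}
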