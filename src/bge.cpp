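#include <Rcpp.h>
#include "bge_scorer.h"
using namespace Rcpp;

// Local BGe score of `child` given `parents` (0-based indices), computed
// cold (no cache).  X must already be on the scale scoring should see.
// [[Rcpp::export]]
double bge_local_score_cpp(NumericMatrix X, int child0, IntegerVector parents0,
                           double am, double aw, double t,
                           Nullable<LogicalMatrix> mask) {
  BgeScorer sc;
  sc.am = am;
  sc.aw = aw;
  sc.t = t;
  sc.precompute(X, mask);
  std::vector<int> pa(parents0.begin(), parents0.end());
  return sc.localScore(child0, pa);
}
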