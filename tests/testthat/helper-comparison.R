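# The replicated Raf comparison is expensive, and two distinct scientific
# checks (reconstruction-accuracy ordering and the beta-posterior contrast)
# read from the same runs, so the result is computed once per session.
.comparisonCache <- new.env(parent = emptyenv())

rafComparisonRuns <- function() {
  if (!is.null(.comparisonCache$cmp)) return(.comparisonCache$cmp)
  gold <- rafGoldStandard()
  reps <- simulateReplicates(gold, k = 5, design = rafDesign(), seed = 1)
  schemes <- list(
    BN = list(method = "BN"),
    `BN-I` = list(method = "BN-I"),
    `BN-E100` = list(method = "BN-E", beliefs = makeB100(gold)),
    `BN-E50` = list(method = "BN-E", beliefs = makeB50(gold, seed = 1)))
  cmp <- compareMethods(reps, schemes, gold,
                        mcmcConfig(nSteps = 1e5, seed = 1))
  .comparisonCache$cmp <- cmp
  cmp
}
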