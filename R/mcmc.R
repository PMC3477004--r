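#' MCMC configuration
#'
#' Defaults are the settings used for the reference experiments:
#' 5e5 steps with the first half discarded as burn-in, fan-in 3, a uniform
#' beta prior on `[0, betaMax]` with `betaMax = 30`, a reflected-uniform
#' beta proposal of half-width `betaStep = 1`, and thinned diagnostics
#' every 100 steps. The sampler starts from the empty graph and, for BN-E,
#' from `beta = betaMax / 2`.
#'
#' @param nSteps total number of MCMC steps (BN-E counts each sub-move).
#' @param burnInFraction fraction of initial steps discarded, in (0, 1).
#' @param fanIn maximum in-degree of sampled structures.
#' @param seed integer seed controlling every random draw of the run.
#' @param betaMax upper bound of the sampled inverse temperature.
#' @param betaStep half-width of the reflected-uniform beta proposal.
#' @param thinStore interval for log-score records and structure snapshots.
#' @param rawDags accumulate raw DAG samples instead of equivalence-class
#'   representatives (sensitivity analysis only).
#' @return a validated configuration list.
#' @export
mcmcConfig <- function(nSteps = 5e5, burnInFraction = 0.5, fanIn = 3,
                       seed = 1, betaMax = 30, betaStep = 1,
                       thinStore = 100, rawDags = FALSE) {
  if (nSteps < 2) stop("nSteps must be at least 2")
  if (burnInFraction <= 0 || burnInFraction >= 1)
    stop("burnInFraction must lie strictly between 0 and 1")
  if (fanIn < 1) stop("fanIn must be at least 1")
  if (betaMax < 0 || betaStep < 0) stop("beta settings must be non-negative")
  list(nSteps = as.integer(nSteps), burnInFraction = burnInFraction,
       fanIn = as.integer(fanIn), seed = as.integer(seed),
       betaMax = betaMax, betaStep = betaStep,
       thinStore = as.integer(thinStore), rawDags = isTRUE(rawDags))
}

#' Metropolis-Hastings acceptance probability for a structure move
#'
#' `min(1, exp(dLogLik + priorLogRatio) * |N(old)| / |N(new)|)` where
#' `|N(.)|` is the single-edge proposal-neighborhood size from
#' [neighborMoves()]. `priorLogRatio` is 0 under the flat structure prior
#' (BN, BN-I) and `-beta * (E(new) - E(old))` under the Gibbs prior (BN-E);
#' the partition function cancels between two structures at the same beta.
#'
#' @param old,new [BnNetwork-class] structures (new in the neighborhood of
#'   old).
#' @param priorLogRatio log prior ratio new/old (default 0, flat prior).
#' @inheritParams logMarginalLikelihood
#' @param fanIn fan-in restriction defining the neighborhoods.
#' @return acceptance probability in `[0, 1]`.
#' @export
structureAcceptance <- function(old, new, data, hyper = NULL, mask = NULL,
                                priorLogRatio = 0, fanIn = 3,
                                standardize = TRUE) {
  dLog <- logMarginalLikelihood(new, data, hyper, mask, standardize) -
    logMarginalLikelihood(old, data, hyper, mask, standardize)
  nOld <- neighborMoves(old, fanIn)$count
  nNew <- neighborMoves(new, fanIn)$count
  min(1, exp(dLog + priorLogRatio) * nOld / nNew)
}

#' Reflected-uniform proposal for the inverse temperature
#'
#' Draws uniformly from `[betaOld - betaStep, betaOld + betaStep]` and
#' reflects at 0 and `betaMax`, which keeps the proposal density symmetric
#' so its ratio cancels in the joint acceptance rule.
#'
#' @param betaOld current beta in `[0, betaMax]`.
#' @param config an [mcmcConfig()] list (uses `betaStep`, `betaMax`).
#' @return proposed beta, always within `[0, betaMax]`.
#' @export
proposeBeta <- function(betaOld, config) {
  v <- betaOld + stats::runif(1, -config$betaStep, config$betaStep)
  lo <- 0; hi <- config$betaMax
  if (hi <= lo) return(lo)
  range <- 2 * (hi - lo)
  v <- (v - lo) %% range
  lo + ifelse(v > hi - lo, range - v, v)
}

#' Joint acceptance probability for (structure, beta) sub-moves
#'
#' The joint posterior factorizes as P(D|M) P(M|beta) P(beta), and moves
#' alter exactly one of structure and beta. A structure sub-move at fixed
#' beta reduces to [structureAcceptance()] with `priorLogRatio =
#' -beta * dE`. A beta sub-move keeps the likelihood fixed but the
#' partition functions do not cancel: the acceptance is
#' `min(1, exp(-(bNew - bOld) * E(M)) * Z(bOld) / Z(bNew))` under the
#' uniform beta prior (symmetric proposal ratios drop out).
#'
#' @param oldNet,newNet [BnNetwork-class] structures.
#' @param oldBeta,newBeta inverse temperatures before/after the move.
#' @param B a [BeliefMatrix-class] object.
#' @param config an [mcmcConfig()] list (uses `fanIn`).
#' @inheritParams logMarginalLikelihood
#' @return acceptance probability in `[0, 1]`.
#' @export
jointAcceptance <- function(oldNet, oldBeta, newNet, newBeta, data,
                            hyper = NULL, B, config = mcmcConfig(),
                            mask = NULL, standardize = TRUE) {
  oldNet <- asNetwork(oldNet); newNet <- asNetwork(newNet)
  structChanged <- !identical(oldNet@adj, newNet@adj)
  betaChanged <- newBeta != oldBeta
  if (structChanged && betaChanged)
    stop("sub-move discipline: exactly one of structure and beta may change")
  if (structChanged) {
    dE <- energy(newNet, B) - energy(oldNet, B)
    structureAcceptance(oldNet, newNet, data, hyper, mask,
                        priorLogRatio = -oldBeta * dE,
                        fanIn = config$fanIn, standardize = standardize)
  } else {
    e <- energy(oldNet, B)
    logA <- -(newBeta - oldBeta) * e -
      (logPartition(newBeta, B, config$fanIn) -
         logPartition(oldBeta, B, config$fanIn))
    min(1, exp(logA))
  }
}

#' Run structure MCMC
#'
#' Metropolis-Hastings sampling over DAG structures using the BGe marginal
#' likelihood. Three schemes:
#' \describe{
#'   \item{BN}{flat structure prior, all records scored.}
#'   \item{BN-I}{requires `mask`; measurements of a clamped node are
#'     excluded from that node's local score, and posterior accumulation
#'     uses TS-equivalence classes (every edge at an intervened node is
#'     directed).}
#'   \item{BN-E}{requires `beliefs`; samples structures jointly with the
#'     inverse temperature beta of an energy-based Gibbs prior, strictly
#'     alternating structure and beta sub-moves.}
#' }
#' At every retained (post-burn-in) step the current structure is
#' transformed to its equivalence-class representative and tallied:
#' directed class edges add 1 to their direction, undirected class edges
#' add 1 to both directions (the DGE superposition rule); a separate
#' symmetric accumulator tallies plain adjacency for the UGE criterion.
#' Runs with the same data, configuration and seed are bit-reproducible.
#'
#' @param data numeric matrix (records x nodes) with node names as
#'   colnames; columns are standardized internally over all records.
#' @param method `"BN"`, `"BN-I"` or `"BN-E"`.
#' @param config an [mcmcConfig()] list.
#' @param mask logical clamp matrix (BN-I).
#' @param beliefs a [BeliefMatrix-class] (BN-E).
#' @param hyper optional [bgeHyperparams()] override.
#' @return an [McmcTrace-class] object.
#' @export
runMcmc <- function(data, method = c("BN", "BN-I", "BN-E"),
                    config = mcmcConfig(), mask = NULL, beliefs = NULL,
                    hyper = NULL) {
  method <- match.arg(method)
  checkDataset(data)
  nodes <- colnames(data)
  if (method == "BN-I" && is.null(mask))
    stop("method BN-I requires an intervention mask")
  if (method == "BN-E" && is.null(beliefs))
    stop("method BN-E requires a belief matrix")
  if (method != "BN-I") mask <- NULL
  checkMask(mask, data)
  if (is.null(hyper)) hyper <- bgeHyperparams(ncol(data))
  B <- NULL
  if (method == "BN-E") {
    beliefs <- alignBeliefs(beliefs, nodes)
    B <- beliefs@beliefs
  }
  intervened <- integer(0)
  if (method == "BN-I") {
    colnames(mask) <- nodes
    intervened <- which(colSums(mask) > 0) - 1L
  }
  x <- standardizeColumns(data)
  methodCode <- match(method, c("BN", "BN-I", "BN-E")) - 1L
  set.seed(config$seed)
  res <- run_mcmc_cpp(x, mask, methodCode, B, as.integer(intervened),
                      config$nSteps, config$burnInFraction, config$fanIn,
                      config$betaMax, config$betaStep, config$thinStore,
                      hyper$alphaMu, hyper$alphaW, hyper$t0Scale,
                      config$rawDags)
  kinds <- c("add", "delete", "reverse", "beta")
  accept <- data.frame(kind = kinds, proposed = res$proposed,
                       accepted = res$accepted,
                       rate = ifelse(res$proposed > 0,
                                     res$accepted / res$proposed, NA_real_))
  ec <- res$edgeCounts; sk <- res$skelCounts
  dimnames(ec) <- dimnames(sk) <- list(nodes, nodes)
  new("McmcTrace", method = method, nodes = nodes, edgeCounts = ec,
      skelCounts = sk, nRetained = res$nRetained,
      betaSamples = as.numeric(res$betaSamples),
      logScores = as.numeric(res$logScores),
      logScoreSteps = as.integer(res$logScoreSteps),
      acceptance = accept, snapshots = as.list(res$snapshots),
      config = c(config, list(method = method,
                              intervened = nodes[intervened + 1L])))
}

setMethod("show", "McmcTrace", function(object) {
  cat("McmcTrace (", object@method, "): ", length(object@nodes), " nodes, ",
      object@nRetained, " retained samples\n", sep = "")
  if (length(object@betaSamples))
    cat("beta: median", signif(stats::median(object@betaSamples), 3), "\n")
})

#' @rdname bnNetwork
#' @export
setMethod("nodeNames", "McmcTrace", function(x) x@nodes)

#' Two-run convergence check
#'
#' Compares directed edge posteriors from two runs with identical
#' configurations but different seeds. Agreement is a necessary but not a
#' sufficient condition for convergence, and the returned report says so.
#'
#' @param traceA,traceB [McmcTrace-class] objects of the same shape.
#' @param threshold maximum tolerated absolute posterior difference
#'   (default 0.1).
#' @return list with `maxDiff`, `meanDiff`, `pass`, a two-column `scatter`
#'   data.frame of paired posteriors, and a cautionary `note`.
#' @export
checkConvergence <- function(traceA, traceB, threshold = 0.1) {
  if (!identical(traceA@nodes, traceB@nodes))
    stop("traces are over different node sets")
  pa <- edgePosteriors(traceA)@directed
  pb <- edgePosteriors(traceB)@directed
  off <- row(pa) != col(pa)
  d <- abs(pa - pb)[off]
  list(maxDiff = max(d), meanDiff = mean(d), pass = max(d) <= threshold,
       threshold = threshold,
       scatter = data.frame(runA = pa[off], runB = pb[off]),
       note = paste("Posterior agreement between two seeds is a necessary",
                    "but not a sufficient condition for convergence."))
}

#' Exact edge posteriors by exhaustive DAG enumeration
#'
#' Enumerates every DAG on the data's nodes (at most 5), weights each by
#' its marginal likelihood times, optionally, the Gibbs prior factor
#' `exp(-beta * E)` (the partition function is constant across structures
#' and cancels), transforms each DAG to its equivalence-class
#' representative with the same accumulation rule as [runMcmc()], and
#' returns the exact posterior edge probabilities. This is the reference
#' the samplers are validated against on small systems.
#'
#' @inheritParams runMcmc
#' @param beta fixed inverse temperature weighting `beliefs` (default 0).
#' @param fanIn fan-in restriction of the enumerated space.
#' @return an [EdgePosterior-class] object.
#' @export
exactEdgePosterior <- function(data, hyper = NULL, mask = NULL,
                               beliefs = NULL, beta = 0, fanIn = 3,
                               rawDags = FALSE) {
  checkDataset(data)
  nodes <- colnames(data)
  n <- length(nodes)
  if (n > 5) stop("exhaustive enumeration limited to 5 nodes")
  dags <- enumerateDags(n, fanIn = min(fanIn, n - 1), nodes = nodes)
  if (is.null(hyper)) hyper <- bgeHyperparams(n)
  cache <- newScoreCache()
  logw <- vapply(dags, function(g) {
    s <- logMarginalLikelihood(g, data, hyper, mask, cache = cache)
    if (!is.null(beliefs) && beta > 0) s <- s - beta * energy(g, beliefs)
    s
  }, numeric(1))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  intervened <- character(0)
  if (!is.null(mask)) {
    colnames(mask) <- nodes
    intervened <- nodes[colSums(mask) > 0]
  }
  dir <- matrix(0, n, n, dimnames = list(nodes, nodes))
  skel <- dir
  for (k in seq_along(dags)) {
    g <- dags[[k]]
    if (rawDags) {
      dir <- dir + w[k] * (g@adj * 1)
    } else {
      cp <- if (length(intervened)) tsCpdag(g, intervened) else dagToCpdag(g)
      dir <- dir + w[k] * ((cp@directed | cp@undirected) * 1)
    }
    skel <- skel + w[k] * ((g@adj | t(g@adj)) * 1)
  }
  new("EdgePosterior", nodes = nodes, directed = dir, skeleton = skel,
      nSamples = length(dags))
}

#' Persist a trace to plain-text files
#'
#' Writes the directed posterior matrix as CSV, beta samples as a
#' single-column TSV (BN-E only), and run metadata (configuration,
#' acceptance statistics, retained-sample count) as JSON.
#'
#' @param trace an [McmcTrace-class] object.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix (default the method name).
#' @return invisibly, the paths written.
#' @export
writeTrace <- function(trace, dir, prefix = trace@method) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  post <- edgePosteriors(trace)
  pPath <- file.path(dir, paste0(prefix, "_posterior.csv"))
  utils::write.csv(post@directed, pPath, quote = FALSE)
  sPath <- file.path(dir, paste0(prefix, "_skeleton.csv"))
  utils::write.csv(post@skeleton, sPath, quote = FALSE)
  paths <- c(pPath, sPath)
  if (length(trace@betaSamples)) {
    bPath <- file.path(dir, paste0(prefix, "_beta.tsv"))
    utils::write.table(data.frame(beta = trace@betaSamples), bPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, bPath)
  }
  meta <- list(method = trace@method, nodes = trace@nodes,
               nRetained = trace@nRetained,
               config = trace@config[setdiff(names(trace@config), "method")],
               acceptance = trace@acceptance)
  mPath <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, mPath))
}
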