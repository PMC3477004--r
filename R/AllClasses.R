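#' @import methods
NULL

#' Directed acyclic network over named nodes
#'
#' `BnNetwork` holds a directed graph as a logical adjacency matrix with the
#' convention row = parent, column = child. Objects are validated to be
#' square, self-edge free and acyclic; they are the structures scored by
#' [logMarginalLikelihood()] and sampled by [runMcmc()].
#'
#' @slot nodes character vector of node identifiers, fixing the order used
#'   by every matrix in the package.
#' @slot adj logical matrix; `adj[i, j]` is `TRUE` iff there is a directed
#'   edge `nodes[i] -> nodes[j]`.
#' @export
setClass("BnNetwork",
  representation(nodes = "character", adj = "matrix"))

setValidity("BnNetwork", function(object) {
  a <- object@adj
  if (!is.logical(a)) return("adjacency must be a logical matrix")
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (nrow(a) != length(object@nodes))
    return("adjacency dimension must match number of nodes")
  if (anyDuplicated(object@nodes)) return("node names must be unique")
  if (any(diag(a))) return("self-edges are not allowed")
  if (!is_acyclic_cpp(a)) return("graph contains a directed cycle")
  TRUE
})

#' Completed partially directed graph (equivalence-class representative)
#'
#' A `Cpdag` represents a Markov-equivalence class (or a TS-equivalence
#' class under interventions): compelled edges are directed, reversible
#' edges undirected. Produced by [dagToCpdag()] and [tsCpdag()].
#'
#' @slot nodes character vector of node identifiers.
#' @slot directed logical matrix of compelled edges (`[i, j]` = edge i -> j).
#' @slot undirected symmetric logical matrix of reversible adjacencies.
#' @export
setClass("Cpdag",
  representation(nodes = "character", directed = "matrix",
                 undirected = "matrix"))

setValidity("Cpdag", function(object) {
  d <- object@directed; u <- object@undirected
  if (!is.logical(d) || !is.logical(u)) return("edge matrices must be logical")
  if (any(dim(d) != length(object@nodes)) || any(dim(u) != length(object@nodes)))
    return("edge matrix dimensions must match node count")
  if (!identical(u, t(u))) return("undirected matrix must be symmetric")
  if (any(diag(d)) || any(diag(u))) return("self-edges are not allowed")
  if (any((d | t(d)) & u))
    return("a node pair cannot be both directed and undirected")
  TRUE
})

#' Belief matrix of prior edge knowledge
#'
#' Entry `beliefs[i, j]` in `[0, 1]` expresses prior belief in the directed
#' edge i -> j: 0.5 means no information, values near 1 confident presence,
#' values near 0 confident absence. The diagonal is fixed at 0 because
#' structures never contain self-edges. Input to the energy-based Gibbs
#' structure prior of the BN-E sampler.
#'
#' @slot nodes character vector of node identifiers.
#' @slot beliefs numeric matrix with entries in `[0, 1]`, zero diagonal.
#' @export
setClass("BeliefMatrix",
  representation(nodes = "character", beliefs = "matrix"))

setValidity("BeliefMatrix", function(object) {
  b <- object@beliefs
  if (!is.numeric(b) || nrow(b) != ncol(b)) return("beliefs must be square numeric")
  if (nrow(b) != length(object@nodes)) return("dimension/node mismatch")
  if (any(b < 0 | b > 1)) return("belief entries must lie in [0, 1]")
  if (any(diag(b) != 0)) return("diagonal belief entries must be 0")
  TRUE
})

#' MCMC trace of a structure-sampling run
#'
#' Accumulated output of [runMcmc()]: post-burn-in directed-edge tallies
#' (after equivalence-class transformation), symmetric adjacency tallies,
#' sampled inverse-temperature values (BN-E only), a thinned log-score
#' series, acceptance statistics and thinned structure snapshots.
#'
#' @slot method one of `"BN"`, `"BN-I"`, `"BN-E"`.
#' @slot nodes node identifiers.
#' @slot edgeCounts numeric matrix of directed tallies (undirected CPDAG
#'   edges contribute to both directions).
#' @slot skelCounts symmetric numeric matrix of adjacency tallies.
#' @slot nRetained number of post-burn-in samples.
#' @slot betaSamples numeric vector of retained beta values (BN-E).
#' @slot logScores thinned log marginal-likelihood series.
#' @slot logScoreSteps step indices of `logScores`.
#' @slot acceptance data.frame with proposed/accepted counts per move kind.
#' @slot snapshots list of thinned adjacency matrices (diagnostics only).
#' @slot config the configuration list the run was started with.
#' @export
setClass("McmcTrace",
  representation(method = "character", nodes = "character",
                 edgeCounts = "matrix", skelCounts = "matrix",
                 nRetained = "numeric", betaSamples = "numeric",
                 logScores = "numeric", logScoreSteps = "integer",
                 acceptance = "data.frame", snapshots = "list",
                 config = "list"))

#' Marginal posterior probabilities of edges
#'
#' `directed[i, j]` is the posterior probability of the directed edge
#' i -> j under the DGE superposition rule (an undirected equivalence-class
#' edge counts towards both directions); `skeleton[i, j]` is the posterior
#' probability that i and j are adjacent in either orientation, accumulated
#' directly from samples.
#'
#' @slot nodes node identifiers.
#' @slot directed numeric matrix in `[0, 1]`.
#' @slot skeleton symmetric numeric matrix in `[0, 1]`.
#' @slot nSamples number of posterior samples behind the estimates.
#' @export
setClass("EdgePosterior",
  representation(nodes = "character", directed = "matrix",
                 skeleton = "matrix", nSamples = "numeric"))

#' Gold-standard network with a description
#'
#' The known true structure against which reconstructions are evaluated,
#' e.g. the Raf signalling pathway from [rafGoldStandard()].
#'
#' @slot network a [BnNetwork-class] object.
#' @slot description free-text provenance of the network.
#' @export
setClass("GoldStandard",
  representation(network = "BnNetwork", description = "character"))
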