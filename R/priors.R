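#' Construct a belief matrix
#'
#' @param b square numeric matrix with entries in `[0, 1]`; the diagonal is
#'   forced to 0 (structures never contain self-edges).
#' @param nodes node names; default the matrix rownames.
#' @return a [BeliefMatrix-class] object.
#' @export
beliefMatrix <- function(b, nodes = rownames(b)) {
  if (is.null(nodes)) stop("node names required")
  if (any(b < 0 | b > 1)) stop("belief entries must lie in [0, 1]")
  diag(b) <- 0
  dimnames(b) <- list(nodes, nodes)
  new("BeliefMatrix", nodes = as.character(nodes), beliefs = b)
}

#' @rdname beliefMatrix
#' @param x a [BeliefMatrix-class] object.
#' @export
setMethod("beliefs", "BeliefMatrix", function(x) x@beliefs)

#' @rdname bnNetwork
#' @export
setMethod("nodeNames", "BeliefMatrix", function(x) x@nodes)

setMethod("show", "BeliefMatrix", function(object) {
  b <- object@beliefs[upper.tri(object@beliefs) | lower.tri(object@beliefs)]
  cat("BeliefMatrix on", length(object@nodes), "nodes;",
      sum(b != 0.5), "informative entries\n")
})

alignBeliefs <- function(B, nodes) {
  if (!setequal(B@nodes, nodes)) stop("belief matrix node set mismatch")
  beliefMatrix(B@beliefs[nodes, nodes, drop = FALSE], nodes)
}

#' @rdname energy
#' @export
setMethod("energy", signature("BnNetwork", "BeliefMatrix"), function(net, B) {
  B <- alignBeliefs(B, net@nodes)
  m <- net@adj * 1
  e <- abs(B@beliefs - m)
  diag(e) <- 0
  sum(e)
})

#' @rdname energy
#' @export
setMethod("energy", signature("GoldStandard", "BeliefMatrix"),
          function(net, B) energy(net@network, B))

#' Gibbs structure-prior specification
#'
#' @param beta non-negative inverse temperature weighting the prior
#'   knowledge against the data; 0 makes the prior flat, large values
#'   concentrate it on the minimum-energy structure.
#' @param betaMax upper bound of the admissible beta range (default 30).
#' @param fanIn fan-in restriction used by the partition function.
#' @return a validated list of class `"GibbsPriorSpec"`.
#' @export
gibbsPriorSpec <- function(beta, betaMax = 30, fanIn = 3) {
  if (beta < 0 || beta > betaMax) stop("beta must lie in [0, betaMax]")
  structure(list(beta = beta, betaMax = betaMax, fanIn = fanIn),
            class = "GibbsPriorSpec")
}

#' Fan-in-restricted log partition function of the Gibbs prior
#'
#' The normalizer is approximated by a product over nodes of sums over all
#' parent sets of size at most `fanIn` of `exp(-beta * eps)`, where `eps`
#' is the node-wise energy of that parent set. The per-node sum ranges over
#' all parent sets, not only those jointly forming a DAG, so for static
#' networks the result is an upper bound on the true DAG-space normalizer;
#' the fan-in restriction keeps the bound tight. Ratios of the structure
#' prior at fixed beta never involve this term, but beta-moves of the
#' joint sampler do.
#'
#' @param beta non-negative inverse temperature.
#' @param B a [BeliefMatrix-class] object.
#' @param fanIn fan-in restriction (default 3).
#' @return log of the (upper-bound) partition function.
#' @export
logPartition <- function(beta, B, fanIn = 3) {
  if (beta < 0) stop("beta must be non-negative")
  if (fanIn < 0) stop("fanIn must be non-negative")
  log_partition_cpp(B@beliefs, beta, as.integer(fanIn))
}

#' Log Gibbs structure prior
#'
#' `-beta * energy(net, B) - logPartition(beta, B, fanIn)`. At `beta = 0`
#' the prior is constant over structures; prior *ratios* between two
#' structures at the same beta are `exp(-beta * (E1 - E2))` and do not
#' involve the partition function.
#'
#' @param net a [BnNetwork-class] object.
#' @param spec a [gibbsPriorSpec()] list.
#' @param B a [BeliefMatrix-class] object.
#' @return log prior density (up to the DAG-space truncation of Z).
#' @export
logStructurePrior <- function(net, spec, B) {
  -spec$beta * energy(asNetwork(net), B) -
    logPartition(spec$beta, B, spec$fanIn)
}

#' Belief matrices encoding perfect and half-correct knowledge
#'
#' `makeB100` encodes completely correct prior knowledge: entry 1 where
#' the gold standard has a directed edge, 0 elsewhere, so the gold network
#' has energy zero. `makeB50` starts from `makeB100` and flips a seeded,
#' uniformly random half of the off-diagonal ordered-pair entries
#' (`floor(N(N-1)/2)` of them) to `1 - value`, leaving the other half
#' correct; entries stay binary. The realized flipped set is recorded in
#' the `"flipped"` attribute of the returned object.
#'
#' @param gold a [GoldStandard-class] or [BnNetwork-class] object.
#' @param seed integer seed selecting which half is corrupted.
#' @return a [BeliefMatrix-class] object.
#' @examples
#' g <- rafGoldStandard()
#' energy(g, makeB100(g))   # 0
#' @export
makeB100 <- function(gold) {
  net <- asNetwork(gold)
  beliefMatrix(net@adj * 1, net@nodes)
}

#' @rdname makeB100
#' @export
makeB50 <- function(gold, seed) {
  net <- asNetwork(gold)
  n <- length(net@nodes)
  b <- net@adj * 1
  off <- which(row(b) != col(b))
  nFlip <- floor(length(off) / 2)
  # seeded selection without disturbing the caller's RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  sel <- sample(off, nFlip)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  b[sel] <- 1 - b[sel]
  out <- beliefMatrix(b, net@nodes)
  attr(out, "flipped") <- sel
  out
}
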