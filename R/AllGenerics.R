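#' @rdname bnNetwork
#' @param object,x an object of the documented class
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname bnNetwork
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname bnNetwork
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname dagToCpdag
#' @export
setGeneric("directedEdges", function(x) standardGeneric("directedEdges"))

#' @rdname dagToCpdag
#' @export
setGeneric("undirectedEdges", function(x) standardGeneric("undirectedEdges"))

#' @rdname beliefMatrix
#' @export
setGeneric("beliefs", function(x) standardGeneric("beliefs"))

#' Energy of a structure relative to prior knowledge
#'
#' The energy of a network is the entry-wise absolute disagreement between
#' its adjacency matrix and a belief matrix B, summed over all ordered node
#' pairs (the diagonal is excluded; structures never contain self-edges).
#' It is zero for a perfect match between the prior knowledge and the
#' structure and grows with the mismatch. The Gibbs structure prior used by
#' the BN-E sampler is `exp(-beta * E)` up to normalization.
#'
#' @param net a [BnNetwork-class] (or [GoldStandard-class]).
#' @param B a [BeliefMatrix-class] on the same nodes.
#' @return non-negative numeric scalar.
#' @seealso [logStructurePrior()], [logPartition()]
#' @examples
#' g <- bnNetwork(edges = data.frame(from = "A", to = "B"),
#'                nodes = c("A", "B"))
#' energy(g, makeB100(g))  # 0: perfect match
#' @export
setGeneric("energy", function(net, B) standardGeneric("energy"))
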