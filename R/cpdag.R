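cpdagFromStatus <- function(st, nodes) {
  d <- st == 1L
  u <- st == 2L
  dimnames(d) <- dimnames(u) <- list(nodes, nodes)
  new("Cpdag", nodes = nodes, directed = d, undirected = u)
}

#' Markov-equivalence class of a DAG as a CPDAG
#'
#' Converts a DAG to the completed partially directed graph of its
#' Markov-equivalence class: the skeleton is preserved, every v-structure
#' (a pair of converging, non-adjacent parents) stays directed, and the
#' remaining compelled orientations are derived by rule-based closure
#' (Meek orientation rules). Edges whose orientation is not compelled are
#' reported undirected.
#'
#' @param net a [BnNetwork-class] object (must be acyclic, which the class
#'   guarantees).
#' @return a [Cpdag-class] object.
#' @examples
#' chain <- bnNetwork(edges = data.frame(from = c("A", "B"), to = c("B", "C")))
#' dagToCpdag(chain)         # fully undirected: A - B - C
#' @export
dagToCpdag <- function(net) {
  net <- asNetwork(net)
  cpdagFromStatus(dag_to_cpdag_cpp(net@adj), net@nodes)
}

#' TS-equivalence class of a DAG under interventions
#'
#' Two DAGs are transition-sequence (TS) equivalent if they share skeleton,
#' v-structures and the parent sets of every manipulated variable. The
#' class representative is obtained by attaching two dummy parent nodes to
#' each intervened node, converting the augmented DAG to its CPDAG, and
#' stripping the dummies; as a consequence every edge incident to an
#' intervened node comes out directed. The dummy nodes are purely internal
#' and never appear in the result.
#'
#' @param net a [BnNetwork-class] object.
#' @param intervened character vector of intervened node names (may be
#'   empty, in which case the result equals [dagToCpdag()]).
#' @return a [Cpdag-class] object.
#' @examples
#' chain <- bnNetwork(edges = data.frame(from = c("A", "B"), to = c("B", "C")))
#' tsCpdag(chain, "B")       # all edges directed: A -> B -> C
#' @export
tsCpdag <- function(net, intervened = character()) {
  net <- asNetwork(net)
  bad <- setdiff(intervened, net@nodes)
  if (length(bad)) stop("intervened nodes not in network: ",
                        paste(bad, collapse = ", "))
  idx <- match(unique(intervened), net@nodes) - 1L
  cpdagFromStatus(ts_cpdag_cpp(net@adj, as.integer(idx)), net@nodes)
}

#' @rdname dagToCpdag
#' @param x a [Cpdag-class] object.
#' @export
setMethod("directedEdges", "Cpdag", function(x) {
  idx <- which(x@directed, arr.ind = TRUE)
  data.frame(from = x@nodes[idx[, 1]], to = x@nodes[idx[, 2]],
             stringsAsFactors = FALSE)
})

#' @rdname dagToCpdag
#' @export
setMethod("undirectedEdges", "Cpdag", function(x) {
  idx <- which(x@undirected & upper.tri(x@undirected), arr.ind = TRUE)
  data.frame(from = x@nodes[idx[, 1]], to = x@nodes[idx[, 2]],
             stringsAsFactors = FALSE)
})

#' @rdname bnNetwork
#' @export
setMethod("nodeNames", "Cpdag", function(x) x@nodes)

setMethod("show", "Cpdag", function(object) {
  cat("Cpdag with", length(object@nodes), "nodes:",
      sum(object@directed), "directed and",
      sum(object@undirected) / 2, "undirected edges\n")
})
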