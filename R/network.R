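#' Construct a directed acyclic network
#'
#' Builds a [BnNetwork-class] from either a logical adjacency matrix
#' (row = parent, column = child) or an edge data.frame with columns
#' `from` and `to`. Node order is taken from `nodes` (or the matrix
#' dimnames) and fixes the order of every matrix derived from the object.
#'
#' @param adjacency logical (or 0/1) square matrix.
#' @param nodes character vector of node names; defaults to the matrix
#'   rownames or, for an edge list, the sorted union of endpoints.
#' @param edges data.frame with character columns `from`, `to`.
#' @return a validated [BnNetwork-class] object.
#' @examples
#' chain <- bnNetwork(edges = data.frame(from = c("A", "B"), to = c("B", "C")),
#'                    nodes = c("A", "B", "C"))
#' adjacency(chain)
#' @export
bnNetwork <- function(adjacency = NULL, nodes = NULL, edges = NULL) {
  if (is.null(adjacency) && is.null(edges))
    stop("supply either an adjacency matrix or an edge data.frame")
  if (!is.null(adjacency)) {
    if (!is.matrix(adjacency)) stop("adjacency must be a matrix")
    if (is.null(nodes)) nodes <- rownames(adjacency)
    if (is.null(nodes)) nodes <- paste0("X", seq_len(nrow(adjacency)))
    a <- matrix(as.logical(adjacency), nrow(adjacency), ncol(adjacency))
  } else {
    from <- as.character(edges$from); to <- as.character(edges$to)
    if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
    miss <- setdiff(c(from, to), nodes)
    if (length(miss)) stop("edge endpoints not in nodes: ",
                           paste(miss, collapse = ", "))
    a <- matrix(FALSE, length(nodes), length(nodes))
    a[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  }
  dimnames(a) <- list(nodes, nodes)
  new("BnNetwork", nodes = as.character(nodes), adj = a)
}

#' @rdname bnNetwork
#' @export
emptyNetwork <- function(nodes) {
  bnNetwork(adjacency = matrix(FALSE, length(nodes), length(nodes)),
            nodes = nodes)
}

#' @rdname bnNetwork
#' @export
setMethod("nodeNames", "BnNetwork", function(x) x@nodes)

#' @rdname bnNetwork
#' @export
setMethod("adjacency", "BnNetwork", function(x) x@adj)

#' @rdname bnNetwork
#' @export
setMethod("edgeCount", "BnNetwork", function(x) sum(x@adj))

#' @rdname bnNetwork
#' @export
setMethod("nodeNames", "GoldStandard", function(x) x@network@nodes)

#' @rdname bnNetwork
#' @export
setMethod("adjacency", "GoldStandard", function(x) x@network@adj)

#' Edges of a network as a data.frame
#' @param net a [BnNetwork-class] object.
#' @return data.frame with character columns `from` and `to`.
#' @export
networkEdges <- function(net) {
  net <- asNetwork(net)
  idx <- which(net@adj, arr.ind = TRUE)
  data.frame(from = net@nodes[idx[, 1]], to = net@nodes[idx[, 2]],
             stringsAsFactors = FALSE)[order(idx[, 1], idx[, 2]), ,
                                       drop = FALSE]
}

setMethod("show", "BnNetwork", function(object) {
  cat("BnNetwork with", length(object@nodes), "nodes and",
      sum(object@adj), "edges\n")
  cat("nodes:", paste(object@nodes, collapse = ", "), "\n")
})

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard:", object@description, "\n")
  show(object@network)
})

# normalize GoldStandard / BnNetwork to BnNetwork
asNetwork <- function(x) {
  if (is(x, "GoldStandard")) x@network
  else if (is(x, "BnNetwork")) x
  else stop("expected a BnNetwork or GoldStandard object")
}

#' Test a directed graph for acyclicity
#'
#' @param net a [BnNetwork-class] object or a logical/0-1 square adjacency
#'   matrix with zero diagonal.
#' @return `TRUE` iff the graph has no directed cycle.
#' @export
isAcyclic <- function(net) {
  a <- if (is(net, "BnNetwork") || is(net, "GoldStandard"))
    adjacency(asNetwork(net)) else net
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix")
  is_acyclic_cpp(matrix(as.logical(a), nrow(a)))
}

#' Single-edge proposal neighborhood of a DAG
#'
#' Enumerates every add / delete / reverse move whose result is again an
#' acyclic graph respecting the fan-in restriction. The number of valid
#' moves is the proposal-neighborhood size used in the Hastings correction
#' of the structure sampler.
#'
#' @param net a [BnNetwork-class] object.
#' @param fanIn maximum number of parents allowed per node (default 3, the
#'   restriction used throughout).
#' @return list with `moves` (data.frame: `kind` in add/delete/reverse,
#'   `from`, `to`) and `count`, the neighborhood size.
#' @export
neighborMoves <- function(net, fanIn = 3) {
  net <- asNetwork(net)
  if (fanIn < 1) stop("fanIn must be at least 1")
  res <- neighbor_moves_cpp(net@adj, as.integer(fanIn))
  kinds <- c("add", "delete", "reverse")
  list(moves = data.frame(kind = kinds[res$kind],
                          from = net@nodes[res$from],
                          to = net@nodes[res$to],
                          stringsAsFactors = FALSE),
       count = res$count)
}

#' Apply a single-edge move to a network
#'
#' @param net a [BnNetwork-class] object.
#' @param kind `"add"`, `"delete"` or `"reverse"`.
#' @param from,to node names of the edge the move operates on.
#' @return the modified [BnNetwork-class] (validated, so an illegal move
#'   that creates a cycle raises an error).
#' @export
applyMove <- function(net, kind, from, to) {
  net <- asNetwork(net)
  i <- match(from, net@nodes); j <- match(to, net@nodes)
  if (is.na(i) || is.na(j)) stop("unknown node name")
  a <- net@adj
  if (kind == "add") {
    if (a[i, j]) stop("edge already present")
    a[i, j] <- TRUE
  } else if (kind == "delete") {
    if (!a[i, j]) stop("edge not present")
    a[i, j] <- FALSE
  } else if (kind == "reverse") {
    if (!a[i, j]) stop("edge not present")
    a[i, j] <- FALSE; a[j, i] <- TRUE
  } else stop("unknown move kind: ", kind)
  bnNetwork(adjacency = a, nodes = net@nodes)
}

#' Exhaustively enumerate all labeled DAGs on few nodes
#'
#' Lists every directed acyclic graph on `n` labeled nodes whose in-degrees
#' respect `fanIn`. The DAG count grows super-exponentially, so enumeration
#' is refused beyond `n = 5`; it exists as an exact reference for the
#' samplers and the partition-function bound on small systems.
#'
#' @param n number of nodes (at most 5).
#' @param fanIn maximum in-degree (default `n - 1`, i.e. unrestricted).
#' @param nodes optional node names (default `X1..Xn`).
#' @return list of [BnNetwork-class] objects (e.g. 25 DAGs for `n = 3`).
#' @export
enumerateDags <- function(n, fanIn = n - 1, nodes = NULL) {
  if (n > 5) stop("enumeration refused for n > 5 (super-exponential DAG count)")
  if (n < 1) stop("n must be positive")
  if (is.null(nodes)) nodes <- paste0("X", seq_len(n))
  if (length(nodes) != n) stop("nodes must have length n")
  mats <- enumerate_dags_cpp(as.integer(n), as.integer(fanIn))
  lapply(mats, function(m) {
    dimnames(m) <- list(nodes, nodes)
    new("BnNetwork", nodes = nodes, adj = m)
  })
}
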