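#' The Raf signalling pathway gold standard
#'
#' Returns the 11-node consensus Raf signalling network (Raf, Mek, Erk,
#' PLCg, PIP2, PIP3, PKC, PKA, Akt, P38, Jnk; 20 directed edges) shipped
#' as a versioned plain-text fixture. It is the structure data are
#' simulated from and reconstructions are evaluated against.
#'
#' @return a [GoldStandard-class] object.
#' @export
rafGoldStandard <- function() {
  path <- system.file("extdata", "raf_gold_standard.tsv", package = "bnmc",
                      mustWork = TRUE)
  nodes <- c("Raf", "Mek", "Erk", "PLCg", "PIP2", "PIP3", "PKC", "PKA",
             "Akt", "P38", "Jnk")
  net <- readNetworkTsv(path, nodes = nodes, header = TRUE)
  new("GoldStandard", network = net,
      description = "Raf signalling pathway consensus network (11 nodes, 20 edges)")
}

#' Draw interaction weights for a gold-standard network
#'
#' Each gold edge i -> j receives a weight whose magnitude is uniform on
#' `[0.5, 2]` and whose sign is +/-1 with probability one half; off-edge
#' entries are zero. Together with `sigma` this specifies the
#' linear-Gaussian generative model `x_j ~ Normal(sum_i w[i,j] x_i, sigma^2)`.
#'
#' @param gold a [GoldStandard-class] or [BnNetwork-class] object.
#' @param sigma conditional standard deviation (default 0.1).
#' @param seed integer seed.
#' @return list of class `"WeightSet"` with elements `weights` (numeric
#'   matrix, parent row x child column) and `sigma`.
#' @export
drawWeights <- function(gold, sigma = 0.1, seed = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  net <- asNetwork(gold)
  n <- length(net@nodes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  idx <- which(net@adj)
  w <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
  w[idx] <- stats::runif(length(idx), 0.5, 2) *
    sample(c(-1, 1), length(idx), replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(weights = w, sigma = sigma, seed = seed),
            class = "WeightSet")
}

#' Intervention design of a simulated experiment
#'
#' A design is a list of record blocks, each either observational or
#' clamping one node up or down, plus the values clamped nodes are fixed
#' at. [rafDesign()] returns the down-sampled flow-cytometry composition:
#' 16 observational records plus 14 records for each of 6 interventions
#' (Akt, PKC, PIP2 and Mek inhibited; PKC and PKA activated; PKC appears
#' in both lists as two distinct blocks), 100 records in total. With
#' `observationalOnly = TRUE` a single 100-record observational block is
#' returned instead.
#'
#' @param blocks data.frame with columns `node` (`NA` for observational),
#'   `direction` (`"none"`, `"down"`, `"up"`) and `count`.
#' @param clampValues named numeric vector with entries `down` and `up`;
#'   the defaults (-1, +1) are of order 10 sigma on the latent scale, so
#'   interventions are informative without numerical pathology.
#' @return list of class `"InterventionDesign"`.
#' @export
interventionDesign <- function(blocks, clampValues = c(down = -1, up = 1)) {
  stopifnot(all(c("node", "direction", "count") %in% names(blocks)))
  if (any(blocks$count <= 0)) stop("block record counts must be positive")
  if (!all(blocks$direction %in% c("none", "down", "up")))
    stop("direction must be none/down/up")
  structure(list(blocks = blocks, clampValues = clampValues),
            class = "InterventionDesign")
}

#' @rdname interventionDesign
#' @param observationalOnly return one purely observational block.
#' @param nObservational record count of the observational-only design.
#' @export
rafDesign <- function(observationalOnly = FALSE, nObservational = 100) {
  if (observationalOnly) {
    blocks <- data.frame(node = NA_character_, direction = "none",
                         count = nObservational, stringsAsFactors = FALSE)
  } else {
    blocks <- data.frame(
      node = c(NA, "Akt", "PKC", "PIP2", "Mek", "PKC", "PKA"),
      direction = c("none", "down", "down", "down", "down", "up", "up"),
      count = c(16, 14, 14, 14, 14, 14, 14), stringsAsFactors = FALSE)
  }
  interventionDesign(blocks)
}

#' Simulate linear-Gaussian data from a gold-standard network
#'
#' Records are generated node by node in topological order: a
#' non-intervened node is drawn from
#' `Normal(sum_parents w * x_parent, sigma^2)` (root nodes from
#' `Normal(0, sigma^2)`), while a node clamped by its block is set
#' deterministically to the design's clamp value and flagged in the mask.
#' Observational blocks yield all-false mask rows.
#'
#' @param gold a [GoldStandard-class] or [BnNetwork-class] object.
#' @param weights a [drawWeights()] result consistent with `gold`.
#' @param design an [interventionDesign()]; default the down-sampled
#'   interventional composition of [rafDesign()] when the gold standard is
#'   Raf-sized, otherwise supply one explicitly.
#' @param seed integer seed.
#' @return list with `data` (numeric records x nodes matrix), `mask`
#'   (logical matrix, `TRUE` = clamped cell), `design`, `weights`, `seed`.
#' @export
simulateGaussian <- function(gold, weights, design, seed = 1) {
  net <- asNetwork(gold)
  bad <- setdiff(stats::na.omit(design$blocks$node), net@nodes)
  if (length(bad)) stop("design intervenes on unknown nodes: ",
                        paste(bad, collapse = ", "))
  simulateGaussianEngine(net, weights, design, seed, squash = FALSE)
}

# topological order of a DAG adjacency (parents before children)
topologicalOrder <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  active <- rep(TRUE, n)
  while (length(order) < n) {
    ready <- which(active & indeg == 0)
    if (!length(ready)) stop("graph contains a directed cycle")
    j <- ready[1]
    order <- c(order, j)
    active[j] <- FALSE
    indeg <- indeg - adj[j, ]
  }
  order
}

#' Replicated simulations from one gold standard
#'
#' Generates `k` independent datasets (fresh weights and fresh noise per
#' replicate, seeds derived deterministically from `seed`) for
#' averaged-over-datasets method comparisons.
#'
#' @inheritParams simulateGaussian
#' @param k number of replicate datasets (default 5).
#' @param sigma conditional standard deviation (default 0.1).
#' @return list of `k` [simulateGaussian()] results.
#' @export
simulateReplicates <- function(gold, k = 5, design = rafDesign(),
                               sigma = 0.1, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * k)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  lapply(seq_len(k), function(i) {
    wts <- drawWeights(gold, sigma = sigma, seed = seeds[2 * i - 1])
    simulateGaussian(gold, wts, design, seed = seeds[2 * i])
  })
}

#' Nonlinear stand-in generator (sigmoid-squashed linear predictor)
#'
#' Synthetic stand-in for saturating, enzyme-kinetics-like responses: the
#' same linear predictor as [simulateGaussian()] is squashed through
#' `tanh` before noise is added. This generator is a synthetic surrogate
#' only and is excluded from the reference comparisons.
#'
#' @inheritParams simulateGaussian
#' @return same structure as [simulateGaussian()].
#' @export
simulateSigmoid <- function(gold, weights, design, seed = 1) {
  out <- simulateGaussianEngine(gold, weights, design, seed, squash = TRUE)
  out
}

simulateGaussianEngine <- function(gold, weights, design, seed, squash) {
  net <- asNetwork(gold)
  nodes <- net@nodes
  topo <- topologicalOrder(net@adj)
  w <- weights$weights; sigma <- weights$sigma
  nRec <- sum(design$blocks$count)
  x <- matrix(0, nRec, length(nodes), dimnames = list(NULL, nodes))
  mask <- matrix(FALSE, nRec, length(nodes), dimnames = list(NULL, nodes))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  r <- 0
  for (b in seq_len(nrow(design$blocks))) {
    node <- design$blocks$node[b]
    dirn <- design$blocks$direction[b]
    ci <- if (is.na(node)) 0L else match(node, nodes)
    for (k in seq_len(design$blocks$count[b])) {
      r <- r + 1
      for (j in topo) {
        if (j == ci) {
          x[r, j] <- design$clampValues[[dirn]]
          mask[r, j] <- TRUE
        } else {
          pa <- which(net@adj[, j])
          mu <- if (length(pa)) sum(w[pa, j] * x[r, pa]) else 0
          if (squash) mu <- tanh(mu)
          x[r, j] <- stats::rnorm(1, mu, sigma)
        }
      }
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(data = x, mask = mask, design = design, weights = weights,
       seed = seed)
}

#' Write a simulation to plain-text files
#'
#' Emits the dataset TSV, the full-matrix mask TSV and a JSON sidecar
#' recording blocks, clamp values, weights and seeds.
#'
#' @param sim a [simulateGaussian()] result.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dPath <- file.path(dir, paste0(prefix, "_data.tsv"))
  mPath <- file.path(dir, paste0(prefix, "_mask.tsv"))
  jPath <- file.path(dir, paste0(prefix, "_design.json"))
  writeDatasetTsv(sim$data, dPath)
  writeMaskTsv(sim$mask, mPath)
  jsonlite::write_json(
    list(blocks = sim$design$blocks,
         clampValues = as.list(sim$design$clampValues),
         sigma = sim$weights$sigma, weightSeed = sim$weights$seed,
         dataSeed = sim$seed, weights = sim$weights$weights),
    jPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(dPath, mPath, jPath))
}
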