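#' Read and write networks, data, masks and belief matrices
#'
#' Plain-text interchange formats used throughout:
#' \itemize{
#'   \item networks: edge-list TSV (`parent<TAB>child`, optional header) or
#'     square adjacency CSV with node names as header row and first column;
#'   \item CPDAGs: edge-list TSV with a third column `directed|undirected`;
#'   \item datasets: TSV with a header row of node names, one record per
#'     line, decimal-point notation;
#'   \item intervention masks: TSV of the same shape with 0/1 entries, or a
#'     compact design file (`node<TAB>comma-separated record indices`);
#'   \item belief matrices: square CSV with node-name header row/column.
#' }
#' All round-trips are lossless.
#'
#' @param path file path.
#' @param net a [BnNetwork-class] object.
#' @param nodes node universe for an edge list whose isolated nodes would
#'   otherwise be lost (optional elsewhere).
#' @param header does the edge-list TSV carry a header line?
#' @name network-io
NULL

#' @rdname network-io
#' @export
readNetworkTsv <- function(path, nodes = NULL, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("edge list needs two columns: parent, child")
  names(df)[1:2] <- c("from", "to")
  bnNetwork(edges = df[, 1:2], nodes = nodes)
}

#' @rdname network-io
#' @export
writeNetworkTsv <- function(net, path) {
  e <- networkEdges(asNetwork(net))
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("parent", "child"))
  invisible(path)
}

#' @rdname network-io
#' @export
readAdjacencyCsv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (!identical(rownames(m), colnames(m)))
    stop("adjacency CSV must have identical row and column names")
  bnNetwork(adjacency = m != 0, nodes = rownames(m))
}

#' @rdname network-io
#' @export
writeAdjacencyCsv <- function(net, path) {
  net <- asNetwork(net)
  m <- matrix(as.integer(net@adj), nrow(net@adj),
              dimnames = dimnames(net@adj))
  utils::write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @param cpdag a [Cpdag-class] object.
#' @export
writeCpdagTsv <- function(cpdag, path) {
  d <- directedEdges(cpdag); u <- undirectedEdges(cpdag)
  out <- rbind(
    if (nrow(d)) cbind(d, type = "directed"),
    if (nrow(u)) cbind(u, type = "undirected"))
  if (is.null(out))
    out <- data.frame(from = character(), to = character(),
                      type = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("from", "to", "type"))
  invisible(path)
}

#' @rdname network-io
#' @param x numeric data matrix (records x nodes) with column names.
#' @export
writeDatasetTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
readDatasetTsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

#' @rdname network-io
#' @param mask logical matrix of clamped cells, same shape as the dataset.
#' @export
writeMaskTsv <- function(mask, path) {
  m <- matrix(as.integer(mask), nrow(mask), dimnames = dimnames(mask))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
readMaskTsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  mode(m) <- "integer"
  m == 1L
}

#' @rdname network-io
#' @param nRecords number of records the compact design file describes.
#' @export
readMaskDesign <- function(path, nodes, nRecords) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  mask <- matrix(FALSE, nRecords, length(nodes),
                 dimnames = list(NULL, nodes))
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("design line must be 'node<TAB>indices': ", ln)
    j <- match(parts[1], nodes)
    if (is.na(j)) stop("unknown node in mask design: ", parts[1])
    idx <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    if (any(is.na(idx)) || any(idx < 1) || any(idx > nRecords))
      stop("record indices out of range for node ", parts[1])
    mask[idx, j] <- TRUE
  }
  mask
}

#' @rdname network-io
#' @param B a [BeliefMatrix-class] object.
#' @export
writeBeliefCsv <- function(B, path) {
  m <- B@beliefs
  dimnames(m) <- list(B@nodes, B@nodes)
  utils::write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
readBeliefCsv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  beliefMatrix(m, rownames(m))
}
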