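#' Edge posteriors from a trace
#'
#' Directed posteriors are the post-burn-in directed-edge tallies divided
#' by the number of retained samples (an undirected equivalence-class edge
#' counted towards both directions); the skeleton posterior is the
#' fraction of retained samples in which two nodes are adjacent in either
#' orientation, accumulated directly from samples rather than derived from
#' the directed matrix.
#'
#' @param trace an [McmcTrace-class] object with at least one retained
#'   sample.
#' @return an [EdgePosterior-class] object.
#' @export
edgePosteriors <- function(trace) {
  if (trace@nRetained < 1) stop("trace has no post-burn-in samples")
  new("EdgePosterior", nodes = trace@nodes,
      directed = trace@edgeCounts / trace@nRetained,
      skeleton = trace@skelCounts / trace@nRetained,
      nSamples = trace@nRetained)
}

setMethod("show", "EdgePosterior", function(object) {
  cat("EdgePosterior over", length(object@nodes), "nodes from",
      object@nSamples, "samples\n")
})

#' @rdname bnNetwork
#' @export
setMethod("nodeNames", "EdgePosterior", function(x) x@nodes)

# Mann-Whitney AUC with midrank tie handling
aucFromScores <- function(scores, labels) {
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve and AUC of an edge ranking against a gold standard
#'
#' Under the directed criterion (DGE) all ordered node pairs are ranked by
#' their directed posterior and the positives are the gold standard's
#' directed edges; under the undirected criterion (UGE) unordered pairs
#' are ranked by the skeleton posterior and the positives are the gold
#' skeleton. The AUC is the Mann-Whitney statistic of the ranking, with
#' tied scores contributing their mid-rank; a perfect predictor attains
#' 1.00 and random scores concentrate around 0.50. Self-pairs are always
#' excluded.
#'
#' @param posterior an [EdgePosterior-class], or a plain numeric score
#'   matrix interpreted as directed edge scores (UGE then uses the
#'   pairwise maximum of the two directions).
#' @param gold a [GoldStandard-class] or [BnNetwork-class] object on the
#'   same nodes.
#' @param criterion `"DGE"` or `"UGE"`.
#' @return list of class `"RocResult"`: `auc`, `curve` (data.frame of
#'   false/true-positive fractions along the ranking), `criterion`,
#'   `nPositives`, `nPairs`.
#' @export
rocAuc <- function(posterior, gold, criterion = c("DGE", "UGE")) {
  criterion <- match.arg(criterion)
  goldNet <- asNetwork(gold)
  nodes <- goldNet@nodes
  if (is(posterior, "EdgePosterior")) {
    if (!setequal(posterior@nodes, nodes)) stop("node sets do not match")
    dscore <- posterior@directed[nodes, nodes]
    sscore <- posterior@skeleton[nodes, nodes]
  } else if (is.matrix(posterior)) {
    if (any(dim(posterior) != length(nodes)))
      stop("score matrix dimension does not match gold standard")
    dscore <- posterior
    sscore <- pmax(posterior, t(posterior))
  } else stop("posterior must be an EdgePosterior or a score matrix")
  if (criterion == "DGE") {
    sel <- row(dscore) != col(dscore)
    scores <- dscore[sel]
    labels <- adjacency(goldNet)[sel]
  } else {
    sel <- upper.tri(sscore)
    scores <- sscore[sel]
    a <- adjacency(goldNet)
    labels <- (a | t(a))[sel]
  }
  auc <- aucFromScores(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]) / sum(labels)
  fp <- cumsum(!labels[ord]) / sum(!labels)
  structure(list(auc = auc,
                 curve = data.frame(fp = c(0, fp), tp = c(0, tp)),
                 criterion = criterion, nPositives = sum(labels),
                 nPairs = length(labels)),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat("RocResult (", x$criterion, "): AUC = ", round(x$auc, 4), " over ",
      x$nPairs, " candidate pairs (", x$nPositives, " positives)\n",
      sep = "")
  invisible(x)
}

#' Posterior summary of the sampled inverse temperature
#'
#' Gaussian-kernel density of the sampled beta values on `[0, betaMax]`,
#' with the median and a central 90 percent interval. Large sampled values
#' mean the prior knowledge is in good agreement with the data and is
#' being integrated; mass near zero means the sampler has effectively
#' switched the prior knowledge off.
#'
#' @param trace an [McmcTrace-class] from a BN-E run.
#' @param bandwidth kernel bandwidth; default automatic (`bw.nrd0`).
#' @return list with `density` (data.frame `beta`, `density`), `median`,
#'   `q05`, `q95`, `n`.
#' @export
betaPosteriorSummary <- function(trace, bandwidth = NULL) {
  b <- trace@betaSamples
  if (!length(b))
    stop("trace carries no beta samples (only BN-E traces do)")
  betaMax <- trace@config$betaMax
  if (stats::sd(b) == 0) {
    dens <- data.frame(beta = b[1], density = Inf)
  } else {
    d <- if (is.null(bandwidth))
      stats::density(b, from = 0, to = betaMax)
    else stats::density(b, bw = bandwidth, from = 0, to = betaMax)
    # renormalize to unit mass on the bounded support
    mass <- sum(d$y) * diff(d$x[1:2])
    dens <- data.frame(beta = d$x, density = d$y / mass)
  }
  list(density = dens, median = stats::median(b),
       q05 = unname(stats::quantile(b, 0.05)),
       q95 = unname(stats::quantile(b, 0.95)), n = length(b))
}

#' Compare inference schemes over replicated datasets
#'
#' Runs every configured scheme on every dataset, evaluates the directed
#' (DGE) and undirected (UGE) AUC of the resulting edge posteriors against
#' the gold standard, and summarizes each (scheme, criterion) cell by its
#' mean and standard deviation over datasets.
#'
#' @param datasets list of [simulateGaussian()] results (or lists with
#'   elements `data` and optionally `mask`).
#' @param schemes named list configuring the runs; each element is a list
#'   with `method` (`"BN"`, `"BN-I"`, `"BN-E"`) and, for BN-E, `beliefs`
#'   (a [BeliefMatrix-class]). The element name labels the scheme in the
#'   output.
#' @param gold the [GoldStandard-class] to evaluate against.
#' @param config an [mcmcConfig()] list; each run gets a distinct seed
#'   derived deterministically from `config$seed`.
#' @param outDir optional directory; when given, every run's trace is
#'   persisted via [writeTrace()].
#' @return list with `summary` (data.frame: scheme, criterion, mean_auc,
#'   sd_auc, n_datasets), `perRun` (one row per run and criterion) and
#'   `betaMedians` (named list of per-run beta medians for BN-E schemes).
#' @export
compareMethods <- function(datasets, schemes, gold, config = mcmcConfig(),
                           outDir = NULL) {
  if (length(datasets) < 2)
    warning("fewer than 2 datasets: standard deviations are degenerate")
  goldNet <- asNetwork(gold)
  perRun <- list()
  betaMedians <- list()
  for (s in seq_along(schemes)) {
    sch <- schemes[[s]]
    label <- names(schemes)[s]
    for (d in seq_along(datasets)) {
      ds <- datasets[[d]]
      if (!setequal(colnames(ds$data), goldNet@nodes))
        stop("dataset ", d, " node set does not match the gold standard")
      # seed varies by scheme only: replicate datasets decorrelate the runs,
      # and identical copies of one dataset reproduce identical traces
      cfg <- config
      cfg$seed <- as.integer((config$seed + 7919L * s) %%
                               .Machine$integer.max)
      trace <- runMcmc(ds$data, method = sch$method, config = cfg,
                       mask = if (identical(sch$method, "BN-I")) ds$mask,
                       beliefs = sch$beliefs)
      if (!is.null(outDir))
        writeTrace(trace, outDir, prefix = paste0(label, "_d", d))
      post <- edgePosteriors(trace)
      for (crit in c("DGE", "UGE")) {
        perRun[[length(perRun) + 1]] <- data.frame(
          scheme = label, dataset = d, criterion = crit,
          auc = rocAuc(post, goldNet, crit)$auc,
          stringsAsFactors = FALSE)
      }
      if (length(trace@betaSamples))
        betaMedians[[label]] <- c(betaMedians[[label]],
                                  stats::median(trace@betaSamples))
    }
  }
  perRun <- do.call(rbind, perRun)
  agg <- stats::aggregate(auc ~ scheme + criterion, perRun,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  summary <- data.frame(scheme = agg$scheme, criterion = agg$criterion,
                        mean_auc = agg$auc[, "mean"],
                        sd_auc = agg$auc[, "sd"],
                        n_datasets = agg$auc[, "n"],
                        stringsAsFactors = FALSE)
  list(summary = summary, perRun = perRun, betaMedians = betaMedians)
}

#' Bar chart of a method comparison
#'
#' Grouped bars of mean AUC per scheme and criterion with one-standard-
#' deviation error bars.
#'
#' @param comparison a [compareMethods()] result.
#' @param main plot title.
#' @return invisibly, the bar midpoints.
#' @export
plotComparison <- function(comparison, main = "Reconstruction accuracy") {
  s <- comparison$summary
  tab <- tapply(s$mean_auc, list(s$scheme, s$criterion), identity)
  sds <- tapply(s$sd_auc, list(s$scheme, s$criterion), identity)
  mid <- graphics::barplot(tab, beside = TRUE, ylim = c(0, 1.05),
                           legend.text = rownames(tab), ylab = "AUC",
                           main = main)
  graphics::arrows(mid, tab - sds, mid, tab + sds, angle = 90, code = 3,
                   length = 0.04)
  graphics::abline(h = 0.5, lty = 3)
  invisible(mid)
}

#' Kernel-density plot of sampled inverse temperatures
#'
#' @param summaries named list of [betaPosteriorSummary()] results, one
#'   line per run.
#' @param main plot title.
#' @export
plotBetaDensity <- function(summaries, main = "Posterior of beta") {
  xr <- range(unlist(lapply(summaries, function(s) s$density$beta)))
  yr <- range(0, unlist(lapply(summaries,
                               function(s) s$density$density[
                                 is.finite(s$density$density)])))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "beta",
                 ylab = "density", main = main)
  for (i in seq_along(summaries))
    graphics::lines(summaries[[i]]$density$beta,
                    summaries[[i]]$density$density, lty = i, col = i)
  graphics::legend("topright", legend = names(summaries),
                   lty = seq_along(summaries), col = seq_along(summaries))
}
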