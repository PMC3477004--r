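makeTrace <- function(dir, skel, n = 1) {
  nodes <- rownames(dir)
  new("McmcTrace", method = "BN", nodes = nodes, edgeCounts = dir,
      skelCounts = skel, nRetained = n, betaSamples = numeric(0),
      logScores = numeric(0), logScoreSteps = integer(0),
      acceptance = data.frame(), snapshots = list(),
      config = mcmcConfig(nSteps = 10))
}

test_that("single-sample posteriors follow the superposition rule", {
  nodes <- c("A", "B", "C")
  # one retained sample whose CPDAG has A -> B compelled
  dir <- matrix(0, 3, 3, dimnames = list(nodes, nodes)); dir["A", "B"] <- 1
  skel <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  skel["A", "B"] <- skel["B", "A"] <- 1
  p <- edgePosteriors(makeTrace(dir, skel))
  expect_equal(p@directed["A", "B"], 1)
  expect_equal(p@directed["B", "A"], 0)
  expect_equal(p@skeleton["A", "B"], 1)

  # a fully undirected chain CPDAG counts both directions
  cd <- chain3Data(30, seed = 51)
  tr <- runMcmc(cd$sim$data, "BN", mcmcConfig(nSteps = 2, thinStore = 1,
                                              seed = 1))
  expect_equal(tr@nRetained, 1)
  p1 <- edgePosteriors(tr)
  expect_true(all(p1@directed %in% c(0, 1)))
  expect_identical(unname(p1@directed), unname(t(p1@directed)) * 1)
  expect_error(edgePosteriors(makeTrace(dir, skel, n = 0)), "samples")
})

test_that("ROC/AUC: perfect, random, gold-indicator and tie handling", {
  g <- rafGoldStandard()
  a <- adjacency(g)
  # the gold standard's own indicator ranks all positives first
  expect_identical(rocAuc(a * 1, g, "DGE")$auc, 1)
  expect_identical(rocAuc((a | t(a)) * 1, g, "UGE")$auc, 1)
  # a graded score that still ranks every gold edge above every non-edge
  set.seed(52)
  sc <- a * runif(121, 0.6, 1) + (!a) * runif(121, 0, 0.4)
  diag(sc) <- 0
  expect_equal(rocAuc(sc, g, "DGE")$auc, 1)
  # tied scores contribute their mid-rank
  toy <- bnNetwork(edges = data.frame(from = "A", to = "B"),
                   nodes = c("A", "B", "C"))
  s <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  s["A", "B"] <- 0.7; s["B", "A"] <- 0.7; s["A", "C"] <- 0.2
  labels <- adjacency(toy)[row(s) != col(s)]
  scores <- s[row(s) != col(s)]
  expect_equal(rocAuc(s, toy, "DGE")$auc, oracleAuc(scores, labels))
  expect_error(rocAuc(s, emptyNetwork(c("A", "B", "C")), "DGE"),
               "undefined")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  g <- rafGoldStandard()
  set.seed(53)
  sc <- matrix(runif(121), 11, 11,
               dimnames = list(nodeNames(g), nodeNames(g)))
  diag(sc) <- 0
  a1 <- rocAuc(sc, g, "DGE")$auc
  expect_identical(rocAuc(exp(4 * sc), g, "DGE")$auc, a1)
  expect_identical(rocAuc(sc^3 + 2, g, "DGE")$auc, a1)
})

test_that("rank-based AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  for (rep in 1:100) {
    nPairs <- sample(20:60, 1)
    scores <- round(runif(nPairs), sample(c(1, 2, 6), 1)) # forces ties
    labels <- runif(nPairs) < 0.4
    if (!any(labels) || all(labels)) next
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(oracleAuc(scores, labels), ref, tolerance = 1e-12)
    # and the package path through a score matrix
  }
  g <- rafGoldStandard()
  sc <- matrix(runif(121), 11, 11,
               dimnames = list(nodeNames(g), nodeNames(g)))
  diag(sc) <- 0
  lab <- adjacency(g)[row(sc) != col(sc)]
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = sc[row(sc) != col(sc)], quiet = TRUE,
    direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(rocAuc(sc, g, "DGE")$auc, ref, tolerance = 1e-12)
})

test_that("ROC curve fractions are monotone and end at (1, 1)", {
  g <- rafGoldStandard()
  set.seed(55)
  sc <- matrix(runif(121), 11, 11,
               dimnames = list(nodeNames(g), nodeNames(g)))
  diag(sc) <- 0
  roc <- rocAuc(sc, g, "DGE")
  expect_true(all(diff(roc$curve$tp) >= 0))
  expect_true(all(diff(roc$curve$fp) >= 0))
  expect_equal(utils::tail(roc$curve$tp, 1), 1)
  expect_equal(utils::tail(roc$curve$fp, 1), 1)
})

test_that("beta posterior summaries are normalized densities", {
  cd <- chain3Data(30, seed = 56)
  B <- makeB50(cd$gold, seed = 1)
  tr <- runMcmc(cd$sim$data, "BN-E",
                mcmcConfig(nSteps = 2e4, seed = 3, betaMax = 10),
                beliefs = B)
  s <- betaPosteriorSummary(tr)
  dx <- diff(s$density$beta[1:2])
  expect_equal(sum(s$density$density) * dx, 1, tolerance = 1e-3)
  expect_gte(s$q05, 0)
  expect_lte(s$q95, 10)
  # a constant chain degenerates to a point mass
  trc <- tr
  trc@betaSamples <- rep(2.5, 100)
  sc <- betaPosteriorSummary(trc)
  expect_equal(sc$median, 2.5)
  expect_equal(sc$density$beta, 2.5)
  # traces without beta samples are rejected
  trBN <- runMcmc(cd$sim$data, "BN", mcmcConfig(nSteps = 1000, seed = 1))
  expect_error(betaPosteriorSummary(trBN), "beta")
})

test_that("identical dataset copies yield zero between-run spread", {
  cd <- chain3Data(40, seed = 57)
  cmp <- compareMethods(list(cd$sim, cd$sim),
                        list(BN = list(method = "BN")), cd$gold,
                        mcmcConfig(nSteps = 5000, seed = 2))
  expect_true(all(cmp$summary$sd_auc == 0))
  expect_equal(nrow(cmp$summary), 2) # DGE and UGE
  expect_true(all(cmp$summary$n_datasets == 2))
})
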