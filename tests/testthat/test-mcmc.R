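test_that("structure acceptance matches a directly coded MH formula", {
  cd <- chain3Data(40, seed = 23)
  x <- cd$sim$data
  set.seed(33)
  for (rep in 1:10) {
    old <- bnNetwork(randomDag(3, pEdge = 0.5, fanIn = 2,
                               nodes = colnames(x)))
    mv <- neighborMoves(old, fanIn = 2)
    pick <- mv$moves[sample(nrow(mv$moves), 1), ]
    new <- applyMove(old, pick$kind, pick$from, pick$to)
    plr <- runif(1, -1, 1)
    # independent evaluation, neighborhood sizes by brute force
    direct <- min(1, exp(
      logMarginalLikelihood(new, x) - logMarginalLikelihood(old, x) + plr) *
        oracleMoves(adjacency(old), 2) / oracleMoves(adjacency(new), 2))
    expect_equal(structureAcceptance(old, new, x, priorLogRatio = plr,
                                     fanIn = 2),
                 direct, tolerance = 1e-12)
  }
  # degenerate and symmetric cases accept with probability one
  g <- bnNetwork(edges = data.frame(from = "A", to = "B"),
                 nodes = colnames(x))
  expect_equal(structureAcceptance(g, g, x), 1)
})

test_that("beta proposal is reflected, bounded and symmetric", {
  cfg <- mcmcConfig(betaMax = 5, betaStep = 1)
  set.seed(34)
  draws0 <- replicate(2000, proposeBeta(0, cfg))
  expect_true(all(draws0 >= 0 & draws0 <= 1))
  drawsTop <- replicate(2000, proposeBeta(5, cfg))
  expect_true(all(drawsTop >= 4 & drawsTop <= 5))
  draws <- replicate(1e5, proposeBeta(2.3, cfg))
  expect_true(all(draws >= 0 & draws <= 5))
  # symmetry: transition rates between two neighbourhoods agree
  b1 <- 2.3; b2 <- 3.0; eps <- 0.15
  from1 <- mean(abs(replicate(1e5, proposeBeta(b1, cfg)) - b2) < eps)
  from2 <- mean(abs(replicate(1e5, proposeBeta(b2, cfg)) - b1) < eps)
  expect_equal(from1, from2, tolerance = 0.08)
})

test_that("joint acceptance follows the factorized posterior", {
  cd <- chain3Data(40, seed = 24)
  x <- cd$sim$data
  nodes <- colnames(x)
  set.seed(35)
  B <- beliefMatrix(matrix(runif(9), 3, 3), nodes)
  cfg <- mcmcConfig(fanIn = 2)
  old <- bnNetwork(randomDag(3, fanIn = 2, nodes = nodes))
  mv <- neighborMoves(old, fanIn = 2)$moves[1, ]
  new <- applyMove(old, mv$kind, mv$from, mv$to)
  beta <- 1.4
  expect_equal(
    jointAcceptance(old, beta, new, beta, x, B = B, config = cfg),
    structureAcceptance(old, new, x,
                        priorLogRatio = -beta * (energy(new, B) -
                                                   energy(old, B)),
                        fanIn = 2))
  # beta-only sub-move at zero energy: only the partition functions remain
  zeroE <- bnNetwork(beliefs(makeB100(old)) == 1, nodes)
  b100 <- makeB100(old)
  a <- jointAcceptance(zeroE, 1, zeroE, 2.5, x, B = b100, config = cfg)
  expect_equal(a, min(1, exp(logPartition(1, b100, 2) -
                               logPartition(2.5, b100, 2))))
  expect_error(jointAcceptance(old, 1, new, 2, x, B = B, config = cfg),
               "sub-move")
})

test_that("samplers are reproducible and method requirements enforced", {
  cd <- chain3Data(30, seed = 25)
  x <- cd$sim$data
  cfg <- mcmcConfig(nSteps = 4000, seed = 77)
  t1 <- runMcmc(x, "BN", cfg)
  t2 <- runMcmc(x, "BN", cfg)
  expect_identical(t1@edgeCounts, t2@edgeCounts)
  expect_identical(t1@logScores, t2@logScores)
  expect_error(runMcmc(x, "BN-I", cfg), "mask")
  expect_error(runMcmc(x, "BN-E", cfg), "belief")
})

test_that("BN-I with an all-false mask reproduces BN exactly", {
  cd <- chain3Data(30, seed = 26)
  x <- cd$sim$data
  mask <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  cfg <- mcmcConfig(nSteps = 6000, seed = 5)
  tBN <- runMcmc(x, "BN", cfg)
  tBNI <- runMcmc(x, "BN-I", cfg, mask = mask)
  expect_identical(tBN@edgeCounts, tBNI@edgeCounts)
  expect_identical(tBN@skelCounts, tBNI@skelCounts)
})

test_that("edge posteriors converge to the exhaustive-enumeration answer", {
  cd <- chain3Data(50, seed = 27)
  x <- cd$sim$data
  ex <- exactEdgePosterior(x)
  tr <- runMcmc(x, "BN", mcmcConfig(nSteps = 1e5, seed = 2))
  expect_lt(max(abs(edgePosteriors(tr)@directed - ex@directed)), 0.05)
  expect_lt(max(abs(edgePosteriors(tr)@skeleton - ex@skeleton)), 0.05)
  # BN-E at beta fixed to 0 behaves like BN
  B <- makeB50(cd$gold, seed = 3)
  trE0 <- runMcmc(x, "BN-E", mcmcConfig(nSteps = 1e5, seed = 3,
                                        betaMax = 0, betaStep = 0),
                  beliefs = B)
  expect_lt(max(abs(edgePosteriors(trE0)@directed - ex@directed)), 0.05)
})

test_that("the structure kernel satisfies detailed balance analytically", {
  # pi(x) A(x->y) / |N(x)| must equal pi(y) A(y->x) / |N(y)| for the
  # posterior over structures, by direct evaluation of the MH formula
  cd <- chain3Data(35, seed = 28)
  x <- cd$sim$data
  set.seed(36)
  for (rep in 1:8) {
    old <- bnNetwork(randomDag(3, fanIn = 2, nodes = colnames(x)))
    mv <- neighborMoves(old, fanIn = 2)
    pick <- mv$moves[sample(nrow(mv$moves), 1), ]
    new <- applyMove(old, pick$kind, pick$from, pick$to)
    logPiOld <- logMarginalLikelihood(old, x)
    logPiNew <- logMarginalLikelihood(new, x)
    flowFwd <- exp(logPiOld) *
      structureAcceptance(old, new, x, fanIn = 2) / mv$count
    flowBwd <- exp(logPiNew) *
      structureAcceptance(new, old, x, fanIn = 2) /
      neighborMoves(new, fanIn = 2)$count
    expect_equal(flowFwd, flowBwd, tolerance = 1e-10)
  }
})

test_that("beta chain stays in range and tracks prior quality", {
  g <- rafGoldStandard()
  w <- drawWeights(g, seed = 41)
  sim <- simulateGaussian(g, w, rafDesign(observationalOnly = TRUE),
                          seed = 42)
  cfg <- mcmcConfig(nSteps = 3e4, seed = 6)
  tr100 <- runMcmc(sim$data, "BN-E", cfg, beliefs = makeB100(g))
  tr50 <- runMcmc(sim$data, "BN-E", cfg, beliefs = makeB50(g, seed = 2))
  expect_true(all(tr100@betaSamples >= 0 & tr100@betaSamples <= cfg$betaMax))
  expect_gt(median(tr100@betaSamples), median(tr50@betaSamples))
})

test_that("convergence report compares two runs honestly", {
  cd <- chain3Data(40, seed = 29)
  x <- cd$sim$data
  trA <- runMcmc(x, "BN", mcmcConfig(nSteps = 5e4, seed = 10))
  trB <- runMcmc(x, "BN", mcmcConfig(nSteps = 5e4, seed = 11))
  self <- checkConvergence(trA, trA)
  expect_identical(self$maxDiff, 0)
  expect_true(self$pass)
  two <- checkConvergence(trA, trB, threshold = 0.1)
  expect_true(two$pass)
  expect_match(two$note, "not a sufficient")
  expect_equal(nrow(two$scatter), 6)
  y <- cbind(x, D = x[, 1])
  expect_error(checkConvergence(trA, runMcmc(y, "BN",
                                             mcmcConfig(nSteps = 1000))),
               "node sets")
})
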