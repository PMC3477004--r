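test_that("parentless local score matches numerical quadrature", {
  set.seed(3)
  # single-variable domain
  x1 <- matrix(rnorm(8, 0.3, 0.8), ncol = 1, dimnames = list(NULL, "A"))
  h1 <- bgeHyperparams(1)
  expect_equal(
    bgeLocalScore(x1, "A", standardize = FALSE, hyper = h1),
    oracleParentlessScore(x1[, 1], 1, h1$alphaMu, h1$alphaW, h1$t0Scale),
    tolerance = 1e-4)
  # parentless node inside a 3-node domain (projected prior changes)
  x3 <- matrix(rnorm(24), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  h3 <- bgeHyperparams(3)
  expect_equal(
    bgeLocalScore(x3, "B", standardize = FALSE, hyper = h3),
    oracleParentlessScore(x3[, "B"], 3, h3$alphaMu, h3$alphaW, h3$t0Scale),
    tolerance = 1e-4)
})

test_that("mask semantics: clamped records drop from the child score only", {
  set.seed(4)
  x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  mask <- matrix(FALSE, 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  mask[5:10, "B"] <- TRUE
  # masked call equals physically deleting the clamped records of B
  expect_identical(
    bgeLocalScore(x, "B", "A", mask = mask, standardize = FALSE),
    bgeLocalScore(x[-(5:10), ], "B", "A", standardize = FALSE,
                  hyper = bgeHyperparams(3)))
  # other nodes keep every record
  expect_identical(
    bgeLocalScore(x, "A", mask = mask, standardize = FALSE),
    bgeLocalScore(x, "A", standardize = FALSE))
  # a fully clamped child contributes log of unit evidence
  mask[, "B"] <- TRUE
  expect_identical(bgeLocalScore(x, "B", "A", mask = mask), 0)
})

test_that("total score decomposes and is invariant to column order", {
  set.seed(5)
  x <- matrix(rnorm(80), ncol = 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  net <- emptyNetwork(c("A", "B", "C", "D"))
  expect_equal(
    logMarginalLikelihood(net, x),
    sum(vapply(colnames(x), function(v) bgeLocalScore(x, v), numeric(1))))
  # data columns permuted: alignment by name must give the same score
  g <- bnNetwork(edges = data.frame(from = c("A", "C"), to = c("B", "B")),
                 nodes = c("A", "B", "C", "D"))
  expect_equal(logMarginalLikelihood(g, x),
               logMarginalLikelihood(g, x[, c(3, 1, 4, 2)]))
  expect_error(logMarginalLikelihood(g, `colnames<-`(x, letters[1:4])),
               "node names")
})

test_that("Markov-equivalent DAGs score identically on observational data", {
  set.seed(6)
  x <- matrix(rnorm(50 * 3), ncol = 3,
              dimnames = list(NULL, c("X1", "X2", "X3")))
  dags <- enumerateDags(3, nodes = colnames(x))
  scores <- vapply(dags, logMarginalLikelihood, numeric(1), data = x)
  keys <- vapply(dags, function(g) oracleClassKey(adjacency(g)),
                 character(1))
  for (k in unique(keys)) {
    s <- scores[keys == k]
    expect_lt(max(s) - min(s), 1e-8)
  }
  # and distinct classes do not all collapse to one value
  expect_gt(length(unique(round(scores, 6))), 1)
})

test_that("an intervention mask breaks score equivalence", {
  cd <- chain3Data(40, seed = 21)
  x <- cd$sim$data
  ab <- bnNetwork(edges = data.frame(from = "A", to = "B"),
                  nodes = colnames(x))
  ba <- bnNetwork(edges = data.frame(from = "B", to = "A"),
                  nodes = colnames(x))
  expect_equal(logMarginalLikelihood(ab, x), logMarginalLikelihood(ba, x),
               tolerance = 1e-10)
  mask <- matrix(FALSE, nrow(x), 3, dimnames = list(NULL, colnames(x)))
  mask[1:15, "B"] <- TRUE
  expect_gt(abs(logMarginalLikelihood(ab, x, mask = mask) -
                  logMarginalLikelihood(ba, x, mask = mask)), 1e-6)
})

test_that("scores are invariant to affine rescaling of a column", {
  set.seed(8)
  x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  g <- bnNetwork(edges = data.frame(from = "A", to = "B"),
                 nodes = colnames(x))
  y <- x
  y[, "B"] <- 7.3 * y[, "B"] - 40
  expect_equal(logMarginalLikelihood(g, x), logMarginalLikelihood(g, y),
               tolerance = 1e-6)
})

test_that("the score cache is transparent", {
  cd <- chain3Data(30, seed = 22)
  x <- cd$sim$data
  mask <- cd$sim$mask
  cache <- newScoreCache()
  for (g in enumerateDags(3, nodes = colnames(x))[1:10]) {
    cold <- logMarginalLikelihood(g, x, mask = mask)
    warm <- logMarginalLikelihood(g, x, mask = mask, cache = cache)
    warm2 <- logMarginalLikelihood(g, x, mask = mask, cache = cache)
    expect_identical(cold, warm)
    expect_identical(warm, warm2)
  }
})

test_that("hyper-parameter validation enforces a proper prior", {
  expect_error(bgeHyperparams(3, alphaW = 3), "alphaW")
  expect_error(bgeHyperparams(3, alphaMu = 0), "alphaMu")
  h <- bgeHyperparams(11)
  expect_equal(h$alphaW, 13)
  expect_equal(h$t0Scale, 0.5)
})
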