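test_that("the Raf gold standard is the expected 11-node DAG", {
  g <- rafGoldStandard()
  expect_s4_class(g, "GoldStandard")
  expect_length(nodeNames(g), 11)
  expect_true(isAcyclic(g))
  expect_equal(sum(adjacency(g)), 20)
  # every protein targeted by the interventional design is present
  expect_true(all(c("Akt", "PKC", "PIP2", "Mek", "PKA") %in% nodeNames(g)))
  # compatible with the fan-in restriction used throughout
  expect_true(all(colSums(adjacency(g)) <= 3))
  # canonical signalling cascade edges
  e <- networkEdges(g@network)
  expect_true(any(e$from == "Raf" & e$to == "Mek"))
  expect_true(any(e$from == "Mek" & e$to == "Erk"))
})

test_that("interaction weights honor magnitude, sign and seed contracts", {
  g <- rafGoldStandard()
  w1 <- drawWeights(g, seed = 10)
  onEdge <- w1$weights[adjacency(g)]
  expect_true(all(abs(onEdge) >= 0.5 & abs(onEdge) <= 2))
  expect_true(all(w1$weights[!adjacency(g)] == 0))
  expect_identical(drawWeights(g, seed = 10)$weights, w1$weights)
  expect_false(identical(drawWeights(g, seed = 11)$weights, w1$weights))
  # sign symmetry: pool signs across many seeded draws
  signs <- unlist(lapply(1:500, function(s)
    sign(drawWeights(g, seed = s)$weights[adjacency(g)])))
  bt <- binom.test(sum(signs > 0), length(signs), p = 0.5)
  expect_gt(bt$p.value, 0.01)
  expect_error(drawWeights(g, sigma = 0), "sigma")
})

test_that("the interventional design reproduces the sampled composition", {
  d <- rafDesign()
  expect_equal(sum(d$blocks$count), 100)
  iv <- d$blocks[d$blocks$direction != "none", ]
  expect_equal(nrow(iv), 6)
  expect_true(all(iv$count == 14))
  expect_setequal(iv$node[iv$direction == "down"],
                  c("Akt", "PKC", "PIP2", "Mek"))
  expect_setequal(unique(iv$node[iv$direction == "up"]), c("PKC", "PKA"))
  obs <- rafDesign(observationalOnly = TRUE)
  expect_equal(nrow(obs$blocks), 1)
  expect_equal(sum(obs$blocks$count), 100)
})

test_that("linear-Gaussian sampling follows the generative law", {
  g <- bnNetwork(edges = data.frame(from = "A", to = "B"),
                 nodes = c("A", "B"))
  w <- drawWeights(g, sigma = 0.1, seed = 1)
  des <- interventionDesign(data.frame(node = NA_character_,
                                       direction = "none", count = 10000))
  sim <- simulateGaussian(g, w, des, seed = 2)
  # root node: mean 0, sd sigma (3 standard errors at n = 1e4)
  expect_lt(abs(mean(sim$data[, "A"])), 3 * 0.1 / sqrt(10000))
  expect_equal(sd(sim$data[, "A"]), 0.1, tolerance = 0.01)
  # child residuals are Normal(0, sigma^2)
  res <- sim$data[, "B"] - w$weights["A", "B"] * sim$data[, "A"]
  expect_equal(sd(res), 0.1, tolerance = 0.01)
  expect_gt(shapiro.test(sample(res, 3000))$p.value, 1e-4)
  expect_false(any(sim$mask))
})

test_that("clamped nodes are deterministic and flagged", {
  g <- rafGoldStandard()
  w <- drawWeights(g, seed = 3)
  sim <- simulateGaussian(g, w, rafDesign(), seed = 4)
  expect_equal(dim(sim$data), c(100, 11))
  blocks <- rafDesign()$blocks
  r0 <- cumsum(c(0, blocks$count))
  for (b in seq_len(nrow(blocks))) {
    rows <- (r0[b] + 1):r0[b + 1]
    if (blocks$direction[b] == "none") {
      expect_false(any(sim$mask[rows, ]))
    } else {
      node <- blocks$node[b]
      expect_true(all(sim$mask[rows, node]))
      expect_equal(var(sim$data[rows, node]), 0)
      expect_equal(unique(sim$data[rows, node]),
                   unname(rafDesign()$clampValues[blocks$direction[b]]))
      expect_false(any(sim$mask[rows, setdiff(colnames(sim$mask), node)]))
    }
  }
  expect_identical(simulateGaussian(g, w, rafDesign(), seed = 4)$data,
                   sim$data)
  expect_false(identical(simulateGaussian(g, w, rafDesign(), seed = 5)$data,
                         sim$data))
})

test_that("replicates are independent but reproducible", {
  g <- rafGoldStandard()
  reps <- simulateReplicates(g, k = 3, seed = 8)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]]$data, reps[[2]]$data))
  expect_false(identical(reps[[1]]$weights$weights,
                         reps[[2]]$weights$weights))
  again <- simulateReplicates(g, k = 3, seed = 8)
  expect_identical(reps[[2]]$data, again[[2]]$data)
})

test_that("the sigmoid stand-in saturates the linear predictor", {
  g <- bnNetwork(edges = data.frame(from = "A", to = "B"),
                 nodes = c("A", "B"))
  w <- drawWeights(g, sigma = 0.05, seed = 6)
  des <- interventionDesign(data.frame(node = "A", direction = "up",
                                       count = 2000),
                            clampValues = c(down = -5, up = 5))
  sim <- simulateSigmoid(g, w, des, seed = 7)
  expect_equal(mean(sim$data[, "B"]), tanh(5 * w$weights["A", "B"]),
               tolerance = 0.01)
})
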