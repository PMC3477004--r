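# Independent reference implementations used to validate package code.
# Everything here is deliberately naive (brute force, enumeration,
# quadrature) and shares no code with the implementation under test.

`%||%` <- function(a, b) if (is.null(a)) b else a

# acyclicity via repeated leaf stripping
oracleAcyclic <- function(adj) {
  a <- adj * 1
  repeat {
    if (nrow(a) == 0) return(TRUE)
    sinks <- which(rowSums(a) == 0)
    if (!length(sinks)) return(FALSE)
    a <- a[-sinks, -sinks, drop = FALSE]
  }
}

# every conceivable single-edge change, validity-tested from scratch
oracleMoves <- function(adj, fanIn) {
  n <- nrow(adj)
  count <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (adj[i, j]) {
      a <- adj; a[i, j] <- FALSE
      if (oracleAcyclic(a) && all(colSums(a) <= fanIn)) count <- count + 1
      a <- adj; a[i, j] <- FALSE; a[j, i] <- TRUE
      if (oracleAcyclic(a) && all(colSums(a) <= fanIn)) count <- count + 1
    } else {
      a <- adj; a[i, j] <- TRUE
      if (oracleAcyclic(a) && all(colSums(a) <= fanIn)) count <- count + 1
    }
  }
  count
}

# skeleton + v-structure signature identifying a Markov-equivalence class
oracleClassKey <- function(adj) {
  n <- nrow(adj)
  skel <- which((adj | t(adj)) & upper.tri(adj))
  vs <- character(0)
  for (j in seq_len(n)) {
    pa <- which(adj[, j])
    if (length(pa) >= 2) {
      for (a in pa) for (b in pa) {
        if (a < b && !adj[a, b] && !adj[b, a])
          vs <- c(vs, paste(a, b, j, sep = "-"))
      }
    }
  }
  paste(paste(skel, collapse = ","), "|", paste(sort(vs), collapse = ","))
}

# random DAG via a random topological order, capped in-degree
randomDag <- function(n, pEdge = 0.4, fanIn = n - 1, nodes = NULL) {
  ord <- sample(n)
  a <- matrix(FALSE, n, n)
  for (jj in 2:n) {
    j <- ord[jj]
    cand <- ord[seq_len(jj - 1)]
    for (i in cand[sample.int(length(cand))]) {
      if (sum(a[, j]) >= fanIn) break
      if (runif(1) < pEdge) a[i, j] <- TRUE
    }
  }
  if (is.null(nodes)) nodes <- paste0("N", seq_len(n))
  dimnames(a) <- list(nodes, nodes)
  a
}

# 2-D quadrature of the Normal x Normal-Gamma integrand for a parentless
# node: the projected parameter prior on a single variable in an n-node
# domain is tau ~ Gamma((alphaW - n + 1)/2, rate = t0/2) and
# mu | tau ~ Normal(0, 1/(alphaMu * tau)).
oracleParentlessScore <- function(x, nDomain, alphaMu, alphaW, t0) {
  shape <- (alphaW - nDomain + 1) / 2
  rate <- t0 / 2
  fTau <- function(tau) {
    vapply(tau, function(tt) {
      inner <- function(mu) {
        vapply(mu, function(m)
          prod(stats::dnorm(x, m, 1 / sqrt(tt))) *
            stats::dnorm(m, 0, 1 / sqrt(alphaMu * tt)), numeric(1))
      }
      stats::integrate(inner, -Inf, Inf, rel.tol = 1e-10)$value *
        stats::dgamma(tt, shape = shape, rate = rate)
    }, numeric(1))
  }
  log(stats::integrate(fTau, 0, Inf, rel.tol = 1e-9)$value)
}

# AUC by explicit pairwise comparison (ties count one half)
oracleAuc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# per-node energy of a parent set against a belief matrix
oracleNodeEnergy <- function(B, child, parents) {
  n <- nrow(B)
  e <- 0
  for (i in seq_len(n)) {
    if (i == child) next
    e <- e + abs(B[i, child] - as.numeric(i %in% parents))
  }
  e
}

# observational linear-Gaussian data on a small chain network
chain3Data <- function(nRecords = 50, seed = 9, wSeed = 2) {
  g <- bnNetwork(edges = data.frame(from = c("A", "B"), to = c("B", "C")),
                 nodes = c("A", "B", "C"))
  w <- drawWeights(g, seed = wSeed)
  des <- interventionDesign(data.frame(node = NA_character_,
                                       direction = "none",
                                       count = nRecords))
  list(gold = g, sim = simulateGaussian(g, w, des, seed = seed))
}
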