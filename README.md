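# bnmc

Structure learning of Gaussian Bayesian networks by Metropolis–Hastings
MCMC, with intervention-aware scoring and informative structure priors.

## What problem this solves

Regulatory and signalling pathways are networks, and the measurements we
have of their components (expression levels, phosphoprotein abundances)
rarely identify the network outright. `bnmc` is for researchers in systems
biology who want to *reconstruct a directed network from continuous
measurements* and to know how much extra leverage two common additions
give:

* **interventions** — experiments in which some components were clamped
  (inhibited or activated), so their values are no longer produced by the
  system's own dynamics;
* **prior knowledge** — beliefs about which edges exist, e.g. derived from
  pathway databases, encoded as a matrix `B` with entries in [0, 1].

## The model

A Bayesian network couples a DAG `M` with the factorization
`P(X1..XN) = ∏ P(Xi | X_parents(i))`. Structures are scored by the BGe
marginal likelihood `P(D|M) = ∫ P(D|q, M) P(q|M) dq` (Gaussian likelihood,
Normal–Wishart prior, closed form) and sampled with Metropolis–Hastings
over single-edge moves (add / delete / reverse, fan-in 3), acceptance

```
A = min{ 1,  [P(D|Mnew) P(Mnew) |N(Mold)|] / [P(D|Mold) P(Mold) |N(Mnew)|] }
```

Three samplers:

| scheme | data | structure prior | what it adds |
|--------|------|-----------------|--------------|
| BN     | observational | flat | baseline |
| BN-I   | interventional + clamp mask | flat | clamped records leave the clamped node's score; posteriors accumulate TS-equivalence classes |
| BN-E   | any | Gibbs: `P(M|β) ∝ exp(−β E(M))`, `E(M) = Σ |B_ij − M_ij|` | samples `β` jointly with `M`, so the data decide how much to trust `B` |

Posterior output is a matrix of marginal edge probabilities (accumulated
over equivalence-class representatives, so unidentifiable directions are
reported honestly), evaluated against a gold-standard network by ROC AUC
under a directed (DGE) and an undirected (UGE) criterion.

A linear-Gaussian generator reproduces the classic down-sampled
flow-cytometry design on the 11-node Raf signalling pathway: 100 records =
16 observational + 14 for each of 6 interventions, `σ = 0.1`, edge weights
uniform on ±[0.5, 2].

## Worked example

```r
library(bnmc)
gold <- rafGoldStandard()                 # 11 nodes, 20 edges
reps <- simulateReplicates(gold, k = 5, design = rafDesign(), seed = 1)
schemes <- list(
  BN        = list(method = "BN"),
  `BN-I`    = list(method = "BN-I"),
  `BN-E100` = list(method = "BN-E", beliefs = makeB100(gold)),
  `BN-E50`  = list(method = "BN-E", beliefs = makeB50(gold, seed = 1)))
cmp <- compareMethods(reps, schemes, gold, mcmcConfig(nSteps = 1e5, seed = 1))
cmp$summary
```

```
   scheme criterion  mean_auc     sd_auc n_datasets
1      BN       DGE 0.6895000 0.13891950          5
2 BN-E100       DGE 0.9353889 0.02814384          5
3  BN-E50       DGE 0.6588889 0.09599222          5
4    BN-I       DGE 0.8509444 0.12361963          5
5      BN       UGE 0.7955714 0.11413874          5
6 BN-E100       UGE 0.9474286 0.05027628          5
7  BN-E50       UGE 0.7717143 0.07096205          5
8    BN-I       UGE 0.8308571 0.11404260          5
```

Reading this: interventions (BN-I) and correct prior knowledge (BN-E100)
both lift directed-edge accuracy far above the plain sampler — they break
the equivalence-class symmetries that make directions unidentifiable from
observational data alone. Half-corrupted knowledge (BN-E50) neither helps
nor hurts: the jointly sampled inverse temperature collapses towards zero
(`cmp$betaMedians` shows medians ≈ 0.1–0.6 for B50 versus ≈ 2–16 for
B100), effectively switching the unreliable prior off.

Small-system check against exact enumeration:

```r
cd  <- simulateGaussian(g3 <- bnNetwork(edges = data.frame(
         from = c("A", "B"), to = c("B", "C"))),
         drawWeights(g3, seed = 2),
         interventionDesign(data.frame(node = NA, direction = "none",
                                       count = 50)), seed = 9)
tr  <- runMcmc(cd$data, "BN", mcmcConfig(nSteps = 2e5, seed = 11))
ex  <- exactEdgePosterior(cd$data)       # all 25 DAGs on 3 nodes
max(abs(edgePosteriors(tr)@directed - ex@directed))
#> 0.0037
```

## Command line

A thin CLI over the same functions lives in `inst/cli/bnmc`
(`Rscript $(Rscript -e 'cat(system.file("cli/bnmc", package="bnmc"))') ...`):
subcommands `fixtures`, `simulate`, `infer` (runs every chain twice and
writes a two-seed convergence report; exit code 3 on failure), `eval`,
`compare`. Exit codes: 0 success, 2 input error, 3 convergence failure.

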