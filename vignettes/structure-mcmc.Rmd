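---
title: "Structure MCMC for Gaussian Bayesian networks: models, priors and design choices"
author: "bnmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure MCMC for Gaussian Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnmc)
```

## The inference problem

A Bayesian network over variables $X_1,\dots,X_N$ pairs a directed acyclic
graph $M$ with conditional distributions so that
$P(X_1,\dots,X_N) = \prod_i P(X_i \mid X_{\pi_i[M]})$, where $\pi_i[M]$ are
the parents of node $i$. Given a data matrix $D$ (records $\times$ nodes),
score-based structure learning weighs each candidate graph by its marginal
likelihood $P(D \mid M) = \int P(D \mid q, M)\, P(q \mid M)\, dq$. Because
the number of DAGs grows super-exponentially and the posterior over
structures is diffuse at realistic sample sizes, we do not search for one
best graph: we sample graphs from $P(M \mid D)$ with Metropolis-Hastings
MCMC and report marginal posterior probabilities of individual edges.

The package implements three samplers that share this skeleton:

* **BN** — plain structure MCMC under a flat structure prior;
* **BN-I** — intervention-aware MCMC for data in which some measurements
  were externally clamped (e.g. chemically inhibited or activated
  proteins);
* **BN-E** — MCMC over structures *jointly* with an inverse-temperature
  hyper-parameter $\beta$ that weighs an energy-based prior built from a
  belief matrix of prior edge knowledge.

## Scoring: the BGe marginal likelihood

The data are continuous, so the closed-form marginal likelihood is the BGe
metric: a Gaussian likelihood integrated against a Normal-Wishart parameter
prior. The score decomposes into per-node terms, each depending only on the
node and its parents; a single-edge move therefore changes at most two
local terms, which is what makes long MCMC runs cheap. Local scores are
memoized (cache keys include the child's clamped-record signature, so
observational and interventional runs can share infrastructure), and cached
values reproduce cold computation bit-for-bit.

Concrete hyper-parameters (the standard Geiger-Heckerman choice): data are
standardized per column (mean 0, variance 1), the prior mean is zero,
$\alpha_\mu = 1$, $\alpha_w = N + 2$, and the prior scatter matrix is
$t_0 I$ with $t_0 = \alpha_\mu (\alpha_w - N - 1)/(\alpha_\mu + 1)$, a
proper prior. Standardization statistics use **all** records, including
clamped ones, so that masked and unmasked scoring see identical scales;
`bgeLocalScore(..., standardize = FALSE)` is available when the caller has
already fixed the scale (the package's own tests use it to verify that a
masked score equals, exactly, the score on a dataset with the clamped
records physically removed). The single-node score is verified against
direct numerical quadrature of the Normal $\times$ Normal-Gamma integrand
to $10^{-4}$.

Two properties matter scientifically. On purely observational data the BGe
metric is *score equivalent*: Markov-equivalent DAGs (same skeleton, same
v-structures) receive identical scores, so edge directions within an
equivalence class are not identifiable. Interventions break that symmetry:
measurements of a clamped node are excluded from that node's local score
(and only that node's), so $A \to B$ and $B \to A$ generally score
differently once $B$ is clamped in part of the records. This asymmetry is
the mechanism by which interventional data recover edge directions.

## Equivalence classes and posterior accumulation

Reported posteriors are honest about identifiability. At every retained
step the sampled DAG is transformed to its class representative before it
is tallied:

* BN and BN-E use the CPDAG (v-structures oriented, then Meek-rule
  closure). A directed class edge adds 1 to its direction; an undirected
  class edge adds 1 to *both* directions — the superposition rule used by
  the directed evaluation criterion below.
* BN-I uses the TS-equivalence class: two dummy parents are attached to
  every intervened node, the augmented DAG is converted to a CPDAG, and
  the dummies are stripped. Every edge incident to an intervened node is
  thereby directed. Dummy node identifiers are internal and never leak
  into results.

A separate symmetric accumulator tallies plain adjacency (is there an edge
between $i$ and $j$ in either direction), which is what the undirected
evaluation needs; it is deliberately *not* derived from the directed
matrix, because under the superposition rule both directed entries of a
reversible edge can approach 1 while the adjacency frequency is the
quantity with a clean interpretation. Accumulating raw DAGs instead is
available (`rawDags = TRUE`) for sensitivity analysis.

## The energy prior and the joint sampler

Prior knowledge enters as a belief matrix $B$ with entries in $[0,1]$:
$B_{ij} = 0.5$ means no information about edge $i \to j$, values near 1
(0) encode confident presence (absence). The energy of a structure is
$E(M) = \sum_{i \ne j} |B_{ij} - M_{ij}|$ — zero iff the structure matches
the prior exactly. Self-pairs are excluded: structures never contain
self-edges, and any fixed diagonal convention would only shift $E$ by a
constant that cancels in every acceptance ratio; excluding it keeps the
"perfect match has zero energy" property clean.

The structure prior is the Gibbs distribution
$P(M \mid \beta) \propto e^{-\beta E(M)}$. Its normalizer is approximated
by a per-node product over fan-in-restricted parent sets,
$Z(\beta) = \prod_n \sum_{\pi} e^{-\beta \varepsilon(n, \pi)}$, which for
static networks is an upper bound on the true DAG-space sum (the product
ranges over all parent-set combinations, DAG or not); the fan-in
restriction of 3 keeps the bound tight, and the package's tests verify the
bound exhaustively on up to 4 nodes. $Z$ never appears in
structure-vs-structure ratios, but it *does* appear in $\beta$-moves, where
it is recomputed exactly at every proposal from precomputed per-node energy
spectra (176 parent sets per node at 11 nodes and fan-in 3 — too cheap to
be worth interpolating).

The joint sampler targets $P(M, \beta \mid D) \propto P(D \mid M)
P(M \mid \beta) P(\beta)$ and strictly alternates two sub-moves:

1. a structure move at fixed $\beta$ (a uniform draw from the valid
   add/delete/reverse neighborhood, with the Hastings correction
   $|\mathcal N(M_{old})| / |\mathcal N(M_{new})|$);
2. a $\beta$ move at fixed structure: a uniform proposal of half-width
   `betaStep` reflected at 0 and `betaMax`, which keeps the proposal
   symmetric so only the energy term and the partition-function ratio
   remain.

$P(\beta)$ is uniform on $[0, \beta_{max}]$ with $\beta_{max} = 30$:
the sampled posteriors of interest either concentrate near zero (prior
knowledge in conflict with the data) or spread over moderate values, and a
bounded uniform prior adds no structure of its own. `betaStep = 1`
gives $\beta$ acceptance rates in a healthy range in the regimes exercised
here. Edge reversal is a single move (not delete-plus-add), validity-checked
for acyclicity. The chain starts at the empty graph and $\beta_{max}/2$.

The sampled $\beta$ values are themselves a diagnostic: with a fully
correct belief matrix (`makeB100`) the posterior of $\beta$ spreads over
large values (the prior is integrated), whereas with a half-corrupted one
(`makeB50`) it collapses towards zero — the model switches unreliable
knowledge off rather than letting it damage the reconstruction.

## Synthetic data: what is emulated, and what is not

The generator emulates the down-sampled interventional design of the
flow-cytometry study of the Raf signalling pathway. The gold standard
(`rafGoldStandard()`) is the 11-node, 20-edge consensus network; the
interventional design (`rafDesign()`) is 16 observational records plus 14
records for each of 6 interventions (Akt, PKC, PIP2, Mek inhibited; PKC,
PKA activated — PKC intentionally appears in both lists, as two distinct
blocks), 100 records in total.

Data follow a linear-Gaussian law: each node is
$\mathcal N(\sum_k w_{ki} x_k, \sigma^2)$ over its parents, with
$\sigma = 0.1$ and $|w| \sim U[0.5, 2]$ with random sign, drawn fresh per
replicate. Clamped nodes are set deterministically to $-1$ (inhibition) or
$+1$ (activation): the magnitudes are not dictated by the emulated design,
so they were fixed once at order $10\sigma$ — informative without
numerical pathology — and are configurable. All draws are seeded and
regeneration is bit-identical.

What the generator does **not** emulate: measurement noise that is
non-Gaussian or heteroscedastic, saturating enzyme kinetics, and the
marginal distributions of real cytometry measurements. A
sigmoid-squashed variant (`simulateSigmoid()`) is provided as a clearly
labelled synthetic stand-in for saturating responses, and is excluded from
the reference comparisons. Passing tests on the Gaussian generator
therefore demonstrate correctness of the inference machinery under its own
generative assumptions, not performance on real cytometry data.

## Evaluation

Edge posteriors define a ranking of candidate edges, evaluated against the
gold standard two ways: **DGE** ranks all ordered pairs by the directed
posterior (positives = gold's directed edges), **UGE** ranks unordered
pairs by the skeleton posterior (positives = gold's skeleton). The AUC is
computed by the rank (Mann-Whitney) formula with mid-ranks for ties — the
tie rule is our choice, checked against an established ROC implementation
to $10^{-12}$. A perfect predictor scores 1.00; random scores average
0.50. Whether UGE should use adjacency frequency or the maximum of the two
directed entries is not canonical; the package accumulates adjacency
frequency (declared above), and a plain score matrix fed to `rocAuc()`
falls back to the pairwise maximum.

`compareMethods()` orchestrates the replicated comparison: each scheme runs
on each dataset (run seeds derived from the configuration seed and the
scheme only, so identical dataset copies reproduce identical runs), and
each (scheme, criterion) cell is summarized by mean and standard deviation
over datasets. Two-seed convergence checking (`checkConvergence()`)
compares directed posteriors from two independent chains; agreement is a
necessary but not sufficient condition, and the report says so.

## Numerical and degenerate-input choices

* Constant data columns are centred but not scaled; the proper Wishart
  prior keeps every local score finite. A genuinely singular posterior
  scatter (possible only with an improper prior scale) raises an error.
* A child whose records are all clamped contributes 0 (log of unit
  evidence) to the total score.
* `betaMax = 0` pins $\beta$ at zero, which reduces BN-E to BN and is the
  supported way of running BN-E at a fixed temperature (together with
  `betaStep = 0`).
* Neighborhood counting treats "add $i \to j$ when $j \to i$ exists" as
  invalid via the reachability test, so reversal is the only way to flip
  an edge.
* CPDAG completion uses v-structure orientation plus Meek rules R1-R3,
  sufficient when starting from a DAG's own pattern; correctness is tested
  exhaustively on 4 nodes against a skeleton-plus-v-structure oracle.

## Problem sizes used by the test suite

Exhaustive reference computations use 3-4 nodes (25 and 543 DAGs), where
exact posteriors, score equivalence and the partition bound can be checked
without approximation. Sampler-versus-enumeration agreement is tested at
$2 \times 10^5$ steps on 3 nodes (tolerance 0.05 in maximum absolute edge
posterior). The replicated Raf comparison runs 5 interventional datasets of
100 records at $10^5$ steps per run — enough for the orderings of interest
(BN-I and BN-E with correct knowledge beat BN on directed accuracy;
corrupted knowledge neither helps nor hurts) to be stable across seeds
while keeping the default suite quick; production analyses should use the
$5 \times 10^5$-step default and two-seed convergence checks.

## Known limitations

* The partition function is an upper bound for static networks; its effect
  on $\beta$-moves is a mild bias towards smaller $\beta$, investigated
  and found benign in this model family, but it is an approximation.
* Only one belief matrix with one $\beta$ is supported.
* No missing data, no discrete (multinomial/BDe) scoring, no latent-
  variable equivalence (PAGs), and no PDAG-to-DAG extension: the CPDAG
  machinery serves posterior accumulation, not general causal reasoning.
* Posterior accumulation at every retained step is exact but makes traces
  memory-proportional to `nSteps / thinStore` only through snapshots;
  accumulators themselves are $O(N^2)$.

## A worked example

```{r example, eval = FALSE}
gold <- rafGoldStandard()
reps <- simulateReplicates(gold, k = 5, design = rafDesign(), seed = 1)
schemes <- list(
  BN        = list(method = "BN"),
  `BN-I`    = list(method = "BN-I"),
  `BN-E100` = list(method = "BN-E", beliefs = makeB100(gold)),
  `BN-E50`  = list(method = "BN-E", beliefs = makeB50(gold, seed = 1)))
cmp <- compareMethods(reps, schemes, gold,
                      mcmcConfig(nSteps = 1e5, seed = 1))
cmp$summary
plotComparison(cmp)
```
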