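---
title: "Propagation and screening: the model behind rwrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagation and screening: the model behind rwrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrscreen)
```

# The model

`rwrscreen` prioritizes candidate disease genes in three steps:
propagation from validated genes over a confidence-weighted
protein–protein interaction (PPI) network, extraction of high-probability
candidates, and a cascade of three screening filters. This vignette
explains each step, the assumptions behind it, the parameters that
matter, and the numerical and design choices the implementation makes.

## The network and its transition operator

The network is undirected, with one positive confidence weight per edge
(STRING combined scores, integers 1–999, in typical use). Construction
(`buildNetwork()`) enforces: no self-loops (dropped with a warning — a
protein's interaction with itself carries no information for
propagation between genes); duplicate listings of a pair collapse to
one edge, keeping the **maximum** score when they disagree (STRING
files list each pair in both directions with equal scores, so a
conflict indicates malformed input; the maximum is the conservative
choice for the linkage filter, which asks whether *any* strong evidence
links two proteins). Node order is fixed to the lexicographic sort of
the identifiers at construction, so every matrix and vector derived
from a network is reproducible byte-for-byte.

The transition operator is the column-normalized adjacency matrix:
`M[i,j] = w(i,j) / sum_k w(k,j)`, the probability of stepping from j to
its neighbor i proportionally to edge confidence. Every column over a
connected node sums to exactly 1; an isolated node's column is zero.
The operator is kept as a sparse `Matrix::dgCMatrix`, so the walk runs
comfortably at interactome scale (~19k nodes, ~4M edges).

One notational subtlety: the update is sometimes written with a
transposed normalized adjacency matrix, which applied literally is a
row-stochastic operator and does not conserve probability. `rwrscreen`
uses the standard mass-conserving reading — multiply the
column-stochastic `M` by the current probability vector — which is the
fixed-point definition used throughout the random-walk-with-restart
(RWR) literature.

## The walk

With seed distribution `P0` (each of the `m` validated genes gets
`1/m`), restart probability `r`, and `M` as above:

```
P(t+1) = (1 - r) * M %*% P(t) + r * P0,    P(0) = P0
```

iterated until the L1 change drops below `tol`. Because the map
contracts at factor `(1 - r)` per step, convergence at `r = 0.8` takes
roughly `log(tol)/log(0.2)` ≈ 9 iterations regardless of network size;
the `maxIter = 10000` guard therefore never triggers on sane input, and
tripping it is reported as a classified non-convergence error rather
than a warning. The fixed point solves
`P = r (I − (1−r) M)⁻¹ P0`, and the test suite checks the iterate
against exactly that dense linear solve on networks small enough to
invert (≤ 50 nodes).

Parameters:

| parameter | default | meaning |
|---|---|---|
| `r` | 0.8 | restart probability; higher keeps mass near the seeds. 0.8 is the value established in prior RWR prioritization work, and we keep it. |
| `tol` | 1e-6 | L1 stopping tolerance; well below the 1e-5 candidate cutoff, so iteration error cannot move a gene across the cutoff. |
| `probThreshold` | 1e-5 | inclusive candidate cutoff on the converged probability. |

Two contracts worth noting. First, *seed genes are excluded from the
candidate set*: the goal is novel genes, and a seed passing through the
filters would contaminate every downstream count. Because seeds are
excluded either way, it does not matter whether the cutoff is applied
before or after the exclusion. Second, *isolated nodes leak mass*
(their transition column is zero); the walk warns when the converged
vector sums to less than 1 by more than 1e-9 instead of silently
renormalizing, because a renormalization would quietly change every
probability against the documented fixed point.

# The three screening filters

Propagation alone has a known failure mode: central (hub) nodes
accumulate probability *whatever* the seeds are. The three filters
attack this and two other failure modes in sequence.

## Permutation Z-score

`permutationTest()` draws `nPerm` random seed sets of size `m`
uniformly from all network nodes, re-runs the walk for each, and
records every candidate's probability. The Z-score
`(Pro − ProM)/ProSTD` then measures how specific a candidate's
probability is to the *actual* seeds; `Z > 1.96` (strict) passes.

Design choices made here, and why:

- **Self-seeded draws are excluded from a candidate's own null**
  (`excludeSelfDraws = TRUE`). When the candidate itself is sampled
  into a random set it receives at least `r/m` restart mass directly —
  at default fixture scale 0.04, roughly an order of magnitude above
  anything propagation can deliver. Left in, these spikes dominate the
  null standard deviation and push every Z-score toward zero, making
  the filter vacuous; the magnitudes of published Z-scores from this
  kind of screen are only reproducible with the self-draws excluded.
  The null then answers the right question: how much probability does
  this gene receive *from* a random seed set elsewhere in the network?
  `excludeSelfDraws = FALSE` restores the raw all-draws summary.
- **Sample (n−1) standard deviation**: the null is an estimated
  distribution from draws; at `nPerm = 1000` the difference from the
  population form is negligible, but the sample estimator is the
  principled one.
- **`ProSTD = 0`** (all null draws identical — possible on tiny or
  degenerate networks) would make the ratio undefined; the score is
  defined as +Inf when `Pro > ProM`, −Inf when below, 0 when equal,
  which preserves pass/fail semantics without crashing.
- **Uniform draws vs degree-matched**: uniform sampling over all nodes
  is the default (the literal reading of "randomly constructed" sets);
  `degreeMatched = TRUE` draws each replacement from the degree decile
  of the seed it replaces, a stricter null for hub-dominated networks,
  offered because hub bias is precisely what this filter targets.
- Random sets *may* contain true seed genes; with 1375 seeds in a 19k
  network some overlap is unavoidable, and excluding them would bias
  the null low.

## Maximum linkage score

`MLS(g) = max Q(g, g′)` over validated genes `g′` — the strongest
direct edge to any validated gene; genes never adjacent to a validated
gene score 0. The cut is **inclusive** at 900, STRING's
highest-confidence band. This filter removes candidates that ranked
high only through long, individually weak paths.

## Maximum enrichment score

Each gene g gets a functional profile `V(g)`: for every annotation
term F (GO terms, KEGG pathways — any GMT file), the score
`ES(g,F) = −log10 P(X ≥ m)` where the hypergeometric `X` counts how
many of g's `n` network neighbors fall into F's `M` genes out of a
universe of `N`. The upper tail is computed with
`stats::phyper(log.p = TRUE)` so deep tails do not underflow; the test
suite verifies it against exhaustive `choose()` enumeration for every
configuration with `N ≤ 20` at 1e-10. The upper summation limit is
`min(n, M)` — identical to summing to `n` since larger overlaps have
zero mass, but numerically explicit. `m = 0` gives a tail of exactly 1
and a score of exactly 0; a neighbor-less gene gets an all-zero profile
with a warning.

`MES(g)` is the maximum cosine similarity between `V(g)` and any
validated gene's profile; cosine of a zero-norm vector is defined as 0.
For non-negative profiles the similarity lies in [0, 1]. The cut is
inclusive at 0.98 ("threshold 0.98" is read as ≥, matching the other
inclusive cut).

Choices: `N` defaults to 20000 (approximately the human protein-coding
gene count) and is configurable, since the right universe depends on
the annotation source. Neighbors are counted at *any* positive
confidence by default (`neighborMinScore = 0`), the literal reading of
"interacting genes"; a cutoff is exposed for stricter profiles.
Validated genes' own profiles are computed on the full network (not a
seed-excluded one): the profile describes a gene's functional
neighborhood, which does not change with its seed status.

## The cascade

`applyFilters()` computes all three scores for every candidate and
flags the cuts (`Z` strict, `MLS` and `MES` inclusive); a gene passing
all three is *inferred*. With `lazy = TRUE`, MLS is computed only for
Z-passing genes and MES only for genes passing both earlier filters —
skipped scores are recorded as `NA`, never as a computed 0, so a
missing value is always distinguishable from a true zero. The results
table is sorted by descending MES with ties broken by gene identifier,
making output order deterministic.

# The synthetic benchmark

`makeBenchmark()` builds the desk-scale test bed used throughout the
test suite:

- **Background**: a preferential-attachment (Barabási–Albert) graph,
  `attachDegree = 3` edges per incoming node. Preferential attachment
  is chosen deliberately: it produces the heavy-tailed hub structure of
  real PPI networks, i.e. exactly the bias the permutation filter must
  control. Background weights are uniform integers in [100, 899] —
  kept *below* the 900 band so that the only highest-confidence
  structure is the planted module, mirroring the separation the
  linkage filter assumes in real STRING data.
- **Planted module**: 40 of the 500 nodes; each within-module pair is
  added independently with probability 0.8 at confidence 950 (existing
  edges upgraded to the maximum). Half the module becomes the seed set,
  half is withheld as ground truth.
- **Annotations**: 8 module terms, each covering ≥ 80% of the module
  plus a few random fillers, and 40 background terms of 10–40 random
  genes — giving module genes (seeds *and* truths) strongly parallel
  enrichment profiles while decoys' profiles point elsewhere.

Every generator is bit-reproducible under its `rngSeed`, and the
composed bundle serializes to plain text (STRING-dialect links file,
gene lists, GMT, JSON parameter manifest) and back losslessly.

What the benchmark does *not* emulate: STRING's separate evidence
channels (only the combined score is modeled), realistic score
distributions (real combined scores are heavily skewed low),
annotation hierarchies (terms are flat sets, as in GMT), and scale.
Passing the recovery test therefore shows the pipeline's machinery is
correct and its filters discriminate under planted signal; it does not
certify biological performance on real interactomes.

Recovery behaviour at defaults (500 nodes, module 40, 200
permutations): across seeds the pipeline recovers ≥ 70% — typically
95–100% — of withheld module genes with ≤ 10% (typically 0) decoys in
the inferred set. These margins are deliberately loose so that the
property is stable across RNG seeds rather than tuned to any one draw.

# Reproducibility and the pipeline driver

`runPipeline()` wires the stages together and writes, next to the
results table, a JSON manifest holding every parameter, the MD5 of
every input file, and the per-stage counts (candidates → Z-pass →
MLS-pass → inferred) — the run's audit trail. No timestamps go into
output files, so two runs with the same configuration and `rngSeed` are
byte-identical, a property the test suite asserts on file hashes. All
package randomness flows through `withr::with_seed`, so library calls
never disturb the caller's RNG state.

Problem sizes in the test suite are chosen for tight feedback loops:
oracle comparisons on ≤ 50-node networks (dense solves are exact
there), calibration on a 60-node graph with ~2400 Monte Carlo draws
(standard error ~0.04 on the mean Z), and recovery on the 500-node
default benchmark with `nPerm = 200` (the null mean stabilizes well
before 200 draws at that scale; 1000 remains the production default).

# Known limitations

- The permutation null re-runs one walk per draw; at full interactome
  scale with `nPerm = 1000` this is the dominant cost (roughly 9 sparse
  matrix–vector products per walk). The operator is factored once, but
  the draws are not parallelized.
- Uniform random seed sets under-represent hub effects relative to a
  degree-matched null; the option exists but is not the default.
- No multiple-testing correction is applied across candidates — the
  cascade is a screening heuristic, not a calibrated discovery
  procedure, and its thresholds (1.96, 900, 0.98) are conventions, not
  error-rate guarantees.
- Identifiers are opaque strings; mapping between gene and protein
  namespaces is upstream preparation, not the package's job.
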