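# rwrscreen

Network propagation and screening for disease-gene prioritization.

## The problem

Many diseases have a core of validated associated genes, but the full
gene complement is unknown. Because interacting proteins tend to share
function, the neighborhood of the validated genes in a protein–protein
interaction (PPI) network is the natural place to look for new
candidates. `rwrscreen` implements a guilt-by-association pipeline for
exactly this setting: given a confidence-weighted PPI network (STRING
combined scores, 1–999) and a list of validated disease genes, it ranks
every other protein by network propagation and then screens the
high-ranking ones with three orthogonal filters that control the usual
failure modes (hub bias, weak linkage, functional incoherence).

It is aimed at computational biologists who have a disease gene list
(e.g. from DisGeNET) and a STRING-style edge list, and want a
reproducible, parameterized, testable version of this analysis at any
scale — from a 500-node synthetic benchmark to the full human
interactome.

## The method

**Propagation.** A random walk with restart (RWR) over the weighted
network. With `M` the column-normalized adjacency matrix (entry
`M[i,j]` = weight(i,j) / Σ_k weight(k,j)), seed distribution `P0`
(1/m on each of the m validated genes), and restart probability
`r = 0.8`:

    P(t+1) = (1 − r) · M · P(t) + r · P0

iterated from `P(0) = P0` until ‖P(t+1) − P(t)‖₁ < 1e-6. Nodes with
converged probability ≥ 1e-5 (seeds excluded) are the raw candidates.

**Screening.** Each candidate g is then scored three ways:

1. *Permutation Z-score* — the walk is re-run on `nPerm` random seed
   sets of the same size m; `Z(g) = (Pro(g) − ProM(g)) / ProSTD(g)`
   standardizes g's true-seed probability against the mean and standard
   deviation of its random-seed probabilities. Genes with `Z > 1.96`
   pass. Draws in which g itself was sampled as a seed are excluded
   from its own null by default (`excludeSelfDraws`), since the direct
   restart mass r/m would otherwise swamp the null standard deviation.
2. *Maximum linkage score* — `MLS(g) = max Q(g, g′)` over validated
   genes g′, where Q is the edge confidence. `MLS ≥ 900` (STRING's
   highest-confidence band) passes.
3. *Maximum enrichment score* — for every gene, a functional profile
   `V(g)` holds, per annotation term F, the hypergeometric enrichment
   `ES(g,F) = −log10 P(X ≥ m)` of the overlap m between g's network
   neighbors (n of them) and F's gene set (M of N genes total).
   `MES(g) = max cos(V(g), V(g′))` over validated g′; `MES ≥ 0.98`
   passes.

Candidates passing all three filters are the **inferred genes**.

## Worked example

A synthetic benchmark plants a densely interconnected high-confidence
module in a preferential-attachment background, uses half the module as
seeds, and asks the pipeline to recover the withheld half:

```r
library(rwrscreen)

b <- makeBenchmark(nNodes = 200, moduleSize = 20, rngSeed = 42)
d <- tempfile(); writeFixtureBundle(b, d)

cfg <- pipelineConfig(network     = file.path(d, "network.txt"),
                      seeds       = file.path(d, "seeds.txt"),
                      annotations = file.path(d, "terms.gmt"),
                      outDir      = file.path(d, "out"),
                      nPerm = 200, rngSeed = 1)
res <- runPipeline(cfg)
head(res$records[, c("gene","probability","z_score","mls","mes","inferred")], 5)
#>   gene probability z_score mls    mes inferred
#> 1 g167    0.007517   5.521 950 0.9954     TRUE
#> 2 g196    0.008936   9.185 950 0.9936     TRUE
#> 3 g066    0.008646   4.339 950 0.9924     TRUE
#> 4 g095    0.009619   4.200 950 0.9923     TRUE
#> 5 g149    0.009036   5.226 950 0.9918     TRUE
```

The manifest records the cascade: 158 candidates cleared the 1e-5
probability cutoff, 10 passed the Z-score filter, 8 of those passed the
linkage filter, and all 8 passed the enrichment filter — and those 8
inferred genes are 8 of the 10 withheld module members, with no decoys.
Each row reads like a line of a results table: g167 sits two orders of
magnitude above the probability cutoff, is 5.5 null standard deviations
above its random-seed expectation, touches a validated gene at
confidence 950, and its functional profile is nearly parallel
(cos = 0.995) to a validated gene's.

The same pipeline runs from the shell:

```sh
inst/cli/rwrscreen simulate --out fx/ --n-nodes 200 --module-size 20
inst/cli/rwrscreen run --network fx/network.txt --seeds fx/seeds.txt \
    --annotations fx/terms.gmt --out out/ --n-perm 200 --rng-seed 1
```

For a real analysis, point `--network` at a STRING
`protein.links.*.txt.gz` file, `--seeds` at your Ensembl protein list,
and `--annotations` at a GMT file of GO/KEGG gene sets.

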