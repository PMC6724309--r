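# netamp — Network Perturbation Amplitude scoring for two-layer causal networks

`netamp` quantifies how strongly a treatment perturbs a causal biological
network, using only a transcriptomic contrast (per-gene log2 fold-changes and
t- or Wald z-statistics). It is aimed at systems toxicology and systems
biology analyses in which curated cause-and-effect network models — a signed
functional *backbone* of protein activities and processes, plus a
*transcript layer* of downstream genes forming each node's expression
footprint — are scored against treatment-versus-control comparisons.

## The method

Gene fold-changes β are propagated backwards onto the backbone by solving a
constrained least-squares smoothing problem over the signed two-layer graph:

```
min_f  Σ_{x→y} ( f(x) − σ(x→y)·f(y) )²    s.t.  f|_V0 = β
```

where σ ∈ {+1, −1} is the edge sign and V0 the transcript layer. The unique
minimizer is `f = −L3⁻¹ L2 β`, with L3 and L2 blocks of the signed Laplacian.
The **Network Perturbation Amplitude** is the edge-averaged coherence of the
inferred backbone profile:

```
NPA = (1/|E|) Σ_{e∈E} ( f(e0) + σ(e)·f(e1) )²  =  fᵀQf / |E|  ≥ 0
```

Each score carries three companion statistics — a delta-method 95%
confidence interval propagated from the gene-level standard errors
(`se = |foldChange/t|`), and two permutation tests that reshuffle the
transcript layer (**O**) or the backbone (**K**) — and is called significant
only when all three pass. Scores decompose additively into per-node
contributions (leading nodes = the nodes carrying 80% of the score), and
significant scores across a suite of networks aggregate into a relative
**Biological Impact Factor** (BIF) with a δ similarity index between
treatments. A synthetic-data generator produces two-layer networks and
contrasts with planted coherent perturbations, so the whole pipeline is
testable without any external data.

## Worked example

```r
library(netamp)

cfg <- synthConfig(nBackbone = 10, density = 0.4, negProb = 0.5,
                   footprintMin = 5, footprintMax = 8, footprintFraction = 1,
                   amplitude = 1, noiseSd = 0.2, nBackground = 50,
                   balanced = TRUE, seed = 42)
net <- generateNetwork(cfg, name = "demo", family = "stress")
net
#> TwoLayerNetwork 'demo' [family: stress]
#>   backbone: 10 nodes, 25 signed directed edges
#>   transcript layer: 63 genes, 63 footprint edges

ctr <- generateContrast(net, cfg, name = "treated")
res <- scoreContrast(net, ctr, nPerm = 500, seed = 42)
res
#> NpaResult [demo x treated]
#>   NPA = 3.948  95% CI [3.822, 4.074]
#>   p(O) = 0.001996  p(K) = 0.00998  *O*K  (significant)

leadingNodes(res)
#> LeadingNodeSet: 8/10 nodes reach 80% of the NPA
#>   n04 (+), n01 (+), n03 (+), n02 (+), n09 (+), n05 (+), n10 (+), n06 (-)
```

The planted perturbation has amplitude a = 1 on a balanced backbone, whose
noiseless NPA is 4a² = 4; the recovered score 3.95 with a CI of ±0.13 and
both permutation p-values at their near-minimum shows the method recovering
the planted signal and calling it specific to the network's wiring. The
leading-node list names the backbone nodes driving the score, with their
inferred direction (activation `+` / inhibition `-`).

File-based workflows use the same machinery end to end: networks are
tab-separated edge lists (`source  sign  target  layer`), contrasts are
`nodeLabel / foldChange / t` tables, and

```r
cfg <- npaRunConfig(networks = c("net1.tsv", "net2.tsv"),
                    contrasts = "contrasts.tsv",
                    nPerm = 500, seed = 1, outDir = "npa_out")
res <- runNpa(cfg)       # scores every network x contrast cell + files
bif <- runBif(cfg, res)  # relative BIF + delta across network families
```

writes JSON and TSV outputs that are byte-identical across runs with the
same root seed. A thin command-line wrapper with `score`, `bif` and `synth`
subcommands ships in `inst/scripts/netamp-cli.R`.

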