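---
title: "Scoring network perturbation amplitudes from transcriptomic contrasts"
author: "netamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring network perturbation amplitudes from transcriptomic contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netamp)
```

## The model

A two-layer causal network couples a *functional backbone* — signed, directed
edges between molecular activities such as transcription factors, kinases or
processes — to a *transcript layer* of genes whose expression responds to a
backbone node. The transcript edges form each node's expression *footprint*:
the genes it is known to up- or down-regulate. Following the backward-reasoning
paradigm, a measured expression contrast (per-gene log2 fold-changes $\beta$
with t- or Wald z-statistics) is used to infer how strongly the backbone was
perturbed, rather than mapping fold-changes forward onto proteins.

The backbone differential values $f$ solve a constrained least-squares
smoothing problem over the whole two-layer graph,

$$\min_{f}\ \sum_{x \to y}\big(f(x) - \sigma(x\to y)\,f(y)\big)^2
\quad\text{s.t.}\quad f|_{V_0} = \beta,$$

where $\sigma \in \{+1,-1\}$ is the edge sign and $V_0$ the transcript layer,
whose values are pinned to the measured fold-changes. A perturbation that
really acts through the network makes $f$ smooth along activating edges and
anti-smooth along inhibiting ones. The problem is quadratic; writing $L_3$
for the backbone block and $L_2$ for the backbone-gene block of the signed
Laplacian of the two-layer graph (all edges treated as undirected — both
quadratic forms are orientation-invariant), the unique minimizer is
$f = -L_3^{-1} L_2 \beta$. `buildLaplacianBlocks()` factors the solution
operator once per network and reuses it across contrasts and permutations.

The Network Perturbation Amplitude is the edge-averaged coherence of the
inferred profile over the backbone edge set $E$:

$$\mathrm{NPA} \;=\; \frac{1}{|E|}\sum_{e \in E}
\big(f(e_0) + \sigma(e) f(e_1)\big)^2 \;=\; \frac{f^\top Q f}{|E|} \;\ge\; 0 .$$

Note the sign flip between the two forms: the objective *penalizes*
sign-incoherence, the score *rewards* sign-coherent perturbation. Both are
implemented exactly as displayed.

### Structural filters

Two filters precede scoring, in this order:

1. **Under-represented footprints** (`pruneUnderrepresented()`): a backbone
   node with fewer than 5 transcript edges (default, tunable) has all of its
   transcript edges removed — too few genes to support an inference. Pruning
   runs first because it can strip a node's footprint and thereby change the
   second filter's outcome.
2. **Scorability** (`restrictToScorable()`): only backbone nodes with a
   footprinted directed ancestor *and* a footprinted descendant (each
   including the node itself) are kept. Nodes dangling upstream or
   downstream of the anchored region would receive purely extrapolated
   values; they are removed together with their incident edges.

Genes measured in the contrast but absent from the network are ignored;
network genes *not* measured have their transcript edges dropped (absence of
measurement is not evidence of no change), after which both filters are
re-applied (`matchContrast()`).

### Conventions for degenerate input

Backbone self-loops are rejected at read time (undefined in both sums).
Parallel backbone edges are kept and summed term by term: contradictory
parallel edges cancel in the off-diagonal entries while both still count
toward degrees and $|E|$. Node and gene orderings are lexicographic, so all
matrices are independent of file row order. A singular $L_3$ (reciprocal
condition number below $10^{-12}$, e.g. a disconnected backbone component
with no transcript anchor) is an error that names the components involved.

## The three companion statistics

A large NPA alone is not evidence: three statistics decide whether it is a
true positive, and a perturbation is called **significant only when all
three pass**.

* **Confidence interval.** The NPA is a quadratic form
  $\beta^\top M \beta$ with $M = K^\top Q K / |E|$, $K = -L_3^{-1}L_2$.
  First-order (delta-method) propagation of the per-gene standard errors
  $se_g = |\beta_g / t_g|$, genes independent, gives
  $\mathrm{Var} \approx 4\sum_g (M\beta)_g^2 se_g^2$ and a 95% interval
  around the score; the test passes when the lower bound is positive. The
  delta method is accurate when the relative noise is moderate
  ($se/|\beta| \lesssim 0.3$, checked against a parametric bootstrap in the
  test suite); near $\beta \approx 0$ the gradient vanishes and the interval
  collapses — it then fails by convention, which is the desired behaviour.
* **O statistic** (transcript-layer reshuffling): gene labels are permuted
  uniformly across all transcript edges — applied equivalently by permuting
  the entries of $\beta$ — preserving every node's footprint size and sign
  multiset. This asks: does the *assignment* of measured genes to footprints
  matter?
* **K statistic** (backbone reshuffling): backbone node identities are
  relabeled uniformly on the backbone edge list only, each node keeping its
  own footprint, and the blocks are rebuilt. This asks: does the *wiring* of
  the backbone matter?

Both use 500 permutations by default and the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$, whose
smallest value is $1/(n_{\mathrm{perm}}+1)$ — a p-value of exactly zero is
never reported. The 95% null quantile is reported for display; the p-value
is primary. All permutations derive from one root seed through deterministic
per-(network, contrast, statistic) child seeds, so a run is reproducible
byte for byte. Display labels follow the `*O`/`.O` convention (`*` below
0.05, `.` between 0.05 and 0.1) with the CI pass carried as a separate flag.

A property worth knowing: against a perturbation in which every node moves
by the same amount (an all-positive backbone driven coherently), the K
statistic is blind — every relabeling of a topology-preserving permutation
produces the identical score — and the O statistic is equally blind when all
planted fold-changes are equal. Specificity testing needs heterogeneous
perturbation patterns, which is why the power checks in the test suite use
balanced mixed-sign backbones (see below).

## Leading nodes, modules

Because the NPA is positive by construction, interpretation needs the
per-node decomposition. The package uses the symmetric quadratic-form split

$$c_x = \frac{f_x\,(Qf)_x}{|E|}, \qquad \sum_x c_x = \mathrm{NPA},$$

which is exact and standard for quadratic forms; this decomposition formula
is a design choice of this package. The **leading nodes** are the shortest
prefix of the contribution-ranked nodes reaching 80% (default) of the score,
boundary inclusive, ties broken lexicographically. Individual contributions
can be negative (a locally incoherent node); they are kept as-is and sort
last — a deliberate choice over ranking by absolute value, documented here
because the alternative is defensible. Directionality (activation vs
inhibition) is the sign of $f$.

`extractModule()` finds a connected backbone subgraph dense in leading
nodes: node score = mean contribution fraction across contrasts minus a
size penalty, greedy seed-and-grow from the top node, adding the best
neighbour while the subgraph total does not decrease. With zero penalty and
positive contributions this is the seed's connected component; the penalty
(default 0.02, i.e. 2% of the score per node) is the only tuning knob.
Community sub-clustering of large modules is left to igraph directly.

## Aggregation: BIF and δ

With several networks grouped into families (e.g. Cell Stress, Cell Fate),
significant perturbations aggregate into one number per contrast. Network
$i$ receives weight

$$w_i = \frac{1}{|\mathrm{family}(i)|}\cdot\frac{1}{1 + \bar o_i},$$

with $\bar o_i$ the mean Jaccard overlap of backbone node sets against all
other networks — families do not dominate by size, redundant networks do not
double-count. Raw BIF = weighted sum of significant NPA scores;
relative BIF = percent of the reference contrast (auto: the highest raw
BIF). The δ index concatenates the per-network $f$ vectors (zeroed where
non-significant, each network scaled by $\sqrt{w_i/n_i}$) and takes the
cosine similarity with the reference: 1 = same mechanisms, −1 = opposed,
0 = unrelated. These two formulas satisfy the stated qualitative
requirements (family-count and overlap discounting; $\delta \in [-1,1]$ with
$\delta = 1$ for identical mechanisms) but their exact functional form is
this package's choice; both sit behind small, replaceable functions
(`bifWeights()`, `computeDelta()`).

## The synthetic-data generator

`generateNetwork()` / `generateContrast()` emulate the structure the method
consumes: a connected Erdős–Rényi signed backbone (default 20 nodes, 15%
density, 30% inhibiting edges), disjoint footprints of 5–20 genes on 80% of
nodes, 200 decoy genes, and a planted backbone-coherent perturbation. The
planted signal takes a node gauge $s(x) \in \{\pm 1\}$ satisfying
$s(x) = \sigma(x\to y) s(y)$ where possible (breadth-first best effort on
frustrated backbones) and sets $\beta_G = a\,s(x)\,\sigma(x\to G) + \text{noise}$.
In the noiseless limit on a balanced backbone the solver recovers
$f = a\,s$ exactly and $\mathrm{NPA} = 4a^2$ — the closed form used
throughout the tests. `balanced = TRUE` draws backbone signs from a random
gauge so that a perfectly coherent state exists; frustrated backbones are
kept as a condition too, but there only $\mathrm{NPA} > 0$ is asserted.

`noiseSd` is per-replicate gene noise: a contrast averages `pseudoN` (= 10)
replicates, so the injected fold-change error and the reported standard
error coincide at $\mathrm{noiseSd}/\sqrt{\mathrm{pseudoN}}$, and the
synthesized statistic is $t = \beta / se$. This keeps the generator's
uncertainty bookkeeping self-consistent, which the nominal-coverage check of
the confidence interval requires.

What the generator does *not* emulate: count noise and library-size effects
of RNA-seq, correlated genes, shared genes between footprints, hub-dominated
degree distributions, or literature-biased footprint curation. Passing tests
therefore demonstrate correctness of the machinery under idealized
conditions, not performance on real transcriptomes.

## Problem sizes and numerical choices

Scored backbones in practice are order $10^2$ nodes with $10^3$–$10^4$
transcript edges; all matrices are kept dense and $L_3$ (symmetric positive
definite after the filters) is solved directly, which is exact and fast at
this scale. The test suite runs its statistical checks at deliberately small
sizes — backbones of 6–10 nodes, footprints of 5–8 genes, 150–500
permutations, 40–200 replicates per calibration — chosen so the whole suite
completes in well under a minute while the binomial/bootstrap bands remain
informative. The analytic solver is cross-checked against a derivative-free
numerical minimizer of the displayed objective to $10^{-6}$, and the
quadratic-form score against the explicit edge sum to $10^{-10}$, on 50
random instances.

No multiple-testing correction is applied across networks or contrasts, by
design; exact permutation enumeration is not attempted.

## Known limitations

* The leading-node decomposition and the BIF/δ weighting are explicit,
  documented conventions of this package; other decompositions of the same
  quadratic form are possible.
* The delta-method CI degrades when $se/|\beta|$ is large or the score is
  near zero (where it conservatively fails).
* K-statistic power is intrinsically limited against homogeneous
  perturbations (see above) and on backbones with large automorphism groups.
* Gene symbols are opaque strings; no ontology or namespace validation is
  attempted, only optional case folding.
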