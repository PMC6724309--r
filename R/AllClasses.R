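#' @import methods
#' @importFrom stats qnorm quantile rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

#' Two-layer causal network
#'
#' A signed, directed causal network with two layers: a functional
#' \emph{backbone} of molecular entities (protein activities, transcription
#' factors, processes) and a \emph{transcript layer} of genes whose expression
#' is the measurable downstream footprint of backbone nodes. Backbone edges
#' connect backbone nodes; transcript edges connect a backbone node to a gene
#' symbol. Every edge carries a sign, +1 (activation / increases) or -1
#' (inhibition / decreases).
#'
#' @slot name network label.
#' @slot family optional family label used when aggregating several networks
#'   into a Biological Impact Factor; `NA_character_` if unset.
#' @slot backboneNodes character vector of backbone node identifiers.
#' @slot geneNodes character vector of gene symbols present in the transcript
#'   layer (gene symbols are treated as opaque strings).
#' @slot backboneEdges data.frame with columns `source`, `target`, `sign`
#'   (+1/-1); directed, self-loops are not allowed, parallel edges are kept.
#' @slot transcriptEdges data.frame with columns `source` (backbone node),
#'   `gene`, `sign` (+1/-1).
#'
#' @seealso [readNetwork()], [buildLaplacianBlocks()], [generateNetwork()]
#' @export
setClass("TwoLayerNetwork",
  representation(
    name = "character",
    family = "character",
    backboneNodes = "character",
    geneNodes = "character",
    backboneEdges = "data.frame",
    transcriptEdges = "data.frame"
  )
)

setValidity("TwoLayerNetwork", function(object) {
  msgs <- character(0)
  be <- object@backboneEdges
  te <- object@transcriptEdges
  if (!all(c("source", "target", "sign") %in% names(be)))
    msgs <- c(msgs, "backboneEdges must have columns source, target, sign")
  if (!all(c("source", "gene", "sign") %in% names(te)))
    msgs <- c(msgs, "transcriptEdges must have columns source, gene, sign")
  if (length(msgs)) return(msgs)
  if (length(intersect(object@backboneNodes, object@geneNodes)))
    msgs <- c(msgs, "backbone node and gene identifiers must be disjoint")
  if (nrow(be)) {
    if (!all(be$sign %in% c(1, -1)))
      msgs <- c(msgs, "backbone edge signs must be +1 or -1")
    if (any(be$source == be$target))
      msgs <- c(msgs, "self-loops are not allowed in the backbone")
    if (!all(c(be$source, be$target) %in% object@backboneNodes))
      msgs <- c(msgs, "backbone edge endpoints must be declared backbone nodes")
  }
  if (nrow(te)) {
    if (!all(te$sign %in% c(1, -1)))
      msgs <- c(msgs, "transcript edge signs must be +1 or -1")
    if (!all(te$source %in% object@backboneNodes))
      msgs <- c(msgs, "transcript edge sources must be backbone nodes")
    if (!all(te$gene %in% object@geneNodes))
      msgs <- c(msgs, "transcript edge targets must be declared genes")
    if (any(te$gene %in% object@backboneNodes))
      msgs <- c(msgs, "transcript edges must end in a gene, not a backbone node")
  }
  if (length(msgs)) msgs else TRUE
})

#' Signed-Laplacian blocks of a two-layer network
#'
#' The matrix encoding used for scoring. Treating every edge of the two-layer
#' graph as undirected, the full signed Laplacian `L` satisfies
#' `[f; beta]' L [f; beta] = sum over edges (f(x) - sigma(x,y) v(y))^2`, the
#' smoothing objective. `L3` is its backbone-backbone block and `L2` the
#' backbone-gene coupling block, so the constrained minimizer is
#' `f = -L3^{-1} L2 beta`. `Q` encodes the coherence score:
#' `f' Q f / Esize = (1/|E|) sum over backbone edges (f(e0) + sigma(e) f(e1))^2`,
#' the Network Perturbation Amplitude.
#'
#' @slot nodeOrder backbone node ordering (lexicographic) of rows/columns.
#' @slot geneOrder gene ordering (lexicographic) of `L2` columns.
#' @slot L3 symmetric backbone block of the signed Laplacian; diagonal entries
#'   are total (backbone + transcript) degrees, off-diagonals minus the summed
#'   signs of backbone edges.
#' @slot L2 backbone x gene coupling block, minus the summed transcript signs.
#' @slot Q symmetric positive semidefinite scoring matrix: backbone degrees on
#'   the diagonal, plus the summed backbone signs off the diagonal.
#' @slot K the solution operator `-L3^{-1} L2`, factored once and reused for
#'   contrasts and permutations.
#' @slot Esize number of backbone edges, counting multiplicity.
#'
#' @seealso [buildLaplacianBlocks()], [solveDifferentialValues()], [computeNpa()]
#' @export
setClass("LaplacianBlocks",
  representation(
    nodeOrder = "character",
    geneOrder = "character",
    L3 = "matrix",
    L2 = "matrix",
    Q = "matrix",
    K = "matrix",
    Esize = "numeric"
  )
)

setValidity("LaplacianBlocks", function(object) {
  msgs <- character(0)
  n <- length(object@nodeOrder)
  g <- length(object@geneOrder)
  if (!identical(dim(object@L3), c(n, n))) msgs <- c(msgs, "L3 dimension mismatch")
  if (!identical(dim(object@Q), c(n, n))) msgs <- c(msgs, "Q dimension mismatch")
  if (!identical(dim(object@L2), c(n, g))) msgs <- c(msgs, "L2 dimension mismatch")
  if (n && max(abs(object@L3 - t(object@L3))) > 1e-10)
    msgs <- c(msgs, "L3 must be symmetric")
  if (n && max(abs(object@Q - t(object@Q))) > 1e-10)
    msgs <- c(msgs, "Q must be symmetric")
  if (length(object@Esize) != 1L || object@Esize < 1)
    msgs <- c(msgs, "Esize must be a positive count")
  if (length(msgs)) msgs else TRUE
})

#' Expression contrast
#'
#' One treatment-versus-control comparison summarized per gene: a log2
#' fold-change `beta` and its standard error, derived from the reported
#' t- (or Wald z-) statistic as `se = |foldChange / t|`. Genes whose
#' statistic is zero or missing while the fold-change is exactly zero are
#' retained with `se = NA` and are excluded from variance propagation.
#'
#' @slot name contrast label.
#' @slot beta named numeric, gene symbol -> log2 fold-change.
#' @slot se named numeric aligned with `beta`; positive or `NA`.
#' @slot provenance free-text origin of the contrast.
#'
#' @seealso [loadContrasts()], [matchContrast()]
#' @export
setClass("Contrast",
  representation(
    name = "character",
    beta = "numeric",
    se = "numeric",
    provenance = "character"
  )
)

setValidity("Contrast", function(object) {
  msgs <- character(0)
  if (is.null(names(object@beta)) || anyNA(names(object@beta)))
    msgs <- c(msgs, "beta must be named by gene symbol")
  if (anyDuplicated(names(object@beta)))
    msgs <- c(msgs, "duplicate gene symbols in beta")
  if (!all(names(object@se) %in% names(object@beta)))
    msgs <- c(msgs, "beta gene set must contain the se gene set")
  se <- object@se[!is.na(object@se)]
  if (length(se) && (any(!is.finite(se)) || any(se <= 0)))
    msgs <- c(msgs, "non-missing standard errors must be finite and positive")
  if (length(msgs)) msgs else TRUE
})

#' Permutation null distribution for an NPA score
#'
#' @slot kind `"O"` (transcript-layer gene relabeling) or `"K"` (backbone
#'   node relabeling).
#' @slot nPerm number of permutations drawn.
#' @slot nullScores permuted NPA values (all nonnegative).
#' @slot pValue add-one permutation p-value,
#'   `(1 + #\{null >= observed\}) / (1 + nPerm)`, never zero.
#' @slot quantile95 95% quantile of the null scores.
#' @slot seed seed used to draw the permutations.
#' @export
setClass("PermutationNull",
  representation(
    kind = "character",
    nPerm = "integer",
    nullScores = "numeric",
    pValue = "numeric",
    quantile95 = "numeric",
    seed = "integer"
  )
)

setValidity("PermutationNull", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("O", "K")) msgs <- c(msgs, "kind must be 'O' or 'K'")
  if (object@pValue <= 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in (0, 1]")
  if (any(object@nullScores < -1e-12))
    msgs <- c(msgs, "null scores must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Result of scoring one network against one contrast
#'
#' @slot network network name.
#' @slot contrast contrast name.
#' @slot score the NPA value (nonnegative; units: squared log2 fold-change).
#' @slot f named numeric of backbone differential values.
#' @slot contributions named numeric, additive per-node shares of the score
#'   (`f * (Q f) / |E|`); individual entries may be negative, the sum equals
#'   the score.
#' @slot ciLow,ciHigh 95% confidence bounds from delta-method variance
#'   propagation of the gene-level standard errors.
#' @slot pO,pK permutation p-values of the O and K statistics.
#' @slot ciFlag `TRUE` when the confidence interval excludes zero
#'   (`ciLow > 0`).
#' @slot significant `TRUE` when all three statistics pass (CI excludes zero
#'   and both permutation p-values are below 0.05).
#' @slot label compact display label, see [significanceLabel()].
#' @slot nullO,nullK the [PermutationNull-class] objects (or `NULL`).
#' @export
setClass("NpaResult",
  representation(
    network = "character",
    contrast = "character",
    score = "numeric",
    f = "numeric",
    contributions = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pO = "numeric",
    pK = "numeric",
    ciFlag = "logical",
    significant = "logical",
    label = "character",
    nullO = "ANY",
    nullK = "ANY"
  )
)

setValidity("NpaResult", function(object) {
  msgs <- character(0)
  if (object@score < -1e-12) msgs <- c(msgs, "score must be nonnegative")
  tot <- sum(object@contributions)
  denom <- max(abs(object@score), 1e-12)
  if (abs(tot - object@score) / denom > 1e-8)
    msgs <- c(msgs, "contributions must sum to the score")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@ciLow > object@score + 1e-9 || object@ciHigh < object@score - 1e-9))
    msgs <- c(msgs, "score must lie inside its confidence interval")
  if (length(msgs)) msgs else TRUE
})

#' Leading-node decomposition of an NPA score
#'
#' Backbone nodes ranked by decreasing contribution; the leading-node set is
#' the shortest prefix whose cumulative contribution reaches the cutoff
#' fraction (default 0.8) of the score.
#'
#' @slot nodes all backbone nodes, ranked by decreasing contribution (ties
#'   broken lexicographically).
#' @slot cumFraction cumulative contribution fraction at each rank.
#' @slot cutoff the cutoff fraction.
#' @slot nLeading size of the leading set.
#' @slot direction named sign of the differential value per node (+1
#'   activation, -1 inhibition, 0).
#' @export
setClass("LeadingNodeSet",
  representation(
    nodes = "character",
    cumFraction = "numeric",
    cutoff = "numeric",
    nLeading = "integer",
    direction = "numeric"
  )
)

setValidity("LeadingNodeSet", function(object) {
  msgs <- character(0)
  if (object@cutoff <= 0 || object@cutoff > 1)
    msgs <- c(msgs, "cutoff must lie in (0, 1]")
  if (object@nLeading < 1L || object@nLeading > length(object@nodes))
    msgs <- c(msgs, "leading set size out of range")
  if (length(msgs)) msgs else TRUE
})

#' Biological Impact Factor across networks and contrasts
#'
#' @slot raw named numeric, raw weighted BIF per contrast.
#' @slot relative named numeric, percent of the reference contrast's BIF
#'   (reference = 100).
#' @slot reference name of the reference contrast.
#' @slot familyFractions matrix (family x contrast) of contribution fractions;
#'   columns with positive raw BIF sum to 1.
#' @slot delta named numeric in [-1, 1]: cosine similarity of each contrast's
#'   network-wide perturbation pattern with the reference's
#'   (`delta[reference] == 1`).
#' @slot weights named numeric, the per-network aggregation weights.
#' @export
setClass("BifResult",
  representation(
    raw = "numeric",
    relative = "numeric",
    reference = "character",
    familyFractions = "matrix",
    delta = "numeric",
    weights = "numeric"
  )
)

setValidity("BifResult", function(object) {
  msgs <- character(0)
  if (!object@reference %in% names(object@raw))
    msgs <- c(msgs, "reference must be one of the contrasts")
  d <- object@delta[!is.na(object@delta)]
  if (length(d) && any(d < -1 - 1e-9 | d > 1 + 1e-9))
    msgs <- c(msgs, "delta values must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the synthetic two-layer study generator
#'
#' Defines the conditions under which synthetic networks and contrasts are
#' drawn: backbone size and edge density, probability of an inhibiting
#' (negative) edge, the footprint size range and the fraction of backbone
#' nodes carrying a footprint, the planted coherent perturbation amplitude,
#' the gene-level noise standard deviation, the number of unconnected decoy
#' genes, and the pseudo sample size used to synthesize t-statistics.
#'
#' @seealso [synthConfig()], [generateNetwork()], [generateContrast()]
#' @export
setClass("SynthConfig",
  representation(
    nBackbone = "integer",
    density = "numeric",
    negProb = "numeric",
    footprintMin = "integer",
    footprintMax = "integer",
    footprintFraction = "numeric",
    amplitude = "numeric",
    noiseSd = "numeric",
    nBackground = "integer",
    pseudoN = "numeric",
    balanced = "logical",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msgs <- character(0)
  if (object@nBackbone < 2L) msgs <- c(msgs, "nBackbone must be at least 2")
  if (object@density <= 0 || object@density > 1)
    msgs <- c(msgs, "density must lie in (0, 1]")
  for (p in c("negProb", "footprintFraction"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      msgs <- c(msgs, paste(p, "must lie in [0, 1]"))
  if (object@footprintMin < 1L || object@footprintMax < object@footprintMin)
    msgs <- c(msgs, "need 1 <= footprintMin <= footprintMax")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be nonnegative")
  if (object@amplitude < 0) msgs <- c(msgs, "amplitude must be nonnegative")
  if (object@nBackground < 0L) msgs <- c(msgs, "nBackground must be nonnegative")
  if (object@pseudoN <= 0) msgs <- c(msgs, "pseudoN must be positive")
  if (length(msgs)) msgs else TRUE
})

#' End-to-end run configuration
#'
#' Bundles everything a scoring run needs: networks (paths or objects) with
#' optional families, contrasts (paths or objects), the permutation count,
#' the root seed from which all per-(network, contrast, statistic) seeds are
#' derived, the leading-node cutoff, the minimum transcript-layer downstream
#' degree, the output directory and behaviour flags.
#'
#' @seealso [npaRunConfig()], [runNpa()], [runBif()]
#' @export
setClass("RunConfig",
  representation(
    networks = "list",
    families = "character",
    contrasts = "list",
    nPerm = "integer",
    seed = "integer",
    cutoff = "numeric",
    minDownstream = "integer",
    outDir = "character",
    aggregateDuplicates = "character",
    caseInsensitive = "logical",
    saveNull = "logical"
  )
)

setValidity("RunConfig", function(object) {
  msgs <- character(0)
  if (object@nPerm < 1L) msgs <- c(msgs, "nPerm must be positive")
  if (object@cutoff <= 0 || object@cutoff > 1)
    msgs <- c(msgs, "cutoff must lie in (0, 1]")
  if (object@minDownstream < 1L) msgs <- c(msgs, "minDownstream must be >= 1")
  if (!object@aggregateDuplicates %in% c("error", "mean"))
    msgs <- c(msgs, "aggregateDuplicates must be 'error' or 'mean'")
  if (length(msgs)) msgs else TRUE
})
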