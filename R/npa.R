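#' Solve the constrained smoothing problem for backbone differential values
#'
#' The backbone differential values `f` minimize the signed smoothing
#' objective
#' \deqn{\min_f \sum_{x \to y} (f(x) - \sigma(x \to y) f(y))^2
#'   \quad \text{s.t.} \quad f|_{V_0} = \beta,}
#' where the sum runs over all edges of the two-layer graph and the values on
#' the transcript layer `V0` are pinned to the measured log2 fold-changes.
#' The problem is quadratic and solved analytically:
#' `f = -L3^{-1} L2 beta`, evaluated via the pre-factored solution operator
#' stored in the blocks, so repeated solves (contrasts, permutations) are a
#' single matrix product.
#'
#' @param blocks a [LaplacianBlocks-class].
#' @param beta numeric vector of gene log2 fold-changes aligned to
#'   `blocks@geneOrder` (names, if present, are checked).
#' @return named numeric vector of differential values in `blocks@nodeOrder`.
#' @seealso [computeNpa()], [nodeContributions()]
#' @export
solveDifferentialValues <- function(blocks, beta) {
  stopifnot(is(blocks, "LaplacianBlocks"))
  beta <- alignToOrder(beta, blocks@geneOrder, "beta")
  drop(blocks@K %*% beta)
}

#' Network Perturbation Amplitude of a differential-value profile
#'
#' The NPA is the edge-averaged coherence of the inferred backbone
#' perturbation:
#' \deqn{NPA = \frac{1}{|E|} \sum_{e \in E} (f(e_0) + \sigma(e) f(e_1))^2
#'   = \frac{f^T Q f}{|E|},}
#' summing over the backbone edges `E`. It is nonnegative by construction and
#' rewards perturbations that are sign-coherent along the causal edges.
#'
#' @param blocks a [LaplacianBlocks-class].
#' @param f numeric vector of differential values aligned to
#'   `blocks@nodeOrder`.
#' @return the NPA score (a single nonnegative number, units of squared log2
#'   fold-change).
#' @export
computeNpa <- function(blocks, f) {
  stopifnot(is(blocks, "LaplacianBlocks"))
  f <- alignToOrder(f, blocks@nodeOrder, "f")
  max(0, drop(crossprod(f, blocks@Q %*% f)) / blocks@Esize)
}

#' Per-node additive decomposition of the NPA
#'
#' Splits the quadratic form symmetrically over nodes:
#' `contribution[x] = f[x] * (Q f)[x] / |E|`. The shares sum exactly to the
#' NPA; individual shares can be negative when a node's differential value is
#' locally incoherent with its neighbourhood.
#'
#' @inheritParams computeNpa
#' @return named numeric vector of contributions in `blocks@nodeOrder`.
#' @export
setMethod("nodeContributions", "LaplacianBlocks", function(object, f, ...) {
  f <- alignToOrder(f, object@nodeOrder, "f")
  stats::setNames(drop(f * (object@Q %*% f)) / object@Esize, object@nodeOrder)
})

# align a (possibly named) vector to a reference ordering
alignToOrder <- function(x, order, what) {
  if (length(x) != length(order))
    stop(what, " has length ", length(x), " but ", length(order),
         " entries are expected")
  if (!is.null(names(x))) {
    if (!setequal(names(x), order))
      stop(what, " names do not match the expected ordering")
    x <- x[order]
  }
  unname(x)
}

#' Score one network against one contrast
#'
#' The full single-cell pipeline: map the contrast onto the transcript layer,
#' re-apply the structural filters, build the Laplacian blocks, solve for the
#' backbone differential values, compute the NPA and its per-node
#' decomposition, then the three companion statistics — the delta-method 95%
#' confidence interval and the O (transcript-layer) and K (backbone)
#' permutation tests. The perturbation is called significant only when all
#' three pass.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param contrast a [Contrast-class].
#' @param nPerm permutations per test (default 500).
#' @param seed integer seed controlling both permutation tests
#'   (child seeds are derived per statistic, so the two nulls are
#'   independent yet reproducible).
#' @param minDownstream minimum footprint size (default 5).
#' @param caseInsensitive match gene symbols after case folding.
#' @param saveNull keep the full null score vectors in the result.
#' @return an [NpaResult-class].
#' @examples
#' cfg <- synthConfig(nBackbone = 6, seed = 7)
#' net <- generateNetwork(cfg)
#' ctr <- generateContrast(net, cfg)
#' res <- scoreContrast(net, ctr, nPerm = 100, seed = 7)
#' npaScore(res)
#' @export
scoreContrast <- function(net, contrast, nPerm = 500L, seed = 1L,
                          minDownstream = 5L, caseInsensitive = FALSE,
                          saveNull = FALSE) {
  m <- matchContrast(net, contrast, minDownstream, caseInsensitive)
  blocks <- buildLaplacianBlocks(m$network)
  f <- solveDifferentialValues(blocks, m$beta)
  score <- computeNpa(blocks, f)
  contrib <- nodeContributions(blocks, f)
  ci <- confidenceInterval(blocks, m$beta, m$se)
  nullO <- permutationNull(blocks, m$beta, kind = "O", nPerm = nPerm,
                           seed = deriveSeed(seed, net@name, contrast@name, "O"))
  nullK <- permutationNull(blocks, m$beta, kind = "K", nPerm = nPerm,
                           seed = deriveSeed(seed, net@name, contrast@name, "K"))
  buildNpaResult(net@name, contrast@name, score,
                 stats::setNames(f, blocks@nodeOrder), contrib,
                 ci[1], ci[2], nullO, nullK, saveNull)
}

buildNpaResult <- function(network, contrastName, score, f, contrib,
                           ciLow, ciHigh, nullO, nullK, saveNull = FALSE) {
  pO <- nullO@pValue
  pK <- nullK@pValue
  ciFlag <- isTRUE(ciLow > 0)
  res <- methods::new("NpaResult",
    network = network, contrast = contrastName, score = score,
    f = f, contributions = contrib,
    ciLow = ciLow, ciHigh = ciHigh, pO = pO, pK = pK,
    ciFlag = ciFlag,
    significant = ciFlag && pO < 0.05 && pK < 0.05,
    label = "",
    nullO = if (saveNull) nullO else trimNull(nullO),
    nullK = if (saveNull) nullK else trimNull(nullK))
  res@label <- significanceLabel(res)
  res
}

# keep the summary, drop the full null vector
trimNull <- function(pn) {
  pn@nullScores <- c(min = min(pn@nullScores),
                     median = stats::median(pn@nullScores),
                     q95 = pn@quantile95, max = max(pn@nullScores))
  pn
}
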