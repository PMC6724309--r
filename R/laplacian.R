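#' Build the signed-Laplacian blocks of a two-layer network
#'
#' Encodes the network as the matrices used by the scoring machinery. All
#' edges are treated as undirected here: both quadratic forms below are
#' invariant to edge orientation, so direction only matters for the
#' scorability filter. With `v = [f; beta]` stacking backbone differential
#' values and gene fold-changes, the full signed Laplacian `L` of the
#' two-layer graph satisfies
#' \deqn{v^T L v = \sum_{x \to y} (f(x) - \sigma(x \to y) f(y))^2,}
#' the smoothing objective, and the backbone scoring matrix `Q` satisfies
#' \deqn{f^T Q f = \sum_{e \in E} (f(e_0) + \sigma(e) f(e_1))^2,}
#' the coherence sum over backbone edges. Concretely, for backbone nodes
#' `x != y`: `L3[x,x]` is the total number of incident edges (backbone plus
#' transcript, counting multiplicity), `L3[x,y]` is minus the summed signs of
#' backbone edges between `x` and `y`, `L2[x,g]` is minus the summed signs of
#' transcript edges `x -> g`, `Q[x,x]` is the backbone degree and `Q[x,y]`
#' plus the summed signs. Parallel edges are summed term by term, so
#' contradictory parallel edges cancel off the diagonal while still counting
#' towards degrees and `|E|`.
#'
#' The solution operator `K = -L3^{-1} L2` is factored once and stored, so
#' that solving for many contrasts or permutations reduces to one
#' matrix-vector product.
#'
#' @param net a [TwoLayerNetwork-class], already pruned and restricted to its
#'   scorable backbone, with at least one backbone edge and one transcript
#'   edge.
#' @return a [LaplacianBlocks-class]. Node and gene orders are lexicographic,
#'   so the matrices do not depend on input row order.
#' @section Errors: if `L3` is numerically singular (reciprocal condition
#'   number below 1e-12) the constrained problem has no unique solution; the
#'   error names the disconnected backbone components responsible.
#' @examples
#' net <- newToyNetwork <- local({
#'   tsv <- tempfile(fileext = ".tsv")
#'   writeLines(c("source\tsign\ttarget\tlayer",
#'                "a\t1\tb\tfunctional",
#'                "a\t1\tG1\ttranscript",
#'                "b\t1\tG2\ttranscript"), tsv)
#'   readNetwork(tsv)
#' })
#' blocks <- buildLaplacianBlocks(net)
#' blocks@L3   # [[2, -1], [-1, 2]]
#' @export
buildLaplacianBlocks <- function(net) {
  stopifnot(is(net, "TwoLayerNetwork"))
  be <- net@backboneEdges
  te <- net@transcriptEdges
  if (!nrow(te)) stop("network has no transcript edges")
  if (!nrow(be)) stop("network has no backbone edges")

  nodes <- sort(net@backboneNodes)
  genes <- sort(unique(te$gene))
  n <- length(nodes)
  g <- length(genes)

  A <- matrix(0, n, n, dimnames = list(nodes, nodes))  # signed backbone adjacency
  degB <- setNames(numeric(n), nodes)                  # backbone degree w/ multiplicity
  for (i in seq_len(nrow(be))) {
    s <- be$source[i]; t <- be$target[i]; sg <- be$sign[i]
    A[s, t] <- A[s, t] + sg
    A[t, s] <- A[t, s] + sg
    degB[s] <- degB[s] + 1
    degB[t] <- degB[t] + 1
  }

  L2 <- matrix(0, n, g, dimnames = list(nodes, genes))
  degT <- setNames(numeric(n), nodes)                  # transcript degree
  for (i in seq_len(nrow(te))) {
    s <- te$source[i]; gn <- te$gene[i]; sg <- te$sign[i]
    L2[s, gn] <- L2[s, gn] - sg
    degT[s] <- degT[s] + 1
  }

  L3 <- -A
  diag(L3) <- degB + degT
  Q <- A
  diag(Q) <- degB

  if (rcond(L3) < 1e-12) {
    comp <- igraph::components(backboneGraph(net))
    if (comp$no > 1) {
      parts <- split(names(comp$membership), comp$membership)
      stop("L3 is singular: the backbone splits into ", comp$no,
           " disconnected components: ",
           paste(vapply(parts, function(p) paste(p, collapse = ","), ""),
                 collapse = " | "))
    }
    stop("L3 is numerically singular; the constrained problem has no unique",
         " solution")
  }
  K <- -solve(L3, L2)

  methods::new("LaplacianBlocks",
    nodeOrder = nodes, geneOrder = genes,
    L3 = L3, L2 = L2, Q = Q, K = K, Esize = as.numeric(nrow(be)))
}
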