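#' Remove under-represented footprints
#'
#' A backbone node whose footprint holds fewer than `minDownstream` transcript
#' edges is considered under-represented: its inferred activity would rest on
#' too few genes. All of its transcript edges are removed (the node itself and
#' the backbone edges stay). Nodes with no transcript edges at all are left
#' untouched.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param minDownstream minimum footprint size to keep (default 5).
#' @return the filtered [TwoLayerNetwork-class].
#' @seealso [restrictToScorable()]
#' @export
pruneUnderrepresented <- function(net, minDownstream = 5L) {
  stopifnot(is(net, "TwoLayerNetwork"))
  if (minDownstream < 1L) stop("minDownstream must be >= 1")
  te <- net@transcriptEdges
  if (!nrow(te)) return(net)
  counts <- table(te$source)
  drop <- names(counts)[counts < minDownstream]
  if (!length(drop)) return(net)
  te2 <- te[!te$source %in% drop, , drop = FALSE]
  rownames(te2) <- NULL
  newTwoLayerNetwork(net@backboneEdges, te2, net@name, net@family,
                     keepNodes = net@backboneNodes)
}

#' Restrict a network to its scorable backbone
#'
#' Differential values are only meaningful for backbone nodes that are tied to
#' measured genes both upstream and downstream: a node is kept exactly when
#' some directed-reachability ancestor of it (itself included) has at least
#' one transcript edge AND some descendant (itself included) has at least one
#' transcript edge. All other backbone nodes, together with their incident
#' backbone and transcript edges, are removed; their values would be pure
#' extrapolation. The operation is idempotent.
#'
#' @param net a [TwoLayerNetwork-class].
#' @return the restricted [TwoLayerNetwork-class].
#' @export
restrictToScorable <- function(net) {
  stopifnot(is(net, "TwoLayerNetwork"))
  bn <- net@backboneNodes
  if (!length(bn)) stop("no scorable nodes: backbone is empty")
  footed <- unique(net@transcriptEdges$source)
  g <- backboneGraph(net, directed = TRUE)
  # reach[i, j] TRUE when a directed path i -> j exists (including i == i)
  reach <- is.finite(igraph::distances(g, mode = "out"))
  ord <- igraph::V(g)$name
  footMask <- ord %in% footed
  hasDesc <- reach[, footMask, drop = FALSE]
  hasAnc <- t(reach)[, footMask, drop = FALSE]
  keep <- ord[rowSums(hasDesc) > 0 & rowSums(hasAnc) > 0]
  if (!length(keep)) stop("no scorable nodes")
  be <- net@backboneEdges
  be <- be[be$source %in% keep & be$target %in% keep, , drop = FALSE]
  te <- net@transcriptEdges
  te <- te[te$source %in% keep, , drop = FALSE]
  rownames(be) <- rownames(te) <- NULL
  newTwoLayerNetwork(be, te, net@name, net@family, keepNodes = keep)
}

#' Apply both structural filters in scoring order
#'
#' Convenience wrapper: [pruneUnderrepresented()] first (pruning can strip a
#' node's footprint and thereby change scorability), then
#' [restrictToScorable()].
#'
#' @inheritParams pruneUnderrepresented
#' @return the filtered [TwoLayerNetwork-class].
#' @export
filterNetwork <- function(net, minDownstream = 5L) {
  restrictToScorable(pruneUnderrepresented(net, minDownstream))
}
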