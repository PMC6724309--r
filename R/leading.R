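#' Leading nodes of a network perturbation
#'
#' The leading nodes are the backbone nodes that drive the score: the
#' shortest prefix of the contribution-ranked node list whose cumulative
#' contribution reaches `cutoff` (default 80%) of the NPA. Contributions are
#' sorted in decreasing order (ties broken lexicographically by node
#' identifier; negative contributions sort last and the prefix rule still
#' terminates). The boundary is inclusive: the prefix stops at the first rank
#' where the cumulative sum is `>= cutoff * score`. Each node also carries
#' its directionality, the sign of its differential value (activation or
#' inhibition) — needed because the NPA itself is positive by construction.
#'
#' @param r an [NpaResult-class] with a strictly positive score.
#' @param cutoff fraction of the score to cover, in (0, 1] (default 0.8).
#' @return a [LeadingNodeSet-class].
#' @export
leadingNodes <- function(r, cutoff = 0.8) {
  stopifnot(is(r, "NpaResult"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  if (r@score <= 0) stop("no perturbation to decompose: the NPA score is zero")
  contrib <- r@contributions
  ord <- order(-contrib, names(contrib))
  ranked <- names(contrib)[ord]
  cum <- cumsum(contrib[ord]) / r@score
  k <- which(cum >= cutoff - 1e-12)[1]
  if (is.na(k)) k <- length(ranked)   # negative tail never reaches the cutoff
  methods::new("LeadingNodeSet",
    nodes = ranked, cumFraction = unname(cum), cutoff = cutoff,
    nLeading = as.integer(k),
    direction = stats::setNames(sign(r@f[ranked]), ranked))
}

#' Signed-rank matrix of leading nodes across contrasts
#'
#' One row per backbone node, one column per contrast; the entry is the
#' node's rank multiplied by its directionality when the node is leading in
#' that contrast, and 0 otherwise. The matrix is the standard heatmap input
#' for comparing perturbation mechanisms across treatments.
#'
#' @param results list of [NpaResult-class] objects from the same network.
#' @param cutoff leading-node cutoff fraction (default 0.8).
#' @return numeric matrix, backbone nodes x contrasts.
#' @export
leadingNodeMatrix <- function(results, cutoff = 0.8) {
  if (is(results, "NpaResult")) results <- list(results)
  nets <- unique(vapply(results, function(r) r@network, ""))
  if (length(nets) != 1)
    stop("all results must come from the same network; got: ",
         paste(nets, collapse = ", "))
  nodes <- sort(unique(unlist(lapply(results, function(r) names(r@f)))))
  cols <- vapply(results, function(r) r@contrast, "")
  m <- matrix(0, length(nodes), length(results),
              dimnames = list(nodes, cols))
  for (j in seq_along(results)) {
    r <- results[[j]]
    if (r@score <= 0) next
    ln <- leadingNodes(r, cutoff)
    lead <- ln@nodes[seq_len(ln@nLeading)]
    m[lead, j] <- seq_along(lead) * ln@direction[lead]
  }
  m
}

#' Extract a leading-node-dense connected backbone module
#'
#' Heuristically finds a high-scoring connected subgraph of the backbone.
#' Each node is scored as its mean contribution fraction across the supplied
#' results minus a size penalty; a greedy seed-and-grow then starts from the
#' top-scoring node and repeatedly adds the highest-scoring neighbouring node
#' while the subgraph total does not decrease (i.e. while the best frontier
#' node scores at least zero). With `sizePenalty = 0` and positive
#' contributions this expands to the seed's whole connected component; larger
#' penalties trim the module to its leading-node-dense core.
#'
#' @param net the [TwoLayerNetwork-class] the results were scored on.
#' @param results list of [NpaResult-class] objects.
#' @param sizePenalty per-node score penalty (default 0.02, i.e. a node must
#'   carry at least 2% of the score on average to pull the module towards
#'   itself).
#' @return an [igraph][igraph::graph_from_data_frame] directed signed
#'   subgraph of the backbone (edge attribute `sign`), always connected.
#' @export
extractModule <- function(net, results, sizePenalty = 0.02) {
  stopifnot(is(net, "TwoLayerNetwork"))
  if (is(results, "NpaResult")) results <- list(results)
  if (!length(results)) stop("no results supplied")
  if (!any(vapply(results, function(r) isTRUE(r@significant), logical(1))))
    stop("no significant network perturbation to extract a module from")
  fracs <- lapply(results, function(r) {
    if (r@score <= 0) return(NULL)
    r@contributions / r@score
  })
  fracs <- Filter(Negate(is.null), fracs)
  nodes <- sort(unique(unlist(lapply(fracs, names))))
  scoreTab <- vapply(nodes, function(x)
    mean(vapply(fracs, function(fr) if (x %in% names(fr)) fr[[x]] else 0,
                numeric(1))), numeric(1)) - sizePenalty

  g <- backboneGraph(net)
  present <- intersect(nodes, igraph::V(g)$name)
  if (!length(present)) stop("no scored node is present in the backbone")
  seed <- present[order(-scoreTab[present], present)][1]
  inSet <- seed
  repeat {
    nbr <- unique(unlist(lapply(igraph::adjacent_vertices(g, inSet),
                                function(v) v$name)))
    frontier <- setdiff(intersect(nbr, present), inSet)
    if (!length(frontier)) break
    best <- frontier[order(-scoreTab[frontier], frontier)][1]
    if (scoreTab[best] < 0) break
    inSet <- c(inSet, best)
  }
  be <- net@backboneEdges
  keep <- be$source %in% inSet & be$target %in% inSet
  igraph::graph_from_data_frame(
    be[keep, c("source", "target", "sign")],
    directed = TRUE,
    vertices = data.frame(name = sort(inSet),
                          score = scoreTab[sort(inSet)]))
}

#' Write a backbone module to disk
#'
#' Writes the module as an edge-list TSV in the network dialect (layer
#' `functional`) and, alongside it, a GraphML file for network viewers.
#'
#' @param module an igraph object from [extractModule()].
#' @param path output TSV path; the GraphML is written to `<path>.graphml`.
#' @return `path`, invisibly.
#' @export
writeModule <- function(module, path) {
  ed <- igraph::as_data_frame(module, what = "edges")
  con <- file(path, open = "wb")
  writeLines("source\tsign\ttarget\tlayer", con)
  if (nrow(ed))
    writeLines(paste(ed$from, ed$sign, ed$to, "functional", sep = "\t"), con)
  close(con)
  igraph::write_graph(module, paste0(path, ".graphml"), format = "graphml")
  invisible(path)
}
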