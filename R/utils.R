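# internal helpers

# run expr with a fixed RNG seed, restoring caller RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seed from a root seed and string tags; stays < 2^31
deriveSeed <- function(root, ...) {
  h <- as.numeric(root) %% 2147483647
  for (tok in unlist(list(...))) {
    for (code in utf8ToInt(as.character(tok)))
      h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483562 + 1)
}

# undirected igraph over the backbone (multi-edges preserved)
backboneGraph <- function(net, directed = FALSE) {
  be <- net@backboneEdges
  igraph::graph_from_data_frame(
    be[, c("source", "target")],
    directed = directed,
    vertices = data.frame(name = net@backboneNodes)
  )
}

emptyBackboneEdges <- function() {
  data.frame(source = character(0), target = character(0),
             sign = numeric(0), stringsAsFactors = FALSE)
}

emptyTranscriptEdges <- function() {
  data.frame(source = character(0), gene = character(0),
             sign = numeric(0), stringsAsFactors = FALSE)
}

# rebuild a TwoLayerNetwork from edge tables, recomputing node sets;
# keepNodes: backbone nodes retained even if isolated
newTwoLayerNetwork <- function(backboneEdges, transcriptEdges, name, family,
                               keepNodes = NULL) {
  bn <- sort(unique(c(backboneEdges$source, backboneEdges$target,
                      transcriptEdges$source, keepNodes)))
  gn <- sort(unique(transcriptEdges$gene))
  methods::new("TwoLayerNetwork",
    name = name, family = family,
    backboneNodes = as.character(bn), geneNodes = as.character(gn),
    backboneEdges = backboneEdges, transcriptEdges = transcriptEdges)
}
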