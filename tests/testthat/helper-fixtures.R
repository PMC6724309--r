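# Fixture builders and independent oracles shared across the suite.

# Write edge tables to the TSV dialect and read them back, so every ad-hoc
# fixture also exercises the reader.
netFromEdges <- function(backbone, transcript, name = "fixture") {
  path <- tempfile(fileext = ".tsv")
  rows <- character(0)
  if (nrow(backbone))
    rows <- c(rows, paste(backbone$source, backbone$sign, backbone$target,
                          "functional", sep = "\t"))
  if (nrow(transcript))
    rows <- c(rows, paste(transcript$source, transcript$sign,
                          transcript$gene, "transcript", sep = "\t"))
  writeLines(c("source\tsign\ttarget\tlayer", rows), path)
  readNetwork(path, name = name)
}

edges <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], sign = as.numeric(m[, 2]), target = m[, 3],
             stringsAsFactors = FALSE)
}

tedges <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], sign = as.numeric(m[, 2]), gene = m[, 3],
             stringsAsFactors = FALSE)
}

# the canonical 2-node example: a -> b (+), one +1 footprint gene each
toyNetwork <- function() {
  netFromEdges(edges("a", 1, "b"),
               tedges("a", 1, "G1", "b", 1, "G2"),
               name = "toy")
}

# ---- independent oracles ----------------------------------------------------

# the smoothing objective evaluated edge by edge over the two-layer graph
objectiveValue <- function(net, f, beta) {
  tot <- 0
  be <- backboneEdges(net)
  for (i in seq_len(nrow(be)))
    tot <- tot + (f[[be$source[i]]] - be$sign[i] * f[[be$target[i]]])^2
  te <- transcriptEdges(net)
  for (i in seq_len(nrow(te)))
    tot <- tot + (f[[te$source[i]]] - te$sign[i] * beta[[te$gene[i]]])^2
  tot
}

# the NPA evaluated as the explicit edge sum
npaEdgeSum <- function(net, f) {
  be <- backboneEdges(net)
  sum((f[be$source] + be$sign * f[be$target])^2) / nrow(be)
}

# generic numerical minimizer of the objective over the backbone values,
# independent of the Laplacian machinery
oracleSolve <- function(net, beta) {
  nodes <- sort(backboneNodes(net))
  fn <- function(x) objectiveValue(net, setNames(x, nodes), beta)
  fit <- optim(rep(0, length(nodes)), fn, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-16))
  setNames(fit$par, nodes)
}

# random small matched instance for property tests
randomInstance <- function(seed, nBackbone = NULL) {
  cfg <- synthConfig(
    nBackbone = if (is.null(nBackbone)) 3 + (seed %% 6) else nBackbone,
    density = 0.7, negProb = 0.4, footprintMin = 1, footprintMax = 5,
    footprintFraction = 1, amplitude = 1, noiseSd = 0.5, nBackground = 0,
    seed = seed)
  net <- generateNetwork(cfg)
  ctr <- generateContrast(net, cfg)
  m <- matchContrast(net, ctr, minDownstream = 1)
  list(net = m$network, blocks = buildLaplacianBlocks(m$network),
       beta = m$beta, se = m$se)
}

# in-memory contrast from a named beta vector
contrastFrom <- function(beta, se = NULL, name = "ctr") {
  if (is.null(se)) se <- setNames(rep(0.25, length(beta)), names(beta))
  methods::new("Contrast", name = name, beta = beta, se = se,
               provenance = "test fixture")
}

# a minimal NpaResult for downstream-module tests (contributions are scaled
# to sum exactly to the score)
resultFrom <- function(network, contrast, f, score = NULL,
                       significant = TRUE, contributions = NULL) {
  if (is.null(contributions)) contributions <- f^2
  if (is.null(score)) score <- sum(contributions)
  if (sum(contributions) != 0)
    contributions <- contributions * (score / sum(contributions))
  methods::new("NpaResult", network = network, contrast = contrast,
               score = score, f = f, contributions = contributions,
               ciLow = if (significant) score * 0.5 else -score,
               ciHigh = score * 1.5,
               pO = if (significant) 0.01 else 0.5,
               pK = if (significant) 0.01 else 0.5,
               ciFlag = significant, significant = significant,
               label = "", nullO = NULL, nullK = NULL)
}
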