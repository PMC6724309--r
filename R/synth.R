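#' Configure the synthetic two-layer study generator
#'
#' Builds a validated [SynthConfig-class]. Defaults describe a small but
#' realistic causal network: a 20-node connected signed backbone at 15% edge
#' density with 30% inhibiting edges, footprints of 5-20 genes on 80% of the
#' backbone nodes, a planted coherent perturbation of amplitude 1 (log2
#' units) observed through gene-level noise of sd 0.1, 200 decoy genes
#' unconnected to the network, and t-statistics synthesized at a pseudo
#' sample size of 10.
#'
#' @param nBackbone backbone node count.
#' @param density backbone edge density in (0, 1].
#' @param negProb probability of an inhibiting (-1) edge sign.
#' @param footprintMin,footprintMax per-node footprint size range (genes).
#' @param footprintFraction fraction of backbone nodes carrying a footprint.
#' @param amplitude planted coherent perturbation amplitude `a`; 0 gives a
#'   pure null contrast.
#' @param noiseSd standard deviation of gene-level noise (log2 units).
#' @param nBackground decoy genes measured but absent from the network.
#' @param pseudoN pseudo sample size for t-statistic synthesis: the reported
#'   `t` is `beta / (noiseSd / sqrt(pseudoN))`.
#' @param balanced when `TRUE`, backbone edge signs are drawn from a random
#'   node gauge (`sigma(x, y) = s(x) s(y)`), so the signed backbone is
#'   balanced and a perfectly coherent perturbation state exists; `negProb`
#'   then only shapes the transcript-edge signs. When `FALSE` (default),
#'   backbone signs are independent coin flips and cycles may be frustrated.
#' @param seed integer seed.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nBackbone = 20L, density = 0.15, negProb = 0.3,
                        footprintMin = 5L, footprintMax = 20L,
                        footprintFraction = 0.8, amplitude = 1,
                        noiseSd = 0.1, nBackground = 200L, pseudoN = 10,
                        balanced = FALSE, seed = 1L) {
  methods::new("SynthConfig",
    nBackbone = as.integer(nBackbone), density = density, negProb = negProb,
    footprintMin = as.integer(footprintMin),
    footprintMax = as.integer(footprintMax),
    footprintFraction = footprintFraction, amplitude = amplitude,
    noiseSd = noiseSd, nBackground = as.integer(nBackground),
    pseudoN = pseudoN, balanced = isTRUE(balanced), seed = as.integer(seed))
}

#' Generate a random two-layer network
#'
#' Draws a connected signed backbone (Erdős–Rényi at the configured density,
#' rejected and redrawn until connected, at most 100 attempts), orients each
#' edge uniformly at random, signs edges -1 with probability `negProb`, then
#' attaches disjoint gene footprints of uniform random size in
#' `[footprintMin, footprintMax]` to a random `footprintFraction` of the
#' backbone nodes, with footprint edge signs drawn the same way. Gene
#' identifiers are `G0001, G0002, ...`. Deterministic given the seed.
#'
#' @param cfg a [SynthConfig-class].
#' @param name,family network metadata.
#' @param seed overrides `cfg@seed` when given.
#' @return a [TwoLayerNetwork-class].
#' @export
generateNetwork <- function(cfg, name = NULL, family = NA_character_,
                            seed = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  if (is.null(seed)) seed <- cfg@seed
  if (is.null(name)) name <- paste0("synth-", seed)
  n <- cfg@nBackbone
  withSeed(seed, {
    g <- NULL
    for (try in seq_len(100)) {
      cand <- igraph::sample_gnp(n, cfg@density)
      if (igraph::is_connected(cand) && igraph::ecount(cand) >= 1) {
        g <- cand
        break
      }
    }
    if (is.null(g))
      stop("could not draw a connected backbone at density ", cfg@density,
           " in 100 attempts; increase the density")
    nodes <- sprintf("n%02d", seq_len(n))
    el <- igraph::as_edgelist(g, names = FALSE)
    flip <- runif(nrow(el)) < 0.5
    el[flip, ] <- el[flip, 2:1]
    esign <- if (cfg@balanced) {
      gauge <- sample(c(-1, 1), n, replace = TRUE)
      gauge[el[, 1]] * gauge[el[, 2]]
    } else {
      ifelse(runif(nrow(el)) < cfg@negProb, -1, 1)
    }
    be <- data.frame(source = nodes[el[, 1]], target = nodes[el[, 2]],
                     sign = esign, stringsAsFactors = FALSE)

    nFoot <- max(1L, round(cfg@footprintFraction * n))
    footed <- sort(sample(nodes, nFoot))
    sizeRange <- seq(cfg@footprintMin, cfg@footprintMax)
    sizes <- if (length(sizeRange) == 1) rep(sizeRange, nFoot)
             else sample(sizeRange, nFoot, replace = TRUE)
    geneId <- 0L
    te <- do.call(rbind, lapply(seq_along(footed), function(i) {
      ids <- geneId + seq_len(sizes[i])
      geneId <<- geneId + sizes[i]
      data.frame(source = footed[i], gene = sprintf("G%04d", ids),
                 sign = ifelse(runif(sizes[i]) < cfg@negProb, -1, 1),
                 stringsAsFactors = FALSE)
    }))
    newTwoLayerNetwork(be, te, name = name, family = as.character(family))
  })
}

#' Coherent sign gauge of a backbone
#'
#' A coherent perturbation assigns each backbone node a sign `s(x)` such that
#' every backbone edge is satisfied: `s(x) = sigma(x -> y) * s(y)`. Such a
#' gauge exists exactly when the signed backbone is balanced; on frustrated
#' (unbalanced) backbones a best-effort gauge from a breadth-first traversal
#' is returned together with the number of violated edges.
#'
#' @param net a [TwoLayerNetwork-class].
#' @return list with `s` (named +/-1 per backbone node) and `frustrated`
#'   (count of backbone edges the gauge violates).
#' @export
plantedGauge <- function(net) {
  stopifnot(is(net, "TwoLayerNetwork"))
  nodes <- net@backboneNodes
  s <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  be <- net@backboneEdges
  adj <- lapply(stats::setNames(nm = nodes), function(x) integer(0))
  for (i in seq_len(nrow(be))) {
    adj[[be$source[i]]] <- c(adj[[be$source[i]]], i)
    adj[[be$target[i]]] <- c(adj[[be$target[i]]], i)
  }
  for (root in nodes) {
    if (!is.na(s[root])) next
    s[root] <- 1
    queue <- root
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      for (i in adj[[x]]) {
        other <- if (be$source[i] == x) be$target[i] else be$source[i]
        want <- be$sign[i] * s[x]   # satisfies s(x) = sigma * s(other)
        if (is.na(s[other])) {
          s[other] <- want
          queue <- c(queue, other)
        }
      }
    }
  }
  frustrated <- sum(s[be$source] != be$sign * s[be$target])
  list(s = s, frustrated = as.integer(frustrated))
}

#' Generate a contrast with a planted coherent perturbation
#'
#' Plants a backbone-coherent perturbation of amplitude `a = cfg@amplitude`:
#' node signs `s(x)` come from [plantedGauge()], and every footprint gene `G`
#' downstream of node `x` through an edge of sign `sigma` receives
#' `beta_G = a * s(x) * sigma + Normal(0, noiseSd^2)`, so that in the
#' noiseless limit the smoothing problem recovers `f(x) = a * s(x)` exactly
#' and the NPA equals `4 a^2` on a balanced backbone. Decoy genes receive
#' pure noise. The t-statistic is synthesized as `beta / seTrue` with
#' `seTrue = noiseSd / sqrt(pseudoN)`. `amplitude = 0` yields a null contrast
#' for calibration. Deterministic given the seed.
#'
#' @param net a [TwoLayerNetwork-class] from [generateNetwork()].
#' @param cfg a [SynthConfig-class].
#' @param name contrast label.
#' @param seed overrides `cfg@seed` when given.
#' @return a [Contrast-class].
#' @export
generateContrast <- function(net, cfg, name = NULL, seed = NULL) {
  stopifnot(is(net, "TwoLayerNetwork"), is(cfg, "SynthConfig"))
  if (is.null(seed)) seed <- cfg@seed
  if (is.null(name)) name <- paste0("contrast-", seed)
  gauge <- plantedGauge(net)
  te <- net@transcriptEdges
  withSeed(seed, {
    genes <- sort(unique(te$gene))
    signal <- stats::setNames(numeric(length(genes)), genes)
    # a gene with several incoming footprint edges averages its signals
    sig <- cfg@amplitude * gauge$s[te$source] * te$sign
    agg <- tapply(sig, te$gene, mean)
    signal[names(agg)] <- agg
    decoys <- if (cfg@nBackground > 0)
      sprintf("BG%04d", seq_len(cfg@nBackground)) else character(0)
    allGenes <- c(genes, decoys)
    # noiseSd is per-replicate gene noise; a contrast averages pseudoN
    # replicates, so the fold-change error and its reported se coincide
    seTrue <- max(cfg@noiseSd, 1e-8) / sqrt(cfg@pseudoN)
    beta <- c(signal, stats::setNames(numeric(length(decoys)), decoys)) +
      rnorm(length(allGenes), 0, if (cfg@noiseSd > 0) seTrue else 0)
    methods::new("Contrast", name = name,
                 beta = beta,
                 se = stats::setNames(rep(seTrue, length(allGenes)), allGenes),
                 provenance = sprintf("synthetic (amplitude=%g, sd=%g, seed=%d)",
                                      cfg@amplitude, cfg@noiseSd,
                                      as.integer(seed)))
  })
}
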