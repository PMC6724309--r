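#' Delta-method confidence interval for the NPA
#'
#' The NPA is a quadratic form in the gene fold-changes:
#' `NPA = beta' M beta` with `M = K' Q K / |E|` and `K = -L3^{-1} L2`.
#' Propagating the per-gene standard errors to first order (genes treated as
#' independent) gives
#' \deqn{Var(NPA) \approx 4 \sum_g (M\beta)_g^2 \, se_g^2,}
#' and the interval `NPA +/- z * sqrt(Var)` at the requested level. The
#' statistic passes when the lower bound is strictly positive; with
#' `beta = 0` the interval collapses to `(0, 0)` and fails by convention.
#'
#' Genes with `se = NA` (no usable t-statistic) contribute no variance.
#'
#' @param blocks a [LaplacianBlocks-class].
#' @param beta gene fold-changes aligned to `blocks@geneOrder`.
#' @param se standard errors aligned with `beta`; positive or `NA`.
#' @param level confidence level (default 0.95).
#' @return numeric of length 2, `c(low, high)`.
#' @export
confidenceInterval <- function(blocks, beta, se, level = 0.95) {
  stopifnot(is(blocks, "LaplacianBlocks"))
  beta <- alignToOrder(beta, blocks@geneOrder, "beta")
  se <- alignToOrder(se, blocks@geneOrder, "se")
  ok <- !is.na(se)
  if (any(se[ok] <= 0)) stop("standard errors must be positive")
  f <- drop(blocks@K %*% beta)
  score <- max(0, drop(crossprod(f, blocks@Q %*% f)) / blocks@Esize)
  mb <- drop(crossprod(blocks@K, blocks@Q %*% f)) / blocks@Esize  # (M beta)_g
  v <- 4 * sum((mb[ok] * se[ok])^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = score - z * sqrt(v), high = score + z * sqrt(v))
}

#' Permutation null distribution of the NPA
#'
#' Tests whether an NPA score is specific to the biology wired into the
#' network by reshuffling network structure and recomputing the score:
#' \describe{
#'   \item{`kind = "O"`}{transcript-layer reshuffling: a uniform random
#'     permutation of the gene labels across all transcript edges, which is
#'     applied equivalently by permuting the `beta` entries over the gene
#'     order. Footprint sizes and sign multisets per backbone node are
#'     preserved.}
#'   \item{`kind = "K"`}{functional-layer reshuffling: a uniform random
#'     relabeling of backbone node identities on the backbone edge list only
#'     (each node keeps its own transcript footprint), after which the blocks
#'     are rebuilt and the score recomputed. The backbone topology is
#'     preserved as an unlabeled signed graph.}
#' }
#' The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + nPerm)`, whose smallest achievable
#' value is `1/(nPerm + 1)`; the 95% null quantile is reported alongside.
#'
#' @param blocks a [LaplacianBlocks-class] of the matched network.
#' @param beta gene fold-changes aligned to `blocks@geneOrder`.
#' @param kind `"O"` or `"K"`.
#' @param nPerm number of permutations (default 500; at least 100 is
#'   recommended for a stable 5% call).
#' @param seed integer seed; the same seed reproduces the same null.
#' @return a [PermutationNull-class].
#' @seealso [permutationO()], [permutationK()] for the network-level wrappers.
#' @export
permutationNull <- function(blocks, beta, kind = c("O", "K"), nPerm = 500L,
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is(blocks, "LaplacianBlocks"))
  nPerm <- as.integer(nPerm)
  if (is.na(nPerm) || nPerm < 1L) stop("nPerm must be a positive integer")
  if (nPerm < 100L)
    warning("nPerm = ", nPerm, " is small; at least 100 is recommended")
  beta <- alignToOrder(beta, blocks@geneOrder, "beta")
  g <- length(blocks@geneOrder)
  n <- length(blocks@nodeOrder)

  f0 <- drop(blocks@K %*% beta)
  observed <- max(0, drop(crossprod(f0, blocks@Q %*% f0)) / blocks@Esize)

  nullScores <- withSeed(seed, {
    if (kind == "O") {
      if (g < 3) stop("transcript-layer permutation needs at least 3 genes")
      B <- vapply(seq_len(nPerm), function(i) beta[sample.int(g)],
                  numeric(g))
      Fm <- blocks@K %*% B
      pmax(0, colSums(Fm * (blocks@Q %*% Fm)) / blocks@Esize)
    } else {
      if (n < 2) stop("backbone permutation needs at least 2 backbone nodes")
      degB <- diag(blocks@Q)
      degT <- diag(blocks@L3) - degB
      M0 <- 2 * diag(degB, n) - blocks@Q   # backbone-only Laplacian part
      b <- drop(blocks@L2 %*% beta)
      vapply(seq_len(nPerm), function(i) {
        p <- sample.int(n)
        L3p <- M0[p, p, drop = FALSE]
        diag(L3p) <- diag(L3p) + degT
        fp <- -solve(L3p, b)
        max(0, drop(crossprod(fp, blocks@Q[p, p, drop = FALSE] %*% fp)) /
              blocks@Esize)
      }, numeric(1))
    }
  })

  p <- (1 + sum(nullScores >= observed - 1e-12)) / (1 + nPerm)
  methods::new("PermutationNull", kind = kind, nPerm = nPerm,
               nullScores = unname(nullScores), pValue = p,
               quantile95 = unname(stats::quantile(nullScores, 0.95)),
               seed = as.integer(seed))
}

#' @describeIn permutationNull transcript-layer ("O") test from a network and
#'   contrast: matches the contrast, rebuilds the blocks, then permutes.
#' @param net a [TwoLayerNetwork-class].
#' @param contrast a [Contrast-class].
#' @param minDownstream,caseInsensitive passed to [matchContrast()].
#' @export
permutationO <- function(net, contrast, nPerm = 500L, seed = 1L,
                         minDownstream = 5L, caseInsensitive = FALSE) {
  m <- matchContrast(net, contrast, minDownstream, caseInsensitive)
  permutationNull(buildLaplacianBlocks(m$network), m$beta, "O", nPerm, seed)
}

#' @describeIn permutationNull functional-layer ("K") test from a network and
#'   contrast.
#' @export
permutationK <- function(net, contrast, nPerm = 500L, seed = 1L,
                         minDownstream = 5L, caseInsensitive = FALSE) {
  m <- matchContrast(net, contrast, minDownstream, caseInsensitive)
  permutationNull(buildLaplacianBlocks(m$network), m$beta, "K", nPerm, seed)
}

#' Compact significance label for an NPA result
#'
#' Encodes the two permutation statistics: `*O` / `*K` when the p-value is
#' below 0.05, `.O` / `.K` when it lies in [0.05, 0.1), nothing otherwise.
#' The confidence-interval statistic is carried separately as the `ciFlag`
#' slot (`*`, interval excludes zero). A perturbation is `significant` only
#' when all three statistics pass.
#'
#' @param r an [NpaResult-class].
#' @return the label string, e.g. `"*O*K"`.
#' @export
significanceLabel <- function(r) {
  stopifnot(is(r, "NpaResult"))
  band <- function(p, tag) {
    if (is.na(p)) "" else if (p < 0.05) paste0("*", tag)
    else if (p < 0.1) paste0(".", tag) else ""
  }
  paste0(band(r@pO, "O"), band(r@pK, "K"))
}
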