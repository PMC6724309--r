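#' Aggregate network perturbations into a Biological Impact Factor
#'
#' Summarizes a networks-by-contrasts panel of NPA results into one number
#' per contrast. Non-significant cells (the strict all-three rule: CI and
#' both permutation statistics) contribute nothing. Each network `i` enters
#' with weight
#' \deqn{w_i = \frac{1}{|family(i)|} \cdot \frac{1}{1 + \bar o_i},}
#' where `|family(i)|` is the number of networks in its family and `o_i` the
#' mean Jaccard overlap of its backbone node set with every other network's —
#' so large families do not dominate by count and redundant networks do not
#' double-count shared biology. The raw BIF of a contrast is the weighted sum
#' of its significant NPA scores; the relative BIF rescales to percent of the
#' reference contrast (by default the contrast with the highest raw BIF, i.e.
#' the treatment showing the strongest perturbation), which reads 100%.
#'
#' @param results list of [NpaResult-class] objects covering a
#'   networks x contrasts panel.
#' @param families named character vector mapping every network name to a
#'   family label; networks absent from it are an error.
#' @param reference contrast name, or `"auto"` to pick the contrast with the
#'   highest raw BIF.
#' @return a [BifResult-class] including the per-family contribution
#'   fractions and the delta similarity index (see [computeDelta()]).
#' @export
computeBif <- function(results, families, reference = "auto") {
  panel <- resultPanel(results)
  missingFam <- setdiff(panel$networks, names(families))
  if (length(missingFam))
    stop("no family assigned to network(s): ",
         paste(missingFam, collapse = ", "))
  fam <- families[panel$networks]
  w <- bifWeights(panel, fam)

  eff <- panel$score * panel$sig            # non-significant cells drop out
  raw <- drop(w %*% eff)
  names(raw) <- panel$contrasts
  if (all(raw == 0))
    warning("no significant network perturbation in any contrast; BIF is 0")

  if (identical(reference, "auto")) {
    reference <- panel$contrasts[which.max(raw)]
  } else if (!reference %in% panel$contrasts) {
    stop("reference contrast '", reference, "' not found")
  }
  relative <- if (raw[reference] > 0) 100 * raw / raw[reference]
              else stats::setNames(rep(NA_real_, length(raw)), names(raw))

  famLevels <- sort(unique(fam))
  ff <- matrix(0, length(famLevels), length(panel$contrasts),
               dimnames = list(famLevels, panel$contrasts))
  for (j in seq_along(panel$contrasts)) {
    contribs <- w * eff[, j]
    if (sum(contribs) > 0)
      ff[, j] <- vapply(famLevels, function(fl)
        sum(contribs[fam == fl]) / sum(contribs), numeric(1))
  }

  delta <- tryCatch(computeDelta(results, reference, families),
                    error = function(e)
                      stats::setNames(rep(NA_real_, length(panel$contrasts)),
                                      panel$contrasts))
  methods::new("BifResult", raw = raw, relative = relative,
               reference = reference, familyFractions = ff, delta = delta,
               weights = stats::setNames(w, panel$networks))
}

#' Similarity of network perturbation mechanisms between contrasts
#'
#' For every contrast, the backbone differential values of all networks are
#' concatenated into one long vector (zeroed for networks whose perturbation
#' is not significant in that contrast), each network's segment scaled by
#' `sqrt(w_i / n_i)` with `w_i` the BIF weight and `n_i` the backbone size,
#' so that no single large network dominates. The delta index of a contrast
#' is the cosine similarity between its vector and the reference contrast's:
#' 1 means the same networks are perturbed through the same mechanisms, -1 a
#' fully opposed perturbation pattern, 0 unrelated mechanisms.
#'
#' @inheritParams computeBif
#' @param reference the reference contrast name.
#' @return named numeric in `[-1, 1]` per contrast; `delta[reference] == 1`.
#' @export
computeDelta <- function(results, reference, families = NULL) {
  panel <- resultPanel(results)
  if (!reference %in% panel$contrasts)
    stop("reference contrast '", reference, "' not found")
  fam <- if (is.null(families))
    stats::setNames(rep("all", length(panel$networks)), panel$networks)
  else families[panel$networks]
  w <- bifWeights(panel, fam)

  vecs <- vapply(seq_along(panel$contrasts), function(j) {
    unlist(lapply(seq_along(panel$networks), function(i) {
      nodes <- panel$nodeSets[[i]]
      r <- panel$cells[[i, j]]
      fvec <- stats::setNames(numeric(length(nodes)), nodes)
      if (!is.null(r) && isTRUE(r@significant))
        fvec[names(r@f)] <- r@f
      fvec * sqrt(w[i] / length(nodes))
    }))
  }, numeric(sum(lengths(panel$nodeSets))))

  ref <- vecs[, match(reference, panel$contrasts)]
  refNorm <- sqrt(sum(ref^2))
  if (refNorm == 0)
    stop("delta is undefined: the reference contrast has no significant",
         " perturbation")
  delta <- apply(vecs, 2, function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) 0 else sum(v * ref) / (nv * refNorm)
  })
  stats::setNames(pmin(1, pmax(-1, delta)), panel$contrasts)
}

# organize a flat result list into a networks x contrasts panel
resultPanel <- function(results) {
  if (is(results, "NpaResult")) results <- list(results)
  if (!length(results)) stop("no results supplied")
  networks <- sort(unique(vapply(results, function(r) r@network, "")))
  contrasts <- unique(vapply(results, function(r) r@contrast, ""))
  cells <- matrix(list(NULL), length(networks), length(contrasts),
                  dimnames = list(networks, contrasts))
  for (r in results) cells[[r@network, r@contrast]] <- r
  score <- matrix(0, length(networks), length(contrasts),
                  dimnames = list(networks, contrasts))
  sig <- score
  for (i in seq_along(networks)) for (j in seq_along(contrasts)) {
    r <- cells[[i, j]]
    if (!is.null(r)) {
      score[i, j] <- r@score
      sig[i, j] <- as.numeric(isTRUE(r@significant))
    }
  }
  nodeSets <- lapply(networks, function(nw) {
    sort(unique(unlist(lapply(results, function(r)
      if (r@network == nw) names(r@f) else NULL))))
  })
  list(networks = networks, contrasts = contrasts, cells = cells,
       score = score, sig = sig, nodeSets = nodeSets)
}

# family-size and overlap-discounted weights, one per network
bifWeights <- function(panel, fam) {
  famSize <- table(fam)
  n <- length(panel$networks)
  obar <- vapply(seq_len(n), function(i) {
    if (n == 1) return(0)
    mean(vapply(setdiff(seq_len(n), i), function(j) {
      a <- panel$nodeSets[[i]]; b <- panel$nodeSets[[j]]
      u <- length(union(a, b))
      if (u == 0) 0 else length(intersect(a, b)) / u
    }, numeric(1)))
  }, numeric(1))
  unname(1 / as.numeric(famSize[fam]) / (1 + obar))
}
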