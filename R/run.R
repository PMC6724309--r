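#' Build a run configuration
#'
#' @param networks networks to score: a character vector of TSV paths or a
#'   list of [TwoLayerNetwork-class] objects (paths and objects may be
#'   mixed).
#' @param contrasts contrasts: a character vector of table paths (each may
#'   hold several contrasts in long format) or a list of [Contrast-class]
#'   objects.
#' @param families optional named character vector, network name -> family
#'   (overrides any family carried by the network itself).
#' @param nPerm permutations per statistic (default 500).
#' @param seed root seed; every per-(network, contrast, statistic) seed is
#'   derived from it deterministically.
#' @param cutoff leading-node cutoff fraction (default 0.8).
#' @param minDownstream minimum footprint size (default 5).
#' @param outDir output directory (created if needed); `NA` disables file
#'   output.
#' @param aggregateDuplicates duplicate-gene policy for contrast files
#'   (`"error"` or `"mean"`).
#' @param caseInsensitive fold gene-symbol case when matching.
#' @param saveNull keep full permutation null vectors in results and JSON.
#' @return a validated [RunConfig-class].
#' @export
npaRunConfig <- function(networks, contrasts, families = character(0),
                         nPerm = 500L, seed = 1L, cutoff = 0.8,
                         minDownstream = 5L, outDir = NA_character_,
                         aggregateDuplicates = "error",
                         caseInsensitive = FALSE, saveNull = FALSE) {
  if (!is.list(networks)) networks <- as.list(networks)
  if (!is.list(contrasts)) contrasts <- as.list(contrasts)
  methods::new("RunConfig",
    networks = networks, families = families, contrasts = contrasts,
    nPerm = as.integer(nPerm), seed = as.integer(seed), cutoff = cutoff,
    minDownstream = as.integer(minDownstream), outDir = outDir,
    aggregateDuplicates = aggregateDuplicates,
    caseInsensitive = caseInsensitive, saveNull = saveNull)
}

resolveNetworks <- function(cfg) {
  nets <- lapply(cfg@networks, function(x) {
    if (is(x, "TwoLayerNetwork")) x else readNetwork(x)
  })
  for (i in seq_along(nets)) {
    nm <- nets[[i]]@name
    if (nm %in% names(cfg@families)) nets[[i]]@family <- cfg@families[[nm]]
  }
  stats::setNames(nets, vapply(nets, function(n) n@name, ""))
}

resolveContrasts <- function(cfg) {
  out <- list()
  for (x in cfg@contrasts) {
    if (is(x, "Contrast")) out[[x@name]] <- x
    else for (cc in loadContrasts(x, cfg@aggregateDuplicates))
      out[[cc@name]] <- cc
  }
  out
}

#' Score every network against every contrast
#'
#' The end-to-end orchestration: for each (network, contrast) cell, map the
#' contrast, apply the structural filters, build the Laplacian blocks, solve
#' for the differential values, score the NPA, compute the confidence
#' interval and both permutation statistics, and decompose into leading
#' nodes. Progress, filter counts and errors are logged to stderr; a network
#' failing its preconditions is skipped (the run only fails if every cell
#' fails). When `cfg@outDir` is set, writes `npa_results.json` plus TSV
#' matrices of scores and p-values and one leading-node matrix per network —
#' all byte-deterministic under a fixed root seed.
#'
#' @param cfg a [RunConfig-class] from [npaRunConfig()].
#' @return invisibly, the list of [NpaResult-class] objects.
#' @seealso [runBif()]
#' @export
runNpa <- function(cfg) {
  stopifnot(is(cfg, "RunConfig"))
  nets <- resolveNetworks(cfg)
  contrasts <- resolveContrasts(cfg)
  if (!length(nets)) stop("no networks configured")
  if (!length(contrasts)) stop("no contrasts configured")

  results <- list()
  failures <- 0L
  for (net in nets) {
    for (cc in contrasts) {
      cellSeed <- cfg@seed
      res <- tryCatch(
        scoreContrast(net, cc, nPerm = cfg@nPerm, seed = cellSeed,
                      minDownstream = cfg@minDownstream,
                      caseInsensitive = cfg@caseInsensitive,
                      saveNull = cfg@saveNull),
        error = function(e) {
          message("[netamp] skipping ", net@name, " x ", cc@name, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) {
        failures <- failures + 1L
        next
      }
      message(sprintf("[netamp] %s x %s: NPA = %.4g %s", net@name, cc@name,
                      res@score, res@label))
      results[[paste(net@name, cc@name, sep = "|")]] <- res
    }
  }
  if (!length(results))
    stop("all ", failures, " (network, contrast) cells failed")

  if (!is.na(cfg@outDir)) writeRunOutputs(results, cfg)
  invisible(results)
}

#' Aggregate a run into the Biological Impact Factor
#'
#' Wraps [computeBif()] / [computeDelta()] over the results of [runNpa()],
#' using each network's family (from the run configuration or the network
#' sidecar). Writes `bif.json` and `bif.tsv` to the output directory when
#' configured.
#'
#' @param cfg the [RunConfig-class] used for the run.
#' @param results list of [NpaResult-class] from [runNpa()].
#' @param reference reference contrast name or `"auto"`.
#' @return a [BifResult-class].
#' @export
runBif <- function(cfg, results, reference = "auto") {
  nets <- resolveNetworks(cfg)
  fams <- vapply(nets, function(n)
    if (is.na(n@family)) "unassigned" else n@family, "")
  bif <- computeBif(results, fams, reference)
  if (!is.na(cfg@outDir)) {
    dir.create(cfg@outDir, recursive = TRUE, showWarnings = FALSE)
    writeJson(bifToList(bif), file.path(cfg@outDir, "bif.json"))
    tab <- data.frame(contrast = names(bif@raw), raw = unname(bif@raw),
                      relative = unname(bif@relative),
                      delta = unname(bif@delta))
    utils::write.table(tab, file.path(cfg@outDir, "bif.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  bif
}

# --- serialization -----------------------------------------------------------

resultToList <- function(r) {
  nullSummary <- function(pn) {
    if (is.null(pn)) return(NULL)
    s <- pn@nullScores
    list(nPerm = pn@nPerm, seed = pn@seed, p = pn@pValue,
         min = unname(if ("min" %in% names(s)) s[["min"]] else min(s)),
         median = unname(if ("median" %in% names(s)) s[["median"]]
                         else stats::median(s)),
         q95 = pn@quantile95,
         max = unname(if ("max" %in% names(s)) s[["max"]] else max(s)),
         scores = if (length(s) > 4 || is.null(names(s))) unname(s) else NULL)
  }
  list(network = r@network, contrast = r@contrast, score = r@score,
       ciLow = r@ciLow, ciHigh = r@ciHigh, pO = r@pO, pK = r@pK,
       ciFlag = r@ciFlag, label = r@label, significant = r@significant,
       f = as.list(r@f), contributions = as.list(r@contributions),
       nullO = nullSummary(r@nullO), nullK = nullSummary(r@nullK))
}

bifToList <- function(bif) {
  list(reference = bif@reference, raw = as.list(bif@raw),
       relative = as.list(bif@relative), delta = as.list(bif@delta),
       weights = as.list(bif@weights),
       familyFractions = lapply(
         stats::setNames(nm = colnames(bif@familyFractions)),
         function(cn) as.list(bif@familyFractions[, cn])))
}

writeJson <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  con <- file(path, open = "wb")
  writeLines(json, con)
  close(con)
  invisible(path)
}

writeRunOutputs <- function(results, cfg) {
  dir.create(cfg@outDir, recursive = TRUE, showWarnings = FALSE)
  ord <- order(vapply(results, function(r) paste(r@network, r@contrast), ""))
  results <- results[ord]
  payload <- list(
    config = list(nPerm = cfg@nPerm, seed = cfg@seed, cutoff = cfg@cutoff,
                  minDownstream = cfg@minDownstream),
    results = lapply(unname(results), resultToList))
  writeJson(payload, file.path(cfg@outDir, "npa_results.json"))

  panel <- resultPanel(results)
  writeMatrix <- function(m, file)
    utils::write.table(data.frame(network = rownames(m), m,
                                  check.names = FALSE),
                       file.path(cfg@outDir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  pO <- pK <- panel$score * NA
  for (i in rownames(panel$score)) for (j in colnames(panel$score)) {
    r <- panel$cells[[i, j]]
    if (!is.null(r)) { pO[i, j] <- r@pO; pK[i, j] <- r@pK }
  }
  writeMatrix(panel$score, "npa_scores.tsv")
  writeMatrix(pO, "npa_pvalues_O.tsv")
  writeMatrix(pK, "npa_pvalues_K.tsv")

  for (nw in panel$networks) {
    sub <- Filter(function(r) r@network == nw && r@score > 0, results)
    if (!length(sub)) next
    lm <- leadingNodeMatrix(sub, cfg@cutoff)
    utils::write.table(data.frame(node = rownames(lm), lm,
                                  check.names = FALSE),
                       file.path(cfg@outDir,
                                 paste0("leading_nodes_", nw, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
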