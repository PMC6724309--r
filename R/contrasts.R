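#' Load expression contrasts from a delimited table
#'
#' Reads one or several contrasts from a TSV/CSV file with header columns
#' `nodeLabel` (gene symbol), `foldChange` (log2) and `t` (t-statistic from a
#' moderated linear model, or the Wald z-statistic for RNA-seq). An optional
#' `contrast` column turns the file into long format holding several
#' contrasts. The per-gene standard error is derived as
#' `se = |foldChange / t|`.
#'
#' Duplicate gene symbols within a contrast are an error unless
#' `aggregateDuplicates = "mean"`, which averages the fold-changes and
#' combines the standard errors as the root mean square. A gene whose `t` is
#' zero or missing carries no usable uncertainty: when its fold-change is
#' also zero the gene is kept with `se = NA` (excluded from variance
#' propagation); a nonzero fold-change with no statistic is an error.
#'
#' @param path path to the table. The separator is taken from the extension
#'   (`.csv` means comma, everything else tab).
#' @param aggregateDuplicates `"error"` (default) or `"mean"`.
#' @param name contrast name used when the file has no `contrast` column
#'   (defaults to the file name).
#' @return a list of [Contrast-class] objects, named by contrast.
#' @seealso [matchContrast()], [writeContrasts()]
#' @export
loadContrasts <- function(path, aggregateDuplicates = c("error", "mean"),
                          name = NULL) {
  aggregateDuplicates <- match.arg(aggregateDuplicates)
  if (!file.exists(path)) stop("contrast file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("nodeLabel", "foldChange", "t")
  if (!all(required %in% names(tab)))
    stop("contrast table must have columns nodeLabel, foldChange, t; missing: ",
         paste(setdiff(required, names(tab)), collapse = ", "))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if ("contrast" %in% names(tab)) {
    groups <- split(tab, tab$contrast)
  } else {
    groups <- stats::setNames(list(tab), name)
  }
  out <- lapply(names(groups), function(cn)
    contrastFromTable(groups[[cn]], cn, aggregateDuplicates,
                      provenance = path))
  stats::setNames(out, names(groups))
}

# build one Contrast from a nodeLabel/foldChange/t data.frame
contrastFromTable <- function(tab, name, aggregateDuplicates = "error",
                              provenance = "in-memory table") {
  gene <- as.character(tab$nodeLabel)
  beta <- as.numeric(tab$foldChange)
  tstat <- as.numeric(tab$t)
  if (anyNA(beta)) stop("contrast '", name, "': missing foldChange values")

  noT <- is.na(tstat) | tstat == 0
  se <- ifelse(noT, NA_real_, abs(beta / tstat))
  bad <- noT & beta != 0
  if (any(bad))
    stop("contrast '", name, "': gene(s) ", paste(head(gene[bad], 3),
         collapse = ", "), " have a nonzero foldChange but no usable ",
         "t-statistic")

  if (anyDuplicated(gene)) {
    if (aggregateDuplicates == "error")
      stop("contrast '", name, "': duplicate nodeLabel(s) ",
           paste(unique(gene[duplicated(gene)])[1:min(3, sum(duplicated(gene)))],
                 collapse = ", "),
           " (use aggregateDuplicates = \"mean\" to average)")
    agg <- function(x, f) vapply(split(x, gene), f, numeric(1))
    beta2 <- agg(beta, mean)
    se2 <- vapply(split(se, gene), function(s) {
      s <- s[!is.na(s)]
      if (!length(s)) NA_real_ else sqrt(mean(s^2))
    }, numeric(1))
    gene <- names(beta2); beta <- unname(beta2); se <- unname(se2)
  }
  methods::new("Contrast", name = name,
               beta = stats::setNames(beta, gene),
               se = stats::setNames(se, gene),
               provenance = provenance)
}

#' Write contrasts to the long-format TSV dialect
#'
#' @param contrasts a list of [Contrast-class] objects.
#' @param path output path; columns `contrast`, `nodeLabel`, `foldChange`,
#'   `t` (with `t = foldChange / se`, 0 where `se` is missing).
#' @return `path`, invisibly.
#' @export
writeContrasts <- function(contrasts, path) {
  if (is(contrasts, "Contrast")) contrasts <- list(contrasts)
  rows <- lapply(contrasts, function(cc) {
    tstat <- ifelse(is.na(cc@se), 0, cc@beta / cc@se)
    data.frame(contrast = cc@name, nodeLabel = names(cc@beta),
               foldChange = unname(cc@beta), t = unname(tstat),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a contrast onto a network's transcript layer
#'
#' Transcript edges whose gene was not measured in the contrast are dropped
#' (absence of measurement is not evidence of no change), after which the
#' structural filters — [pruneUnderrepresented()] and [restrictToScorable()]
#' — are re-applied, since dropping edges can push a footprint below the
#' minimum size or change scorability.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param contrast a [Contrast-class].
#' @param minDownstream minimum footprint size re-applied after matching.
#' @param caseInsensitive match gene symbols after case folding.
#' @return a list with elements `network` (the reduced network), `beta` and
#'   `se` (numeric vectors aligned to the lexicographic gene order of the
#'   reduced transcript layer), and `nMatched` / `nGenes` bookkeeping counts.
#' @section Errors: no gene matched is an error; fewer than half matched is a
#'   warning.
#' @export
matchContrast <- function(net, contrast, minDownstream = 5L,
                          caseInsensitive = FALSE) {
  stopifnot(is(net, "TwoLayerNetwork"), is(contrast, "Contrast"))
  te <- net@transcriptEdges
  netGenes <- unique(te$gene)
  key <- if (caseInsensitive) toupper(names(contrast@beta)) else names(contrast@beta)
  lookup <- if (caseInsensitive) toupper(te$gene) else te$gene
  if (anyDuplicated(key))
    stop("contrast gene symbols collide after case folding")
  hit <- lookup %in% key
  matchedGenes <- unique(te$gene[hit])
  if (!length(matchedGenes))
    stop("no transcript-layer gene of '", net@name,
         "' is present in contrast '", contrast@name, "'")
  if (length(matchedGenes) < 0.5 * length(netGenes))
    warning("only ", length(matchedGenes), "/", length(netGenes),
            " transcript-layer genes of '", net@name,
            "' matched contrast '", contrast@name, "'")

  te2 <- te[hit, , drop = FALSE]
  rownames(te2) <- NULL
  reduced <- newTwoLayerNetwork(net@backboneEdges, te2, net@name, net@family,
                                keepNodes = net@backboneNodes)
  reduced <- filterNetwork(reduced, minDownstream)

  genes <- sort(unique(reduced@transcriptEdges$gene))
  geneKey <- if (caseInsensitive) toupper(genes) else genes
  idx <- match(geneKey, key)
  beta <- stats::setNames(unname(contrast@beta[idx]), genes)
  se <- stats::setNames(unname(contrast@se[idx]), genes)
  list(network = reduced, beta = beta, se = se,
       nMatched = length(matchedGenes), nGenes = length(netGenes))
}
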