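#' @rdname TwoLayerNetwork-class
#' @param object a [TwoLayerNetwork-class] object.
#' @export
setGeneric("backboneNodes", function(object) standardGeneric("backboneNodes"))

#' @rdname TwoLayerNetwork-class
#' @export
setGeneric("geneNodes", function(object) standardGeneric("geneNodes"))

#' @rdname TwoLayerNetwork-class
#' @export
setGeneric("backboneEdges", function(object) standardGeneric("backboneEdges"))

#' @rdname TwoLayerNetwork-class
#' @export
setGeneric("transcriptEdges", function(object) standardGeneric("transcriptEdges"))

#' @rdname TwoLayerNetwork-class
#' @export
setGeneric("networkName", function(object) standardGeneric("networkName"))

#' @rdname TwoLayerNetwork-class
#' @export
setGeneric("networkFamily", function(object) standardGeneric("networkFamily"))

#' @rdname NpaResult-class
#' @param object object to extract from.
#' @export
setGeneric("npaScore", function(object) standardGeneric("npaScore"))

#' @rdname NpaResult-class
#' @export
setGeneric("differentialValues", function(object) standardGeneric("differentialValues"))

#' @rdname NpaResult-class
#' @export
setGeneric("nodeContributions", function(object, ...) standardGeneric("nodeContributions"))

#' @rdname NpaResult-class
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

#' @rdname LeadingNodeSet-class
#' @param object a [LeadingNodeSet-class].
#' @export
setGeneric("leadingNodeNames", function(object) standardGeneric("leadingNodeNames"))

setMethod("backboneNodes", "TwoLayerNetwork", function(object) object@backboneNodes)
setMethod("geneNodes", "TwoLayerNetwork", function(object) object@geneNodes)
setMethod("backboneEdges", "TwoLayerNetwork", function(object) object@backboneEdges)
setMethod("transcriptEdges", "TwoLayerNetwork", function(object) object@transcriptEdges)
setMethod("networkName", "TwoLayerNetwork", function(object) object@name)
setMethod("networkFamily", "TwoLayerNetwork", function(object) object@family)

setMethod("npaScore", "NpaResult", function(object) object@score)
setMethod("differentialValues", "NpaResult", function(object) object@f)
setMethod("nodeContributions", "NpaResult", function(object, ...) object@contributions)
setMethod("isSignificant", "NpaResult", function(object) object@significant)

setMethod("leadingNodeNames", "LeadingNodeSet", function(object)
  object@nodes[seq_len(object@nLeading)])

setMethod("show", "TwoLayerNetwork", function(object) {
  cat("TwoLayerNetwork '", object@name, "'",
      if (!is.na(object@family)) paste0(" [family: ", object@family, "]"), "\n",
      sep = "")
  cat("  backbone: ", length(object@backboneNodes), " nodes, ",
      nrow(object@backboneEdges), " signed directed edges\n", sep = "")
  cat("  transcript layer: ", length(object@geneNodes), " genes, ",
      nrow(object@transcriptEdges), " footprint edges\n", sep = "")
})

setMethod("show", "LaplacianBlocks", function(object) {
  cat("LaplacianBlocks: ", length(object@nodeOrder), " backbone nodes, ",
      length(object@geneOrder), " genes, |E| = ", object@Esize, "\n", sep = "")
})

setMethod("show", "Contrast", function(object) {
  cat("Contrast '", object@name, "': ", length(object@beta), " genes (",
      sum(!is.na(object@se)), " with standard errors)\n", sep = "")
})

setMethod("show", "NpaResult", function(object) {
  cat("NpaResult [", object@network, " x ", object@contrast, "]\n", sep = "")
  cat(sprintf("  NPA = %.4g  95%% CI [%.4g, %.4g]\n",
              object@score, object@ciLow, object@ciHigh))
  cat(sprintf("  p(O) = %.4g  p(K) = %.4g  %s%s\n", object@pO, object@pK,
              object@label,
              if (isTRUE(object@significant)) "  (significant)" else ""))
})

setMethod("show", "PermutationNull", function(object) {
  cat("PermutationNull '", object@kind, "': ", object@nPerm,
      " permutations, p = ", signif(object@pValue, 4),
      ", q95 = ", signif(object@quantile95, 4), "\n", sep = "")
})

setMethod("show", "LeadingNodeSet", function(object) {
  lead <- object@nodes[seq_len(object@nLeading)]
  cat("LeadingNodeSet: ", object@nLeading, "/", length(object@nodes),
      " nodes reach ", 100 * object@cutoff, "% of the NPA\n", sep = "")
  cat("  ", paste0(lead, " (", c("+", "-", "0")[match(sign(object@direction[lead]),
      c(1, -1, 0))], ")", collapse = ", "), "\n", sep = "")
})

setMethod("show", "BifResult", function(object) {
  cat("BifResult (reference: ", object@reference, ")\n", sep = "")
  for (cn in names(object@relative))
    cat(sprintf("  %s: %.1f%%  delta = %.3f\n", cn, object@relative[cn],
                object@delta[cn]))
})
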