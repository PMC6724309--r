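#' Read a two-layer network from a TSV edge list
#'
#' The file is UTF-8, tab-separated, with a required header naming the four
#' columns `source`, `sign`, `target`, `layer` (in any order). Each row is one
#' edge. `layer` is `functional` (backbone-to-backbone) or `transcript`
#' (backbone-to-gene); `sign` is `1`, `-1`, or the causal aliases `increases` /
#' `decreases`. Lines starting with `#` and blank lines are ignored. An
#' optional sidecar file `<path>.meta` with `key=value` lines may carry the
#' network `name` and `family`.
#'
#' Validation applied at read time: malformed rows and unknown tokens raise an
#' error naming the offending line; backbone self-loops are rejected (they are
#' undefined in both quadratic forms); exact duplicate edges are dropped with
#' a warning; a network without a transcript layer is rejected because it has
#' no measurable footprint.
#'
#' @param path path to the edge-list TSV.
#' @param name,family optional overrides for the sidecar/default metadata.
#' @return a validated [TwoLayerNetwork-class].
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("source\tsign\ttarget\tlayer",
#'              "a\t1\tb\tfunctional",
#'              "a\tincreases\tG1\ttranscript",
#'              "b\t-1\tG2\ttranscript"), tsv)
#' net <- readNetwork(tsv, name = "toy")
#' backboneNodes(net)
#' @seealso [writeNetwork()]
#' @export
readNetwork <- function(path, name = NULL, family = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  rows <- raw[keep]
  if (!length(rows)) stop("network file is empty: ", path)

  header <- strsplit(rows[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("source", "sign", "target", "layer")
  if (!setequal(header, required))
    stop("network header must name columns source, sign, target, layer (line ",
         lineNo[1], ")")
  body <- rows[-1]
  bodyLine <- lineNo[-1]
  if (!length(body)) stop("network file has a header but no edges: ", path)

  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop("malformed row (expected ", length(header), " tab-separated fields) ",
         "at line ", bodyLine[bad[1]])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- header
  tab <- tab[, required]

  signMap <- c("1" = 1, "-1" = -1, "increases" = 1, "decreases" = -1,
               "+1" = 1)
  sgn <- signMap[trimws(tab$sign)]
  if (anyNA(sgn))
    stop("unknown sign token '", tab$sign[which(is.na(sgn))[1]], "' at line ",
         bodyLine[which(is.na(sgn))[1]],
         " (expected 1, -1, increases or decreases)")
  layer <- trimws(tab$layer)
  badLayer <- which(!layer %in% c("functional", "transcript"))
  if (length(badLayer))
    stop("unknown layer tag '", layer[badLayer[1]], "' at line ",
         bodyLine[badLayer[1]], " (expected functional or transcript)")

  edges <- data.frame(source = trimws(tab$source), target = trimws(tab$target),
                      sign = unname(sgn), layer = layer,
                      stringsAsFactors = FALSE)
  if (any(edges$source == "" | edges$target == ""))
    stop("empty node identifier at line ",
         bodyLine[which(edges$source == "" | edges$target == "")[1]])

  loop <- edges$layer == "functional" & edges$source == edges$target
  if (any(loop))
    stop("backbone self-loop '", edges$source[which(loop)[1]],
         "' at line ", bodyLine[which(loop)[1]], " is not allowed")

  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) removed from ", basename(path))
    edges <- edges[!dup, , drop = FALSE]
  }

  te <- edges[edges$layer == "transcript", c("source", "target", "sign")]
  names(te) <- c("source", "gene", "sign")
  rownames(te) <- NULL
  if (!nrow(te)) stop("network has no transcript layer")
  be <- edges[edges$layer == "functional", c("source", "target", "sign")]
  rownames(be) <- NULL

  meta <- readSidecar(paste0(path, ".meta"))
  if (is.null(name)) name <- meta[["name"]]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(family)) family <- meta[["family"]]
  if (is.null(family)) family <- NA_character_

  newTwoLayerNetwork(be, te, name = name, family = as.character(family))
}

# key=value sidecar; returns a named list (empty if the file is absent)
readSidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
  out
}

#' Write a two-layer network to the TSV edge-list dialect
#'
#' Inverse of [readNetwork()]; also writes the `<path>.meta` sidecar when the
#' network carries a name or family.
#'
#' @param net a [TwoLayerNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
  be <- net@backboneEdges
  te <- net@transcriptEdges
  tab <- rbind(
    data.frame(source = be$source, sign = be$sign, target = be$target,
               layer = "functional", stringsAsFactors = FALSE),
    data.frame(source = te$source, sign = te$sign, target = te$gene,
               layer = "transcript", stringsAsFactors = FALSE)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("source\tsign\ttarget\tlayer", con)
  if (nrow(tab))
    writeLines(paste(tab$source, tab$sign, tab$target, tab$layer, sep = "\t"),
               con)
  meta <- character(0)
  if (!is.na(net@name)) meta <- c(meta, paste0("name=", net@name))
  if (!is.na(net@family)) meta <- c(meta, paste0("family=", net@family))
  if (length(meta)) writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
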