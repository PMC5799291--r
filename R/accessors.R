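## Accessors for the S4 containers (slot access stays internal).

#' Construct a GeneNetwork from an edge table
#'
#' Builds a simple directed graph from an edge data.frame. Inputs are
#' expected to be already simple; use [buildNetwork()] or [readEdgeList()]
#' for raw tables that may need simplification.
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `mirnas` (semicolon-joined mature miRNA ids).
#' @param loops data.frame of removed self-loops (`gene`, `mirnas`).
#' @param nodes optional character vector of vertex names; defaults to the
#'   genes incident to `edges`. Supplying extra names keeps isolated
#'   vertices, as required for null-model samples of fixed size.
#' @return a [GeneNetwork-class] object.
#' @export
geneNetwork <- function(edges,
                        loops = data.frame(gene = character(),
                                           mirnas = character(),
                                           stringsAsFactors = FALSE),
                        nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  verts <- unique(c(nodes, edges$source, edges$target))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = if (length(verts)) data.frame(name = verts) else NULL)
  new("GeneNetwork", graph = g, loops = loops)
}

## internal: wrap an igraph object (must already be simple)
.wrapIgraph <- function(g, loops = NULL) {
  if (is.null(loops))
    loops <- data.frame(gene = character(), mirnas = character(),
                        stringsAsFactors = FALSE)
  new("GeneNetwork", graph = g, loops = loops)
}

#' @rdname networkAccessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Accessors for GeneNetwork objects
#'
#' `asIgraph()` returns the underlying [igraph::igraph]; `networkNodes()` the
#' vertex (gene) names; `networkEdges()` a data.frame with columns `source`,
#' `target`, `mirnas` (`NA` when the network carries no miRNA labels, e.g.
#' random-graph samples); `removedLoops()` the side table of self-loops
#' removed during simplification; `numNodes()` / `numEdges()` the counts.
#'
#' @param x a [GeneNetwork-class].
#' @name networkAccessors
#' @aliases asIgraph
NULL

setMethod("asIgraph", "GeneNetwork", function(x) x@graph)

#' @rdname networkAccessors
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  nm <- igraph::V(x@graph)$name
  if (is.null(nm)) character() else nm
}

#' @rdname networkAccessors
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  g <- x@graph
  if (igraph::gsize(g) == 0L)
    return(data.frame(source = character(), target = character(),
                      mirnas = character(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g, names = TRUE)
  mirnas <- if ("mirnas" %in% igraph::edge_attr_names(g))
    igraph::E(g)$mirnas else rep(NA_character_, nrow(el))
  data.frame(source = el[, 1], target = el[, 2], mirnas = mirnas,
             stringsAsFactors = FALSE)
}

#' @rdname networkAccessors
#' @export
removedLoops <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  x@loops
}

#' @rdname networkAccessors
#' @export
numNodes <- function(x) igraph::gorder(asIgraph(x))

#' @rdname networkAccessors
#' @export
numEdges <- function(x) igraph::gsize(asIgraph(x))

#' Accessors for CoreDecomposition objects
#'
#' `coreComponents()` returns the list of nontrivial strongly connected
#' components (each a sorted character vector, components ordered by
#' decreasing size); `coreGenes()` the sorted union; `coreSize()` its size.
#'
#' @param x a [CoreDecomposition-class].
#' @name coreAccessors
NULL

#' @rdname coreAccessors
#' @export
coreComponents <- function(x) {
  stopifnot(is(x, "CoreDecomposition"))
  x@components
}

#' @rdname coreAccessors
#' @export
coreGenes <- function(x) {
  stopifnot(is(x, "CoreDecomposition"))
  x@core
}

#' @rdname coreAccessors
#' @export
coreSize <- function(x) length(coreGenes(x))

#' Accessors for TriadCensus objects
#'
#' `censusCounts()` returns the named 16-vector of class counts.
#'
#' @param x a [TriadCensus-class].
#' @export
censusCounts <- function(x) {
  stopifnot(is(x, "TriadCensus"))
  x@counts
}

#' Accessors for MonteCarloResult objects
#'
#' @param x a [MonteCarloResult-class].
#' @name mcAccessors
NULL

#' @rdname mcAccessors
#' @export
pValue <- function(x) {
  stopifnot(is(x, "MonteCarloResult"))
  x@pValue
}

#' @rdname mcAccessors
#' @export
observedStat <- function(x) {
  stopifnot(is(x, "MonteCarloResult"))
  x@observed
}

#' Accessors for LinearSignature objects
#'
#' @param x a [LinearSignature-class].
#' @name signatureAccessors
NULL

#' @rdname signatureAccessors
#' @export
signatureGenes <- function(x) {
  stopifnot(is(x, "LinearSignature"))
  x@genes
}

#' @rdname signatureAccessors
#' @export
signatureWeights <- function(x) {
  stopifnot(is(x, "LinearSignature"))
  stats::setNames(x@weights, x@genes)
}

#' @rdname signatureAccessors
#' @export
signatureOffset <- function(x) {
  stopifnot(is(x, "LinearSignature"))
  x@offset
}

#' @rdname signatureAccessors
#' @export
signatureScaling <- function(x) {
  stopifnot(is(x, "LinearSignature"))
  data.frame(gene = x@genes, mean = x@scaleMeans, sd = x@scaleSds,
             stringsAsFactors = FALSE)
}
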