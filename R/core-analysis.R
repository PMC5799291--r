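## The network core: union of nontrivial (>= 2 nodes) strongly connected
## components. SCCs come from igraph's strong-components routine; the
## package's contract adds deterministic ordering and the >= 2 threshold.

#' Extract the network core
#'
#' Decomposes the network into strongly connected components and keeps the
#' nontrivial ones (at least two nodes). Components are ordered by
#' decreasing size, ties broken by lexicographically smallest member. An
#' acyclic network yields an empty decomposition.
#'
#' @param net a [GeneNetwork-class].
#' @return a [CoreDecomposition-class].
#' @export
extractCore <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  g <- asIgraph(net)
  if (igraph::gorder(g) == 0L)
    return(new("CoreDecomposition", components = list(), core = character()))
  comp <- igraph::components(g, mode = "strong")
  sets <- split(igraph::V(g)$name, comp$membership)
  sets <- sets[vapply(sets, length, 1L) >= 2L]
  sets <- lapply(sets, sort)
  if (length(sets)) {
    sizes <- vapply(sets, length, 1L)
    firsts <- vapply(sets, `[`, "", 1L)
    sets <- unname(sets[order(-sizes, firsts)])
  } else {
    sets <- list()
  }
  core <- sort(as.character(unlist(sets, use.names = FALSE)))
  new("CoreDecomposition", components = sets, core = core)
}

#' Induced subgraph on the core
#'
#' Returns the subgraph of `net` induced by the core genes of `dec`: all
#' edges with both endpoints in the core are retained, including any edges
#' running between different components.
#'
#' @param net a [GeneNetwork-class].
#' @param dec a [CoreDecomposition-class] derived from `net`.
#' @return a [GeneNetwork-class] (empty when the core is empty).
#' @export
coreSubgraph <- function(net, dec) {
  stopifnot(is(net, "GeneNetwork"), is(dec, "CoreDecomposition"))
  core <- coreGenes(dec)
  if (!all(core %in% networkNodes(net)))
    stop("decomposition does not match the network: core genes missing",
         call. = FALSE)
  sub <- igraph::induced_subgraph(asIgraph(net), vids = core)
  .wrapIgraph(sub)
}

#' Degree ranking within the core subgraph
#'
#' Ranks core genes by total degree (in- plus out-edges) in the induced core
#' subgraph, descending, ties broken lexicographically.
#'
#' @param sub a [GeneNetwork-class], typically from [coreSubgraph()].
#' @return data.frame with columns `gene`, `totalDegree`.
#' @export
coreDegreeRanking <- function(sub) {
  stopifnot(is(sub, "GeneNetwork"))
  d <- igraph::degree(asIgraph(sub), mode = "all")
  ord <- order(-d, names(d))
  data.frame(gene = names(d)[ord], totalDegree = unname(d[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Core report as a plain list (JSON-ready)
#'
#' @param net a [GeneNetwork-class].
#' @param dec a [CoreDecomposition-class] from `net`.
#' @return list with component membership, sizes and the induced-subgraph
#'   edge list.
#' @export
coreReport <- function(net, dec) {
  sub <- coreSubgraph(net, dec)
  list(
    components = coreComponents(dec),
    sizes = vapply(coreComponents(dec), length, 1L),
    coreSize = coreSize(dec),
    edges = networkEdges(sub))
}
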