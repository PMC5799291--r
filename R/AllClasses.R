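## S4 classes for the central data objects.

#' GeneNetwork: simplified directed gene-gene network
#'
#' A directed graph whose nodes are gene symbols and whose edge
#' \eqn{A \to B} records that gene \eqn{A} hosts an intragenic miRNA with
#' validated target \eqn{B}. The graph is always *simple*: self-loops are
#' removed (but kept in a side table, since a loop is biologically meaningful
#' self-regulation) and parallel edges are merged with their mediating mature
#' miRNA ids unioned into a single semicolon-joined edge label.
#'
#' Networks produced by [buildNetwork()] additionally carry no isolated
#' nodes; random-graph samples from the null models keep all `n` vertices so
#' that their node count matches the observed network by construction.
#'
#' @slot graph an [igraph::igraph] directed simple graph; vertices are named
#'   by gene symbol; edges may carry a `mirnas` attribute (semicolon-joined
#'   mature miRNA ids).
#' @slot loops a data.frame of removed self-loops with columns `gene`,
#'   `mirnas`.
#'
#' @seealso [buildNetwork()], [networkEdges()], [extractCore()]
#' @export
setClass("GeneNetwork",
  representation(graph = "ANY", loops = "data.frame"),
  prototype(loops = data.frame(gene = character(), mirnas = character(),
                               stringsAsFactors = FALSE)))

setValidity("GeneNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (!igraph::is_directed(g) && igraph::gorder(g) > 0L)
    return("graph must be directed")
  if (any(igraph::which_loop(g))) return("graph must not contain self-loops")
  if (igraph::any_multiple(g)) return("graph must not contain multi-edges")
  if (igraph::gorder(g) > 0L && is.null(igraph::V(g)$name))
    return("vertices must be named")
  if ("mirnas" %in% igraph::edge_attr_names(g)) {
    mi <- igraph::E(g)$mirnas
    if (any(is.na(mi)) || any(!nzchar(mi)))
      return("every edge mirnas label must be a non-empty string")
  }
  if (!all(c("gene", "mirnas") %in% names(object@loops)))
    return("loops table must have columns 'gene' and 'mirnas'")
  TRUE
})

#' CoreDecomposition: nontrivial strongly connected components
#'
#' The network core is the union of all strongly connected components with at
#' least two nodes. Components are stored sorted by decreasing size, ties
#' broken by lexicographically smallest member; each component's genes are
#' sorted.
#'
#' @slot components list of character vectors, each of length >= 2.
#' @slot core character vector, the sorted union of the components.
#' @seealso [extractCore()], [coreSubgraph()]
#' @export
setClass("CoreDecomposition",
  representation(components = "list", core = "character"))

setValidity("CoreDecomposition", function(object) {
  comps <- object@components
  if (length(comps)) {
    if (any(vapply(comps, length, 1L) < 2L))
      return("every component must contain at least two nodes")
    all_genes <- unlist(comps, use.names = FALSE)
    if (anyDuplicated(all_genes))
      return("components must be pairwise disjoint")
    if (!identical(sort(all_genes), object@core))
      return("core must equal the sorted union of the components")
  } else if (length(object@core)) {
    return("core must be empty when there are no components")
  }
  TRUE
})

#' TriadCensus: counts of the 16 three-node isomorphism classes
#'
#' Counts of unordered node triples classified by the isomorphism class of
#' their induced directed subgraph, in the standard 16-class nomenclature
#' (003, 012, 102, 021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D,
#' 120U, 120C, 210, 300). For a complete census the counts sum to
#' \eqn{\binom{n}{3}}.
#'
#' @slot counts named numeric vector of length 16 (names = class labels).
#' @slot nNodes number of nodes of the censused graph.
#' @seealso [triadCensus()], [bruteForceCensus()], [triadClasses()]
#' @export
setClass("TriadCensus",
  representation(counts = "numeric", nNodes = "numeric"))

setValidity("TriadCensus", function(object) {
  if (length(object@counts) != 16L ||
      !identical(names(object@counts), triadClasses()))
    return("counts must be named by the 16 standard triad classes, in order")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (object@nNodes < 0) return("nNodes must be non-negative")
  if (object@nNodes >= 3 &&
      abs(sum(object@counts) - choose(object@nNodes, 3)) > 0.5)
    return("census counts must sum to choose(nNodes, 3)")
  TRUE
})

#' MonteCarloResult: observed statistic against null replicates
#'
#' Result of a Monte Carlo hypothesis test with the conventional add-one
#' p-value estimator \eqn{(r + 1)/(N + 1)}, where \eqn{r} replicates out of
#' \eqn{N} are at least as extreme as the observed statistic in the
#' configured tail. The smallest attainable p-value is \eqn{1/(N+1)}.
#'
#' @slot observed statistic value on the real network.
#' @slot replicates number of null graphs generated.
#' @slot nExtreme number of replicates at least as extreme as `observed`.
#' @slot pValue `(nExtreme + 1) / (replicates + 1)`.
#' @slot tail `"upper"` or `"lower"`.
#' @slot statName label of the statistic, for reporting.
#' @seealso [monteCarloTest()]
#' @export
setClass("MonteCarloResult",
  representation(observed = "numeric", replicates = "numeric",
                 nExtreme = "numeric", pValue = "numeric",
                 tail = "character", statName = "character"))

setValidity("MonteCarloResult", function(object) {
  if (!object@tail %in% c("upper", "lower"))
    return("tail must be 'upper' or 'lower'")
  if (object@nExtreme > object@replicates)
    return("nExtreme cannot exceed replicates")
  p_lo <- 1 / (object@replicates + 1)
  if (object@pValue < p_lo - 1e-12 || object@pValue > 1 + 1e-12)
    return("pValue must lie in [1/(replicates+1), 1]")
  TRUE
})

#' LinearSignature: scaled linear risk classifier
#'
#' A linear decision function over a fixed gene set,
#' \deqn{R(e) = \sum_i w_i e_i - \rho,}
#' where the \eqn{e_i} are expression values (0,1)-scaled with means and
#' standard deviations estimated on the *training* cohort only. A patient is
#' assigned to the high-risk group when \eqn{R \ge 0} and to the low-risk
#' group otherwise.
#'
#' @slot genes ordered character vector of gene symbols.
#' @slot scaleMeans,scaleSds per-gene training means / standard deviations.
#' @slot weights per-gene coefficients \eqn{w_i}.
#' @slot offset the scalar \eqn{\rho}.
#' @seealso [fitSignature()], [riskScore()], [evaluateSignature()]
#' @export
setClass("LinearSignature",
  representation(genes = "character", scaleMeans = "numeric",
                 scaleSds = "numeric", weights = "numeric",
                 offset = "numeric"))

setValidity("LinearSignature", function(object) {
  k <- length(object@genes)
  if (length(object@scaleMeans) != k || length(object@scaleSds) != k ||
      length(object@weights) != k)
    return("genes, scaleMeans, scaleSds and weights must have equal length")
  if (any(object@scaleSds <= 0))
    return("scaleSds must be strictly positive")
  if (length(object@offset) != 1L) return("offset must be a scalar")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges (%d self-loop%s removed)\n",
              numNodes(object), numEdges(object), nrow(object@loops),
              if (nrow(object@loops) == 1L) "" else "s"))
})

setMethod("show", "CoreDecomposition", function(object) {
  sizes <- vapply(object@components, length, 1L)
  cat(sprintf("CoreDecomposition: %d nontrivial SCC%s, core size %d\n",
              length(sizes), if (length(sizes) == 1L) "" else "s",
              length(object@core)))
  if (length(sizes))
    cat("  component sizes:", paste(sizes, collapse = ", "), "\n")
})

setMethod("show", "TriadCensus", function(object) {
  cat(sprintf("TriadCensus on %d nodes (sum %.0f):\n",
              object@nNodes, sum(object@counts)))
  nz <- object@counts[object@counts > 0]
  if (length(nz)) print(nz) else cat("  (all classes empty)\n")
})

setMethod("show", "MonteCarloResult", function(object) {
  cat(sprintf(
    "MonteCarloResult [%s]: observed %.6g, %d/%d replicates as extreme (%s tail), p = %.6g\n",
    object@statName, object@observed, object@nExtreme, object@replicates,
    object@tail, object@pValue))
})

setMethod("show", "LinearSignature", function(object) {
  cat("LinearSignature:", paste(object@genes, collapse = " + "), "\n")
  cat("  weights:", paste(sprintf("%.4f", object@weights), collapse = ", "),
      " offset:", sprintf("%.4f", object@offset), "\n")
})
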