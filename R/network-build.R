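## Construction of the directed gene-gene network: host gene -> target gene
## for every (mature miRNA, target) pair whose precursor lies in a host
## gene. Simplification order: record & remove loops, merge parallel edges
## (miRNA labels unioned), drop isolated nodes.

## Raw (pre, mature, host, target) records prior to simplification.
.rawEdgeRecords <- function(annotations, matMap, targets) {
  r <- merge(targets[, c("matureMirnaId", "targetGene")], matMap,
             by = "matureMirnaId")
  r <- merge(r, annotations[, c("preMirnaId", "hostGene")], by = "preMirnaId")
  unique(r[, c("preMirnaId", "matureMirnaId", "hostGene", "targetGene")])
}

.joinMirnas <- function(x) paste(sort(unique(x)), collapse = ";")

#' Build the miRNA-induced gene-gene network
#'
#' Creates a raw edge `hostGene -> targetGene` for every validated
#' (mature miRNA, target) pair whose precursor lies in an annotated host
#' gene, then simplifies: self-loops are recorded in a side table and
#' removed, parallel edges are merged with their mediating mature-miRNA ids
#' unioned, and isolated nodes are dropped (a host whose miRNA targets only
#' itself disappears entirely).
#'
#' @param annotations data.frame from [readHostAnnotations()], optionally
#'   filtered with [filterMirnaClass()].
#' @param matMap data.frame from [readMatureMap()].
#' @param targets data.frame from [intersectValidatedTargets()].
#' @return a [GeneNetwork-class]. An empty validated-target set yields an
#'   empty network with a warning.
#' @export
buildNetwork <- function(annotations, matMap, targets) {
  raw <- .rawEdgeRecords(annotations, matMap, targets)
  if (nrow(raw) == 0L) {
    warning("no resolvable miRNA-target interactions: empty network")
    return(geneNetwork(data.frame(source = character(),
                                  target = character(),
                                  mirnas = character())))
  }
  is_loop <- raw$hostGene == raw$targetGene
  loops <- raw[is_loop, , drop = FALSE]
  loop_tab <- if (nrow(loops)) {
    agg <- tapply(loops$matureMirnaId, loops$hostGene, .joinMirnas)
    data.frame(gene = names(agg), mirnas = unname(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), mirnas = character(),
               stringsAsFactors = FALSE)
  }
  kept <- raw[!is_loop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("all interactions were self-loops: empty network")
    return(geneNetwork(data.frame(source = character(),
                                  target = character(),
                                  mirnas = character()),
                       loops = loop_tab))
  }
  pair <- paste(kept$hostGene, kept$targetGene, sep = "\r")
  agg <- tapply(kept$matureMirnaId, pair, .joinMirnas)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(
    source = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 2L),
    mirnas = unname(agg),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  geneNetwork(edges, loops = loop_tab)
}

#' Summary counts of a gene network
#'
#' Computes the quantitative characteristics of the simplified network: node
#' role counts (`bothdirN` nodes with in- and out-edges, `outN` out-only,
#' `inN` in-only; `totalN` their sum), edge count, and the numbers of mature
#' miRNAs, pre-miRNAs and host genes that induce at least one retained
#' (non-loop) edge. The identities `totalN == bothdirN + outN + inN` and
#' `hostGenes == bothdirN + outN` hold by construction.
#'
#' @param net the [GeneNetwork-class] built from the same inputs.
#' @inheritParams buildNetwork
#' @return named list with elements `totalN`, `bothdirN`, `outN`, `inN`,
#'   `totalE`, `matMi`, `preMi`, `hostGenes`.
#' @export
summarizeNetwork <- function(net, annotations, matMap, targets) {
  stopifnot(is(net, "GeneNetwork"))
  g <- asIgraph(net)
  din <- igraph::degree(g, mode = "in")
  dout <- igraph::degree(g, mode = "out")
  raw <- .rawEdgeRecords(annotations, matMap, targets)
  kept <- raw[raw$hostGene != raw$targetGene, , drop = FALSE]
  list(
    totalN = igraph::gorder(g),
    bothdirN = sum(din > 0 & dout > 0),
    outN = sum(dout > 0 & din == 0),
    inN = sum(din > 0 & dout == 0),
    totalE = igraph::gsize(g),
    matMi = length(unique(kept$matureMirnaId)),
    preMi = length(unique(kept$preMirnaId)),
    hostGenes = length(unique(kept$hostGene)))
}

#' Genes with the highest in-degree
#'
#' In-degree counts how many distinct host genes regulate a gene through
#' their intragenic miRNAs. Returns the top `k` genes sorted by decreasing
#' in-degree, ties broken lexicographically by gene id; `k` larger than the
#' node count truncates without error.
#'
#' @param net a [GeneNetwork-class].
#' @param k number of genes to return (`k >= 1`).
#' @return data.frame with columns `gene`, `inDegree`.
#' @seealso [inDegreeHistogram()]
#' @export
inDegreeRanking <- function(net, k) {
  stopifnot(is(net, "GeneNetwork"), k >= 1)
  din <- igraph::degree(asIgraph(net), mode = "in")
  ord <- order(-din, names(din))
  top <- head(ord, k)
  data.frame(gene = names(din)[top], inDegree = unname(din[top]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' In-degree histogram
#'
#' Frequency of each in-degree value across all nodes; the sum of
#' `inDegree * count` equals the edge count.
#'
#' @param net a [GeneNetwork-class].
#' @return data.frame with columns `inDegree`, `count`.
#' @export
inDegreeHistogram <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  din <- igraph::degree(asIgraph(net), mode = "in")
  tab <- table(din)
  data.frame(inDegree = as.integer(names(tab)), count = as.integer(tab),
             row.names = NULL)
}

#' Write / read the edge-list TSV
#'
#' The exchange format has columns `source_gene`, `target_gene`, `mirna_ids`
#' (semicolon-joined mature miRNA ids). `readEdgeList()` accepts both
#' already-simplified and raw lists: it merges duplicate ordered pairs,
#' removes self-loops into the side table, and reports whether anything
#' changed on load.
#'
#' @param net a [GeneNetwork-class].
#' @param path file path.
#' @return `writeEdgeList()` returns `path` invisibly; `readEdgeList()`
#'   returns a [GeneNetwork-class].
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "GeneNetwork"))
  e <- networkEdges(net)
  names(e) <- c("source_gene", "target_gene", "mirna_ids")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  df <- .readTable(path)
  .requireColumns(df, c(source_gene = "source_gene",
                        target_gene = "target_gene"), path)
  mirnas <- if ("mirna_ids" %in% names(df)) as.character(df$mirna_ids)
            else rep(NA_character_, nrow(df))
  src <- .normGene(df$source_gene)
  tgt <- .normGene(df$target_gene)
  changed <- FALSE
  is_loop <- src == tgt
  loop_tab <- data.frame(gene = character(), mirnas = character(),
                         stringsAsFactors = FALSE)
  if (any(is_loop)) {
    changed <- TRUE
    agg <- tapply(mirnas[is_loop], src[is_loop],
                  function(x) .joinMirnas(unlist(strsplit(x[!is.na(x)], ";"))))
    loop_tab <- data.frame(gene = names(agg), mirnas = unname(agg),
                           stringsAsFactors = FALSE)
    src <- src[!is_loop]; tgt <- tgt[!is_loop]; mirnas <- mirnas[!is_loop]
  }
  pair <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(pair)) {
    changed <- TRUE
    agg <- tapply(mirnas, pair, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_character_
      else .joinMirnas(unlist(strsplit(x, ";")))
    })
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    src <- vapply(parts, `[`, "", 1L)
    tgt <- vapply(parts, `[`, "", 2L)
    mirnas <- unname(agg)
  }
  if (changed)
    message("edge list simplified on load (loops and/or duplicates present)")
  edges <- data.frame(source = src, target = tgt, mirnas = mirnas,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  if (all(is.na(edges$mirnas))) edges$mirnas <- NULL
  geneNetwork(edges, loops = loop_tab)
}

#' Export a network as GraphML for visualization tools
#'
#' @param net a [GeneNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(net, path) {
  stopifnot(is(net, "GeneNetwork"))
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}
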