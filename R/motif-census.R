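## Triad census: classification of all unordered node triples into the 16
## isomorphism classes of loop-free 3-node directed graphs, standard
## Davis-Leinhardt nomenclature. The efficient path is igraph's edge-based
## C implementation (no enumeration of the ~C(n,3) empty triples); the
## brute-force oracle below classifies every triple from first principles
## via the dyad (mutual/asymmetric/null) census and is kept independent of
## igraph's classifier.

.TRIAD_CLASSES <- c("003", "012", "102", "021D", "021U", "021C",
                    "111D", "111U", "030T", "030C", "201",
                    "120D", "120U", "120C", "210", "300")

#' The 16 triad class labels
#'
#' Standard nomenclature for the isomorphism classes of 3-node loop-free
#' directed graphs, in the conventional census order: `003` (empty), `012`,
#' `102` (one mutual dyad), `021D`/`021U`/`021C`, `111D`/`111U`,
#' `030T`/`030C` (transitive / cyclic triple), `201`, `120D`/`120U`/`120C`,
#' `210`, `300` (fully mutual).
#'
#' @return character vector of length 16.
#' @export
triadClasses <- function() .TRIAD_CLASSES

## Classify one triple from its 3x3 logical adjacency matrix (no diagonal).
## Pure dyad-census logic; used to build the 64-entry code lookup.
.classifyTriadMatrix <- function(M) {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  typ <- vapply(pairs, function(p) {
    fw <- M[p[1], p[2]]; bw <- M[p[2], p[1]]
    if (fw && bw) "m" else if (fw || bw) "a" else "n"
  }, "")
  m <- sum(typ == "m"); a <- sum(typ == "a")
  dout <- rowSums(M); din <- colSums(M)
  key <- paste0(m, a, 3L - m - a)
  switch(key,
    "003" = "003",
    "012" = "012",
    "102" = "102",
    "201" = "201",
    "300" = "300",
    "210" = "210",
    "021" = {                       # two asymmetric arcs, one null dyad
      if (any(dout == 2)) "021D"
      else if (any(din == 2)) "021U"
      else "021C"
    },
    "111" = {                       # one mutual dyad + one asymmetric arc
      mp <- pairs[[which(typ == "m")]]
      third <- setdiff(1:3, mp)
      if (M[third, mp[1]] || M[third, mp[2]]) "111D" else "111U"
    },
    "030" = {                       # three asymmetric arcs
      if (all(dout == 1) && all(din == 1)) "030C" else "030T"
    },
    "120" = {                       # one mutual dyad + two asymmetric arcs
      mp <- pairs[[which(typ == "m")]]
      third <- setdiff(1:3, mp)
      to_dyad <- M[third, mp[1]] + M[third, mp[2]]
      from_dyad <- M[mp[1], third] + M[mp[2], third]
      if (to_dyad == 2) "120D" else if (from_dyad == 2) "120U" else "120C"
    },
    stop("unreachable dyad census ", key))
}

## Decode a 6-bit arc code into the 3x3 adjacency matrix. Bit order:
## (1->2), (2->1), (1->3), (3->1), (2->3), (3->2).
.triadCodeMatrix <- function(code) {
  bits <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L, 16L, 32L)))
  M <- matrix(FALSE, 3, 3)
  M[1, 2] <- bits[1]; M[2, 1] <- bits[2]
  M[1, 3] <- bits[3]; M[3, 1] <- bits[4]
  M[2, 3] <- bits[5]; M[3, 2] <- bits[6]
  M
}

## label for each of the 64 possible arc codes, built once at load
.triadCodeClass <- vapply(0:63, function(code)
  .classifyTriadMatrix(.triadCodeMatrix(code)), "")

.emptyCensus <- function(n) {
  new("TriadCensus",
      counts = stats::setNames(numeric(16L), .TRIAD_CLASSES),
      nNodes = n)
}

#' Triad census of a network
#'
#' Classifies every unordered node triple by the isomorphism class of its
#' *induced* subgraph. Uses an edge-based algorithm (non-empty classes are
#' found from edge-adjacent triples; the empty and single-dyad classes
#' follow arithmetically), so the census of a network with thousands of
#' nodes completes without touching all \eqn{\binom{n}{3}} triples.
#'
#' @param net a [GeneNetwork-class] (simple: no loops or multi-edges).
#' @return a [TriadCensus-class]. Fewer than 3 nodes gives an all-zero
#'   census.
#' @seealso [bruteForceCensus()] for the exhaustive oracle,
#'   [countMotif()] for a single class.
#' @export
triadCensus <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  g <- asIgraph(net)
  n <- igraph::gorder(g)
  if (n < 3L) return(.emptyCensus(n))
  counts <- suppressWarnings(igraph::triad_census(g))
  new("TriadCensus",
      counts = stats::setNames(as.numeric(counts), .TRIAD_CLASSES),
      nNodes = n)
}

#' Brute-force triad census (testing oracle)
#'
#' Naive classification of every one of the \eqn{\binom{n}{3}} node triples
#' from the adjacency matrix, using a first-principles dyad-census
#' classifier. Guarded to graphs of at most 300 nodes. Bitwise identical to
#' [triadCensus()] by construction.
#'
#' @param net a [GeneNetwork-class] with at most 300 nodes.
#' @return a [TriadCensus-class].
#' @export
bruteForceCensus <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  g <- asIgraph(net)
  n <- igraph::gorder(g)
  if (n > 300L)
    stop("bruteForceCensus is guarded to <= 300 nodes (got ", n, ")",
         call. = FALSE)
  if (n < 3L) return(.emptyCensus(n))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  tr <- combn(n, 3L)
  i <- tr[1L, ]; j <- tr[2L, ]; k <- tr[3L, ]
  code <- A[cbind(i, j)] + 2L * A[cbind(j, i)] +
    4L * A[cbind(i, k)] + 8L * A[cbind(k, i)] +
    16L * A[cbind(j, k)] + 32L * A[cbind(k, j)]
  lab <- .triadCodeClass[code + 1L]
  counts <- table(factor(lab, levels = .TRIAD_CLASSES))
  new("TriadCensus",
      counts = stats::setNames(as.numeric(counts), .TRIAD_CLASSES),
      nNodes = n)
}

#' Count one motif class
#'
#' Number of unordered node triples whose induced subgraph belongs to the
#' given class; equals `censusCounts(triadCensus(net))[motif]`.
#'
#' @param net a [GeneNetwork-class].
#' @param motif one of the 16 labels from [triadClasses()], or a name from
#'   [figureMotifs()].
#' @return numeric count.
#' @export
countMotif <- function(net, motif) {
  motif <- .resolveMotif(motif)
  unname(censusCounts(triadCensus(net))[motif])
}

#' Named motif constants
#'
#' Three-node motif shapes highlighted in figures are registered here as
#' named constants resolving to triad-class labels, so analyses can refer
#' to them symbolically and the mapping can be overridden in one place
#' (e.g. if a different figure reading is preferred):
#' `FULL_MUTUAL` (class `300`, the fully bidirectional triple, absent from
#' the real networks), `FIG2A`, `FIG2B`, `FIG2C`. The defaults for the
#' figure motifs are mutual-dyad-containing classes (`201`, `111U`, `102`
#' respectively): `102` (a mutually connected gene pair plus a spectator
#' gene) is the class whose published counts match "sub-network type 3",
#' position 3 of the standard census order.
#'
#' @param overrides optional named character vector replacing individual
#'   entries, values must be valid triad-class labels.
#' @return named character vector of class labels.
#' @export
figureMotifs <- function(overrides = NULL) {
  defaults <- c(FULL_MUTUAL = "300", FIG2A = "201", FIG2B = "111U",
                FIG2C = "102")
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% names(defaults)))
      stop("overrides must be named with a subset of ",
           paste(names(defaults), collapse = ", "), call. = FALSE)
    if (!all(overrides %in% .TRIAD_CLASSES))
      stop("override values must be triad class labels", call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  defaults
}

.resolveMotif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  fm <- figureMotifs()
  if (motif %in% names(fm)) motif <- unname(fm[motif])
  if (!motif %in% .TRIAD_CLASSES)
    stop("invalid motif label ", sQuote(motif), "; expected one of ",
         paste(.TRIAD_CLASSES, collapse = ", "), " or a name from figureMotifs()",
         call. = FALSE)
  motif
}

## ---- non-induced (embedding) counting ----------------------------------

## Number of embeddings of motif code cm into host-triple code ch:
## permutations sigma of the 3 nodes with arcs(sigma(cm)) subset arcs(ch),
## divided by |Aut(cm)|.
.permuteCode <- function(code, perm) {
  M <- .triadCodeMatrix(code)
  P <- M[perm, perm]
  sum(c(P[1, 2], P[2, 1], P[1, 3], P[3, 1], P[2, 3], P[3, 2]) *
        c(1L, 2L, 4L, 8L, 16L, 32L))
}

.PERMS3 <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))

.embeddingCount <- function(motifCode, hostCode) {
  images <- vapply(.PERMS3, function(p) .permuteCode(motifCode, p), 0)
  aut <- sum(images == motifCode)
  hits <- sum(vapply(images, function(im) bitwAnd(im, hostCode) == im, TRUE))
  hits / aut
}

## representative code for each class
.classRepCode <- vapply(.TRIAD_CLASSES, function(cl)
  which(.triadCodeClass == cl)[1L] - 1L, 0L)

#' Count non-induced motif occurrences (subgraph embeddings)
#'
#' Secondary counter for sensitivity checks: counts unordered triples whose
#' induced subgraph *contains* the motif as a (not necessarily induced)
#' subgraph, i.e. subgraph embeddings up to motif automorphism. For classes
#' that are maximal (e.g. `300`) this equals the induced count.
#'
#' @inheritParams countMotif
#' @return numeric count.
#' @export
countMotifEmbeddings <- function(net, motif) {
  motif <- .resolveMotif(motif)
  cen <- censusCounts(triadCensus(net))
  mcode <- .classRepCode[[motif]]
  per_class <- vapply(.TRIAD_CLASSES, function(cl)
    .embeddingCount(mcode, .classRepCode[[cl]]), 0)
  sum(cen * per_class)
}
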