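## Random-graph null models and Monte Carlo testing. Two models, both with
## n and m matched to the observed network: directed Erdos-Renyi G(n,m)
## (every loop-free ordered pair equiprobable) and the fixed-out-degree
## model, in which each node g keeps its out-degree N_g and its set of
## targets is uniform over all C(n-1, N_g) loop-free choices.

#' Random-graph specification
#'
#' Parameter bag for the two null models. For `"erdos_renyi_gnm"` supply
#' `n` and `m`; for `"fixed_outdegree"` supply the per-node out-degree
#' vector (usually taken from the observed network via
#' [outDegreeVector()]).
#'
#' @param model `"erdos_renyi_gnm"` or `"fixed_outdegree"`.
#' @param n node count (G(n,m) only; inferred from `outDegrees` otherwise).
#' @param m edge count (G(n,m) only).
#' @param outDegrees integer vector of per-node out-degrees
#'   (fixed-out-degree only).
#' @return an object of class `"randomGraphSpec"`.
#' @export
randomGraphSpec <- function(model = c("erdos_renyi_gnm", "fixed_outdegree"),
                            n = NULL, m = NULL, outDegrees = NULL) {
  model <- match.arg(model)
  if (model == "erdos_renyi_gnm") {
    stopifnot(!is.null(n), !is.null(m))
    if (m < 0 || m > n * (n - 1))
      stop("m must lie in [0, n(n-1)] for a loop-free directed graph",
           call. = FALSE)
    spec <- list(model = model, n = as.integer(n), m = as.integer(m))
  } else {
    stopifnot(!is.null(outDegrees))
    n <- length(outDegrees)
    if (any(outDegrees < 0) || any(outDegrees > n - 1))
      stop("every out-degree must lie in [0, n-1]", call. = FALSE)
    spec <- list(model = model, n = n, outDegrees = as.integer(outDegrees))
  }
  structure(spec, class = "randomGraphSpec")
}

#' Out-degree vector of a network
#'
#' Convenience accessor used to parameterize the fixed-out-degree model
#' from an observed network.
#'
#' @param net a [GeneNetwork-class].
#' @return named integer vector of out-degrees.
#' @export
outDegreeVector <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  igraph::degree(asIgraph(net), mode = "out")
}

.nodeNames <- function(n) sprintf("v%05d", seq_len(n))

#' Sample a directed Erdos-Renyi G(n,m) graph
#'
#' Draws a directed graph with exactly `m` distinct loop-free edges,
#' uniform over all ordered node pairs. With the same `seed` the same graph
#' is returned.
#'
#' @param n node count.
#' @param m edge count; must not exceed `n(n-1)`.
#' @param seed optional integer seed for reproducibility.
#' @return a [GeneNetwork-class] with `n` vertices (isolated vertices kept,
#'   so the node count matches the observed network by construction).
#' @export
sampleGnm <- function(n, m, seed = NULL) {
  if (m < 0 || m > n * (n - 1))
    stop("m must lie in [0, n(n-1)] for a loop-free directed graph",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnm(n, m, directed = TRUE, loops = FALSE)
  igraph::V(g)$name <- .nodeNames(n)
  .wrapIgraph(g)
}

#' Sample a fixed-out-degree random graph
#'
#' For each node `k` (from 1 to n) a random permutation of
#' `{1, ..., n-1}` is generated by Fisher-Yates shuffle, its first `N_k`
#' elements are selected, and each selected `l` becomes the target `l` (if
#' `l < k`) or `l + 1` (if `l >= k`) -- the index shift that excludes
#' self-loops. The resulting target set of node `k` is uniform over all
#' `choose(n-1, N_k)` admissible sets, and the out-degree vector of every
#' sample equals `outDegrees` exactly.
#'
#' @param outDegrees integer vector `(N_1, ..., N_n)`, each in `[0, n-1]`.
#' @param seed optional integer seed for reproducibility.
#' @return a [GeneNetwork-class] with `n = length(outDegrees)` vertices.
#' @export
sampleFixedOutdegree <- function(outDegrees, seed = NULL) {
  n <- length(outDegrees)
  if (any(outDegrees < 0) || any(outDegrees > n - 1))
    stop("every out-degree must lie in [0, n-1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  outDegrees <- as.integer(outDegrees)
  from <- rep.int(seq_len(n), outDegrees)
  to <- integer(sum(outDegrees))
  pos <- 0L
  for (k in seq_len(n)) {
    Nk <- outDegrees[k]
    if (Nk == 0L) next
    sel <- sample.int(n - 1L, Nk)          # first N_k of a random permutation
    sel <- ifelse(sel < k, sel, sel + 1L)  # index shift skips the loop
    to[(pos + 1L):(pos + Nk)] <- sel
    pos <- pos + Nk
  }
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$name <- .nodeNames(n)
  .wrapIgraph(g)
}

#' Sample from a random-graph specification
#'
#' @param spec a [randomGraphSpec()].
#' @param seed optional integer seed.
#' @return a [GeneNetwork-class].
#' @export
sampleNullGraph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "randomGraphSpec"))
  if (spec$model == "erdos_renyi_gnm")
    sampleGnm(spec$n, spec$m, seed = seed)
  else
    sampleFixedOutdegree(spec$outDegrees, seed = seed)
}

#' Monte Carlo test of a graph statistic against a null model
#'
#' Computes `stat` on the observed network and on `replicates` random
#' graphs from `spec`, and reports the conventional add-one p-value
#' \eqn{(r+1)/(N+1)} where \eqn{r} counts replicates at least as extreme as
#' the observed value (`upper` tail: replicate >= observed; `lower`:
#' replicate <= observed). Replicate statistics are streamed, not retained.
#' Each replicate's seed is drawn up front from `seed`, so replicate `j` is
#' reproducible independently of execution order and the whole result is
#' bit-identical across runs with the same `seed`.
#'
#' @param net observed [GeneNetwork-class].
#' @param stat function taking a [GeneNetwork-class] and returning a single
#'   number; see [motifCountStat()], [coreSizeStat()], [edgeCountStat()].
#' @param spec a [randomGraphSpec()].
#' @param replicates number of null graphs (`>= 1`); 10,000 is the
#'   conventional choice, smaller values suit quick runs.
#' @param tail `"upper"` (over-representation) or `"lower"` (e.g. a core
#'   smaller than random).
#' @param seed integer seed for the replicate stream.
#' @param statName label for reporting.
#' @return a [MonteCarloResult-class].
#' @export
monteCarloTest <- function(net, stat, spec, replicates = 10000,
                           tail = c("upper", "lower"), seed = 1,
                           statName = deparse(substitute(stat))) {
  stopifnot(is(net, "GeneNetwork"), is.function(stat), replicates >= 1)
  tail <- match.arg(tail)
  observed <- stat(net)
  if (!is.numeric(observed) || length(observed) != 1L || !is.finite(observed))
    stop("stat must return a single finite number on the observed network",
         call. = FALSE)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max, replicates)
  nExtreme <- 0L
  for (j in seq_len(replicates)) {
    g <- sampleNullGraph(spec, seed = repSeeds[j])
    s <- tryCatch(stat(g), error = function(e)
      stop("stat failed on replicate ", j, ": ", conditionMessage(e),
           call. = FALSE))
    if (!is.finite(s))
      stop("stat failed on replicate ", j, ": non-finite value",
           call. = FALSE)
    if ((tail == "upper" && s >= observed) ||
        (tail == "lower" && s <= observed))
      nExtreme <- nExtreme + 1L
  }
  new("MonteCarloResult", observed = observed, replicates = replicates,
      nExtreme = nExtreme, pValue = (nExtreme + 1) / (replicates + 1),
      tail = tail, statName = statName)
}

#' Graph statistic factories for Monte Carlo tests
#'
#' `motifCountStat(label)` counts an induced triad class (see
#' [countMotif()]); `coreSizeStat()` measures the size of the network core;
#' `edgeCountStat()` the number of edges (useful as a degenerate check:
#' under the fixed-out-degree model every replicate matches the observed
#' count).
#'
#' @param motif a triad class label or [figureMotifs()] name.
#' @return a function of a [GeneNetwork-class] returning a number.
#' @name graphStats
#' @export
motifCountStat <- function(motif) {
  motif <- .resolveMotif(motif)
  function(net) countMotif(net, motif)
}

#' @rdname graphStats
#' @export
coreSizeStat <- function() function(net) coreSize(extractCore(net))

#' @rdname graphStats
#' @export
edgeCountStat <- function() function(net) numEdges(net)
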