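# Shared fixtures and independent oracles, all built in code.

# toy annotation set: G1 hosts m1 targeting {G1,G2,G3}; G2 hosts m2
# targeting {G1}
toyAnnotations <- function() {
  list(
    ann = data.frame(preMirnaId = c("mir-1", "mir-2"),
                     hostGene = c("G1", "G2"),
                     locationClass = "intronic", orientation = "sense",
                     stringsAsFactors = FALSE),
    matMap = data.frame(matureMirnaId = c("m1", "m2"),
                        preMirnaId = c("mir-1", "mir-2"),
                        stringsAsFactors = FALSE),
    targets = data.frame(matureMirnaId = c("m1", "m1", "m1", "m2"),
                         targetGene = c("G1", "G2", "G3", "G1"),
                         stringsAsFactors = FALSE))
}

# edges {A->B, B->A, B->C, C->D, D->C}: components {A,B} and {C,D}
toyCoreNetwork <- function() {
  geneNetwork(data.frame(source = c("A", "B", "B", "C", "D"),
                         target = c("B", "A", "C", "D", "C"),
                         stringsAsFactors = FALSE))
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# uniform random directed simple graph for property tests
randomNetwork <- function(n, p = 0.1) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  nodes <- sprintf("N%03d", seq_len(n))
  geneNetwork(data.frame(source = nodes[pairs$from[keep]],
                         target = nodes[pairs$to[keep]],
                         stringsAsFactors = FALSE),
              nodes = nodes)
}

# Brute-force SCC oracle: u,v share a component iff u reaches v and v
# reaches u by path search on the edge list (no igraph involved).
reachabilityCoreOracle <- function(net) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  adj <- split(e$target, factor(e$source, levels = nodes))
  reach <- function(s) {
    seen <- stats::setNames(logical(length(nodes)), nodes)
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      nxt <- adj[[v]]
      new <- nxt[!seen[nxt]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
    names(seen)[seen]
  }
  R <- lapply(stats::setNames(nodes, nodes), reach)
  assigned <- character()
  comps <- list()
  for (u in nodes) {
    if (u %in% assigned) next
    comp <- c(u, Filter(function(v) u %in% R[[v]] && v %in% R[[u]],
                        setdiff(R[[u]], u)))
    if (length(comp) >= 2) {
      comps[[length(comps) + 1]] <- sort(comp)
      assigned <- c(assigned, comp)
    }
  }
  sizes <- vapply(comps, length, 1L)
  firsts <- vapply(comps, `[`, "", 1L)
  comps[order(-sizes, firsts)]
}

# direct-summation binomial upper tail (independent of pbinom)
binomSumOracle <- function(k, n, p) {
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# separable two-class toy cohort for classifier-contract tests:
# event class centered at +mu, control at -mu on three genes
separableCohort <- function(nPerClass = 10, mu = 4, genes = c("g1", "g2", "g3")) {
  n <- 2 * nPerClass
  lab <- rep(c("control", "event"), each = nPerClass)
  X <- matrix(rnorm(n * length(genes), sd = 0.3), n, length(genes),
              dimnames = list(NULL, genes))
  X[lab == "event", ] <- X[lab == "event", ] + mu
  X[lab == "control", ] <- X[lab == "control", ] - mu
  d <- data.frame(patientId = sprintf("P%03d", seq_len(n)),
                  recurrenceStatus = ifelse(lab == "event", "recurred",
                                            "recurrence_free"),
                  timeMonths = ifelse(lab == "event", 20, 60),
                  stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(X))
  d$label <- factor(lab, levels = c("control", "event"))
  d
}
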