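test_that("network construction removes loops, merges edges, drops isolates", {
  fx <- toyAnnotations()
  net <- buildNetwork(fx$ann, fx$matMap, fx$targets)
  e <- networkEdges(net)
  expect_setequal(paste(e$source, e$target), c("G1 G2", "G1 G3", "G2 G1"))
  expect_equal(numNodes(net), 3)
  expect_equal(removedLoops(net)$gene, "G1")
  expect_equal(removedLoops(net)$mirnas, "m1")

  # host whose miRNA targets only itself vanishes entirely
  ann <- data.frame(preMirnaId = "mir-h", hostGene = "H",
                    locationClass = "intronic", orientation = "sense")
  mm <- data.frame(matureMirnaId = "mh", preMirnaId = "mir-h")
  tg <- data.frame(matureMirnaId = "mh", targetGene = "H")
  expect_warning(net0 <- buildNetwork(ann, mm, tg), "self-loops")
  expect_equal(numNodes(net0), 0)
  expect_equal(removedLoops(net0)$gene, "H")

  # empty target set -> empty network with warning
  expect_warning(
    netE <- buildNetwork(fx$ann, fx$matMap,
                         fx$targets[0, , drop = FALSE]),
    "empty network")
  expect_equal(numNodes(netE), 0)
})

test_that("parallel edges merge with miRNA labels unioned", {
  ann <- data.frame(preMirnaId = c("mir-1", "mir-2"), hostGene = "A",
                    locationClass = "intronic", orientation = "sense")
  mm <- data.frame(matureMirnaId = c("m1", "m2"),
                   preMirnaId = c("mir-1", "mir-2"))
  tg <- data.frame(matureMirnaId = c("m1", "m2"), targetGene = "B")
  net <- buildNetwork(ann, mm, tg)
  expect_equal(numEdges(net), 1)
  expect_equal(networkEdges(net)$mirnas, "m1;m2")
})

test_that("summary counts satisfy the role identities on the toy network", {
  fx <- toyAnnotations()
  net <- buildNetwork(fx$ann, fx$matMap, fx$targets)
  s <- summarizeNetwork(net, fx$ann, fx$matMap, fx$targets)
  expect_equal(s$totalN, 3)
  expect_equal(s$bothdirN, 2)   # G1, G2
  expect_equal(s$outN, 0)
  expect_equal(s$inN, 1)        # G3
  expect_equal(s$totalE, 3)
  expect_equal(s$matMi, 2)
  expect_equal(s$preMi, 2)
  expect_equal(s$hostGenes, 2)
  expect_equal(s$totalN, s$bothdirN + s$outN + s$inN)
  expect_equal(s$hostGenes, s$bothdirN + s$outN)
})

test_that("summary identities hold across random synthetic inputs", {
  for (seed in 1:5) {
    sim <- simulateAnnotations(nGenes = 60, nMirnas = 25,
                               plantedCycles = list(sprintf("G%04d", 1:3)),
                               seed = seed)
    targets <- intersectValidatedTargets(sim$targetsA, sim$targetsB)
    net <- buildNetwork(sim$hosts, sim$matureMap, targets)
    s <- summarizeNetwork(net, sim$hosts, sim$matureMap, targets)
    expect_equal(s$totalN, s$bothdirN + s$outN + s$inN)
    expect_equal(s$hostGenes, s$bothdirN + s$outN)
    # merged edge count cannot exceed raw pair count
    expect_lte(s$totalE, nrow(targets) * 2)
  }
})

test_that("in-degree ranking sorts by degree then gene id, histogram conserves edges", {
  fx <- toyAnnotations()
  net <- buildNetwork(fx$ann, fx$matMap, fx$targets)
  r <- inDegreeRanking(net, 3)
  expect_equal(r$gene, c("G1", "G2", "G3"))   # all tie at 1, lexicographic
  expect_equal(r$inDegree, c(1, 1, 1))
  # k beyond node count truncates
  expect_equal(nrow(inDegreeRanking(net, 99)), 3)

  # star: 5 edges into X
  star <- geneNetwork(data.frame(source = paste0("S", 1:5), target = "X"))
  expect_equal(inDegreeRanking(star, 1),
               data.frame(gene = "X", inDegree = 5))
  h <- inDegreeHistogram(star)
  expect_equal(sum(h$inDegree * h$count), numEdges(star))
})

test_that("IS-network edges are a subset of F-network edges", {
  sim <- simulateAnnotations(nGenes = 80, nMirnas = 40,
                             plantedCycles = list(sprintf("G%04d", 1:4)),
                             seed = 7)
  targets <- intersectValidatedTargets(sim$targetsA, sim$targetsB)
  fnet <- buildNetwork(sim$hosts, sim$matureMap, targets)
  isnet <- buildNetwork(filterMirnaClass(sim$hosts, "intronic_sense"),
                        sim$matureMap, targets)
  key <- function(net) { e <- networkEdges(net); paste(e$source, e$target) }
  expect_true(all(key(isnet) %in% key(fnet)))
})

test_that("edge-list serialization round-trips and simplifies on load", {
  fx <- toyAnnotations()
  net <- buildNetwork(fx$ann, fx$matMap, fx$targets)
  path <- tempfile(fileext = ".tsv")
  writeEdgeList(net, path)
  back <- readEdgeList(path)
  expect_equal(networkEdges(back), networkEdges(net))
  expect_setequal(networkNodes(back), networkNodes(net))

  # a raw list with a loop and a duplicate is simplified with a message
  raw <- data.frame(source_gene = c("A", "A", "A", "B"),
                    target_gene = c("A", "B", "B", "C"),
                    mirna_ids = c("x", "m1", "m2", "m3"))
  expect_message(net2 <- readEdgeList(writeTsv(raw)), "simplified")
  expect_equal(numEdges(net2), 2)
  e <- networkEdges(net2)
  expect_equal(e$mirnas[e$source == "A"], "m1;m2")
  expect_equal(removedLoops(net2)$gene, "A")
})
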