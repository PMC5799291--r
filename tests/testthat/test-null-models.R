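test_that("G(n,m) sampler honors edge count, capacity and determinism", {
  # m maximal -> the complete loop-free digraph, deterministically
  full <- sampleGnm(3, 6, seed = 1)
  expect_equal(numEdges(full), 6)
  expect_equal(numNodes(full), 3)
  expect_error(sampleGnm(3, 7), "n\\(n-1\\)")

  # same seed -> identical edge set; different seed -> same size
  a <- networkEdges(sampleGnm(10, 20, seed = 42))
  b <- networkEdges(sampleGnm(10, 20, seed = 42))
  expect_identical(a, b)
  for (s in 1:25) {
    g <- sampleGnm(10, 20, seed = s)
    expect_equal(numEdges(g), 20)
    e <- networkEdges(g)
    expect_true(all(e$source != e$target))
    expect_false(anyDuplicated(paste(e$source, e$target)) > 0)
  }
})

test_that("fixed-out-degree sampler preserves degrees exactly, no loops/dups", {
  # forced cases
  dyad <- sampleFixedOutdegree(c(1, 1), seed = 9)
  e <- networkEdges(dyad)
  expect_setequal(paste(e$source, e$target),
                  c("v00001 v00002", "v00002 v00001"))
  expect_equal(numEdges(sampleFixedOutdegree(c(2, 2, 2), seed = 1)), 6)
  expect_error(sampleFixedOutdegree(c(3, 0, 0)), "n-1")

  set.seed(77)
  degs <- sample(0:7, 12, replace = TRUE)
  for (s in 1:200) {
    g <- sampleFixedOutdegree(degs, seed = s)
    expect_equal(unname(outDegreeVector(g)), degs)
    e <- networkEdges(g)
    expect_true(all(e$source != e$target))
    expect_false(anyDuplicated(paste(e$source, e$target)) > 0)
  }
})

test_that("fixed-out-degree target choice is uniform (n=3, N=(1,0,0))", {
  # single out-edge from node 1: exact law P(target = 2) = 1/2
  hits2 <- 0L
  n <- 4000
  set.seed(1234)
  seeds <- sample.int(1e7, n)
  for (s in seeds) {
    e <- networkEdges(sampleFixedOutdegree(c(1, 0, 0), seed = s))
    if (e$target == "v00002") hits2 <- hits2 + 1L
  }
  p <- suppressWarnings(
    stats::chisq.test(c(hits2, n - hits2), p = c(0.5, 0.5)))$p.value
  expect_gt(p, 0.01)
})

test_that("gnm edge-set inclusion is uniform on a small case", {
  # n=4, m=3: all C(12,3)=220 graphs equiprobable; chi-square over draws
  set.seed(55)
  draws <- 20000
  seeds <- sample.int(1e8, draws)
  keys <- vapply(seeds, function(s) {
    e <- networkEdges(sampleGnm(4, 3, seed = s))
    paste(sort(paste(e$source, e$target)), collapse = "|")
  }, "")
  tab <- table(keys)
  expect_equal(length(tab), 220)   # every graph appears
  p <- suppressWarnings(
    stats::chisq.test(as.vector(tab), p = rep(1 / 220, 220)))$p.value
  expect_gt(p, 0.01)
})

test_that("Monte Carlo p-value uses the add-one estimator with its floor", {
  net <- toyCoreNetwork()
  spec <- randomGraphSpec("fixed_outdegree",
                          outDegrees = unname(outDegreeVector(net)))
  # edge count under fixed out-degrees: every replicate equals observed
  mc <- monteCarloTest(net, edgeCountStat(), spec, replicates = 200,
                       tail = "upper", seed = 3)
  expect_equal(pValue(mc), 1)
  mcl <- monteCarloTest(net, edgeCountStat(), spec, replicates = 200,
                        tail = "lower", seed = 3)
  expect_equal(pValue(mcl), 1)

  # observed network has 2 mutual dyads; replicates with these out-degrees
  # essentially never do, so the mutual-containing count is extreme
  mutual <- function(g) countMotif(g, "102") + countMotif(g, "201") +
    countMotif(g, "300") + countMotif(g, "111D") + countMotif(g, "111U") +
    countMotif(g, "120D") + countMotif(g, "120U") + countMotif(g, "120C") +
    countMotif(g, "210")
  mc2 <- monteCarloTest(net, mutual, spec, replicates = 400,
                        tail = "upper", seed = 5)
  expect_gte(pValue(mc2), 1 / 401)
  expect_lte(mc2@nExtreme, mc2@replicates)

  # determinism: same seed, bit-identical result
  mc3 <- monteCarloTest(net, mutual, spec, replicates = 100, seed = 8)
  mc4 <- monteCarloTest(net, mutual, spec, replicates = 100, seed = 8)
  expect_identical(mc3, mc4)

  # stat failure aborts with the replicate index
  bad <- local({
    calls <- 0L
    function(g) {
      calls <<- calls + 1L
      if (calls == 4L) stop("boom")   # observed + 3 replicates
      numEdges(g)
    }
  })
  expect_error(
    monteCarloTest(net, bad, spec, replicates = 10, seed = 1),
    "replicate 3")
})

test_that("random-graph spec validates its invariants", {
  expect_error(randomGraphSpec("erdos_renyi_gnm", n = 3, m = 7), "n\\(n-1\\)")
  expect_error(randomGraphSpec("fixed_outdegree", outDegrees = c(5, 1, 1)),
               "out-degree")
  spec <- randomGraphSpec("erdos_renyi_gnm", n = 6, m = 10)
  expect_equal(numEdges(sampleNullGraph(spec, seed = 2)), 10)
})
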