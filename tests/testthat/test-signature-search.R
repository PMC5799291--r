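test_that("dichotomization assigns classes and excludes the grey zone", {
  scheme <- colorectalScheme()   # 36 / 48 / 1 months
  cohort <- data.frame(
    patientId = paste0("P", 1:6),
    recurrenceStatus = c("recurred", "recurrence_free", "recurrence_free",
                         "recurred", "unknown", "recurred"),
    timeMonths = c(20, 50, 40, 0.5, 60, 40),
    g1 = rnorm(6), stringsAsFactors = FALSE)
  lab <- dichotomize(cohort, scheme)
  expect_equal(nrow(lab), 2)
  expect_equal(as.character(lab$label[lab$patientId == "P1"]), "event")
  expect_equal(as.character(lab$label[lab$patientId == "P2"]), "control")
  ex <- attr(lab, "exclusions")
  expect_equal(ex$earlyEvent, 1)   # recurrence at 0.5 months
  expect_equal(ex$unknown, 1)
  expect_equal(ex$grey, 2)         # 40-month follow-up, 40-month recurrence
  # empty class -> error naming it
  noCtl <- cohort[cohort$recurrenceStatus == "recurred", ]
  expect_error(dichotomize(noCtl, scheme), "control")
  # scheme invariants
  expect_error(dichotomizationScheme(48, 36), ">=")
})

test_that("fitted signature scales training columns to mean 0 / sd 1 and
           classifies R >= 0 as high risk", {
  set.seed(61)
  d <- separableCohort(12)
  sig <- fitSignature(d, c("g1", "g2", "g3"))
  sc <- signatureScaling(sig)
  Xs <- scale(as.matrix(d[, sc$gene]), center = sc$mean, scale = sc$sd)
  expect_equal(unname(colMeans(Xs)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 3), tolerance = 1e-12)

  ev <- evaluateSignature(sig, d, "training")
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auc, 1)

  # boundary: a patient with exactly R = 0 goes to the high-risk group
  scores <- riskScore(sig, d)
  expect_equal(as.character(classifyRisk(sig, d))[scores >= 0],
               rep("high", sum(scores >= 0)))
  w <- signatureWeights(sig)
  # construct an expression point with R exactly 0 by solving along g1
  x0 <- d[1, , drop = FALSE]
  e0 <- sig@scaleMeans
  x0[, c("g1", "g2", "g3")] <- e0   # scaled coords all 0 -> R = -offset
  x0$g1 <- e0[1] + (sig@offset - sum(0 * w[-1])) / w[1] * sig@scaleSds[1]
  expect_equal(riskScore(sig, x0), 0, tolerance = 1e-9)
  expect_equal(as.character(classifyRisk(sig, x0)), "high")

  # zero-variance gene -> error
  d2 <- d; d2$g1 <- 1
  expect_error(fitSignature(d2, c("g1", "g2")), "zero training variance")
  expect_error(fitSignature(d, c("g1", "missing")), "missing")
})

test_that("AUC uses rank comparison with tie correction", {
  lab <- factor(rep(c("control", "event"), each = 10),
                levels = c("control", "event"))
  d <- data.frame(label = lab, g = c(rnorm(10), rnorm(10) + 5))
  sig <- fitSignature(d, "g")
  # all-tied scores give AUC 0.5
  dT <- d; dT$g <- 1  # constant column in evaluation only
  sigC <- new("LinearSignature", genes = "g", scaleMeans = 0, scaleSds = 1,
              weights = 0, offset = 0)   # score identically 0
  expect_equal(evaluateSignature(sigC, d)$auc, 0.5)
  # AUC invariant under strictly increasing transform of the score
  s1 <- riskScore(sig, d)
  r1 <- mircore:::.rankAuc(s1, d$label == "event")
  r2 <- mircore:::.rankAuc(exp(s1 / 2), d$label == "event")
  expect_equal(r1, r2)
  # null scores: AUC near 0.5 on a large sample
  set.seed(71)
  n <- 2000
  auc0 <- mircore:::.rankAuc(rnorm(n), sample(c(TRUE, FALSE), n, TRUE))
  expect_gt(auc0, 0.45); expect_lt(auc0, 0.55)
})

test_that("class weights keep the boundary stable when duplicating a class", {
  set.seed(81)
  d <- separableCohort(10)
  sig1 <- fitSignature(d, c("g1", "g2", "g3"))
  # duplicate every event patient once: weighting is inversely proportional
  # to class size, so the decision boundary stays put on a separable toy
  d2 <- rbind(d, d[d$label == "event", ])
  sig2 <- fitSignature(d2, c("g1", "g2", "g3"))
  expect_equal(as.character(classifyRisk(sig2, d)),
               as.character(classifyRisk(sig1, d)))
})

test_that("exhaustive search filters by thresholds and ranks by mean AUC", {
  set.seed(91)
  sim <- simulateCohorts(nPerCohort = c(120, 80, 80, 100),
                         genes = sprintf("SG%02d", 1:6),
                         plantedSignature = c("SG01", "SG02", "SG03"),
                         classShifts = c(1.5, -1.5, 1.5), seed = 14)
  scheme <- colorectalScheme()
  train <- dichotomize(sim$training, scheme)
  filts <- lapply(sim$filtration, dichotomize, scheme = scheme)
  res <- exhaustiveSearch(train, filts, sprintf("SG%02d", 1:6), setSize = 3)
  expect_true(nrow(res) >= 1)
  expect_equal(res$genes[1], "SG01;SG02;SG03")
  expect_true(all(diff(res$meanAuc) <= 0))
  expect_true(all(res$trainSensitivity >= 0.6 & res$trainSpecificity >= 0.6))
  sigs <- attr(res, "signatures")
  expect_equal(length(sigs), nrow(res))
  expect_equal(paste(signatureGenes(sigs[[1]]), collapse = ";"),
               res$genes[1])

  # universe of exactly setSize genes -> a single candidate
  res1 <- exhaustiveSearch(train, filts, c("SG01", "SG02", "SG03"),
                           setSize = 3)
  expect_lte(nrow(res1), 1)
  expect_error(exhaustiveSearch(train, filts, character(), 3), "empty")

  # result invariant to universe enumeration order
  res2 <- exhaustiveSearch(train, filts, sprintf("SG%02d", c(4, 2, 6, 1, 3, 5)),
                           setSize = 3)
  expect_equal(res2$genes, res$genes)
})

test_that("scaling never leaks from filtration/validation cohorts", {
  set.seed(101)
  sim <- simulateCohorts(genes = sprintf("SG%02d", 1:4),
                         plantedSignature = c("SG01", "SG02", "SG03"),
                         classShifts = c(1.5, 1.5, -1.5), seed = 3)
  scheme <- colorectalScheme()
  train <- dichotomize(sim$training, scheme)
  sig <- fitSignature(train, c("SG01", "SG02", "SG03"))
  val <- dichotomize(sim$validation, scheme)
  ev1 <- evaluateSignature(sig, val)
  # perturbing validation data must not change the scaler (it is frozen in
  # the signature), only the scores of the perturbed patients
  val2 <- val; val2[1, c("SG01", "SG02", "SG03")] <- 100
  sc1 <- riskScore(sig, val); sc2 <- riskScore(sig, val2)
  expect_equal(sc1[-1], sc2[-1])
  expect_identical(signatureScaling(sig), signatureScaling(sig))
})

test_that("log-rank test and KM curves behave on canonical cases", {
  # identical groups -> p = 1
  t0 <- c(5, 10, 15, 20, 25, 30)
  ev <- c(1, 0, 1, 0, 1, 0)
  km <- kmLogrank(c(t0, t0), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(km$pValue, 1, tolerance = 1e-12)
  expect_true(all(c("group", "time", "survival", "nRisk") %in%
                    names(km$curves)))

  # strongly separated exponential survival -> p < 0.001
  set.seed(111)
  tA <- rexp(200, rate = 1); tB <- rexp(200, rate = 5)
  km2 <- kmLogrank(c(tA, tB), rep(1, 400), rep(c("lo", "hi"), each = 200))
  expect_lt(km2$pValue, 0.001)

  # textbook single-event worked example: groups {2+}, {1}; the only event
  # at t=1 with 2 at risk -> observed-expected = 1 - 1/2, var = 1/4,
  # chi-square = 1, p = 0.3173
  km3 <- kmLogrank(c(2, 1), c(0, 1), c("a", "b"))
  expect_equal(km3$pValue, 1 - pchisq(1, 1), tolerance = 1e-8)

  expect_error(kmLogrank(t0, ev, rep("a", 6)), "group")
})

test_that("cross-validation is stratified, seeded, and exact on separable data", {
  set.seed(121)
  d <- separableCohort(15)
  cv <- crossValidate(d, c("g1", "g2", "g3"), folds = 3, seed = 5)
  expect_equal(nrow(cv), 3)
  expect_equal(cv$sensitivity, rep(1, 3))
  expect_equal(cv$specificity, rep(1, 3))
  expect_equal(cv$auc, rep(1, 3))
  expect_identical(cv, crossValidate(d, c("g1", "g2", "g3"), folds = 3,
                                     seed = 5))
  # leave-one-out on a 10-patient toy -> 10 single-patient evaluations
  d10 <- separableCohort(5)
  cv10 <- crossValidate(d10, c("g1", "g2"), folds = 10)
  expect_equal(nrow(cv10), 10)
  # class smaller than folds (and not LOO) -> error
  expect_error(crossValidate(d10, "g1", folds = 7), "smaller")
})
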