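## Synthetic-data generators with planted ground truth. Every generator is
## a pure function of its parameters and seed, and writes the same table
## shapes the readers consume, so the full pipeline is testable without any
## database snapshot or cohort download.

#' Simulate annotation and target tables with planted core cycles
#'
#' Generates a gene universe, plants each requested cycle by hosting a
#' miRNA in every cycle gene that targets the next gene (cyclically), and
#' adds background host-target records that respect a random topological
#' order among non-core genes -- so no unplanned nontrivial strongly
#' connected component can arise and the planted cycles are exactly the
#' network core. Both target tables contain every emitted interaction
#' (plus, in table A only, a few extras that the intersection removes), so
#' [intersectValidatedTargets()] preserves the construction.
#'
#' @param nGenes size of the gene universe (genes `G0001`...).
#' @param nMirnas number of background miRNAs.
#' @param plantedCycles list of character vectors of distinct genes from
#'   the universe; overlapping cycles are an error (ground truth must stay
#'   unambiguous).
#' @param backgroundEdgeRate mean number of extra targets per background
#'   miRNA beyond the first (Poisson).
#' @param seed integer seed.
#' @return list with `hosts`, `matureMap`, `targetsA`, `targetsB` (the four
#'   annotation data.frames) and `truth` (planted components and the seed).
#' @export
simulateAnnotations <- function(nGenes = 200, nMirnas = 60,
                                plantedCycles = list(),
                                backgroundEdgeRate = 1.5, seed = 1) {
  stopifnot(nGenes >= 3, backgroundEdgeRate >= 0)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  core <- unlist(plantedCycles, use.names = FALSE)
  if (anyDuplicated(core))
    stop("planted cycles must not share genes", call. = FALSE)
  if (!all(core %in% genes))
    stop("planted cycle genes must belong to the generated universe",
         call. = FALSE)
  hosts <- list(); map <- list(); ints <- list()
  emit <- function(pre, host, target, loc = "intronic", ori = "sense") {
    mat <- paste0(tolower(pre), "-5p")
    hosts[[length(hosts) + 1L]] <<- data.frame(
      pre_mirna_id = pre, host_gene = host, location_class = loc,
      orientation = ori, stringsAsFactors = FALSE)
    map[[length(map) + 1L]] <<- data.frame(
      mature_mirna_id = mat, pre_mirna_id = pre, stringsAsFactors = FALSE)
    ints[[length(ints) + 1L]] <<- data.frame(
      mature_mirna_id = mat, target_gene = target, stringsAsFactors = FALSE)
  }
  ## planted cycles: gene i hosts a miRNA targeting gene i+1 (cyclically)
  for (ci in seq_along(plantedCycles)) {
    cyc <- plantedCycles[[ci]]
    for (i in seq_along(cyc))
      emit(sprintf("mir-c%d-%d", ci, i), cyc[i],
           cyc[if (i == length(cyc)) 1L else i + 1L])
  }
  ## background: topological order over non-core genes, core genes last, so
  ## background arcs (strictly forward) can never close a cycle
  noncore <- setdiff(genes, core)
  topo <- c(sample(noncore), core)
  loc_pool <- c("intronic", "intronic", "intronic", "exonic")
  ori_pool <- c("sense", "sense", "sense", "antisense")
  for (b in seq_len(nMirnas)) {
    hpos <- sample.int(max(length(noncore) - 1L, 1L), 1L)
    host <- topo[hpos]
    later <- topo[(hpos + 1L):length(topo)]
    k <- min(1L + rpois(1L, backgroundEdgeRate), length(later))
    targets <- sample(later, k)
    pre <- sprintf("mir-b%d", b)
    loc <- sample(loc_pool, 1L); ori <- sample(ori_pool, 1L)
    for (tg in targets) emit(pre, host, tg, loc, ori)
  }
  hosts <- unique(do.call(rbind, hosts))
  map <- unique(do.call(rbind, map))
  ints <- unique(do.call(rbind, ints))
  targetsA <- ints; targetsA$source <- "db_a"
  targetsB <- ints; targetsB$source <- "db_b"
  ## extras in A only: forward arcs among non-core genes, dropped by the
  ## intersection (and acyclic anyway)
  if (length(noncore) >= 4L) {
    extra <- data.frame(
      mature_mirna_id = paste0("mir-x", 1:2, "-5p"),
      target_gene = topo[c(3L, 4L)],
      source = "db_a", stringsAsFactors = FALSE)
    targetsA <- rbind(targetsA, extra)
  }
  ## normalize to the reader's output shape
  shape <- function(df) data.frame(
    matureMirnaId = tolower(df$mature_mirna_id),
    targetGene = toupper(df$target_gene),
    source = df$source, stringsAsFactors = FALSE)
  list(
    hosts = data.frame(preMirnaId = tolower(hosts$pre_mirna_id),
                       hostGene = toupper(hosts$host_gene),
                       locationClass = hosts$location_class,
                       orientation = hosts$orientation,
                       stringsAsFactors = FALSE),
    matureMap = data.frame(matureMirnaId = tolower(map$mature_mirna_id),
                           preMirnaId = tolower(map$pre_mirna_id),
                           stringsAsFactors = FALSE),
    targetsA = shape(targetsA),
    targetsB = shape(targetsB),
    truth = list(plantedCoreComponents = lapply(plantedCycles, sort),
                 genes = genes, seed = seed))
}

#' Simulate an RPKM-like expression matrix with planted genes
#'
#' Background transcripts are log-normal with heterogeneous locations
#' (`mu_t ~ Normal(locationMean, locationSd)`, per-transcript scale
#' `sigma_t ~ Uniform(scaleRange)`). Planted genes draw their location from
#' the same distribution shifted up by `locationShift` (log units) and
#' their scale multiplied by `dispersionFactor`, so a zero shift with
#' factor 1 makes them exchangeable with the background (the null
#' calibration case).
#'
#' @param nTranscripts,nSamples matrix dimensions.
#' @param plantedGenes character ids for the planted transcripts (they are
#'   added under these names; remaining transcripts are `T00001`...).
#' @param locationShift log-units shift of planted locations (>= 2 gives a
#'   strong high-expression set).
#' @param dispersionFactor multiplier in (0, 1] for planted scales.
#' @param locationMean,locationSd,scaleRange background hyperparameters.
#' @param seed integer seed.
#' @return list with `matrix` (transcripts x samples) and `truth`.
#' @export
simulateExpression <- function(nTranscripts = 5000, nSamples = 50,
                               plantedGenes = character(),
                               locationShift = 2, dispersionFactor = 0.5,
                               locationMean = 1, locationSd = 0.8,
                               scaleRange = c(0.4, 1.0), seed = 1) {
  stopifnot(dispersionFactor > 0, dispersionFactor <= 1,
            length(plantedGenes) < nTranscripts)
  set.seed(seed)
  nBg <- nTranscripts - length(plantedGenes)
  ids <- c(plantedGenes, sprintf("T%05d", seq_len(nBg)))
  mu <- rnorm(nTranscripts, locationMean, locationSd)
  sigma <- runif(nTranscripts, scaleRange[1], scaleRange[2])
  planted <- seq_along(plantedGenes)
  mu[planted] <- mu[planted] + locationShift
  sigma[planted] <- sigma[planted] * dispersionFactor
  m <- exp(mu + sigma * matrix(rnorm(nTranscripts * nSamples),
                               nTranscripts, nSamples))
  rownames(m) <- ids
  colnames(m) <- sprintf("S%03d", seq_len(nSamples))
  list(matrix = m,
       truth = list(plantedGenes = plantedGenes,
                    locationShift = locationShift,
                    dispersionFactor = dispersionFactor, seed = seed))
}

.oneCohort <- function(n, genes, plantedSignature, classShifts,
                       greyFraction, eventRate, scheme, unknownFraction,
                       prefix) {
  status <- character(n); t <- numeric(n)
  u <- runif(n)
  isUnknown <- u < unknownFraction
  isGrey <- !isUnknown & u < unknownFraction + greyFraction
  latentEvent <- runif(n) < eventRate
  X <- matrix(rnorm(n * length(genes)), n, length(genes),
              dimnames = list(NULL, genes))
  if (length(plantedSignature)) {
    cols <- match(plantedSignature, genes)
    X[latentEvent, cols] <- X[latentEvent, cols] +
      rep(classShifts, each = sum(latentEvent))
  }
  hz <- scheme$eventHorizonMonths; cmin <- scheme$controlMinFollowupMonths
  me <- scheme$minEventMonths
  for (i in seq_len(n)) {
    if (isUnknown[i]) {
      status[i] <- "unknown"; t[i] <- runif(1, 0, cmin)
    } else if (isGrey[i]) {
      status[i] <- "recurrence_free"; t[i] <- runif(1, hz, cmin - 1e-6)
    } else if (latentEvent[i]) {
      ## event time: exponential hazard (mean 18 mo) truncated to (me, hz]
      status[i] <- "recurred"
      lam <- 1 / 18
      u <- runif(1)
      t[i] <- me - log(1 - u * (1 - exp(-lam * (hz - me)))) / lam
    } else {
      status[i] <- "recurrence_free"; t[i] <- cmin + rexp(1, 1 / 24)
    }
  }
  cohort <- data.frame(patientId = sprintf("%s%04d", prefix, seq_len(n)),
                       recurrenceStatus = status, timeMonths = t,
                       stringsAsFactors = FALSE)
  cbind(cohort, as.data.frame(X))
}

#' Simulate training / filtration / validation cohorts
#'
#' Generates four cohorts with the structure the signature search expects:
#' per-patient log-scale expression for `genes` (standard normal noise),
#' with the planted-signature genes shifted between classes by
#' `classShifts` (signs may differ, mirroring oppositely directed
#' expression changes); recurrence status and event/follow-up times are
#' drawn so that [dichotomize()] under `scheme` reproduces the intended
#' classes, with a `greyFraction` of patients emitted into the grey zone.
#'
#' @param nPerCohort integer vector of length 4: training, two filtration,
#'   validation cohort sizes.
#' @param genes gene universe for the expression columns.
#' @param plantedSignature subset of `genes` carrying signal.
#' @param classShifts per-planted-gene mean shift (in SD units) of the
#'   event class; length must match `plantedSignature`.
#' @param greyFraction fraction of patients emitted into the grey zone.
#' @param eventRate event-class probability among non-grey patients.
#' @param scheme the [dichotomizationScheme()] the cohorts are built for.
#' @param unknownFraction fraction with unknown recurrence status.
#' @param seed integer seed.
#' @return list with `training`, `filtration` (list of 2), `validation`
#'   and `truth`.
#' @export
simulateCohorts <- function(nPerCohort = c(120, 80, 80, 100),
                            genes = sprintf("SG%02d", 1:8),
                            plantedSignature = character(),
                            classShifts = numeric(),
                            greyFraction = 0.15, eventRate = 0.4,
                            scheme = colorectalScheme(),
                            unknownFraction = 0, seed = 1) {
  stopifnot(length(nPerCohort) == 4, greyFraction >= 0, greyFraction < 1,
            length(classShifts) == length(plantedSignature),
            all(plantedSignature %in% genes))
  set.seed(seed)
  mk <- function(n, prefix) .oneCohort(n, genes, plantedSignature,
                                       classShifts, greyFraction, eventRate,
                                       scheme, unknownFraction, prefix)
  list(training = mk(nPerCohort[1], "TR"),
       filtration = list(mk(nPerCohort[2], "F1"), mk(nPerCohort[3], "F2")),
       validation = mk(nPerCohort[4], "VA"),
       truth = list(plantedSignature = sort(plantedSignature),
                    classShifts = classShifts, greyFraction = greyFraction,
                    eventRate = eventRate, seed = seed))
}

#' Write simulated inputs to a directory
#'
#' Writes the tables produced by the simulators in the TSV formats consumed
#' by the readers, plus the ground truth as JSON.
#'
#' @param sim output of [simulateAnnotations()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeSimulatedAnnotations <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(hosts = file.path(dir, "hosts.tsv"),
             matureMap = file.path(dir, "mature_map.tsv"),
             targetsA = file.path(dir, "targets_a.tsv"),
             targetsB = file.path(dir, "targets_b.tsv"),
             truth = file.path(dir, "truth.json"))
  wr <- function(df, path, names_out) {
    names(df) <- names_out
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(sim$hosts, paths[["hosts"]],
     c("pre_mirna_id", "host_gene", "location_class", "orientation"))
  wr(sim$matureMap, paths[["matureMap"]], c("mature_mirna_id", "pre_mirna_id"))
  wr(sim$targetsA[, 1:2], paths[["targetsA"]],
     c("mature_mirna_id", "target_gene"))
  wr(sim$targetsB[, 1:2], paths[["targetsB"]],
     c("mature_mirna_id", "target_gene"))
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
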