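## Run configuration and stage orchestration. One structured YAML document
## per run; reports are written as JSON/TSV into the output directory and
## listed in a checksum manifest, so reruns with the same config and seed
## are bit-identical.

.CONFIG_DEFAULTS <- list(
  mirnaClass = "all_intragenic",
  nullModel = list(model = "fixed_outdegree", replicates = 10000,
                   seed = 1, tail = "upper", motif = "FIG2C"),
  expression = list(statistic = "median", stratum = 0.25,
                    direction = "top"),
  signature = list(setSize = 3, trainThreshold = 0.6,
                   filtrationThreshold = 0.5, cost = 1,
                   scheme = list(eventHorizonMonths = 36,
                                 controlMinFollowupMonths = 48,
                                 minEventMonths = 1)),
  outputDir = "mircore-out")

.KNOWN_KEYS <- list(
  top = c("inputs", "mirnaClass", "nullModel", "expression", "signature",
          "outputDir"),
  inputs = c("hosts", "matureMap", "targetsA", "targetsB",
             "expressionMatrix", "coreGenes", "training", "filtration",
             "validation"),
  nullModel = c("model", "replicates", "seed", "tail", "motif"),
  expression = c("statistic", "stratum", "direction"),
  signature = c("setSize", "trainThreshold", "filtrationThreshold", "cost",
                "scheme"),
  scheme = c("eventHorizonMonths", "controlMinFollowupMonths",
             "minEventMonths"))

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key ", sQuote(unknown[1L]), " in ", where,
         call. = FALSE)
}

#' Read and validate a run configuration
#'
#' `readRunConfig()` parses a YAML document; `validateRunConfig()` checks
#' the keys, fills defaults (null model: fixed out-degree, 10,000
#' replicates, seed 1; signature thresholds 0.6 / 0.5, set size 3) and
#' verifies constraints. Unknown keys and constraint violations are errors
#' naming the offending field.
#'
#' @param path path to a YAML config file.
#' @param cfg a config list (as parsed from YAML).
#' @return the fully resolved config list (class `"mircoreConfig"`).
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @export
validateRunConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  .checkKeys(cfg, .KNOWN_KEYS$top, "config")
  if (!is.null(cfg$inputs)) .checkKeys(cfg$inputs, .KNOWN_KEYS$inputs,
                                       "inputs")
  for (blk in c("nullModel", "expression", "signature"))
    if (!is.null(cfg[[blk]])) .checkKeys(cfg[[blk]], .KNOWN_KEYS[[blk]], blk)
  if (!is.null(cfg$signature$scheme))
    .checkKeys(cfg$signature$scheme, .KNOWN_KEYS$scheme, "signature$scheme")
  out <- .CONFIG_DEFAULTS
  out$inputs <- cfg$inputs
  for (blk in c("nullModel", "expression", "signature"))
    if (!is.null(cfg[[blk]]))
      out[[blk]] <- modifyList(out[[blk]], cfg[[blk]])
  for (k in c("mirnaClass", "outputDir"))
    if (!is.null(cfg[[k]])) out[[k]] <- cfg[[k]]
  chk <- function(ok, field, value)
    if (!ok) stop("config constraint violated: ", field, " = ", value,
                  call. = FALSE)
  chk(out$mirnaClass %in% c("all_intragenic", "intronic_sense"),
      "mirnaClass", out$mirnaClass)
  chk(out$nullModel$model %in% c("erdos_renyi_gnm", "fixed_outdegree"),
      "nullModel$model", out$nullModel$model)
  chk(out$nullModel$replicates >= 1, "nullModel$replicates",
      out$nullModel$replicates)
  chk(out$nullModel$tail %in% c("upper", "lower"), "nullModel$tail",
      out$nullModel$tail)
  chk(out$expression$stratum > 0 && out$expression$stratum < 1,
      "expression$stratum", out$expression$stratum)
  chk(out$expression$direction %in% c("top", "bottom"),
      "expression$direction", out$expression$direction)
  chk(out$signature$setSize >= 1, "signature$setSize", out$signature$setSize)
  for (f in c("trainThreshold", "filtrationThreshold"))
    chk(out$signature[[f]] > 0 && out$signature[[f]] < 1,
        paste0("signature$", f), out$signature[[f]])
  structure(out, class = c("mircoreConfig", "list"))
}

.stageError <- function(stage, need) {
  stop("dependency error: stage '", stage, "' requires ", need, call. = FALSE)
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order
#' (`build` -> `core` -> `census` -> `mc-test`; `expr-rank`;
#' `signature-search`), writing each stage's report into the configured
#' output directory. Downstream stages re-load the edge-list artifact, so a
#' stage requested without its upstream artifact present is a dependency
#' error. Every report embeds the resolved config seed; the returned
#' manifest lists all written artifacts with MD5 checksums.
#'
#' @param cfg a validated config from [validateRunConfig()].
#' @param stages character subset of
#'   `c("build", "core", "census", "mc-test", "expr-rank",
#'   "signature-search")`.
#' @return data.frame manifest (`artifact`, `path`, `md5`), invisibly.
#' @export
runPipeline <- function(cfg, stages = c("build", "core", "census")) {
  stopifnot(inherits(cfg, "mircoreConfig"))
  all_stages <- c("build", "core", "census", "mc-test", "expr-rank",
                  "signature-search")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage ", sQuote(bad[1L]), call. = FALSE)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  edgesPath <- file.path(cfg$outputDir, "edges.tsv")
  artifacts <- character()
  put <- function(name, path) artifacts[[name]] <<- path
  writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  needEdges <- function(stage) {
    if (!file.exists(edgesPath)) .stageError(stage, "the edges artifact")
    readEdgeList(edgesPath)
  }

  if ("build" %in% stages) {
    ins <- cfg$inputs
    for (f in c("hosts", "matureMap", "targetsA", "targetsB"))
      if (is.null(ins[[f]])) .stageError("build", paste0("inputs$", f))
    ann <- filterMirnaClass(readHostAnnotations(ins$hosts), cfg$mirnaClass)
    matMap <- readMatureMap(ins$matureMap)
    targets <- intersectValidatedTargets(
      readTargetTable(ins$targetsA, "db_a"),
      readTargetTable(ins$targetsB, "db_b"))
    net <- buildNetwork(ann, matMap, targets)
    writeEdgeList(net, edgesPath)
    put("edges", edgesPath)
    summ <- summarizeNetwork(net, ann, matMap, targets)
    summ$mirnaClass <- cfg$mirnaClass
    put("summary", writeJson(summ, file.path(cfg$outputDir, "summary.json")))
  }
  if ("core" %in% stages) {
    net <- needEdges("core")
    dec <- extractCore(net)
    put("core", writeJson(coreReport(net, dec),
                          file.path(cfg$outputDir, "core.json")))
    writeEdgeList(coreSubgraph(net, dec),
                  file.path(cfg$outputDir, "core_edges.tsv"))
    put("coreEdges", file.path(cfg$outputDir, "core_edges.tsv"))
  }
  if ("census" %in% stages) {
    net <- needEdges("census")
    cen <- triadCensus(net)
    put("census", writeJson(as.list(censusCounts(cen)),
                            file.path(cfg$outputDir, "census.json")))
  }
  if ("mc-test" %in% stages) {
    net <- needEdges("mc-test")
    nm <- cfg$nullModel
    spec <- if (nm$model == "erdos_renyi_gnm")
      randomGraphSpec("erdos_renyi_gnm", n = numNodes(net),
                      m = numEdges(net))
    else
      randomGraphSpec("fixed_outdegree",
                      outDegrees = outDegreeVector(net))
    mc <- monteCarloTest(net, motifCountStat(nm$motif), spec,
                         replicates = nm$replicates, tail = nm$tail,
                         seed = nm$seed,
                         statName = paste0("motif:", nm$motif))
    put("mcTest", writeJson(
      list(statistic = paste0("motif:", nm$motif), model = nm$model,
           observed = observedStat(mc), replicates = nm$replicates,
           tail = nm$tail, seed = nm$seed, pValue = pValue(mc)),
      file.path(cfg$outputDir, "mc.json")))
  }
  if ("expr-rank" %in% stages) {
    ins <- cfg$inputs
    for (f in c("expressionMatrix", "coreGenes"))
      if (is.null(ins[[f]])) .stageError("expr-rank", paste0("inputs$", f))
    summaries <- summarizeTranscripts(readExpressionMatrix(
      ins$expressionMatrix))
    geneSet <- readLines(ins$coreGenes)
    geneSet <- toupper(trimws(geneSet[nzchar(geneSet)]))
    ex <- cfg$expression
    res <- testStratumEnrichment(summaries, geneSet, ex$statistic,
                                 ex$stratum, ex$direction)
    res$statistic <- ex$statistic
    res$direction <- ex$direction
    res$quantileConvention <- "type 7 (linear interpolation)"
    put("exprRank", writeJson(res, file.path(cfg$outputDir, "expr.json")))
  }
  if ("signature-search" %in% stages) {
    ins <- cfg$inputs
    for (f in c("training", "filtration", "validation", "coreGenes"))
      if (is.null(ins[[f]])) .stageError("signature-search",
                                         paste0("inputs$", f))
    sg <- cfg$signature
    scheme <- dichotomizationScheme(sg$scheme$eventHorizonMonths,
                                    sg$scheme$controlMinFollowupMonths,
                                    sg$scheme$minEventMonths)
    train <- dichotomize(readCohort(ins$training), scheme)
    filt <- lapply(ins$filtration,
                   function(p) dichotomize(readCohort(p), scheme))
    genes <- readLines(ins$coreGenes)
    genes <- toupper(trimws(genes[nzchar(genes)]))
    res <- exhaustiveSearch(train, filt, genes, setSize = sg$setSize,
                            thresholds = list(train = sg$trainThreshold,
                                              filtration =
                                                sg$filtrationThreshold),
                            cost = sg$cost)
    report <- list(nCandidates = choose(length(genes), sg$setSize),
                   nPassed = nrow(res), ranking = res)
    if (nrow(res)) {
      best <- attr(res, "signatures")[[1L]]
      valCohort <- readCohort(ins$validation)
      val <- dichotomize(valCohort, scheme)
      report$validation <- evaluateSignature(best, val, "validation")
      km <- kmLogrank(valCohort$timeMonths,
                      valCohort$recurrenceStatus == "recurred",
                      classifyRisk(best, valCohort))
      report$logrankP <- km$pValue
      write.table(km$curves, file.path(cfg$outputDir, "km_curves.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      put("kmCurves", file.path(cfg$outputDir, "km_curves.csv"))
    }
    put("search", writeJson(report,
                            file.path(cfg$outputDir, "search.json")))
  }
  manifest <- data.frame(artifact = names(artifacts),
                         path = unname(artifacts),
                         md5 = unname(tools::md5sum(unname(artifacts))),
                         stringsAsFactors = FALSE, row.names = NULL)
  write.table(manifest, file.path(cfg$outputDir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
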