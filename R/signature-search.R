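## Exhaustive search for prognostic gene signatures. Cohorts are
## dichotomized into event (recurrence within a horizon) and control
## (recurrence-free with long enough follow-up) classes, the remaining
## "grey zone" is excluded; a class-weighted linear SVM is fitted on the
## training cohort for every candidate gene subset, filtered by
## sensitivity/specificity thresholds on the training and filtration
## cohorts, and survivors are ranked by mean AUC.

.STATUS_LEVELS <- c("recurred", "recurrence_free", "unknown")

#' Cohort dichotomization scheme
#'
#' Time windows (in months) defining the two outcome classes. Event class:
#' recurrence with event time in `(minEventMonths, eventHorizonMonths]`
#' (recurrences at or before `minEventMonths` are excluded as likely
#' residual disease). Control class: recurrence-free with follow-up of at
#' least `controlMinFollowupMonths`. Everyone else -- including patients
#' with unknown recurrence status -- is excluded as the "grey zone".
#'
#' `colorectalScheme()` uses recurrence within 3 years vs recurrence-free
#' follow-up of at least 4 years, excluding first-month recurrences;
#' `breastScheme()` uses recurrence within 5 years vs follow-up of at
#' least 7 years.
#'
#' @param eventHorizonMonths latest event time counted as an event.
#' @param controlMinFollowupMonths minimum follow-up for controls; must be
#'   at least `eventHorizonMonths`.
#' @param minEventMonths early-event exclusion bound (default 0).
#' @return an object of class `"dichotomizationScheme"`.
#' @export
dichotomizationScheme <- function(eventHorizonMonths,
                                  controlMinFollowupMonths,
                                  minEventMonths = 0) {
  stopifnot(eventHorizonMonths > 0,
            controlMinFollowupMonths >= eventHorizonMonths,
            minEventMonths >= 0)
  structure(list(eventHorizonMonths = eventHorizonMonths,
                 controlMinFollowupMonths = controlMinFollowupMonths,
                 minEventMonths = minEventMonths),
            class = "dichotomizationScheme")
}

#' @rdname dichotomizationScheme
#' @export
colorectalScheme <- function() dichotomizationScheme(36, 48, 1)

#' @rdname dichotomizationScheme
#' @export
breastScheme <- function() dichotomizationScheme(60, 84, 0)

#' Dichotomize a cohort into event and control classes
#'
#' @param cohort data.frame with columns `patientId`, `recurrenceStatus`
#'   (`"recurred"`, `"recurrence_free"` or `"unknown"`), `timeMonths`
#'   (event time for recurred patients, follow-up otherwise) and one column
#'   per gene (log-scaled expression).
#' @param scheme a [dichotomizationScheme()].
#' @return the labeled subset: the cohort rows assigned to a class, with an
#'   added factor column `label` (levels `control`, `event`), and an
#'   attribute `"exclusions"` counting `grey`, `unknown` and `earlyEvent`
#'   exclusions. Errors if either class comes out empty.
#' @export
dichotomize <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "dichotomizationScheme"),
            all(c("patientId", "recurrenceStatus", "timeMonths") %in%
                  names(cohort)))
  status <- as.character(cohort$recurrenceStatus)
  if (!all(status %in% .STATUS_LEVELS))
    stop("recurrenceStatus must be one of ",
         paste(.STATUS_LEVELS, collapse = ", "), call. = FALSE)
  t <- cohort$timeMonths
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  is_event <- status == "recurred" & t > scheme$minEventMonths &
    t <= scheme$eventHorizonMonths
  is_control <- status == "recurrence_free" &
    t >= scheme$controlMinFollowupMonths
  early <- status == "recurred" & t <= scheme$minEventMonths
  unknown <- status == "unknown"
  grey <- !is_event & !is_control & !early & !unknown
  for (cls in c("event", "control")) {
    nn <- if (cls == "event") sum(is_event) else sum(is_control)
    if (nn == 0L)
      stop("dichotomization leaves the ", cls, " class empty", call. = FALSE)
  }
  out <- cohort[is_event | is_control, , drop = FALSE]
  out$label <- factor(ifelse(is_event[is_event | is_control],
                             "event", "control"),
                      levels = c("control", "event"))
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(grey = sum(grey), unknown = sum(unknown),
                                  earlyEvent = sum(early))
  out
}

#' Read a patient cohort table
#'
#' Delimited table with a patient id column, a recurrence status column, a
#' time column (months) and per-gene expression columns (all remaining
#' numeric columns unless `geneCols` is given).
#'
#' @param path file path.
#' @param idCol,statusCol,timeCol column names in the file.
#' @param geneCols optional character vector of gene columns.
#' @param statusMap optional named character vector mapping file status
#'   labels to `"recurred"`, `"recurrence_free"`, `"unknown"`.
#' @return cohort data.frame as expected by [dichotomize()].
#' @export
readCohort <- function(path, idCol = "patient_id",
                       statusCol = "recurrence_status",
                       timeCol = "time_months", geneCols = NULL,
                       statusMap = NULL) {
  df <- .readTable(path)
  .requireColumns(df, c(id = idCol, status = statusCol, time = timeCol), path)
  status <- as.character(df[[statusCol]])
  if (!is.null(statusMap)) {
    hit <- match(status, names(statusMap))
    status[!is.na(hit)] <- unname(statusMap)[hit[!is.na(hit)]]
  }
  if (is.null(geneCols))
    geneCols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                        c(idCol, timeCol))
  out <- data.frame(patientId = as.character(df[[idCol]]),
                    recurrenceStatus = status,
                    timeMonths = as.numeric(df[[timeCol]]),
                    stringsAsFactors = FALSE)
  cbind(out, df[, geneCols, drop = FALSE])
}

## scale a gene matrix with given means/sds (training-derived)
.scaleWith <- function(X, means, sds) sweep(sweep(X, 2L, means), 2L, sds, "/")

#' Fit a class-weighted linear SVM signature
#'
#' Estimates per-gene means and standard deviations on the training subset,
#' (0,1)-scales the training expression, and fits a linear-kernel SVM with
#' class weights inversely proportional to the class sizes
#' (`n/(2 n_class)`, so duplicating a class leaves total class weight
#' balanced). The decision function is re-expressed as an explicit linear
#' risk score \eqn{R(e) = \sum w_i e_i - \rho}, oriented so that
#' \eqn{R \ge 0} means high risk (event).
#'
#' @param training labeled subset from [dichotomize()].
#' @param genes character vector of gene columns to use.
#' @param cost SVM regularization parameter C (default 1).
#' @return a [LinearSignature-class].
#' @export
fitSignature <- function(training, genes, cost = 1) {
  stopifnot("label" %in% names(training), length(genes) >= 1L)
  miss <- setdiff(genes, names(training))
  if (length(miss))
    stop("gene(s) missing from the cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(training[, genes, drop = FALSE])
  y <- training$label
  stopifnot(is.factor(y), identical(levels(y), c("control", "event")))
  means <- colMeans(X)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("gene(s) with zero training variance: ",
         paste(genes[sds == 0], collapse = ", "), call. = FALSE)
  Xs <- .scaleWith(X, means, sds)
  nt <- table(y)
  cw <- c(control = nrow(X) / (2 * nt[["control"]]),
          event = nrow(X) / (2 * nt[["event"]]))
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
  ## SV columns follow the input column order, i.e. `genes`
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  ## orient so that R >= 0 corresponds to the predicted event class
  f <- drop(Xs %*% w) - rho
  pred <- as.character(predict(fit, Xs))
  agree <- mean((f >= 0) == (pred == "event"))
  if (agree < 0.5) { w <- -w; rho <- -rho }
  new("LinearSignature", genes = genes, scaleMeans = unname(means),
      scaleSds = unname(sds), weights = unname(w), offset = rho)
}

#' Risk score and risk-group classification
#'
#' `riskScore()` applies the signature's training-derived scaling to a
#' cohort and returns the continuous score \eqn{R}; `classifyRisk()`
#' thresholds it at zero (`R >= 0` is high risk).
#'
#' @param sig a [LinearSignature-class].
#' @param cohort data.frame containing the signature's gene columns.
#' @return `riskScore()`: numeric vector; `classifyRisk()`: factor with
#'   levels `low`, `high`.
#' @export
riskScore <- function(sig, cohort) {
  stopifnot(is(sig, "LinearSignature"))
  miss <- setdiff(sig@genes, names(cohort))
  if (length(miss))
    stop("gene(s) missing from the cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(cohort[, sig@genes, drop = FALSE])
  Xs <- .scaleWith(X, sig@scaleMeans, sig@scaleSds)
  unname(drop(Xs %*% sig@weights)) - sig@offset
}

#' @rdname riskScore
#' @export
classifyRisk <- function(sig, cohort) {
  factor(ifelse(riskScore(sig, cohort) >= 0, "high", "low"),
         levels = c("low", "high"))
}

## rank-based AUC of scores for binary labels, ties handled by mid-ranks
.rankAuc <- function(scores, isEvent) {
  ne <- sum(isEvent); nc <- sum(!isEvent)
  if (ne == 0L || nc == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[isEvent]) - ne * (ne + 1) / 2) / (ne * nc)
}

#' Evaluate a signature on a labeled cohort
#'
#' Sensitivity is the fraction of event-class patients classified high
#' risk; specificity the fraction of control-class patients classified low
#' risk; AUC is computed from the continuous risk score by rank comparison
#' with mid-rank tie correction (a constant score gives AUC 0.5).
#'
#' @param sig a [LinearSignature-class].
#' @param cohort labeled subset from [dichotomize()].
#' @param cohortRole optional label (`"training"`, `"filtration"`,
#'   `"validation"`) carried through to the result.
#' @return list with `sensitivity`, `specificity`, `auc`, `cohortRole`.
#' @export
evaluateSignature <- function(sig, cohort, cohortRole = NA_character_) {
  stopifnot("label" %in% names(cohort))
  scores <- riskScore(sig, cohort)
  isEvent <- cohort$label == "event"
  high <- scores >= 0
  list(sensitivity = mean(high[isEvent]),
       specificity = mean(!high[!isEvent]),
       auc = .rankAuc(scores, isEvent),
       cohortRole = cohortRole)
}

#' Exhaustive search over gene subsets
#'
#' Fits a signature on the training cohort for every size-`setSize` subset
#' of the gene universe (lexicographic enumeration), discards candidates
#' whose training sensitivity *or* specificity falls below
#' `thresholds$train`, then discards survivors whose sensitivity or
#' specificity on *any* filtration cohort falls below
#' `thresholds$filtration`. Filtration cohorts are scored with the
#' training-derived scaling only. Survivors are ranked by the arithmetic
#' mean of the AUCs over the training and filtration cohorts, descending
#' (ties broken by gene names for reproducibility).
#'
#' @param training labeled training subset from [dichotomize()].
#' @param filtrations list of labeled filtration subsets.
#' @param genesUniverse character vector of candidate genes (must be
#'   non-empty and present in every cohort).
#' @param setSize subset size (default 3).
#' @param thresholds list with elements `train` (default 0.6) and
#'   `filtration` (default 0.5).
#' @param cost SVM cost parameter.
#' @return data.frame, one row per surviving subset, sorted by decreasing
#'   `meanAuc`: columns `genes` (semicolon-joined), `trainSensitivity`,
#'   `trainSpecificity`, `trainAuc`, `filtAuc<i>`..., `meanAuc`. The
#'   fitted [LinearSignature-class] objects are attached as the
#'   `"signatures"` attribute, in row order. Zero survivors give a
#'   zero-row data.frame.
#' @export
exhaustiveSearch <- function(training, filtrations, genesUniverse,
                             setSize = 3,
                             thresholds = list(train = 0.6, filtration = 0.5),
                             cost = 1) {
  stopifnot(setSize >= 1, is.list(filtrations))
  if (!length(genesUniverse)) stop("empty gene universe", call. = FALSE)
  genesUniverse <- sort(unique(genesUniverse))
  if (setSize > length(genesUniverse))
    stop("setSize exceeds the gene universe size", call. = FALSE)
  stopifnot(is.numeric(thresholds$train), is.numeric(thresholds$filtration))
  sets <- combn(genesUniverse, setSize, simplify = FALSE)
  nf <- length(filtrations)
  rows <- list(); sigs <- list()
  for (gs in sets) {
    sig <- fitSignature(training, gs, cost = cost)
    tr <- evaluateSignature(sig, training, "training")
    if (tr$sensitivity < thresholds$train ||
        tr$specificity < thresholds$train) next
    fevs <- lapply(filtrations, evaluateSignature, sig = sig,
                   cohortRole = "filtration")
    ok <- all(vapply(fevs, function(ev)
      ev$sensitivity >= thresholds$filtration &&
        ev$specificity >= thresholds$filtration, TRUE))
    if (!ok) next
    aucs <- c(tr$auc, vapply(fevs, `[[`, 0, "auc"))
    row <- data.frame(genes = paste(gs, collapse = ";"),
                      trainSensitivity = tr$sensitivity,
                      trainSpecificity = tr$specificity,
                      trainAuc = tr$auc,
                      stringsAsFactors = FALSE)
    if (nf) for (i in seq_len(nf)) row[[paste0("filtAuc", i)]] <- aucs[i + 1]
    row$meanAuc <- mean(aucs)
    rows[[length(rows) + 1L]] <- row
    sigs[[length(sigs) + 1L]] <- sig
  }
  if (!length(rows)) {
    out <- data.frame(genes = character(), trainSensitivity = numeric(),
                      trainSpecificity = numeric(), trainAuc = numeric(),
                      meanAuc = numeric(), stringsAsFactors = FALSE)
    attr(out, "signatures") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$meanAuc, out$genes)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "signatures") <- sigs[ord]
  out
}

#' Kaplan-Meier curves and two-tailed log-rank test
#'
#' Compares survival between groups (e.g. predicted high- vs low-risk) with
#' the log-rank test and exports Kaplan-Meier curve coordinates for
#' plotting.
#'
#' @param timeMonths numeric event/censoring times.
#' @param event logical or 0/1; `TRUE`/1 = event observed.
#' @param group factor or vector with two levels.
#' @return list with `pValue` (two-tailed log-rank) and `curves`, a
#'   data.frame with columns `group`, `time`, `survival`, `nRisk`.
#' @export
kmLogrank <- function(timeMonths, event, group) {
  group <- factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L)
    stop("each group must be non-empty", call. = FALSE)
  event <- as.integer(event)
  sd_ <- survival::survdiff(survival::Surv(timeMonths, event) ~ group)
  p <- 1 - pchisq(sd_$chisq, df = length(sd_$n) - 1)
  sf <- survival::survfit(survival::Surv(timeMonths, event) ~ group)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = sf$time, survival = sf$surv, nRisk = sf$n.risk,
                       stringsAsFactors = FALSE)
  list(pValue = p, curves = curves)
}

#' Stratified k-fold cross-validation of a signature
#'
#' Splits the training cohort into `folds` class-stratified folds
#' (assignment seeded and reproducible), fits the signature afresh on each
#' training part -- including re-estimating the scaling -- and evaluates on
#' the held-out part.
#'
#' @param training labeled subset from [dichotomize()].
#' @param genes gene subset.
#' @param folds number of folds (`>= 2`); must not exceed the smaller
#'   class size, except `folds == nrow(training)` (leave-one-out), where
#'   single-patient folds necessarily carry one class and the metrics not
#'   defined on a fold are `NA`/`NaN`.
#' @param cost SVM cost parameter.
#' @param seed integer seed for the fold assignment.
#' @return data.frame with one row per fold (`fold`, `sensitivity`,
#'   `specificity`, `auc`) and the across-fold means as the `"means"`
#'   attribute.
#' @export
crossValidate <- function(training, genes, folds, cost = 1, seed = 1) {
  stopifnot(folds >= 2, "label" %in% names(training))
  y <- training$label
  n <- nrow(training)
  if (folds == n) {                      # leave-one-out
    fold <- seq_len(n)
  } else {
    if (min(table(y)) < folds)
      stop("a class is smaller than the number of folds", call. = FALSE)
    set.seed(seed)
    fold <- integer(n)
    for (cls in levels(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  }
  rows <- lapply(seq_len(folds), function(f) {
    sig <- fitSignature(training[fold != f, , drop = FALSE], genes,
                        cost = cost)
    ev <- evaluateSignature(sig, training[fold == f, , drop = FALSE])
    data.frame(fold = f, sensitivity = ev$sensitivity,
               specificity = ev$specificity, auc = ev$auc)
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, c("sensitivity", "specificity",
                                         "auc")], na.rm = TRUE)
  out
}
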