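## Expression-level ranking and binomial enrichment of core genes.
## Expression variance is quantified as the third-to-first quartile ratio,
## which is ranking-equivalent to the interquartile range of log-scaled
## values whenever Q1 > 0.

.asExpressionMatrix <- function(mat) {
  if (is(mat, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input requires the SummarizedExperiment package")
    mat <- SummarizedExperiment::assay(mat)
  }
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    stop("expression matrix must have transcript row names", call. = FALSE)
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop("expression matrix is empty", call. = FALSE)
  if (any(!is.finite(mat)))
    stop("expression values must be finite", call. = FALSE)
  mat
}

#' Read a transcripts-by-samples expression matrix
#'
#' Delimited text with transcripts in rows (first column = transcript id)
#' and a header row of sample ids. Values are RPKM-like non-negative
#' expression levels or preprocessed log-expression.
#'
#' @param path file path (tab- or comma-separated, sniffed).
#' @return numeric matrix with transcript row names and sample column names.
#' @export
readExpressionMatrix <- function(path) {
  df <- .readTable(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  .asExpressionMatrix(m)
}

#' Per-transcript quantile summaries
#'
#' Computes the median, first and third quartile of each transcript across
#' samples (quantile convention: linear interpolation between order
#' statistics, R type 7), and the variance ratio Q3/Q1, defined only when
#' Q1 > 0.
#'
#' @param mat numeric matrix (transcripts x samples) with row names, or a
#'   `SummarizedExperiment`.
#' @return data.frame with columns `transcript`, `median`, `q1`, `q3`,
#'   `varianceRatio` (`NA` where Q1 <= 0).
#' @export
summarizeTranscripts <- function(mat) {
  mat <- .asExpressionMatrix(mat)
  qs <- t(apply(mat, 1L, quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE, type = 7))
  vr <- ifelse(qs[, 1] > 0, qs[, 3] / qs[, 1], NA_real_)
  data.frame(transcript = rownames(mat), q1 = qs[, 1], median = qs[, 2],
             q3 = qs[, 3], varianceRatio = vr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-set membership in a rank stratum
#'
#' Ranks all transcripts by the chosen statistic (`direction = "top"`:
#' descending; `"bottom"`: ascending; ties get average ranks) and counts
#' how many gene-set members fall within the leading stratum, whose cutoff
#' is `floor(stratum * total)`. Genes absent from the summaries are dropped
#' from `n` with a warning (matching cohorts in which not every core gene
#' was measured). For `statistic = "variance_ratio"`, transcripts with an
#' undefined ratio are excluded from the ranking; apply
#' [varianceHalfFilter()] first to reproduce the low-variance analysis.
#'
#' @param summaries data.frame from [summarizeTranscripts()].
#' @param geneSet character vector of gene/transcript ids.
#' @param statistic one of `"median"`, `"q1"`, `"q3"`, `"variance_ratio"`.
#' @param stratum fraction in (0,1), e.g. 0.25 for a quarter.
#' @param direction `"top"` or `"bottom"`.
#' @return list with elements `k` (members in the stratum), `n` (set size
#'   after dropping missing genes), `stratumFraction`, `cutoff`, `total`,
#'   `missing` (dropped gene ids).
#' @export
stratumMembership <- function(summaries, geneSet,
                              statistic = c("median", "q1", "q3",
                                            "variance_ratio"),
                              stratum = 0.25,
                              direction = c("top", "bottom")) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  stopifnot(stratum > 0, stratum < 1)
  col <- switch(statistic, median = "median", q1 = "q1", q3 = "q3",
                variance_ratio = "varianceRatio")
  vals <- summaries[[col]]
  keep <- !is.na(vals)
  vals <- vals[keep]
  ids <- summaries$transcript[keep]
  geneSet <- unique(geneSet)
  missing <- setdiff(geneSet, ids)
  if (length(missing)) {
    warning(length(missing), " gene(s) absent from the ranking dropped: ",
            paste(missing, collapse = ", "))
    geneSet <- setdiff(geneSet, missing)
  }
  if (!length(geneSet))
    stop("gene set empty after intersection with the ranking", call. = FALSE)
  r <- if (direction == "top") rank(-vals, ties.method = "average")
       else rank(vals, ties.method = "average")
  total <- length(vals)
  cutoff <- floor(stratum * total)
  k <- sum(r[match(geneSet, ids)] <= cutoff)
  list(k = k, n = length(geneSet), stratumFraction = stratum,
       cutoff = cutoff, total = total, missing = missing)
}

#' Exact binomial upper-tail probability
#'
#' \deqn{P(X \ge k) = \sum_{j=k}^{n} \binom{n}{j} p^j (1-p)^{n-j}}
#' at full floating precision. This is the enrichment p-value for observing
#' `k` of `n` gene-set members inside a stratum containing a fraction `p`
#' of all transcripts.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n set size.
#' @param p stratum fraction, in (0,1).
#' @return the exact upper-tail probability.
#' @export
binomialUpperTail <- function(k, n, p) {
  if (length(k) != 1L || length(n) != 1L || length(p) != 1L ||
      k < 0 || k > n || n < 1 || p <= 0 || p >= 1)
    stop("domain error: need 0 <= k <= n, n >= 1, 0 < p < 1", call. = FALSE)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Test gene-set enrichment in a rank stratum
#'
#' Combines [stratumMembership()] with [binomialUpperTail()]: the null
#' hypothesis is that each gene-set member falls in the stratum
#' independently with probability equal to the stratum fraction.
#'
#' @inheritParams stratumMembership
#' @return list with `k`, `n`, `stratumFraction`, `pValue`, `missing`.
#' @export
testStratumEnrichment <- function(summaries, geneSet,
                                  statistic = c("median", "q1", "q3",
                                                "variance_ratio"),
                                  stratum = 0.25,
                                  direction = c("top", "bottom")) {
  mem <- stratumMembership(summaries, geneSet, statistic, stratum, direction)
  mem$pValue <- binomialUpperTail(mem$k, mem$n, stratum)
  mem
}

#' Keep the upper half of transcripts by first-quartile expression
#'
#' Drops low-expression transcripts before the variance analysis: ranks by
#' Q1 descending and retains the upper `floor(n/2)`. Retained transcripts
#' are guaranteed to have Q1 > 0 (any with non-positive Q1 are dropped with
#' a message), so the variance ratio is defined for all of them.
#'
#' @param summaries data.frame from [summarizeTranscripts()].
#' @return the filtered summaries data.frame.
#' @export
varianceHalfFilter <- function(summaries) {
  stopifnot(is.data.frame(summaries), "q1" %in% names(summaries))
  n <- nrow(summaries)
  keep_n <- floor(n / 2)
  ord <- order(-summaries$q1, summaries$transcript)
  out <- summaries[head(ord, keep_n), , drop = FALSE]
  bad <- out$q1 <= 0
  if (any(bad)) {
    message("dropping ", sum(bad),
            " retained transcript(s) with non-positive first quartile")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
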