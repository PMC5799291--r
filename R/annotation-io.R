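## Reading and validating the annotation tables: intragenic pre-miRNAs with
## their host genes, the mature <-> precursor map, and the two validated
## miRNA-target interaction tables whose intersection defines the edge set.

.LOCATION_CLASSES <- c("intronic", "exonic")
.ORIENTATIONS <- c("sense", "antisense")

## Sniff the delimiter of a header line: tab wins over comma.
.sniffSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  read.delim(path, sep = .sniffSep(path), header = TRUE,
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

.requireColumns <- function(df, colMap, path) {
  missing <- setdiff(unname(colMap), names(df))
  if (length(missing))
    stop("format error in '", basename(path), "': missing column",
         if (length(missing) > 1L) "s" else "", " ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
}

## Gene identifier namespace: upper-cased official symbols, with an optional
## user-supplied synonym map applied after upper-casing.
.normGene <- function(x, synonyms = NULL) {
  x <- toupper(trimws(x))
  if (!is.null(synonyms)) {
    hit <- match(x, toupper(names(synonyms)))
    x[!is.na(hit)] <- toupper(unname(synonyms)[hit[!is.na(hit)]])
  }
  x
}

## Mature/precursor ids are matched case-insensitively (lower-cased), exact
## otherwise: no -3p/-5p collapsing.
.normMirna <- function(x) tolower(trimws(x))

.normEnum <- function(x, allowed, column, path) {
  x <- tolower(trimws(x))
  bad <- which(!x %in% allowed)
  if (length(bad))
    stop("value error in '", basename(path), "', column '", column,
         "', row ", bad[1L], ": unknown label ", sQuote(x[bad[1L]]),
         " (expected one of ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  x
}

#' Read intragenic miRNA host-gene annotations
#'
#' Reads a delimited table (tab or comma, sniffed from the header) of
#' intragenic pre-miRNAs with their host genes and location class, of the
#' kind exported by intragenic-miRNA databases. Location is normalized to
#' `intronic`/`exonic`, orientation to `sense`/`antisense`; gene symbols are
#' upper-cased and passed through the optional synonym map.
#'
#' @param path path to the table.
#' @param colMap named character vector mapping the canonical field names
#'   `pre_mirna_id`, `host_gene`, `location_class`, `orientation` to the
#'   column names used in the file.
#' @param synonyms optional named character vector mapping gene synonyms to
#'   official symbols.
#' @return data.frame with columns `preMirnaId`, `hostGene`,
#'   `locationClass`, `orientation`, one row per pre-miRNA record.
#' @export
readHostAnnotations <- function(path,
                                colMap = c(pre_mirna_id = "pre_mirna_id",
                                           host_gene = "host_gene",
                                           location_class = "location_class",
                                           orientation = "orientation"),
                                synonyms = NULL) {
  df <- .readTable(path)
  .requireColumns(df, colMap, path)
  out <- data.frame(
    preMirnaId = .normMirna(df[[colMap[["pre_mirna_id"]]]]),
    hostGene = .normGene(df[[colMap[["host_gene"]]]], synonyms),
    locationClass = .normEnum(df[[colMap[["location_class"]]]],
                              .LOCATION_CLASSES, colMap[["location_class"]],
                              path),
    orientation = .normEnum(df[[colMap[["orientation"]]]],
                            .ORIENTATIONS, colMap[["orientation"]], path),
    stringsAsFactors = FALSE)
  bad <- which(!nzchar(out$preMirnaId))
  if (length(bad))
    stop("value error in '", basename(path), "', row ", bad[1L],
         ": empty pre_mirna_id", call. = FALSE)
  bad <- which(!nzchar(out$hostGene) | is.na(out$hostGene))
  if (length(bad))
    stop("value error in '", basename(path), "', row ", bad[1L],
         ": empty host_gene", call. = FALSE)
  dup <- duplicated(out)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate annotation row(s)")
    out <- out[!dup, , drop = FALSE]
  }
  conflicting <- unique(out$preMirnaId[duplicated(out$preMirnaId)])
  if (length(conflicting))
    stop("value error in '", basename(path), "': pre-miRNA ",
         sQuote(conflicting[1L]),
         " annotated with conflicting records", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read the mature-to-precursor miRNA map
#'
#' One row per (mature miRNA, pre-miRNA) pair; the mapping may be
#' many-to-many (a mature miRNA can derive from several precursors).
#'
#' @inheritParams readHostAnnotations
#' @param colMap named character vector mapping `mature_mirna_id` and
#'   `pre_mirna_id` to file column names.
#' @return data.frame with columns `matureMirnaId`, `preMirnaId`.
#' @export
readMatureMap <- function(path,
                          colMap = c(mature_mirna_id = "mature_mirna_id",
                                     pre_mirna_id = "pre_mirna_id")) {
  df <- .readTable(path)
  .requireColumns(df, colMap, path)
  out <- data.frame(
    matureMirnaId = .normMirna(df[[colMap[["mature_mirna_id"]]]]),
    preMirnaId = .normMirna(df[[colMap[["pre_mirna_id"]]]]),
    stringsAsFactors = FALSE)
  bad <- which(!nzchar(out$matureMirnaId) | !nzchar(out$preMirnaId))
  if (length(bad))
    stop("value error in '", basename(path), "', row ", bad[1L],
         ": empty miRNA identifier", call. = FALSE)
  unique(out)
}

#' Read a miRNA-target interaction table
#'
#' Reads one source database's export of experimentally validated
#' miRNA-target interactions. Duplicate (mature miRNA, target) rows -- both
#' databases report one row per supporting experiment -- are deduplicated
#' with a message.
#'
#' @inheritParams readHostAnnotations
#' @param source label identifying the database this table came from
#'   (e.g. `"db_a"`); the two tables passed to
#'   [intersectValidatedTargets()] must carry distinct sources.
#' @param colMap named character vector mapping `mature_mirna_id` and
#'   `target_gene` to file column names.
#' @return data.frame with columns `matureMirnaId`, `targetGene`, `source`.
#' @export
readTargetTable <- function(path, source,
                            colMap = c(mature_mirna_id = "mature_mirna_id",
                                       target_gene = "target_gene"),
                            synonyms = NULL) {
  stopifnot(is.character(source), length(source) == 1L, nzchar(source))
  df <- .readTable(path)
  .requireColumns(df, colMap, path)
  out <- data.frame(
    matureMirnaId = .normMirna(df[[colMap[["mature_mirna_id"]]]]),
    targetGene = .normGene(df[[colMap[["target_gene"]]]], synonyms),
    stringsAsFactors = FALSE)
  dup <- duplicated(out)
  if (any(dup)) {
    message("deduplicated ", sum(dup), " repeated interaction row(s) in '",
            basename(path), "'")
    out <- out[!dup, , drop = FALSE]
  }
  out$source <- source
  rownames(out) <- NULL
  out
}

#' Intersect two validated-target tables
#'
#' A miRNA-target pair counts as validated when it is present simultaneously
#' in both source databases. The operation is symmetric in its arguments and
#' an empty intersection is a valid (empty) result.
#'
#' @param a,b data.frames with columns `matureMirnaId`, `targetGene` and a
#'   `source` column; the two tables must carry distinct `source` tags.
#' @return data.frame with columns `matureMirnaId`, `targetGene`, sorted,
#'   without duplicates.
#' @export
intersectValidatedTargets <- function(a, b) {
  for (df in list(a, b))
    stopifnot(all(c("matureMirnaId", "targetGene", "source") %in% names(df)))
  if (length(intersect(unique(a$source), unique(b$source))) &&
      nrow(a) && nrow(b))
    stop("the two target tables must be tagged with distinct sources",
         call. = FALSE)
  key <- function(df) unique(paste(df$matureMirnaId, df$targetGene,
                                   sep = "\r"))
  common <- intersect(key(a), key(b))
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- data.frame(
    matureMirnaId = vapply(parts, `[`, "", 1L),
    targetGene = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE)
  out <- out[order(out$matureMirnaId, out$targetGene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter annotations by miRNA class
#'
#' `"all_intragenic"` is the identity; `"intronic_sense"` keeps records with
#' `locationClass == "intronic"` and `orientation == "sense"` only (the
#' IS-network restriction).
#'
#' @param annotations data.frame from [readHostAnnotations()].
#' @param spec one of `"all_intragenic"`, `"intronic_sense"`.
#' @return the filtered annotation data.frame.
#' @export
filterMirnaClass <- function(annotations,
                             spec = c("all_intragenic", "intronic_sense")) {
  spec <- match.arg(spec)
  if (spec == "all_intragenic") return(annotations)
  out <- annotations[annotations$locationClass == "intronic" &
                       annotations$orientation == "sense", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a validated-target set as a two-column TSV
#'
#' @param targets data.frame from [intersectValidatedTargets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeValidatedTargets <- function(targets, path) {
  stopifnot(all(c("matureMirnaId", "targetGene") %in% names(targets)))
  write.table(targets[, c("matureMirnaId", "targetGene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
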