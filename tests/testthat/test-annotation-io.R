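test_that("host annotation reader parses, normalizes and validates", {
  df <- data.frame(pre_mirna_id = c("MIR-A", "mir-b", "mir-c"),
                   host_gene = c("gene1", "Gene2", "GENE3"),
                   location_class = c("Intronic", "intronic", "exonic"),
                   orientation = c("sense", "Sense", "antisense"))
  path <- writeTsv(df)
  ann <- readHostAnnotations(path)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$preMirnaId, c("mir-a", "mir-b", "mir-c"))
  expect_equal(ann$hostGene, c("GENE1", "GENE2", "GENE3"))
  expect_equal(ann$locationClass, c("intronic", "intronic", "exonic"))
  expect_equal(ann$orientation, c("sense", "sense", "antisense"))

  # comma-separated dialect is sniffed
  pathCsv <- tempfile(fileext = ".csv")
  write.csv(df, pathCsv, row.names = FALSE, quote = FALSE)
  expect_equal(readHostAnnotations(pathCsv), ann)

  # missing column -> format error naming it
  expect_error(readHostAnnotations(writeTsv(df[, -2])), "host_gene")
  # unknown class label -> value error with row number
  bad <- df; bad$location_class[2] <- "weird"
  expect_error(readHostAnnotations(writeTsv(bad)), "row 2")
  # empty host gene -> value error naming the row
  bad <- df; bad$host_gene[3] <- ""
  expect_error(readHostAnnotations(writeTsv(bad)), "row 3")
  # conflicting duplicate precursor records -> error
  bad <- rbind(df, data.frame(pre_mirna_id = "MIR-A", host_gene = "OTHER",
                              location_class = "intronic",
                              orientation = "sense"))
  expect_error(readHostAnnotations(writeTsv(bad)), "conflicting")
})

test_that("synonym map is applied after upper-casing", {
  df <- data.frame(pre_mirna_id = "mir-a", host_gene = "OldName",
                   location_class = "intronic", orientation = "sense")
  ann <- readHostAnnotations(writeTsv(df), synonyms = c(oldname = "NEWNAME"))
  expect_equal(ann$hostGene, "NEWNAME")
})

test_that("target tables deduplicate per-experiment rows with a message", {
  df <- data.frame(mature_mirna_id = c("m1", "m1", "m2"),
                   target_gene = c("G1", "G1", "G2"))
  expect_message(tab <- readTargetTable(writeTsv(df), "db_a"),
                 "deduplicated")
  expect_equal(nrow(tab), 2)
  expect_equal(unique(tab$source), "db_a")
})

test_that("validated targets are the symmetric intersection of two sources", {
  a <- data.frame(matureMirnaId = c("m1", "m1"), targetGene = c("G1", "G2"),
                  source = "db_a", stringsAsFactors = FALSE)
  b <- data.frame(matureMirnaId = c("m1", "m1"), targetGene = c("G2", "G3"),
                  source = "db_b", stringsAsFactors = FALSE)
  ab <- intersectValidatedTargets(a, b)
  expect_equal(ab, data.frame(matureMirnaId = "m1", targetGene = "G2",
                              stringsAsFactors = FALSE))
  expect_equal(intersectValidatedTargets(b, a), ab)

  # disjoint lists -> empty result, not an error
  c_ <- data.frame(matureMirnaId = "m9", targetGene = "G9", source = "db_b",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(intersectValidatedTargets(a, c_)), 0)
  # same source tag -> error
  a2 <- a; a2$source <- "db_b"
  expect_error(intersectValidatedTargets(a2, b), "distinct sources")
})

test_that("intersection properties hold on random tables", {
  set.seed(11)
  for (rep in 1:20) {
    mk <- function(src) data.frame(
      matureMirnaId = sample(paste0("m", 1:6), 25, replace = TRUE),
      targetGene = sample(paste0("G", 1:8), 25, replace = TRUE),
      source = src, stringsAsFactors = FALSE)
    a <- mk("db_a"); b <- mk("db_b")
    ab <- intersectValidatedTargets(a, b)
    ba <- intersectValidatedTargets(b, a)
    expect_identical(ab, ba)
    expect_lte(nrow(ab), min(nrow(unique(a[, 1:2])), nrow(unique(b[, 1:2]))))
    expect_false(anyDuplicated(ab) > 0)
  }
})

test_that("miRNA class filter keeps intronic sense records and is idempotent", {
  ann <- data.frame(
    preMirnaId = paste0("mir-", 1:4),
    hostGene = paste0("G", 1:4),
    locationClass = c("intronic", "intronic", "exonic", "exonic"),
    orientation = c("sense", "antisense", "sense", "antisense"),
    stringsAsFactors = FALSE)
  expect_identical(filterMirnaClass(ann, "all_intragenic"), ann)
  is_ <- filterMirnaClass(ann, "intronic_sense")
  expect_equal(is_$preMirnaId, "mir-1")
  expect_identical(filterMirnaClass(is_, "intronic_sense"), is_)
  expect_true(all(is_$preMirnaId %in% ann$preMirnaId))
  # only exonic records -> empty
  exonic <- ann[ann$locationClass == "exonic", ]
  expect_equal(nrow(filterMirnaClass(exonic, "intronic_sense")), 0)
  expect_error(filterMirnaClass(ann, "everything"))
})
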