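test_that("immunoSEQ tables parse with productive-only totals", {
  p <- writeFixtureTable(list(iRow("AAA", 10), iRow("CCC", 5),
                              iRow("GGG", 5)))
  s <- readClonotypeTable(p, subjectId = "S1")
  expect_s4_class(s, "RepertoireSample")
  expect_equal(nrow(cloneTable(s)), 3L)
  expect_equal(totalTemplates(s), 20L)

  # an out-of-frame clone is retained but excluded from the total
  p2 <- writeFixtureTable(list(iRow("AAA", 10),
                               iRow("TTT", 2, frame = "Out", aa = "CAS*F")))
  s2 <- readClonotypeTable(p2)
  expect_equal(nrow(cloneTable(s2)), 2L)
  expect_equal(totalTemplates(s2), 10L)
  expect_equal(uniqueProductiveClonotypes(s2), 1L)
})

test_that("duplicate rearrangement rows are merged by summing counts", {
  p <- writeFixtureTable(list(iRow("AAA", 3), iRow("CCC", 1),
                              iRow("AAA", 4)))
  s <- readClonotypeTable(p)
  tab <- cloneTable(s)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$templates[tab$rearrangement == "AAA"], 7L)
})

test_that("the same repertoire parses identically from both dialects", {
  rowsI <- list(iRow("AAA", 10), iRow("CCC", 5),
                iRow("TTT", 2, frame = "Out", aa = "CX*"))
  rowsA <- list(aRow("AAA", 10), aRow("CCC", 5),
                aRow("TTT", 2, productive = "F", aa = "CX*"))
  sI <- readClonotypeTable(writeFixtureTable(rowsI, "immunoseq"),
                           sampleId = "x")
  sA <- readClonotypeTable(writeFixtureTable(rowsA, "airr"),
                           sampleId = "x")
  tI <- cloneTable(sI)[order(cloneTable(sI)$rearrangement),
                       c("rearrangement", "productive", "templates")]
  tA <- cloneTable(sA)[order(cloneTable(sA)$rearrangement),
                       c("rearrangement", "productive", "templates")]
  rownames(tI) <- rownames(tA) <- NULL
  expect_identical(tI, tA)
})

test_that("write/read round trip preserves keys, counts and flags", {
  for (dialect in c("immunoseq", "airr")) {
    s <- exampleSample(c(AAAA = 17L, CCCC = 3L, GGGG = 1L),
                       productive = c(TRUE, TRUE, FALSE))
    p <- tempfile(fileext = ".tsv")
    writeClonotypeTable(s, p, dialect = dialect)
    s2 <- readClonotypeTable(p, dialect = dialect)
    a <- cloneTable(s)[, c("rearrangement", "productive", "templates")]
    b <- cloneTable(s2)[, c("rearrangement", "productive", "templates")]
    expect_identical(a[order(a$rearrangement), ]$templates,
                     b[order(b$rearrangement), ]$templates)
    expect_identical(a[order(a$rearrangement), ]$productive,
                     b[order(b$rearrangement), ]$productive)
  }
})

test_that("gzip-compressed tables are read transparently", {
  s <- exampleSample(c(AAAA = 5L, CCCC = 2L))
  p <- tempfile(fileext = ".tsv.gz")
  writeClonotypeTable(s, p)
  s2 <- readClonotypeTable(p)
  expect_equal(totalTemplates(s2), 7L)
})

test_that("malformed clonotype tables fail with informative errors", {
  # missing column named in the message
  p <- tempfile(fileext = ".tsv")
  writeLines(c("rearrangement\tamino_acid\tv_gene\tj_gene\ttemplates",
               "AAA\tCASSF\tV\tJ\t5"), p)
  expect_error(readClonotypeTable(p), "frame_type")
  # negative count carries the line number
  p2 <- writeFixtureTable(list(iRow("AAA", 5), iRow("CCC", -1)))
  expect_error(readClonotypeTable(p2), "line 3")
  # fractional count rejected
  p3 <- writeFixtureTable(list(iRow("AAA", "2.5")))
  expect_error(readClonotypeTable(p3), "template count")
  # header-only file
  p4 <- writeFixtureTable(list())
  expect_error(readClonotypeTable(p4), "empty")
  # refusing to write an empty repertoire
  empty <- new("RepertoireSample", clones = data.frame(
    rearrangement = character(0), cdr3_aa = character(0),
    v_gene = character(0), j_gene = character(0),
    productive = logical(0), templates = integer(0)))
  expect_error(writeClonotypeTable(empty, tempfile()), "empty")
})

test_that("clone frequencies are counts over productive totals", {
  expect_equal(cloneFrequencies(exampleSample(c(a = 10, b = 30))),
               c(a = 0.25, b = 0.75))
  expect_equal(cloneFrequencies(exampleSample(c(a = 7))), c(a = 1))
  expect_equal(cloneFrequencies(exampleSample(c(a = 1, b = 1, c = 2))),
               c(a = 0.25, b = 0.25, c = 0.5))
  f <- cloneFrequencies(zipfSample())
  expect_equal(sum(f), 1, tolerance = 1e-9)
  # degenerate sample: only non-productive templates
  bad <- exampleSample(c(a = 5), productive = FALSE)
  expect_error(cloneFrequencies(bad), "degenerate")
})

test_that("sample validity catches malformed clone tables", {
  expect_error(exampleSample(c(a = 1), timepoint = "week9"), "timepoint")
  expect_error(exampleSample(c(a = 1), compartment = "plasma"),
               "compartment")
  tab <- data.frame(rearrangement = c("A", "A"), productive = TRUE,
                    templates = 1L)
  expect_error(RepertoireSample("x", "s", "pre_tx", "pbmc", "bulk", tab),
               "duplicate")
  # '*' in a productive CDR3 is invalid, fine in a non-productive one
  tab2 <- data.frame(rearrangement = "A", cdr3_aa = "CAS*F",
                     productive = TRUE, templates = 1L)
  expect_error(RepertoireSample("x", "s", "pre_tx", "pbmc", "bulk", tab2),
               "amino-acid")
  tab2$productive <- FALSE
  expect_s4_class(RepertoireSample("x", "s", "pre_tx", "pbmc", "bulk", tab2),
                  "RepertoireSample")
})

test_that("manifests validate ids, labels, combinations and files", {
  dir <- tempfile(); dir.create(dir)
  for (f in c("a.tsv", "b.tsv", "c.tsv", "d.tsv"))
    writeClonotypeTable(exampleSample(c(AAA = 5L)), file.path(dir, f))
  man <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    path = c("a.tsv", "b.tsv", "c.tsv", "d.tsv"),
    subject_id = "SUBJ", timepoint = c("pre_tx", "pre_tx", "m3", "wk2"),
    compartment = c("pbmc", "mlr_sort", "pbmc", "urine"),
    subset = c("bulk", "cd4", "bulk", "bulk"),
    induction_group = "campath", biopsy_status = "stable")
  mp <- file.path(dir, "manifest.tsv")
  write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- readManifest(mp)
  expect_equal(nrow(m), 4L)
  expect_true(all(file.exists(m$path)))
  samples <- loadManifestSamples(m)
  expect_named(samples, c("s1", "s2", "s3", "s4"))

  bad <- man; bad$sample_id[2] <- "s1"
  write.table(bad, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readManifest(mp), "s1")

  bad <- man; bad$compartment[1] <- "plasma"
  write.table(bad, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readManifest(mp), "plasma")

  bad <- man; bad$path[3] <- "missing.tsv"
  write.table(bad, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readManifest(mp), "missing.tsv")

  bad <- man; bad$timepoint[2] <- "pre_tx"; bad$compartment[2] <- "pbmc"
  bad$subset[2] <- "bulk"
  write.table(bad, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readManifest(mp), "combination")
})
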