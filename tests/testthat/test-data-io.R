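test_that("count matrix TSV and MatrixMarket round-trips are exact", {
  m <- matrix(0:5, 2, 3, dimnames = list(c("g1", "g2"),
                                         c("s1", "s2", "s3")))
  storage.mode(m) <- "integer"
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(m, tf)
  expect_identical(readCountMatrix(tf), m)

  des <- trioDesign(3)
  big <- randomCounts(50, des, seed = 42)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(big, tf2)
  expect_identical(readCountMatrix(tf2), big)

  mf <- withr::local_tempfile(fileext = ".mtx")
  writeCountMatrix(big, mf, format = "mtx")
  expect_identical(readCountMatrix(mf, format = "mtx"), big)
})

test_that("malformed count input is rejected with named errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t5\t-3", "g2\t1\t2"), tf)
  err <- tryCatch(readCountMatrix(tf), error = identity)
  expect_s3_class(err, "triohet_error_invalid_count")
  expect_match(conditionMessage(err), "g1")
  expect_match(conditionMessage(err), "s2")

  writeLines(c("gene_id\ts1", "g1\t1.5"), tf)
  expect_s3_class(tryCatch(readCountMatrix(tf), error = identity),
                  "triohet_error_invalid_count")
  writeLines(c("gene_id\ts1", "g1\tNA"), tf)
  expect_s3_class(tryCatch(readCountMatrix(tf), error = identity),
                  "triohet_error_invalid_count")
  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), tf)
  expect_s3_class(tryCatch(readCountMatrix(tf), error = identity),
                  "triohet_error_duplicate_id")
  expect_s3_class(tryCatch(readCountMatrix("no/such/file.tsv"),
                           error = identity),
                  "triohet_error_missing_file")
})

test_that("design reader parses roles and rejects unknown ones", {
  des <- trioDesign(3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeDesign(des, tf)
  rt <- readDesign(tf)
  expect_equal(nrow(rt), 9L)
  expect_equal(unname(table(rt$role)[c("female_parent", "male_parent",
                                       "hybrid")]),
               rep(3L, 3), ignore_attr = TRUE)

  bad <- des; bad$role[1] <- "parent3"
  write.table(bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(tryCatch(readDesign(tf), error = identity),
                  "triohet_error_unknown_role")
  dup <- des; dup$sample_id[2] <- dup$sample_id[1]
  write.table(dup, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(tryCatch(readDesign(tf), error = identity),
                  "triohet_error_duplicate_id")
})

test_that("design x counts cross-validation catches missing samples", {
  des <- trioDesign(2)
  m <- randomCounts(5, des)
  extra <- rbind(des, data.frame(sample_id = "X_1", role = "hybrid",
                                 replicate = 3L))
  err <- tryCatch(TrioExperiment(m, extra), error = identity)
  expect_s3_class(err, "triohet_error_design_mismatch")
  expect_match(conditionMessage(err), "X_1")
})

test_that("GMT and two-column annotations of the same mapping agree", {
  gf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc one\tg1\tg2", "T2\tdesc two\tg2\tg3\tg2"), gf)
  a1 <- readAnnotation(gf, "gmt")
  expect_setequal(geneSets(a1)$T1, c("g1", "g2"))
  expect_setequal(geneSets(a1)$T2, c("g2", "g3"))   # duplicate collapsed
  expect_length(geneSets(a1)$T2, 2L)

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tterm_id", "g1\tT1", "g2\tT1", "g2\tT2", "g3\tT2"),
             tf)
  a2 <- readAnnotation(tf, "tsv2col")
  expect_setequal(termIds(a2), termIds(a1))
  for (id in termIds(a1))
    expect_setequal(geneSets(a2)[[id]], geneSets(a1)[[id]])

  writeLines(c("T1\tonly-description"), gf)
  err <- tryCatch(readAnnotation(gf, "gmt"), error = identity)
  expect_s3_class(err, "triohet_error_malformed")
  expect_match(conditionMessage(err), "line 1")
})

test_that("annotation GMT write -> read is the identity", {
  ann <- TermAnnotation(list(A = c("g1", "g2"), B = c("g3")),
                        c("set a", "set b"))
  gf <- withr::local_tempfile(fileext = ".gmt")
  writeAnnotationGmt(ann, gf)
  rt <- readAnnotation(gf, "gmt")
  expect_identical(geneSets(rt), geneSets(ann))
  expect_identical(unname(termNames(rt)), unname(termNames(ann)))
})

test_that("TrioExperiment validity rejects bad inputs and shows design", {
  des <- trioDesign(2)
  m <- randomCounts(4, des)
  x <- TrioExperiment(m, des)
  expect_s4_class(x, "TrioExperiment")
  expect_equal(as.character(sampleRoles(x)), des$role)
  expect_output(show(x), "female_parent=2")
  bad <- m; bad[1, 1] <- -1L
  expect_error(TrioExperiment(bad, des), "negative")
})
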