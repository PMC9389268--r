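test_that("classification agrees with the exhaustive 27-trio truth table", {
  tt <- patternTruthTable()
  got <- classifyPattern(tt$sHF, tt$sHM, tt$sFM)
  expect_equal(as.character(got), tt$expected)
  # the partition: 12 patterns + conserved cover 13 trios, 14 are ambiguous
  expect_equal(sum(tt$expected == "ambiguous"), 14L)
  expect_equal(length(unique(tt$expected)), 14L)
  counts <- table(tt$expected)
  expect_true(all(counts[setdiff(names(counts), "ambiguous")] == 1L))
})

test_that("swapping the parents permutes the patterns as expected", {
  tt <- patternTruthTable()
  flip <- c(minus = "plus", zero = "zero", plus = "minus")
  swapMap <- c(P1 = "P2", P2 = "P1", P3 = "P6", P6 = "P3", P4 = "P5",
               P5 = "P4", P7 = "P9", P9 = "P7", P8 = "P8",
               P10 = "P12", P12 = "P10", P11 = "P11",
               conserved = "conserved", ambiguous = "ambiguous")
  orig <- as.character(classifyPattern(tt$sHF, tt$sHM, tt$sFM))
  # parent swap: s_HF and s_HM exchange, s_FM reverses direction
  swapped <- as.character(classifyPattern(tt$sHM, tt$sHF,
                                          unname(flip[tt$sFM])))
  expect_equal(swapped, unname(swapMap[orig]))
})

test_that("pattern-to-category mapping is total and fixed", {
  pats <- paste0("P", 1:12)
  expect_equal(as.character(patternCategory5(pats)),
               c("additive", "additive",
                 "paternal_dominant", "paternal_dominant",
                 "maternal_dominant", "maternal_dominant",
                 rep("below_low_parent", 3), rep("above_high_parent", 3)))
  expect_equal(as.character(patternCategory3(pats)),
               c(rep("additive", 2), rep("dominant", 4),
                 rep("over_dominant", 6)))
  expect_equal(as.character(patternCategory3(c("conserved", "ambiguous"))),
               c("none", "none"))
})

test_that("sign trios orient themselves from contrast metadata", {
  x <- twoGroupExperiment(50, n = 3, muA = 100,
                          muB = c(rep(800, 25), rep(100, 25)), seed = 14)
  # add a hybrid group equal to the female parent
  m <- trioCounts(x)
  set.seed(15)
  h <- matrix(rnbinom(50 * 3, mu = rowMeans(m[, 1:3]), size = 20), 50, 3)
  m2 <- cbind(m, h)
  colnames(m2) <- c(colnames(m), paste0("H_", 1:3))
  des <- rbind(data.frame(sample_id = colnames(m),
                          role = as.character(sampleRoles(x)),
                          replicate = rep(1:3, 2)),
               data.frame(sample_id = paste0("H_", 1:3), role = "hybrid",
                          replicate = 1:3))
  xt <- TrioExperiment(m2, des)
  deHF <- deTest(xt, contrastSpec("hybrid", "female_parent"))
  deHM <- deTest(xt, contrastSpec("hybrid", "male_parent"))
  deFM <- deTest(xt, contrastSpec("female_parent", "male_parent"))
  # same contrasts fitted the other way round must give identical trios
  deHFr <- deTest(xt, contrastSpec("female_parent", "hybrid"))
  deFMr <- deTest(xt, contrastSpec("male_parent", "female_parent"))
  for (g in c("g00001", "g00030")) {
    expect_identical(signTrio(deHF, deHM, deFM, g),
                     signTrio(deHFr, deHM, deFMr, g))
  }
  expect_s3_class(tryCatch(signTrio(deHF, deHM, deFM, "nope"),
                           error = identity), "triohet_error_gene_mismatch")
  # a gene where H = F < M: hybrid matches the female parent (maternal)
  asg <- assignPatterns(deHF, deHM, deFM)
  g1 <- as.data.frame(asg[asg$gene_id == "g00001", ])
  expect_equal(as.character(g1$pattern), "P5")
  expect_equal(as.character(g1$category5), "maternal_dominant")
})

test_that("pattern summaries report counts and proportions correctly", {
  asg <- S4Vectors::DataFrame(
    gene_id = sprintf("g%02d", 1:12),
    pattern = c("P1", rep("P3", 3), rep("P10", 6), "conserved",
                "ambiguous"))
  asg$category5 <- patternCategory5(asg$pattern)
  asg$category3 <- patternCategory3(asg$pattern)
  s <- summarizePatterns(asg)
  expect_equal(s$n_classified, 10L)
  expect_equal(s$n_total, 12L)
  c3 <- setNames(s$category3$proportion, s$category3$label)
  expect_equal(c3[["additive"]], 0.10)
  expect_equal(c3[["dominant"]], 0.30)
  expect_equal(c3[["over_dominant"]], 0.60)
  expect_equal(sum(c3[c("additive", "dominant", "over_dominant")]), 1,
               tolerance = 1e-12)

  allCons <- S4Vectors::DataFrame(gene_id = "g1", pattern = "conserved")
  allCons$category5 <- patternCategory5(allCons$pattern)
  allCons$category3 <- patternCategory3(allCons$pattern)
  expect_warning(s0 <- summarizePatterns(allCons), "no classified")
  expect_true(all(is.na(s0$category3$proportion)))
  expect_equal(s0$n_classified, 0L)
})
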