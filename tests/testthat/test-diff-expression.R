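test_that("identical groups give log2fc 0 and p 1", {
  des <- trioDesign(3)[1:6, ]           # two parents only
  m <- randomCounts(30, des[1:3, ], mu = 60, seed = 3)
  m <- cbind(m, m)                       # male group duplicates female group
  colnames(m) <- des$sample_id
  x <- TrioExperiment(m, des)
  for (method in c("nb_wald", "welch_log")) {
    res <- deTest(x, contrastSpec("male_parent", "female_parent"),
                  method = method)
    expect_equal(res$log2fc, rep(0, nrow(res)))
    expect_equal(res$p, rep(1, nrow(res)))
    expect_true(all(res$call == "ns"))
  }
})

test_that("swapping contrast orientation negates log2fc, keeps p", {
  x <- twoGroupExperiment(100, n = 4, muA = 100, muB = 100, seed = 11)
  a <- deTest(x, contrastSpec("male_parent", "female_parent"))
  b <- deTest(x, contrastSpec("female_parent", "male_parent"))
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p, a$p)
})

test_that("calls are invariant to a global library-size multiple", {
  set.seed(21)
  mu <- exp(runif(300, log(30), log(800)))
  x <- twoGroupExperiment(300, n = 4, muA = mu,
                          muB = mu * rep(c(1, 4), length.out = 300),
                          seed = 21)
  res1 <- deTest(x, contrastSpec("male_parent", "female_parent"))
  des <- data.frame(sample_id = colnames(x),
                    role = as.character(sampleRoles(x)),
                    replicate = rep(1:4, 2))
  x3 <- TrioExperiment(trioCounts(x) * 3L, des)
  res3 <- deTest(x3, contrastSpec("male_parent", "female_parent"))
  expect_gte(mean(res1$call == res3$call), 0.98)
})

test_that("untested genes are flagged, not silently dropped", {
  des <- trioDesign(2)[1:4, ]
  m <- randomCounts(10, des, mu = 40, seed = 8)
  m[3, ] <- 0L
  x <- TrioExperiment(m, des)
  res <- deTest(x, contrastSpec("male_parent", "female_parent"))
  expect_equal(res$call[3], "untested")
  expect_true(is.na(res$p[3]))
  expect_equal(nrow(res), 10L)
})

test_that("replicate and group preconditions are enforced", {
  des <- trioDesign(2)
  m <- randomCounts(5, des)
  x <- TrioExperiment(m, des)
  oneRep <- TrioExperiment(m[, c(1, 3, 4)], des[c(1, 3, 4), ])
  expect_s3_class(tryCatch(
    deTest(oneRep, contrastSpec("male_parent", "female_parent")),
    error = identity), "triohet_error_replicates")
  parentsOnly <- TrioExperiment(m[, 1:4], des[1:4, ])
  expect_s3_class(tryCatch(
    deTest(parentsOnly, contrastSpec("hybrid", "female_parent")),
    error = identity), "triohet_error_missing_group")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(1.0), 1.0)
  set.seed(12)
  for (i in 1:5) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_equal(q, bruteForceBH(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # nondecreasing in p rank
  }
  expect_s3_class(tryCatch(bhAdjust(c(0.5, 1.2)), error = identity),
                  "triohet_error_argument")
})

test_that("DEG calling applies the p and fold-change thresholds", {
  res <- S4Vectors::DataFrame(gene_id = c("a", "b", "c", "d"),
                              log2fc = log2(c(3, 1.5, 10, 1/3)),
                              p = c(0.01, 0.01, 0.2, 0.04),
                              q = c(0.02, 0.02, 0.3, 0.08))
  out <- callDEGs(res)
  expect_equal(out$call, c("up", "ns", "ns", "down"))
  outQ <- callDEGs(res, useQ = TRUE)
  expect_equal(outQ$call, c("up", "ns", "ns", "ns"))
  expect_s3_class(tryCatch(callDEGs(res, fcThresh = 1), error = identity),
                  "triohet_error_argument")
})

test_that("DEG sets shrink monotonically as the fold threshold rises", {
  set.seed(5)
  mu <- exp(runif(400, log(20), log(500)))
  fcs <- rep(c(1, 2, 4, 8), length.out = 400)
  x <- twoGroupExperiment(400, n = 3, muA = mu, muB = mu * fcs, seed = 5)
  res <- deTest(x, contrastSpec("male_parent", "female_parent"))
  at2 <- degSet(callDEGs(res, fcThresh = 2))
  at4 <- degSet(callDEGs(res, fcThresh = 4))
  expect_true(all(at4 %in% at2))
  expect_lt(length(at4), length(at2))
})

test_that("Venn region counts match brute-force membership enumeration", {
  oc <- overlapCounts(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                           C = "3"))
  expect_equal(oc$regions[["A&B&C"]], 1L)
  expect_equal(oc$regions[["A"]], 1L)
  expect_equal(oc$regions[["B"]], 1L)
  expect_equal(oc$regions[["A&B"]], 1L)
  expect_equal(oc$totals, c(A = 3L, B = 3L, C = 1L))

  disj <- overlapCounts(list(A = "x", B = "y"))
  expect_equal(disj$regions[["A&B"]], 0L)

  set.seed(77)
  for (i in 1:3) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(j)
      sample(letters, sample(3:15, 1)))
    names(sets) <- LETTERS[seq_len(k)]
    oc <- overlapCounts(sets)
    # oracle: classify each universe element by its exact membership vector
    uni <- unique(unlist(sets))
    key <- vapply(uni, function(g)
      paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
            collapse = "&"), "")
    for (r in names(oc$regions))
      expect_equal(oc$regions[[r]], sum(key == r), ignore_attr = TRUE)
    expect_equal(sum(oc$regions), length(uni))
  }
  expect_s3_class(tryCatch(overlapCounts(list(a = "x")), error = identity),
                  "triohet_error_argument")
})

test_that("nb_wald agrees with an established NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(99)
  mu <- exp(runif(200, log(50), log(1000)))
  fcs <- rep(c(1, 1, 4, 1/4), length.out = 200)
  x <- twoGroupExperiment(200, n = 4, muA = mu, muB = mu * fcs, seed = 99)
  res <- deTest(x, contrastSpec("male_parent", "female_parent"))
  cond <- factor(as.character(sampleRoles(x)),
                 levels = c("female_parent", "male_parent"))
  dds <- DESeq2::DESeqDataSetFromMatrix(trioCounts(x),
                                        S4Vectors::DataFrame(cond = cond),
                                        ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dr <- DESeq2::results(dds)
  expect_gt(cor(res$log2fc, dr$log2FoldChange, use = "complete.obs"), 0.95)
  strong <- !is.na(dr$padj) & dr$padj < 0.01 & abs(dr$log2FoldChange) > 1
  ours <- res$call %in% c("up", "down")
  expect_gt(mean(ours[strong]), 0.9)
})
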