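# shared in-code fixtures; nothing is stored on disk

trioDesign <- function(nReps = 3L) {
  data.frame(
    sample_id = paste0(rep(c("F", "M", "H"), each = nReps), "_",
                       rep(seq_len(nReps), 3L)),
    role = rep(c("female_parent", "male_parent", "hybrid"), each = nReps),
    replicate = rep(seq_len(nReps), 3L))
}

randomCounts <- function(nGenes, design, mu = 50, seed = 1L) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nrow(design), mu), nGenes, nrow(design),
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              design$sample_id))
  storage.mode(m) <- "integer"
  m
}

# two-group experiment (female vs male parent) with per-gene NB counts,
# used by the DE tests; muB defaults to muA (global null)
twoGroupExperiment <- function(nGenes, n, muA, muB = muA, dispersion = 0.05,
                               seed = 1L) {
  set.seed(seed)
  muA <- rep_len(muA, nGenes); muB <- rep_len(muB, nGenes)
  des <- data.frame(
    sample_id = c(paste0("F_", seq_len(n)), paste0("M_", seq_len(n))),
    role = rep(c("female_parent", "male_parent"), each = n),
    replicate = rep(seq_len(n), 2L))
  m <- cbind(
    matrix(rnbinom(nGenes * n, mu = muA, size = 1 / dispersion), nGenes, n),
    matrix(rnbinom(nGenes * n, mu = muB, size = 1 / dispersion), nGenes, n))
  dimnames(m) <- list(sprintf("g%05d", seq_len(nGenes)), des$sample_id)
  TrioExperiment(m, des)
}

# literal 27-row trio -> pattern truth table, written by hand from the
# classification's defining orderings (independent of the implementation)
patternTruthTable <- function() {
  g <- expand.grid(sHF = c("minus", "zero", "plus"),
                   sHM = c("minus", "zero", "plus"),
                   sFM = c("minus", "zero", "plus"),
                   stringsAsFactors = FALSE)
  expected <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    hf <- g$sHF[i]; hm <- g$sHM[i]; fm <- g$sFM[i]
    expected[i] <-
      if (hf == "zero" && hm == "zero" && fm == "zero") "conserved"
      else if (hf == "minus" && hm == "plus" && fm == "plus") "P1"
      else if (hf == "plus" && hm == "minus" && fm == "minus") "P2"
      else if (hf == "plus" && hm == "zero" && fm == "minus") "P3"
      else if (hf == "minus" && hm == "zero" && fm == "plus") "P4"
      else if (hf == "zero" && hm == "minus" && fm == "minus") "P5"
      else if (hf == "zero" && hm == "plus" && fm == "plus") "P6"
      else if (hf == "minus" && hm == "minus" && fm == "plus") "P7"
      else if (hf == "minus" && hm == "minus" && fm == "zero") "P8"
      else if (hf == "minus" && hm == "minus" && fm == "minus") "P9"
      else if (hf == "plus" && hm == "plus" && fm == "plus") "P10"
      else if (hf == "plus" && hm == "plus" && fm == "zero") "P11"
      else if (hf == "plus" && hm == "plus" && fm == "minus") "P12"
      else "ambiguous"
  }
  g$expected <- expected
  g
}

# literal O(m^2) Benjamini-Hochberg step-up, independent of p.adjust
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, 1.0)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
enumHyperTail <- function(k, n, M, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  hits <- colSums(draws <= M)          # genes 1..M carry the annotation
  mean(hits >= k)
}
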