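## planted mean structure: per pattern, exponents (in effect-size units) of
## the female-parent, hybrid and male-parent means above the gene's baseline
PATTERN_EXPONENTS <- list(
  conserved = c(0, 0, 0),
  P1  = c(2, 1, 0), P2  = c(0, 1, 2),
  P3  = c(0, 1, 1), P4  = c(1, 0, 0),
  P5  = c(0, 0, 1), P6  = c(1, 1, 0),
  P7  = c(2, 0, 1), P8  = c(1, 0, 1), P9  = c(1, 0, 2),
  P10 = c(1, 2, 0), P11 = c(0, 1, 0), P12 = c(0, 2, 1))

#' Configuration for the trio count simulator
#'
#' Defaults emulate a replicated trio RNA-seq experiment: three genotypes
#' (two inbred parents, one hybrid) with \code{nReps} biological replicates
#' each, negative-binomial counts with variance \eqn{\mu + d\mu^2},
#' log-normal baseline expression, log-uniform library-size variation and
#' log-uniform gene lengths.  Pattern fractions plant ground-truth
#' inheritance patterns; the default fractions make 60\% of
#' differentially expressed genes over-dominant, 30\% dominant and 10\%
#' additive (the structure reported for strongly heterotic trios), with
#' 40\% of all genes conserved.
#'
#' @param nGenes number of genes (default 500).
#' @param nReps replicates per genotype (default 3).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of the
#'   baseline (lowest-level) mean count per gene.
#' @param dispersion NB dispersion d in \code{var = mu + d mu^2}
#'   (constant; default 0.05).
#' @param dispersionShape optional gamma shape; when given, per-gene
#'   dispersions are gamma with mean \code{dispersion}.
#' @param patternFractions named fractions over P1..P12 and
#'   \code{conserved}, summing to 1.
#' @param effectSize log2 separation between adjacent planted expression
#'   levels (default 2).
#' @param librarySizeRange relative depth factors, drawn log-uniform.
#' @param geneLengthRange gene lengths in bp, drawn log-uniform.
#' @param seed integer seed, mandatory: identical configs reproduce
#'   bitwise-identical data.
#' @return validated list of class \code{"trioSimConfig"}.
#' @export
simConfig <- function(nGenes = 500L, nReps = 3L,
                      baselineMeanlog = log(100), baselineSdlog = 1,
                      dispersion = 0.05, dispersionShape = NULL,
                      patternFractions = NULL, effectSize = 2,
                      librarySizeRange = c(0.5, 2),
                      geneLengthRange = c(200, 10000),
                      seed) {
  if (missing(seed) || is.null(seed))
    .stopf("argument", "a seed is mandatory for reproducible simulation")
  if (is.null(patternFractions))
    patternFractions <- c(conserved = 0.40,
                          P1 = 0.03, P2 = 0.03,
                          P3 = 0.045, P4 = 0.045, P5 = 0.045, P6 = 0.045,
                          P7 = 0.06, P8 = 0.06, P9 = 0.06,
                          P10 = 0.06, P11 = 0.06, P12 = 0.06)
  bad <- setdiff(names(patternFractions), names(PATTERN_EXPONENTS))
  if (length(bad))
    .stopf("invalid_fractions", "unknown pattern(s): %s",
           paste(bad, collapse = ", "))
  if (any(patternFractions < 0) ||
      abs(sum(patternFractions) - 1) > 1e-9)
    .stopf("invalid_fractions",
           "pattern fractions must be non-negative and sum to 1")
  if (effectSize <= 0) .stopf("argument", "effectSize must be > 0")
  if (dispersion <= 0) .stopf("argument", "dispersion must be > 0")
  structure(list(nGenes = as.integer(nGenes), nReps = as.integer(nReps),
                 baselineMeanlog = baselineMeanlog,
                 baselineSdlog = baselineSdlog,
                 dispersion = dispersion,
                 dispersionShape = dispersionShape,
                 patternFractions = patternFractions,
                 effectSize = effectSize,
                 librarySizeRange = librarySizeRange,
                 geneLengthRange = geneLengthRange,
                 seed = as.integer(seed)),
            class = "trioSimConfig")
}

#' Simulate a trio count matrix with known inheritance patterns
#'
#' Each gene gets a planted pattern (multinomial-free: exact counts by
#' largest remainder, then shuffled), a baseline mean, and genotype means
#' separated by \code{effectSize} log2 units according to the pattern's
#' ordering (e.g. P11 plants equal parents with the hybrid one effect size
#' above; P1 plants female > hybrid > male).  Counts are NB with
#' \code{var = mu + d mu^2}, means scaled by each sample's library factor.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{experiment} (a [TrioExperiment-class] with gene
#'   lengths), \code{truth} (DataFrame: gene_id, pattern, mu_f, mu_h, mu_m,
#'   dispersion), \code{libFactors} and \code{config}.
#' @export
simulateTrio <- function(cfg) {
  stopifnot(inherits(cfg, "trioSimConfig"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- cfg$nGenes
  ## exact planted counts by largest remainder
  fr <- cfg$patternFractions
  raw <- fr * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  pattern <- sample(rep(names(fr), cnt))
  gid <- sprintf("g%05d", seq_len(n))
  mu0 <- stats::rlnorm(n, cfg$baselineMeanlog, cfg$baselineSdlog)
  disp <- if (is.null(cfg$dispersionShape)) rep(cfg$dispersion, n)
          else stats::rgamma(n, shape = cfg$dispersionShape,
                             rate = cfg$dispersionShape / cfg$dispersion)
  disp <- pmax(disp, 1e-6)
  expo <- do.call(rbind, PATTERN_EXPONENTS[pattern])
  muF <- mu0 * 2^(cfg$effectSize * expo[, 1L])
  muH <- mu0 * 2^(cfg$effectSize * expo[, 2L])
  muM <- mu0 * 2^(cfg$effectSize * expo[, 3L])

  roles <- rep(TRIO_ROLES, each = cfg$nReps)
  sid <- paste0(rep(c("F", "M", "H"), each = cfg$nReps),
                "_", rep(seq_len(cfg$nReps), 3L))
  lib <- exp(stats::runif(length(sid), log(cfg$librarySizeRange[1L]),
                          log(cfg$librarySizeRange[2L])))
  names(lib) <- sid
  muRole <- cbind(female_parent = muF, male_parent = muM, hybrid = muH)
  counts <- matrix(0L, n, length(sid), dimnames = list(gid, sid))
  for (s in seq_along(sid))
    counts[, s] <- stats::rnbinom(n, mu = muRole[, roles[s]] * lib[s],
                                  size = 1 / disp)
  lengths <- data.frame(
    gene_id = gid,
    length_bp = as.integer(round(exp(stats::runif(
      n, log(cfg$geneLengthRange[1L]), log(cfg$geneLengthRange[2L]))))))
  design <- data.frame(sample_id = sid, role = roles,
                       replicate = rep(seq_len(cfg$nReps), 3L))
  truth <- DataFrame(gene_id = gid, pattern = pattern,
                     mu_f = muF, mu_h = muH, mu_m = muM,
                     dispersion = disp)
  list(experiment = TrioExperiment(counts, design, lengths),
       truth = truth, libFactors = lib, config = cfg)
}

#' Simulate phenotype replicates around planted genotype means
#'
#' Log-normal replicates with coefficient of variation \code{cv} around
#' each genotype mean; at \code{cv = 0} replicates equal the means exactly,
#' so [heterosisIndices()] on replicate means recovers the planted
#' heterosis without error.
#'
#' @param f1Mean,pfMean,pmMean planted genotype means (> 0).
#' @param cv coefficient of variation (>= 0; default 0.05).
#' @param nReps replicates per genotype (default 3).
#' @param seed integer seed.
#' @return data.frame with columns role, replicate, value.
#' @export
simulatePhenotype <- function(f1Mean, pfMean, pmMean, cv = 0.05,
                              nReps = 3L, seed) {
  if (any(c(f1Mean, pfMean, pmMean) <= 0))
    .stopf("argument", "phenotype means must be > 0")
  if (cv < 0) .stopf("argument", "cv must be >= 0")
  set.seed(as.integer(seed))
  means <- c(female_parent = pfMean, male_parent = pmMean,
             hybrid = f1Mean)
  draw <- function(m) {
    if (cv == 0) return(rep(m, nReps))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(nReps, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(role = rep(names(means), each = nReps),
             replicate = rep(seq_len(nReps), 3L),
             value = unlist(lapply(means, draw), use.names = FALSE))
}

#' Write the pinned demonstration dataset
#'
#' Generates a 500-gene, 3x3-replicate trio with the default planted
#' pattern fractions (seed 101) plus a term annotation containing one term
#' drawn entirely from planted above-high-parent genes (so it must come out
#' over-represented in the over-dominant DEG list) and 20 random decoy
#' terms, and writes everything as the same plain-text formats the readers
#' accept.  Identical calls reproduce byte-identical files.
#'
#' @param outdir writable output directory (created if needed).
#' @param seed integer seed (default 101).
#' @param nGenes,nReps dataset size (defaults 500 genes, 3 replicates).
#' @return named character vector of the written paths, invisibly.
#' @export
defaultFixture <- function(outdir, seed = 101L, nGenes = 500L,
                           nReps = 3L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- simConfig(nGenes = nGenes, nReps = nReps, seed = seed)
  sim <- simulateTrio(cfg)
  x <- sim$experiment
  ## annotation: one planted term from above-high-parent genes + decoys
  gid <- rownames(x)
  over <- gid[sim$truth$pattern %in% c("P10", "P11", "P12")]
  planted <- over[seq_len(min(25L, length(over)))]
  sets <- list(T_PLANTED = planted)
  nTerm <- 20L
  sizes <- sample(10:50, nTerm, replace = TRUE)
  for (i in seq_len(nTerm))
    sets[[sprintf("T%03d", i)]] <- sample(gid, sizes[i])
  ann <- TermAnnotation(sets, c("planted over-represented set",
                                sprintf("random decoy set %d",
                                        seq_len(nTerm))))
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             design = file.path(outdir, "design.tsv"),
             lengths = file.path(outdir, "gene_lengths.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             annotation = file.path(outdir, "annotation.gmt"),
             config = file.path(outdir, "sim_config.yaml"))
  writeCountMatrix(trioCounts(x), paths[["counts"]])
  writeDesign(data.frame(sample_id = colnames(x),
                         role = as.character(sampleRoles(x)),
                         replicate = colData(x)$replicate),
              paths[["design"]])
  writeGeneLengths(data.frame(gene_id = rownames(x),
                              length_bp = geneLengths(x)),
                   paths[["lengths"]])
  .writeTsv(as.data.frame(sim$truth), paths[["truth"]])
  writeAnnotationGmt(ann, paths[["annotation"]])
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                   paths[["config"]])
  invisible(paths)
}
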