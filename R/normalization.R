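#' Fragments per kilobase per million mapped fragments
#'
#' \code{FPKM[g,s] = counts[g,s] * 1e9 / (totals[s] * length_bp[g])}.
#' The effective length is the annotated gene length; totals default to the
#' column sums of the count matrix (the only library-size measure available
#' downstream of a count matrix), and can be overridden with externally
#' supplied totals of mapped fragments.
#'
#' @param x a [TrioExperiment-class] with gene lengths, or a count matrix.
#' @param lengths per-gene lengths in bp (required when \code{x} is a
#'   matrix; taken from \code{rowData} otherwise).
#' @param totals optional per-sample positive totals, named by sample.
#' @return a numeric matrix of FPKM values, same dimnames as the counts.
#' @examples
#' # 100 fragments on a 2 kb gene in a library of 1e6 -> FPKM 50
#' computeFPKM(matrix(100L, 1, 1, dimnames = list("g", "s")),
#'             lengths = 2000, totals = 1e6)
#' @export
computeFPKM <- function(x, lengths = NULL, totals = NULL) {
  if (is(x, "TrioExperiment")) {
    m <- trioCounts(x)
    if (is.null(lengths)) lengths <- geneLengths(x)
  } else m <- as.matrix(x)
  if (is.null(lengths))
    .stopf("missing_length", "gene lengths are required for FPKM")
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(m) || anyNA(lengths) || any(lengths <= 0))
    .stopf("missing_length",
           "need one strictly positive length per gene (%d genes)", nrow(m))
  if (is.null(totals)) totals <- colSums(m)
  totals <- as.numeric(totals)
  if (length(totals) != ncol(m) || any(!is.finite(totals)) ||
      any(totals <= 0))
    .stopf("zero_total", "per-sample totals must all be positive")
  fpkm <- sweep(m / lengths, 2L, totals, "/") * 1e9
  dimnames(fpkm) <- dimnames(m)
  fpkm
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' \code{counts[g,s] / geomean_g}, where \code{geomean_g} is the geometric
#' mean of gene g across samples and reference genes are those with nonzero
#' counts in every sample.  Factors are rescaled to geometric mean 1, so a
#' sample sequenced twice as deeply gets a factor sqrt(2) larger relative
#' to its partner in a two-sample comparison.
#'
#' @param x a [TrioExperiment-class] or count matrix.
#' @return named positive numeric vector, geometric mean 1.
#' @export
sizeFactorsMedianRatio <- function(x) {
  m <- if (is(x, "TrioExperiment")) trioCounts(x) else as.matrix(x)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    .stopf("no_reference_gene",
           "no gene has nonzero counts in every sample")
  lm <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lm)
  sf <- apply(exp(lm - geo), 2L, stats::median)
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Expression-presence filter
#'
#' A gene counts as expressed within a genotype when its mean FPKM over
#' that genotype's replicates exceeds \code{minFpkm}.  With
#' \code{scope = "all_genotypes"} (the default) a gene is kept only when
#' expressed in the female parent, the male parent and the hybrid
#' simultaneously; \code{"any_genotype"} keeps genes expressed anywhere.
#'
#' @param fpkm FPKM matrix (genes x samples) as from [computeFPKM()].
#' @param design design data.frame (or a [TrioExperiment-class], from which
#'   the design is taken).
#' @param minFpkm detection threshold, FPKM units; mean must be strictly
#'   greater.  Default 0.
#' @param scope \code{"all_genotypes"} or \code{"any_genotype"}.
#' @return character vector of kept gene ids.
#' @export
filterExpressed <- function(fpkm, design, minFpkm = 0,
                            scope = c("all_genotypes", "any_genotype")) {
  scope <- match.arg(scope)
  if (minFpkm < 0) .stopf("argument", "minFpkm must be >= 0")
  if (is(design, "TrioExperiment"))
    design <- data.frame(sample_id = colnames(design),
                         role = as.character(sampleRoles(design)),
                         replicate = colData(design)$replicate)
  design <- .validateDesign(design)
  missing <- setdiff(design$sample_id, colnames(fpkm))
  if (length(missing))
    .stopf("design_mismatch", "design sample(s) absent from FPKM matrix: %s",
           paste(missing, collapse = ", "))
  roles <- unique(design$role)
  means <- vapply(roles, function(r) {
    cols <- design$sample_id[design$role == r]
    rowMeans(fpkm[, cols, drop = FALSE])
  }, numeric(nrow(fpkm)))
  keep <- if (scope == "all_genotypes")
    rowSums(means > minFpkm) == length(roles)
  else rowSums(means > minFpkm) > 0
  rownames(fpkm)[keep]
}
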