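#' Specify a pairwise genotype contrast
#'
#' A contrast compares the \code{numerator} genotype against the
#' \code{denominator}: positive log2 fold changes and "up" calls mean the
#' numerator group is higher.  The default label follows the
#' \code{<numerator>_vs_<denominator>} convention (e.g. \code{H_vs_F} for
#' hybrid over female parent).
#'
#' @param numerator,denominator genotype roles (distinct), each one of
#'   \code{"female_parent"}, \code{"male_parent"}, \code{"hybrid"}.
#' @param label optional label; defaults to abbreviated roles.
#' @return a list of class \code{"trioContrast"}.
#' @export
contrastSpec <- function(numerator, denominator, label = NULL) {
  numerator <- match.arg(numerator, TRIO_ROLES)
  denominator <- match.arg(denominator, TRIO_ROLES)
  if (numerator == denominator)
    .stopf("argument", "contrast groups must differ")
  abbrev <- c(female_parent = "F", male_parent = "M", hybrid = "H")
  if (is.null(label))
    label <- paste0(abbrev[[numerator]], "_vs_", abbrev[[denominator]])
  structure(list(numerator = numerator, denominator = denominator,
                 label = label), class = "trioContrast")
}

#' The three canonical trio contrasts
#'
#' Hybrid vs each parent (hybrid as numerator) and female vs male parent.
#'
#' @return named list of [contrastSpec()] objects
#'   \code{H_vs_F}, \code{H_vs_M}, \code{F_vs_M}.
#' @export
trioContrasts <- function() {
  cs <- list(contrastSpec("hybrid", "female_parent"),
             contrastSpec("hybrid", "male_parent"),
             contrastSpec("female_parent", "male_parent"))
  names(cs) <- vapply(cs, `[[`, "", "label")
  cs
}

#' Pairwise differential expression between genotype groups
#'
#' Counts are normalized internally by median-of-ratios size factors
#' (computed on all samples of \code{x}).  Genes with zero counts in every
#' sample of both groups are excluded from testing and reported with
#' \code{call = "untested"}.
#'
#' Method \code{"nb_wald"} fits a per-gene negative binomial
#' (variance \eqn{\mu + d\mu^2}): the dispersion d is a method-of-moments
#' estimate pooled across the two groups and floored at 1e-8, and the Wald
#' statistic on the difference of log group means (pseudocount 1, delta-method
#' standard error) is referred to a t distribution with
#' \eqn{n_1 + n_2 - 2} degrees of freedom, which keeps the test close to
#' nominal size at the small replicate numbers typical of trio designs.
#' Method \code{"welch_log"} is a Welch t-test on \code{log2(normalized
#' count + 1)}; zero-variance genes get p = 1.
#'
#' @param x a [TrioExperiment-class].
#' @param contrast a [contrastSpec()] (or a character pair
#'   \code{c(numerator, denominator)} of roles).
#' @param method \code{"nb_wald"} (default) or \code{"welch_log"}.
#' @param pThresh,fcThresh,useQ DEG-calling thresholds, see [callDEGs()].
#' @param sizeFactors optional pre-computed named size factors.
#' @return a [S4Vectors::DataFrame] with columns \code{gene_id},
#'   \code{mean_a} (denominator group), \code{mean_b} (numerator group),
#'   \code{log2fc}, \code{p}, \code{q}, \code{call}; the contrast is kept in
#'   \code{metadata()$contrast}.
#' @export
deTest <- function(x, contrast, method = c("nb_wald", "welch_log"),
                   pThresh = 0.05, fcThresh = 2, useQ = FALSE,
                   sizeFactors = NULL) {
  stopifnot(is(x, "TrioExperiment"))
  method <- match.arg(method)
  if (!inherits(contrast, "trioContrast")) {
    stopifnot(length(contrast) == 2L)
    contrast <- contrastSpec(contrast[[1L]], contrast[[2L]])
  }
  roles <- as.character(sampleRoles(x))
  colsB <- which(roles == contrast$numerator)
  colsA <- which(roles == contrast$denominator)
  if (!length(colsA) || !length(colsB))
    .stopf("missing_group", "contrast group absent from design: %s",
           if (!length(colsA)) contrast$denominator else contrast$numerator)
  if (length(colsA) < 2L || length(colsB) < 2L)
    .stopf("replicates", "each contrast group needs >= 2 replicates")
  m <- trioCounts(x)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  norm <- sweep(m, 2L, sizeFactors[colnames(m)], "/")
  A <- norm[, colsA, drop = FALSE]
  B <- norm[, colsB, drop = FALSE]
  tested <- rowSums(m[, c(colsA, colsB), drop = FALSE]) > 0

  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  log2fc <- log2((mb + 1) / (ma + 1))
  p <- rep(NA_real_, nrow(m))

  if (method == "nb_wald") {
    s2 <- (rowSums((A - ma)^2) + rowSums((B - mb)^2)) / (na + nb - 2)
    mo <- (na * ma + nb * mb) / (na + nb)
    disp <- pmax((s2 - mo) / mo^2, 1e-8)
    beta <- log(mb + 1) - log(ma + 1)
    se <- sqrt((1 / (ma + 1) + disp) / na + (1 / (mb + 1) + disp) / nb)
    p[tested] <- 2 * stats::pt(-abs(beta / se)[tested], df = na + nb - 2)
  } else {
    la <- log2(A + 1); lb <- log2(B + 1)
    mla <- rowMeans(la); mlb <- rowMeans(lb)
    va <- rowSums((la - mla)^2) / (na - 1)
    vb <- rowSums((lb - mlb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
    tstat <- (mlb - mla) / sqrt(se2)
    pw <- 2 * stats::pt(-abs(tstat), df = df)
    pw[se2 == 0] <- 1          # zero-variance (incl. tied) genes
    p[tested] <- pw[tested]
  }
  q <- rep(NA_real_, length(p))
  q[tested] <- bhAdjust(p[tested])
  res <- DataFrame(gene_id = rownames(m), mean_a = unname(ma),
                   mean_b = unname(mb), log2fc = unname(log2fc),
                   p = unname(p), q = q)
  res <- callDEGs(res, pThresh = pThresh, fcThresh = fcThresh, useQ = useQ)
  metadata(res)$contrast <- contrast
  metadata(res)$method <- method
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, \code{q_(i) = min_{j >= i} m p_(j) / j} clipped
#' to 1 (delegated to \code{stats::p.adjust}), after validating the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    .stopf("argument", "p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is \code{up} when its (raw or adjusted) p-value is below
#' \code{pThresh} and its fold change \code{(mean_b+1)/(mean_a+1)} exceeds
#' \code{fcThresh}; \code{down} when the fold change is below
#' \code{1/fcThresh}; otherwise \code{ns}.  The defaults (p < 0.05,
#' fold change > 2 or < 0.5, raw p) are the conventional thresholds for
#' this analysis.  Untested genes keep \code{call = "untested"}.
#'
#' @param results a DataFrame from [deTest()] (columns \code{log2fc},
#'   \code{p}, \code{q}).
#' @param pThresh significance threshold on p (or q).
#' @param fcThresh fold-change threshold, must be > 1.
#' @param useQ use BH-adjusted q instead of raw p.
#' @return \code{results} with a (re)computed \code{call} column.
#' @export
callDEGs <- function(results, pThresh = 0.05, fcThresh = 2, useQ = FALSE) {
  if (fcThresh <= 1) .stopf("argument", "fcThresh must be > 1")
  stat <- if (useQ) results$q else results$p
  fc <- 2^results$log2fc
  call <- rep("ns", nrow(results))
  call[!is.na(stat) & stat < pThresh & fc > fcThresh] <- "up"
  call[!is.na(stat) & stat < pThresh & fc < 1 / fcThresh] <- "down"
  call[is.na(stat)] <- "untested"
  results$call <- call
  results
}

#' Extract the DEG id set from a DE table
#'
#' @param results DataFrame from [deTest()].
#' @param direction \code{"both"}, \code{"up"} or \code{"down"}.
#' @return character vector of gene ids.
#' @export
degSet <- function(results, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") results$call %in% c("up", "down")
          else results$call == direction
  as.character(results$gene_id[keep])
}

#' Exclusive region counts of a Venn partition
#'
#' For 2-4 named sets, counts every exclusive region of the Venn diagram
#' (keys are set names joined by \code{"&"}) plus each set's total.
#'
#' @param sets named list of 2-4 character vectors.
#' @return list with elements \code{totals} (named integer vector) and
#'   \code{regions} (named integer vector over all 2^k - 1 combinations).
#' @export
overlapCounts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) .stopf("argument", "overlapCounts needs 2-4 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    .stopf("argument", "sets must have unique names")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  regions <- integer(nrow(combos))
  nms <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    mask <- unlist(combos[i, ])
    nms[i] <- paste(names(sets)[mask], collapse = "&")
    if (length(universe))
      regions[i] <- sum(apply(member, 1L, function(r) all(r == mask)))
  }
  names(regions) <- nms
  list(totals = lengths(sets), regions = regions)
}
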