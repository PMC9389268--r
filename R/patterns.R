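## The trio -> pattern classification table.
##
## A gene's inheritance pattern is determined by three significant-direction
## calls: hybrid vs female parent (s_HF), hybrid vs male parent (s_HM) and
## female vs male parent (s_FM); "plus" means the first member is
## significantly higher, "zero" means no significant difference.
##
## P1/P2   hybrid strictly between significantly different parents (additive)
## P3/P4   hybrid equals the male parent while the parents differ
##         (paternal expression-level dominance)
## P5/P6   hybrid equals the female parent (maternal dominance)
## P7-P9   hybrid significantly below both parents (parents >, =, < resp.)
## P10-P12 hybrid significantly above both parents (parents >, =, < resp.)
## All-zero trios are "conserved"; the 13 remaining sign combinations are
## internally inconsistent at the chosen thresholds and are "ambiguous".
## Within each dominant pair the lower index is the case where the matched
## parent is the higher-expressed one (a labelling convention).

SIGN_LEVELS <- c("minus", "zero", "plus")
PATTERN_LEVELS <- c(paste0("P", 1:12), "conserved", "ambiguous")

.patternKey <- function(sHF, sHM, sFM) paste(sHF, sHM, sFM, sep = "|")

.patternTable <- local({
  def <- rbind(
    c("minus", "plus",  "plus",  "P1"),
    c("plus",  "minus", "minus", "P2"),
    c("plus",  "zero",  "minus", "P3"),
    c("minus", "zero",  "plus",  "P4"),
    c("zero",  "minus", "minus", "P5"),
    c("zero",  "plus",  "plus",  "P6"),
    c("minus", "minus", "plus",  "P7"),
    c("minus", "minus", "zero",  "P8"),
    c("minus", "minus", "minus", "P9"),
    c("plus",  "plus",  "plus",  "P10"),
    c("plus",  "plus",  "zero",  "P11"),
    c("plus",  "plus",  "minus", "P12"),
    c("zero",  "zero",  "zero",  "conserved"))
  structure(def[, 4L], names = .patternKey(def[, 1L], def[, 2L], def[, 3L]))
})

CATEGORY5_MAP <- c(P1 = "additive", P2 = "additive",
                   P3 = "paternal_dominant", P4 = "paternal_dominant",
                   P5 = "maternal_dominant", P6 = "maternal_dominant",
                   P7 = "below_low_parent", P8 = "below_low_parent",
                   P9 = "below_low_parent",
                   P10 = "above_high_parent", P11 = "above_high_parent",
                   P12 = "above_high_parent",
                   conserved = "none", ambiguous = "none")

CATEGORY3_MAP <- c(additive = "additive",
                   paternal_dominant = "dominant",
                   maternal_dominant = "dominant",
                   below_low_parent = "over_dominant",
                   above_high_parent = "over_dominant",
                   none = "none")

#' Classify sign trios into inheritance patterns
#'
#' Maps each (s_HF, s_HM, s_FM) significant-direction trio to one of the
#' twelve inheritance patterns P1-P12, \code{"conserved"} (all three calls
#' non-significant) or \code{"ambiguous"} (sign combinations with no
#' consistent ordering of the three genotypes).  The mapping is total over
#' all 27 trios and deterministic.
#'
#' @param sHF,sHM,sFM character vectors over \code{"minus"}, \code{"zero"},
#'   \code{"plus"}: direction of hybrid vs female parent, hybrid vs male
#'   parent, and female vs male parent (\code{"plus"} = first member
#'   significantly higher).
#' @return factor with levels P1..P12, conserved, ambiguous.
#' @examples
#' classifyPattern("minus", "plus", "plus")   # F > H > M: additive (P1)
#' classifyPattern("plus", "plus", "zero")    # above both equal parents: P11
#' @export
classifyPattern <- function(sHF, sHM, sFM) {
  for (s in list(sHF, sHM, sFM))
    if (!all(s %in% SIGN_LEVELS))
      .stopf("argument", "signs must be one of %s",
             paste(SIGN_LEVELS, collapse = ", "))
  pat <- .patternTable[.patternKey(sHF, sHM, sFM)]
  pat[is.na(pat)] <- "ambiguous"
  factor(unname(pat), levels = PATTERN_LEVELS)
}

#' Five- and three-way category of an inheritance pattern
#'
#' P1-P2 are additive; P3-P4 paternal and P5-P6 maternal expression-level
#' dominance (together "dominant"); P7-P9 below the low parent and P10-P12
#' above the high parent (together "over_dominant").  Conserved and
#' ambiguous genes map to "none".
#'
#' @param pattern factor/character of pattern labels.
#' @return for \code{patternCategory5} a factor over additive,
#'   paternal_dominant, maternal_dominant, below_low_parent,
#'   above_high_parent, none; for \code{patternCategory3} a factor over
#'   additive, dominant, over_dominant, none.
#' @export
patternCategory5 <- function(pattern) {
  factor(unname(CATEGORY5_MAP[as.character(pattern)]),
         levels = unique(unname(CATEGORY5_MAP)))
}

#' @rdname patternCategory5
#' @export
patternCategory3 <- function(pattern) {
  factor(unname(CATEGORY3_MAP[as.character(patternCategory5(pattern))]),
         levels = unique(unname(CATEGORY3_MAP)))
}

## orient a DE table so that `numerator` vs `denominator` matches the
## requested pair, flipping up/down if the table was fitted the other way
.orientCalls <- function(res, numerator, denominator) {
  ct <- metadata(res)$contrast
  if (is.null(ct))
    .stopf("argument", "DE table lacks contrast metadata (run deTest)")
  if (ct$numerator == numerator && ct$denominator == denominator)
    return(res$call)
  if (ct$numerator == denominator && ct$denominator == numerator) {
    flipped <- res$call
    flipped[res$call == "up"] <- "down"
    flipped[res$call == "down"] <- "up"
    return(flipped)
  }
  .stopf("argument", "DE table contrast %s vs %s does not involve %s vs %s",
         ct$numerator, ct$denominator, numerator, denominator)
}

.callToSign <- function(call) {
  out <- rep("zero", length(call))    # ns and untested count as no difference
  out[call == "up"] <- "plus"
  out[call == "down"] <- "minus"
  out
}

#' Significant-direction trio for one gene
#'
#' Derives the (s_HF, s_HM, s_FM) trio from the DEG calls of the three
#' pairwise contrasts.  Each table's orientation is read from its contrast
#' metadata, so tables fitted as e.g. F_vs_H are flipped automatically.
#'
#' @param deHF,deHM,deFM DE tables (from [deTest()]) for the hybrid/female,
#'   hybrid/male and female/male contrasts, in either orientation.
#' @param gene a single gene id present in all three tables.
#' @return named character vector \code{c(s_HF=, s_HM=, s_FM=)}.
#' @export
signTrio <- function(deHF, deHM, deFM, gene) {
  ids <- list(deHF$gene_id, deHM$gene_id, deFM$gene_id)
  idx <- vapply(ids, function(g) match(gene, g), 1L)
  if (anyNA(idx))
    .stopf("gene_mismatch", "gene '%s' missing from a DE table", gene)
  c(s_HF = .callToSign(.orientCalls(deHF, "hybrid", "female_parent")[idx[1L]]),
    s_HM = .callToSign(.orientCalls(deHM, "hybrid", "male_parent")[idx[2L]]),
    s_FM = .callToSign(.orientCalls(deFM, "female_parent",
                                    "male_parent")[idx[3L]]))
}

#' Assign inheritance patterns to genes from three DE tables
#'
#' The classified universe defaults to the union of DEGs over the three
#' contrasts (genes significant in at least one comparison); set
#' \code{universe = "tested"} to classify every tested gene (non-DEGs then
#' mostly come out conserved).
#'
#' @inheritParams signTrio
#' @param universe \code{"degs"} (default) or \code{"tested"}.
#' @return a [S4Vectors::DataFrame] with columns \code{gene_id},
#'   \code{s_HF}, \code{s_HM}, \code{s_FM}, \code{pattern},
#'   \code{category5}, \code{category3}.
#' @export
assignPatterns <- function(deHF, deHM, deFM,
                           universe = c("degs", "tested")) {
  universe <- match.arg(universe)
  common <- Reduce(intersect, list(as.character(deHF$gene_id),
                                   as.character(deHM$gene_id),
                                   as.character(deFM$gene_id)))
  callHF <- .orientCalls(deHF, "hybrid", "female_parent")
  callHM <- .orientCalls(deHM, "hybrid", "male_parent")
  callFM <- .orientCalls(deFM, "female_parent", "male_parent")
  cHF <- callHF[match(common, deHF$gene_id)]
  cHM <- callHM[match(common, deHM$gene_id)]
  cFM <- callFM[match(common, deFM$gene_id)]
  keep <- if (universe == "degs")
    cHF %in% c("up", "down") | cHM %in% c("up", "down") |
      cFM %in% c("up", "down")
  else cHF != "untested" | cHM != "untested" | cFM != "untested"
  genes <- common[keep]
  sHF <- .callToSign(cHF[keep]); sHM <- .callToSign(cHM[keep])
  sFM <- .callToSign(cFM[keep])
  pattern <- classifyPattern(sHF, sHM, sFM)
  DataFrame(gene_id = genes, s_HF = sHF, s_HM = sHM, s_FM = sFM,
            pattern = pattern,
            category5 = patternCategory5(pattern),
            category3 = patternCategory3(pattern))
}

#' Summarize pattern assignments
#'
#' Counts and proportions per pattern, per five-way category and per
#' three-way category.  By default proportions are over classified genes
#' (patterns P1-P12), excluding conserved and ambiguous ones; with
#' \code{denominator = "all"} they are over every assigned gene.
#'
#' @param assignments DataFrame from [assignPatterns()].
#' @param denominator \code{"classified"} (default) or \code{"all"}.
#' @return list with data.frames \code{patterns}, \code{category5},
#'   \code{category3} (columns label, n, proportion) plus
#'   \code{n_classified} and \code{n_total}.  When no gene is classified
#'   the proportions are NA and a warning is raised.
#' @export
summarizePatterns <- function(assignments,
                              denominator = c("classified", "all")) {
  denominator <- match.arg(denominator)
  if (nrow(assignments) == 0L)
    .stopf("argument", "no pattern assignments to summarize")
  pat <- factor(as.character(assignments$pattern), levels = PATTERN_LEVELS)
  classified <- !(pat %in% c("conserved", "ambiguous"))
  denomN <- if (denominator == "classified") sum(classified)
            else length(pat)
  if (denomN == 0L)
    warning("no classified genes; proportions are NA")
  prop <- function(n) if (denomN == 0L) rep(NA_real_, length(n))
                      else n / denomN
  tab <- function(f, levels, excludeNone = FALSE) {
    counts <- table(factor(as.character(f), levels = levels))
    df <- data.frame(label = names(counts), n = as.integer(counts))
    p <- prop(df$n)
    if (excludeNone && denominator == "classified")
      p[df$label %in% c("none", "conserved", "ambiguous")] <- NA_real_
    df$proportion <- p
    df
  }
  list(patterns = tab(pat, PATTERN_LEVELS, excludeNone = TRUE),
       category5 = tab(assignments$category5,
                       unique(unname(CATEGORY5_MAP)), excludeNone = TRUE),
       category3 = tab(assignments$category3,
                       unique(unname(CATEGORY3_MAP)), excludeNone = TRUE),
       n_classified = sum(classified),
       n_total = length(pat))
}
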