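#' Mid-parent, high-parent and low-parent heterosis indices
#'
#' With F1 the hybrid value and HP, MP, LP the high-parent, mid-parent
#' (arithmetic mean) and low-parent values:
#' \deqn{OPH\% = (F_1 - HP)/HP \times 100}
#' \deqn{MPH\% = (F_1 - MP)/MP \times 100}
#' \deqn{BPH\% = (F_1 - LP)/LP \times 100}
#' For positive values with distinct parents, OPH < MPH < BPH always.
#'
#' @param f1 hybrid trait value(s).
#' @param pf,pm female- and male-parent values (vectorized).
#' @return data.frame with columns \code{oph}, \code{mph}, \code{bph}
#'   (percent).
#' @examples
#' heterosisIndices(6, 4, 2)  # oph 50, mph 100, bph 200
#' @export
heterosisIndices <- function(f1, pf, pm) {
  n <- max(length(f1), length(pf), length(pm))
  f1 <- rep_len(as.numeric(f1), n)
  pf <- rep_len(as.numeric(pf), n)
  pm <- rep_len(as.numeric(pm), n)
  hp <- pmax(pf, pm); lp <- pmin(pf, pm); mp <- (pf + pm) / 2
  if (any(hp == 0) || any(lp == 0) || any(mp == 0))
    .stopf("zero_parent", "parent values must be nonzero for ratio indices")
  data.frame(oph = (f1 - hp) / hp * 100,
             mph = (f1 - mp) / mp * 100,
             bph = (f1 - lp) / lp * 100)
}

#' Per-gene expression heterosis
#'
#' For a gene with mean hybrid expression \code{f1} and mid-parent mean
#' \code{mp} (both FPKM), the fold change is \code{FC = f1/mp} and the
#' expression-heterosis percent is \code{H = (f1 - mp)/mp * 100}, so
#' \code{H = (FC - 1) * 100} identically.
#'
#' @param f1 hybrid mean expression (FPKM), vectorized.
#' @param mp mid-parent mean expression, strictly positive.
#' @param geneId optional gene ids.
#' @return data.frame with columns (\code{gene_id},) \code{f1}, \code{mp},
#'   \code{fc}, \code{h_pct}.
#' @seealso [formatHeterosisTable()] for the conventional 2-decimal
#'   presentation.
#' @export
expressionHeterosis <- function(f1, mp, geneId = NULL) {
  n <- max(length(f1), length(mp))
  f1 <- rep_len(as.numeric(f1), n); mp <- rep_len(as.numeric(mp), n)
  if (any(!is.finite(mp)) || any(mp <= 0))
    .stopf("zero_parent", "mid-parent expression must be > 0")
  fc <- f1 / mp
  out <- data.frame(f1 = f1, mp = mp, fc = fc, h_pct = (fc - 1) * 100)
  if (!is.null(geneId)) out <- cbind(gene_id = as.character(geneId), out)
  out
}

#' Round an expression-heterosis table for reporting
#'
#' Rounds F1, MP and FC to 2 decimals and formats the heterosis percent as
#' \code{"xx.xx\%"}, the conventional presentation of such tables.
#'
#' @param eh data.frame from [expressionHeterosis()].
#' @return data.frame with rounded columns and character \code{h_pct}.
#' @export
formatHeterosisTable <- function(eh) {
  eh$f1 <- round(eh$f1, 2)
  eh$mp <- round(eh$mp, 2)
  eh$fc <- round(eh$fc, 2)
  eh$h_pct <- sprintf("%.2f%%", eh$h_pct)
  eh
}

#' Expression heterosis for every gene of a trio
#'
#' Computes genotype mean FPKM per gene, the mid-parent mean
#' \code{(F + M)/2}, and [expressionHeterosis()] for genes with positive
#' mid-parent expression.
#'
#' @param fpkm FPKM matrix as from [computeFPKM()].
#' @param design trio design data.frame (or [TrioExperiment-class]).
#' @param genes optional subset of gene ids.
#' @return data.frame with gene_id, f1, mp, fc, h_pct (genes with
#'   mid-parent mean 0 are dropped).
#' @export
trioExpressionHeterosis <- function(fpkm, design, genes = NULL) {
  if (is(design, "TrioExperiment"))
    design <- data.frame(sample_id = colnames(design),
                         role = as.character(sampleRoles(design)),
                         replicate = colData(design)$replicate)
  design <- .validateDesign(design)
  if (!is.null(genes)) fpkm <- fpkm[intersect(genes, rownames(fpkm)), ,
                                    drop = FALSE]
  gm <- function(r) rowMeans(
    fpkm[, design$sample_id[design$role == r], drop = FALSE])
  f1 <- gm("hybrid"); mp <- (gm("female_parent") + gm("male_parent")) / 2
  ok <- mp > 0
  expressionHeterosis(f1[ok], mp[ok], geneId = rownames(fpkm)[ok])
}

#' Potassium content from a flame-photometry measurement
#'
#' \code{K+\% = C * V / (G * 1e6) * 100}, with C the concentration (ppm)
#' read off the standard curve, V the extract volume (mL) and G the dry
#' sample weight (g); 1e6 converts ppm to a mass fraction.
#'
#' @param C concentration in ppm (>= 0).
#' @param V extract volume in mL (> 0).
#' @param G dry sample weight in g (> 0).
#' @return potassium content in percent.
#' @examples
#' kplusContent(20, 100, 0.5)  # 0.4 %
#' @export
kplusContent <- function(C, V, G) {
  n <- max(length(C), length(V), length(G))
  C <- rep_len(as.numeric(C), n); V <- rep_len(as.numeric(V), n)
  G <- rep_len(as.numeric(G), n)
  if (any(G <= 0) || any(V <= 0))
    .stopf("argument", "volume and sample weight must be > 0")
  if (any(C < 0)) .stopf("argument", "concentration must be >= 0")
  C * V / (G * 1e6) * 100
}

#' Relative expression by the 2^-ddCt method
#'
#' \code{2^-((Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator))}: the qPCR expression of a
#' target gene normalized to a reference gene and to a calibrator sample.
#'
#' @param ctTargetSample,ctRefSample,ctTargetCalibrator,ctRefCalibrator
#'   cycle-threshold values (finite, vectorized).
#' @return relative expression fold change(s).
#' @export
ddctRelativeExpression <- function(ctTargetSample, ctRefSample,
                                   ctTargetCalibrator, ctRefCalibrator) {
  ct <- cbind(ctTargetSample, ctRefSample, ctTargetCalibrator,
              ctRefCalibrator)
  if (any(!is.finite(ct)))
    .stopf("argument", "all Ct values must be finite")
  ddct <- (ct[, 1L] - ct[, 2L]) - (ct[, 3L] - ct[, 4L])
  unname(2^(-ddct))
}
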