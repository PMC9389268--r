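#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

## genotype roles of a trio design, in fixed order
TRIO_ROLES <- c("female_parent", "male_parent", "hybrid")

#' TrioExperiment: counts and design for a parent-hybrid trio
#'
#' An S4 container (extending
#' \linkS4class{RangedSummarizedExperiment}'s parent class
#' \linkS4class{SummarizedExperiment}) holding a gene x sample matrix of
#' non-negative integer fragment counts together with the trio design:
#' every sample is one replicate of the female parent, the male parent or
#' their F1 hybrid.  Gene lengths (bp), when known, live in
#' \code{rowData(x)$length_bp} and feed FPKM computation.
#'
#' @slot .. no new slots; the class fixes the interpretation of the
#'   \code{"counts"} assay and of \code{colData} columns \code{role} and
#'   \code{replicate}.
#'
#' @seealso [TrioExperiment()] the constructor, [computeFPKM()],
#'   [deTest()], [simulateTrio()]
#' @export
setClass("TrioExperiment", contains = "SummarizedExperiment")

setValidity("TrioExperiment", function(object) {
  msg <- character(0)
  if (!("counts" %in% names(assays(object))))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (nrow(m) < 1L || ncol(m) < 1L)
      msg <- c(msg, "count matrix needs at least 1 gene and 1 sample")
    if (anyNA(m) || any(!is.finite(m)))
      msg <- c(msg, "counts contain NA or non-finite entries")
    else if (any(m < 0))
      msg <- c(msg, "counts contain negative entries")
    else if (any(m != round(m)))
      msg <- c(msg, "counts contain non-integer entries")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids must be present and unique")
  }
  cd <- colData(object)
  if (!all(c("role", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have columns 'role' and 'replicate'")
  else {
    if (!all(as.character(cd$role) %in% TRIO_ROLES))
      msg <- c(msg, sprintf("unknown role(s): %s",
                            paste(setdiff(unique(as.character(cd$role)),
                                          TRIO_ROLES), collapse = ", ")))
    if (any(cd$replicate < 1) || any(cd$replicate != round(cd$replicate)))
      msg <- c(msg, "replicate must be a positive integer")
  }
  if ("length_bp" %in% colnames(rowData(object))) {
    len <- rowData(object)$length_bp
    if (any(!is.na(len) & len <= 0))
      msg <- c(msg, "gene lengths must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TrioExperiment
#'
#' @param counts integer matrix, genes x samples, with unique row and column
#'   names.
#' @param design data.frame with columns \code{sample_id}, \code{role}
#'   (one of \code{"female_parent"}, \code{"male_parent"}, \code{"hybrid"})
#'   and \code{replicate}.  Every \code{sample_id} must be a column of
#'   \code{counts}; columns are reordered to match the design.
#' @param lengths optional data.frame with columns \code{gene_id},
#'   \code{length_bp} covering every gene (required later for FPKM).
#'
#' @return a validated [TrioExperiment-class] object.
#' @examples
#' cm <- matrix(rpois(12, 40), 4, 3,
#'              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' des <- data.frame(sample_id = paste0("s", 1:3),
#'                   role = c("female_parent", "male_parent", "hybrid"),
#'                   replicate = 1L)
#' TrioExperiment(cm, des)
#' @export
TrioExperiment <- function(counts, design, lengths = NULL) {
  if (!is.matrix(counts))
    counts <- as.matrix(counts)
  design <- .validateDesign(design)
  missing <- setdiff(design$sample_id, colnames(counts))
  if (length(missing))
    .stopf("design_mismatch",
           "design sample(s) absent from count matrix: %s",
           paste(missing, collapse = ", "))
  extra <- setdiff(colnames(counts), design$sample_id)
  if (length(extra))
    .stopf("design_mismatch",
           "count matrix sample(s) absent from design: %s",
           paste(extra, collapse = ", "))
  counts <- counts[, design$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  cd <- DataFrame(role = factor(design$role, levels = TRIO_ROLES),
                  replicate = as.integer(design$replicate),
                  row.names = design$sample_id)
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(lengths)) {
    lengths <- .validateLengths(lengths)
    missing <- setdiff(rownames(counts), lengths$gene_id)
    if (length(missing))
      .stopf("missing_length",
             "%d gene(s) in the count matrix have no length, e.g. %s",
             length(missing), missing[1L])
    rd$length_bp <- lengths$length_bp[match(rownames(counts),
                                            lengths$gene_id)]
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  new("TrioExperiment", se)
}

#' @describeIn TrioExperiment genotype role of each sample, as a factor with
#'   levels female_parent, male_parent, hybrid.
#' @param x a TrioExperiment.
#' @export
sampleRoles <- function(x) {
  stopifnot(is(x, "TrioExperiment"))
  colData(x)$role
}

#' @describeIn TrioExperiment per-gene lengths in bp (NULL when not set).
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "TrioExperiment"))
  rowData(x)$length_bp
}

#' @describeIn TrioExperiment the raw count matrix.
#' @export
trioCounts <- function(x) {
  stopifnot(is(x, "TrioExperiment"))
  assay(x, "counts")
}

#' @describeIn TrioExperiment compact display including the trio design.
#' @param object a TrioExperiment.
#' @export
setMethod("show", "TrioExperiment", function(object) {
  callNextMethod()
  tab <- table(sampleRoles(object))
  cat("trio design:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

## ---- term annotation -------------------------------------------------------

#' TermAnnotation: flat term-to-gene-set mapping
#'
#' Holds a collection of named gene sets (GO terms, pathways, ...) as flat
#' sets; no ontology structure is modelled.  Built by [readAnnotation()] or
#' directly from a named list.
#'
#' @slot sets named list of unique character vectors (one per term).
#' @slot termNames character vector of human-readable names, parallel to
#'   \code{sets}.
#' @export
setClass("TermAnnotation",
         representation(sets = "list", termNames = "character"))

setValidity("TermAnnotation", function(object) {
  msg <- character(0)
  ids <- names(object@sets)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "term ids must be unique non-empty names of 'sets'")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "every term must have a non-empty gene set")
  if (length(object@termNames) != length(object@sets))
    msg <- c(msg, "termNames must parallel sets")
  if (length(msg)) msg else TRUE
})

#' Construct a TermAnnotation
#'
#' @param sets named list of character vectors of gene ids.
#' @param termNames optional character vector of descriptions (defaults to
#'   the term ids).
#' @return a [TermAnnotation-class] object; duplicate genes within a term
#'   are collapsed (set semantics).
#' @export
TermAnnotation <- function(sets, termNames = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(termNames)) termNames <- names(sets)
  new("TermAnnotation", sets = sets,
      termNames = as.character(termNames))
}

#' @describeIn TermAnnotation term identifiers.
#' @param x a TermAnnotation.
#' @export
termIds <- function(x) names(x@sets)

#' @describeIn TermAnnotation named list of gene sets.
#' @export
geneSets <- function(x) x@sets

#' @describeIn TermAnnotation human-readable term names, named by term id.
#' @export
termNames <- function(x) structure(x@termNames, names = names(x@sets))

#' @describeIn TermAnnotation compact display.
#' @param object a TermAnnotation.
#' @export
setMethod("show", "TermAnnotation", function(object) {
  cat(sprintf("TermAnnotation with %d terms covering %d genes\n",
              length(object@sets),
              length(unique(unlist(object@sets)))))
})

## internal design / length validators shared with readers

.validateDesign <- function(design) {
  need <- c("sample_id", "role", "replicate")
  if (!all(need %in% colnames(design)))
    .stopf("design_columns", "design needs columns: %s",
           paste(need, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$role <- as.character(design$role)
  if (anyDuplicated(design$sample_id))
    .stopf("duplicate_id", "duplicate sample_id in design: %s",
           design$sample_id[duplicated(design$sample_id)][1L])
  bad <- setdiff(unique(design$role), TRIO_ROLES)
  if (length(bad))
    .stopf("unknown_role", "unknown role(s) in design: %s (expected %s)",
           paste(bad, collapse = ", "), paste(TRIO_ROLES, collapse = ", "))
  rep <- suppressWarnings(as.numeric(design$replicate))
  if (anyNA(rep) || any(rep < 1) || any(rep != round(rep)))
    .stopf("bad_replicate", "replicate must be a positive integer")
  design$replicate <- as.integer(rep)
  design
}

.validateLengths <- function(lengths) {
  need <- c("gene_id", "length_bp")
  if (!all(need %in% colnames(lengths)))
    .stopf("length_columns", "gene length table needs columns: %s",
           paste(need, collapse = ", "))
  lengths$gene_id <- as.character(lengths$gene_id)
  if (anyDuplicated(lengths$gene_id))
    .stopf("duplicate_id", "duplicate gene_id in length table")
  len <- suppressWarnings(as.numeric(lengths$length_bp))
  if (anyNA(len) || any(len <= 0) || any(len != round(len)))
    .stopf("bad_length", "length_bp must be a positive integer")
  lengths$length_bp <- as.integer(len)
  lengths
}
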