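#' Read a gene x sample count matrix
#'
#' TSV dialect: tab-separated with a mandatory header row of sample ids; the
#' first column holds gene ids.  MatrixMarket dialect: an integer coordinate
#' \code{.mtx} file accompanied by sidecar files \code{<stem>.rownames.txt}
#' and \code{<stem>.colnames.txt} (one id per line).  Counts must be complete
#' non-negative integers; malformed input is rejected, never coerced.
#'
#' @param path file path (the \code{.mtx} file itself for MatrixMarket).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return an integer matrix with unique dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCountMatrix(matrix(0:5, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), tf)
#' readCountMatrix(tf)
#' @export
readCountMatrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- .readTsv(path, "count matrix")
    if (ncol(df) < 2L)
      .stopf("malformed", "count TSV needs a gene id column plus samples")
    gid <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- gid
  } else {
    if (!file.exists(path))
      .stopf("missing_file", "MatrixMarket file not found: '%s'", path)
    stem <- sub("\\.mtx$", "", path)
    rn <- paste0(stem, ".rownames.txt")
    cn <- paste0(stem, ".colnames.txt")
    for (side in c(rn, cn))
      if (!file.exists(side))
        .stopf("missing_file", "MatrixMarket sidecar not found: '%s'", side)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
  }
  .checkCountMatrix(m)
}

.checkCountMatrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopf("malformed", "count matrix must carry gene and sample ids")
  if (anyDuplicated(rownames(m)))
    .stopf("duplicate_id", "duplicate gene id: %s",
           rownames(m)[duplicated(rownames(m))][1L])
  if (anyDuplicated(colnames(m)))
    .stopf("duplicate_id", "duplicate sample id: %s",
           colnames(m)[duplicated(colnames(m))][1L])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    .stopf("invalid_count", "non-numeric or missing count at gene '%s', sample '%s'",
           rownames(m)[idx[1L]], colnames(m)[idx[2L]])
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    .stopf("invalid_count", "negative count at gene '%s', sample '%s'",
           rownames(m)[idx[1L]], colnames(m)[idx[2L]])
  }
  if (any(m != round(m))) {
    idx <- which(m != round(m), arr.ind = TRUE)[1L, ]
    .stopf("invalid_count", "non-integer count at gene '%s', sample '%s'",
           rownames(m)[idx[1L]], colnames(m)[idx[2L]])
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' Inverse of [readCountMatrix()]; round-trips are exact.
#'
#' @param m integer matrix with dimnames.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"mtx"} (with id sidecars).
#' @return the path, invisibly.
#' @export
writeCountMatrix <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- .checkCountMatrix(as.matrix(m))
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    .writeTsv(df, path)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(m), paste0(stem, ".rownames.txt"))
    writeLines(colnames(m), paste0(stem, ".colnames.txt"))
  }
  invisible(path)
}

#' Read a trio sample design table
#'
#' TSV with columns \code{sample_id}, \code{role}
#' (\code{female_parent} / \code{male_parent} / \code{hybrid}) and
#' \code{replicate}.
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
readDesign <- function(path) {
  .validateDesign(.readTsv(path, "design"))
}

#' @rdname readDesign
#' @param design validated design data.frame.
#' @export
writeDesign <- function(design, path) {
  .writeTsv(.validateDesign(design), path)
}

#' Read a gene length table
#'
#' TSV with columns \code{gene_id} and \code{length_bp} (positive integers).
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
readGeneLengths <- function(path) {
  .validateLengths(.readTsv(path, "gene length"))
}

#' @rdname readGeneLengths
#' @param lengths validated length data.frame.
#' @export
writeGeneLengths <- function(lengths, path) {
  .writeTsv(.validateLengths(lengths), path)
}

#' Read a term-to-gene annotation
#'
#' Two encodings of the same mapping are accepted and give identical
#' [TermAnnotation-class] objects: the Broad GMT dialect
#' (\code{term <TAB> description <TAB> gene1 <TAB> gene2 ...}) and a
#' two-column TSV of \code{gene_id <TAB> term_id} rows (with header).
#'
#' @param path file path.
#' @param format \code{"gmt"} or \code{"tsv2col"}.
#' @return a [TermAnnotation-class].
#' @export
readAnnotation <- function(path, format = c("gmt", "tsv2col")) {
  format <- match.arg(format)
  if (!file.exists(path))
    .stopf("missing_file", "annotation file not found: '%s'", path)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list(); nms <- character(0)
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L || !nzchar(f[1L]))
        .stopf("malformed", "malformed GMT line %d: need term, description, >=1 gene", i)
      genes <- unique(f[-(1:2)])
      genes <- genes[nzchar(genes)]
      if (!length(genes))
        .stopf("malformed", "GMT line %d has an empty gene set", i)
      if (f[1L] %in% names(sets))
        .stopf("duplicate_id", "duplicate term id in GMT: %s", f[1L])
      sets[[f[1L]]] <- genes
      nms <- c(nms, f[2L])
    }
    TermAnnotation(sets, nms)
  } else {
    df <- .readTsv(path, "annotation")
    if (!all(c("gene_id", "term_id") %in% colnames(df)))
      .stopf("malformed", "two-column annotation needs columns gene_id, term_id")
    if (any(!nzchar(df$term_id)) || any(!nzchar(df$gene_id)))
      .stopf("malformed", "empty gene or term id in annotation row %d",
             which(!nzchar(df$term_id) | !nzchar(df$gene_id))[1L])
    sets <- split(as.character(df$gene_id), as.character(df$term_id))
    TermAnnotation(sets)
  }
}

#' Write a TermAnnotation as GMT
#'
#' @param ann a [TermAnnotation-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotationGmt <- function(ann, path) {
  stopifnot(is(ann, "TermAnnotation"))
  nms <- termNames(ann)
  lines <- vapply(termIds(ann), function(id)
    paste(c(id, nms[[id]], geneSets(ann)[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a TrioExperiment from files
#'
#' Convenience loader joining counts, design and (optionally) gene lengths,
#' with cross-validation of sample and gene ids.
#'
#' @param counts path to the count matrix.
#' @param design path to the design TSV.
#' @param lengths optional path to the gene length TSV.
#' @param format count matrix format, \code{"tsv"} or \code{"mtx"}.
#' @return a [TrioExperiment-class].
#' @export
readTrioExperiment <- function(counts, design, lengths = NULL,
                               format = c("tsv", "mtx")) {
  m <- readCountMatrix(counts, format)
  des <- readDesign(design)
  len <- if (!is.null(lengths)) readGeneLengths(lengths)
  TrioExperiment(m, des, len)
}
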