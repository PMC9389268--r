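# Classed conditions so callers can distinguish failure modes programmatically.
# Every validation failure in the package signals a condition of class
# "triohet_error_<kind>" (also inheriting "triohet_error").

.stopf <- function(kind, fmt, ..., call. = FALSE) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(paste0("triohet_error_", kind),
                                     "triohet_error")))
}

.assertScalarNumeric <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("argument", "'%s' must be a single finite number", name)
  invisible(x)
}

#' @importFrom utils read.delim write.table
.readTsv <- function(path, what) {
  if (!file.exists(path))
    .stopf("missing_file", "%s file not found: '%s'", what, path)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "")
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
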