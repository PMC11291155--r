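# TSV output shared by all stages: header row, tab-separated, floats
# written with full precision so tables round-trip losslessly.

#' Write a stage-output table as TSV
#'
#' @param rows A data.frame, or a list of named lists/vectors (one per row).
#' @param path Output path.
#' @param schema Optional ordered character vector of field names; every
#'   row must supply every schema field (missing fields are an error naming
#'   the field and the row index).
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, schema = NULL) {
  if (is.data.frame(rows)) {
    if (is.null(schema)) schema <- names(rows)
    miss <- setdiff(schema, names(rows))
    if (length(miss) > 0)
      stop("missing field '", miss[1], "' in row 1")
    df <- rows[, schema, drop = FALSE]
  } else {
    stopifnot(is.list(rows))
    if (is.null(schema)) schema <- names(rows[[1]])
    for (i in seq_along(rows)) {
      miss <- setdiff(schema, names(rows[[i]]))
      if (length(miss) > 0)
        stop("missing field '", miss[1], "' in row ", i)
    }
    cols <- lapply(schema, function(f)
      unlist(lapply(rows, function(r) r[[f]]), use.names = FALSE))
    df <- stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE), schema)
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path Input path.
#' @return A data.frame with types inferred (numerics parsed back at full
#'   precision).
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
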