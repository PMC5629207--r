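`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic row order: sort by every column, left to right
.sort_rows <- function(df) {
  if (nrow(df) < 2L) return(df)
  ord <- do.call(order, unname(as.list(df)))
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.flatten_list_cols <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) paste(as.character(x), collapse = ";"),
                         character(1))
    }
  }
  df
}

#' Write a result table as a deterministic TSV
#'
#' All result record types in the package are plain data frames; this writer
#' emits them with a fixed column order, tab separation, no quoting, and
#' (by default) rows sorted lexicographically by every column so repeated
#' runs produce byte-identical files.
#'
#' @param records a data frame (list columns are collapsed with `";"`).
#' @param path output file path.
#' @param sort sort rows for determinism (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sort = TRUE) {
  df <- .flatten_list_cols(as.data.frame(records))
  if (sort) df <- .sort_rows(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
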