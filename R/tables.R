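# Delimited/JSON table output with fixed numeric precision and atomic writes.

# Default serialisation precision: percentage-like columns to 2 decimals,
# mass-like columns to 5. Column-name heuristics are documented here and
# overridable per call.
default_digits_for <- function(colnames) {
  d <- rep(NA_integer_, length(colnames))
  d[grepl("mass|m_?z|da$", colnames, ignore.case = TRUE)] <- 5L
  d[grepl("percent|inhibition|dh|ier|frequency|r_squared", colnames,
          ignore.case = TRUE)] <- 2L
  names(d) <- colnames
  d
}

#' Write a uniform table of records to disk
#'
#' Rows may be a data.frame or a list of identically-named records (lists).
#' Column order is the schema order of the first record and is deterministic.
#' Numeric columns are serialised at a fixed precision: by default 2 decimals
#' for percentage-like columns and 5 for mass-like columns (overridable via
#' `digits`, a named integer vector keyed by column). Files are written
#' atomically (temporary file + rename) so interrupted runs never leave a
#' truncated output.
#'
#' @param rows data.frame, or list of uniform named lists.
#' @param path Output path.
#' @param format One of "tsv", "csv", "json".
#' @param digits Named integer vector of per-column decimal places; columns
#'   not named keep the heuristic default, `NA` leaves a column unformatted.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, format = c("tsv", "csv", "json"),
                        digits = NULL) {
  format <- match.arg(format)
  df <- rows_to_df(rows)
  digs <- default_digits_for(names(df))
  if (!is.null(digits)) {
    stopifnot(!is.null(names(digits)))
    digs[names(digits)] <- as.integer(digits)
  }
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.na(digs[[j]])) {
      df[[j]] <- formatC(df[[j]], format = "f", digits = digs[[j]])
    }
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", format))
  on.exit(unlink(tmp), add = TRUE)
  ok <- tryCatch({
    switch(format,
      tsv = utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                               row.names = FALSE),
      csv = utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE),
      json = jsonlite::write_json(df, tmp, dataframe = "rows",
                                  auto_unbox = TRUE))
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (ok && !file.rename(tmp, path)) {
    stop(sprintf("cannot write %s (rename failed)", path), call. = FALSE)
  }
  invisible(path)
}

rows_to_df <- function(rows) {
  if (is.data.frame(rows)) return(rows)
  if (!is.list(rows)) stop("`rows` must be a data.frame or list of records",
                           call. = FALSE)
  if (length(rows) == 0L) {
    stop("empty record list with no schema; pass a zero-row data.frame instead",
         call. = FALSE)
  }
  schema <- names(rows[[1L]])
  if (is.null(schema)) stop("records must be named lists", call. = FALSE)
  for (i in seq_along(rows)) {
    if (!identical(names(rows[[i]]), schema)) {
      stop(sprintf("record %d does not match the schema of record 1 (%s)",
                   i, paste(schema, collapse = ", ")), call. = FALSE)
    }
  }
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}
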