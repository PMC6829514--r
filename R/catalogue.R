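# Activity-annotated short-peptide catalogue with exact-sequence lookup.
#
# The catalogue is the local, user-supplied stand-in for a hosted bioactive
# peptide database (BIOPEP-UWM style): short peptides (typically 2-12
# residues) annotated with a controlled-vocabulary activity label such as
# "ACE inhibitor" or "DPP-IV inhibitor". Matching is exact and
# direction-sensitive: "AE" and "EA" are distinct peptides and routinely
# carry different activities.

#' Build a peptide catalogue from entries
#'
#' @param entries data.frame with columns `id`, `sequence`, `activity` and
#'   optionally `reference`.
#' @param min_len Minimum peptide length admitted (default 2: single residues
#'   are excluded unless requested).
#' @return An object of class `peptide_catalogue` with elements `entries`
#'   (validated data.frame with column `peptide`), `activities` (sorted
#'   unique labels) and `max_len` (longest entry peptide).
#' @export
peptide_catalogue <- function(entries, min_len = 2L) {
  stopifnot(is.data.frame(entries))
  required <- c("id", "sequence", "activity")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop(sprintf("catalogue is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"reference" %in% names(entries)) entries$reference <- ""
  peptide <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    peptide[i] <- tryCatch(
      validate_sequence(entries$sequence[i]),
      error = function(e) stop(sprintf("catalogue row %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    if (nchar(peptide[i]) < min_len) {
      stop(sprintf("catalogue row %d: peptide '%s' shorter than min_len = %d",
                   i, peptide[i], min_len), call. = FALSE)
    }
  }
  activity <- trimws(as.character(entries$activity))
  if (any(!nzchar(activity))) {
    stop("catalogue contains empty activity label(s)", call. = FALSE)
  }
  df <- data.frame(id = as.character(entries$id), peptide = peptide,
                   activity = activity,
                   reference = as.character(entries$reference),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[c("peptide", "activity")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (peptide, activity) entr%s",
                    sum(dup), if (sum(dup) == 1L) "y" else "ies"),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(entries = df,
                 activities = sort(unique(df$activity)),
                 max_len = max(nchar(df$peptide)),
                 min_len = as.integer(min_len)),
            class = "peptide_catalogue")
}

#' Load a peptide catalogue from a delimited file
#'
#' Expects a UTF-8 TSV with header columns `id`, `sequence`, `activity` and
#' optional `reference`; lines starting with `#` are comments. Duplicate
#' (peptide, activity) pairs are collapsed with a warning; activity labels
#' are trimmed but otherwise preserved verbatim.
#'
#' @param path Path to the TSV file.
#' @param min_len Minimum peptide length admitted (default 2).
#' @return A `peptide_catalogue`.
#' @seealso [demo_catalogue_path()] for the bundled synthetic demo catalogue.
#' @export
load_catalogue <- function(path, min_len = 2L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  peptide_catalogue(raw, min_len = min_len)
}

#' Path to the bundled synthetic demo catalogue
#'
#' A small synthetic table (~150 entries) of literature-typical ACE- and
#' DPP-IV-inhibitory di- and tri-peptides plus a handful of other activity
#' labels, bundled for tests and examples. It is NOT a copy of any hosted
#' database; real analyses should load a user-supplied catalogue.
#'
#' @return File path of the bundled TSV.
#' @export
demo_catalogue_path <- function() {
  system.file("extdata", "catalogue_demo_synthetic.tsv", package = "pepscreen",
              mustWork = TRUE)
}

#' Exact-sequence catalogue lookup
#'
#' Case-normalised, direction-sensitive exact match of one peptide against
#' the catalogue. Returns the sorted set of activity labels annotated to that
#' exact sequence (empty character vector if absent).
#'
#' @param catalogue A `peptide_catalogue`.
#' @param peptide Peptide sequence to look up.
#' @return Character vector of activity labels.
#' @export
lookup <- function(catalogue, peptide) {
  stopifnot(inherits(catalogue, "peptide_catalogue"))
  p <- validate_sequence(peptide)
  sort(unique(catalogue$entries$activity[catalogue$entries$peptide == p]))
}

#' @export
print.peptide_catalogue <- function(x, ...) {
  cat(sprintf("Peptide catalogue: %d entries, %d activities, peptide length %d-%d\n",
              nrow(x$entries), length(x$activities), x$min_len, x$max_len))
  counts <- sort(table(x$entries$activity), decreasing = TRUE)
  for (a in names(counts)) cat(sprintf("  %-28s %d\n", a, counts[[a]]))
  invisible(x)
}
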