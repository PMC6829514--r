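# FASTA input/output for protein records.
#
# A protein collection is a plain data.frame with columns
#   id          - accession-like identifier (first token of the header)
#   description - rest of the header line (may be "")
#   sequence    - validated canonical sequence
# Identifiers must be unique within one collection.

#' Construct a protein record collection
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of sequences (validated).
#' @param description Optional character vector of free-text descriptions.
#' @return A data.frame with columns id, description, sequence.
#' @export
protein_records <- function(id, sequence, description = "") {
  stopifnot(length(id) == length(sequence))
  description <- rep_len(as.character(description), length(id))
  sequence <- vapply(seq_along(sequence), function(i) {
    validate_sequence(sequence[[i]], what = sprintf("record '%s'", id[[i]]))
  }, character(1))
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate identifier(s): %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
         call. = FALSE)
  }
  data.frame(id = as.character(id), description = description,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' Wrapped or unwrapped multi-record FASTA. The identifier is the first
#' whitespace-delimited token of the header; the description is everything
#' after it. Sequences are canonicalised with [validate_sequence()]; a record
#' containing a non-canonical character fails with an error naming the record
#' and the character.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame of protein records (id, description, sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  # BStringSet accepts arbitrary characters so that our validator, not the
  # parser, reports offending residues.
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  protein_records(id = ids, sequence = as.character(set), description = desc)
}

#' Write protein records to a FASTA file
#'
#' @param proteins A protein record data.frame (see [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(is.data.frame(proteins),
            all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::AAStringSet(proteins$sequence)
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  names(set) <- ifelse(nzchar(desc), paste(proteins$id, desc), proteins$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
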