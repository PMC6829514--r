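# Canonical amino-acid alphabet and sequence validation.

#' The 20 canonical amino-acid one-letter codes
#'
#' Ambiguity and non-standard codes (B, J, O, U, X, Z) are deliberately
#' excluded: cleavage rules and catalogue matching are defined only on the
#' canonical residues, so ambiguous input is rejected rather than mapped.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate and canonicalise an amino-acid sequence
#'
#' Strips whitespace and line breaks, uppercases, and checks that every
#' remaining character is one of the 20 canonical residue codes. Ambiguity
#' codes (B, J, O, U, X, Z), digits, gaps and any other character raise an
#' error naming the first offending character and its position in the cleaned
#' sequence. Validation is idempotent.
#'
#' @param raw Character scalar, the raw sequence.
#' @param what Optional label (e.g. a record identifier) used in error
#'   messages.
#' @return The canonical uppercase sequence string.
#' @examples
#' validate_sequence("ids legsvsr")  # "IDSLEGSVSR"
#' @export
validate_sequence <- function(raw, what = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single character string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]+", "", raw))
  if (!nzchar(s)) {
    stop(sprintf("empty sequence%s",
                 if (is.null(what)) "" else paste0(" in ", what)),
         call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET20)
  if (length(bad)) {
    stop(sprintf(
      "invalid residue '%s' at position %d%s (only the 20 canonical one-letter codes are accepted; ambiguity codes such as B, J, O, U, X, Z are rejected)",
      chars[bad[1L]], bad[1L],
      if (is.null(what)) "" else paste0(" in ", what)), call. = FALSE)
  }
  s
}

# Internal: validate a residue-set specification (character vector or a
# single string like "KR"); returns a character vector of unique residues.
as_residue_set <- function(x, field = "residue set") {
  if (is.null(x) || length(x) == 0L) return(character(0))
  x <- toupper(unlist(strsplit(as.character(x), "", fixed = TRUE)))
  bad <- setdiff(x, AA_ALPHABET20)
  if (length(bad)) {
    stop(sprintf("%s contains non-canonical residue(s): %s",
                 field, paste(bad, collapse = ", ")), call. = FALSE)
  }
  unique(x)
}
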