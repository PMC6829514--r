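# Digestion engine: cleavage-site enumeration, complete digestion with
# optional missed cleavages, and sequential multi-enzyme digestion.

# Internal: accept a protein as a one-row record data.frame or a bare
# sequence string; returns list(id, sequence).
as_protein <- function(protein) {
  if (is.data.frame(protein)) {
    if (nrow(protein) != 1L) {
      stop("expected a single protein record (one row)", call. = FALSE)
    }
    return(list(id = protein$id[[1L]],
                sequence = validate_sequence(protein$sequence[[1L]],
                                             what = protein$id[[1L]])))
  }
  if (is.character(protein) && length(protein) == 1L) {
    return(list(id = "protein", sequence = validate_sequence(protein)))
  }
  stop("`protein` must be a one-row record data.frame or a sequence string",
       call. = FALSE)
}

rule_fires_at <- function(chars, i, rule) {
  p1 <- chars[i]
  p1p <- chars[i + 1L]
  p2 <- if (i >= 2L) chars[i - 1L] else NA_character_
  fires <- p1 %in% rule$p1_allow ||
    (length(rule$p2_allow) > 0L && !is.na(p2) && p2 %in% rule$p2_allow)
  if (!fires) return(FALSE)
  if (p1 %in% rule$p1_block) return(FALSE)
  if (length(rule$p1prime_allow) > 0L && !(p1p %in% rule$p1prime_allow)) {
    return(FALSE)
  }
  !(p1p %in% rule$p1prime_block)
}

#' Enumerate cleavage sites of an enzyme on a protein
#'
#' Site `i` denotes the peptide bond between residues `i` and `i + 1`
#' (1-based). A site cleaves iff any of the enzyme's rules fires there; the
#' result is strictly increasing and deterministic.
#'
#' @param protein One-row protein record data.frame, or a sequence string.
#' @param enzyme A `cleavage_enzyme`, or the name of a registered enzyme.
#' @return Integer vector of site positions in `[1, length - 1]`.
#' @export
cleavage_sites <- function(protein, enzyme) {
  p <- as_protein(protein)
  enz <- resolve_enzyme(enzyme)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  sites <- logical(n - 1L)
  for (rule in enz$rules) {
    for (i in seq_len(n - 1L)) {
      if (!sites[i] && rule_fires_at(chars, i, rule)) sites[i] <- TRUE
    }
  }
  which(sites)
}

# Internal: fragments from a sorted site vector. Zero-missed fragments
# partition the parent; with max_missed = m every run of <= m + 1 consecutive
# zero-missed fragments is additionally emitted with its internal uncleaved
# site count. Ordered by (start, end).
fragments_from_sites <- function(id, sequence, sites, max_missed = 0L) {
  n <- nchar(sequence)
  bounds <- c(0L, sites, n)          # fragment j spans bounds[j]+1 .. bounds[j+1]
  k <- length(bounds) - 1L           # number of zero-missed fragments
  out <- list()
  for (j in seq_len(k)) {
    upper <- min(k, j + max_missed)
    for (jj in j:upper) {
      out[[length(out) + 1L]] <- c(start = bounds[j] + 1L, end = bounds[jj + 1L],
                                   n_missed = jj - j)
    }
  }
  m <- do.call(rbind, out)
  df <- data.frame(parent_id = id, start = as.integer(m[, "start"]),
                   end = as.integer(m[, "end"]),
                   sequence = substring(sequence, m[, "start"], m[, "end"]),
                   n_missed = as.integer(m[, "n_missed"]),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Digest a protein with one enzyme
#'
#' Complete digestion: every fireable site is cut. With `max_missed = 0` the
#' fragments partition the parent (their concatenation restores it); with
#' `max_missed = m` every peptide spanning up to `m` internal uncleaved sites
#' is additionally reported with its `n_missed` count (the MS search
#' convention, e.g. "2 maximum missed cleavages").
#'
#' @inheritParams cleavage_sites
#' @param max_missed Non-negative integer, maximum missed cleavages.
#' @return data.frame of fragments: parent_id, start, end (1-based
#'   inclusive), sequence, n_missed; ordered by (start, end).
#' @export
digest <- function(protein, enzyme, max_missed = 0L) {
  stopifnot(length(max_missed) == 1L, max_missed >= 0L)
  p <- as_protein(protein)
  sites <- cleavage_sites(p$sequence, enzyme)
  fragments_from_sites(p$id, p$sequence, sites, as.integer(max_missed))
}

#' Sequential digestion with several enzymes
#'
#' Models sequential complete digestions (e.g. Lys-C followed by trypsin):
#' equivalent to cutting at the union of each enzyme's site set. Fragments
#' partition the parent.
#'
#' @inheritParams cleavage_sites
#' @param enzymes List of `cleavage_enzyme` objects (or registry names), in
#'   digestion order.
#' @return data.frame of fragments as in [digest()], all with `n_missed = 0`.
#' @export
digest_sequential <- function(protein, enzymes) {
  if (inherits(enzymes, "cleavage_enzyme") || is.character(enzymes)) {
    enzymes <- as.list(enzymes)
  }
  stopifnot(length(enzymes) >= 1L)
  p <- as_protein(protein)
  sites <- sort(unique(unlist(lapply(enzymes, function(e) {
    cleavage_sites(p$sequence, e)
  }))))
  fragments_from_sites(p$id, p$sequence, as.integer(sites), 0L)
}
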