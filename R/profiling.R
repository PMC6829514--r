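# Local re-implementation of the three database-tool semantics:
#   * activity profile of a protein (all catalogue peptides occurring as
#     substrings, with locations; occurrence counting),
#   * active fragments of a digest (whole released peptides matched exactly
#     against the catalogue; a fragment merely *containing* a catalogue
#     peptide is NOT a hit),
#   * per-enzyme / per-activity aggregation and ranking.

#' Profile the potential biological activity of a protein
#'
#' Finds every occurrence (including overlapping and repeated occurrences) of
#' every catalogue peptide as a substring of the protein. Counts are
#' occurrence counts per activity: a peptide occurring twice counts twice and
#' a multi-activity peptide contributes one count per activity annotation.
#' Use `distinct = TRUE` to count each distinct peptide once per activity.
#'
#' @param protein One-row protein record data.frame, or a sequence string.
#' @param catalogue A `peptide_catalogue`.
#' @param distinct Count distinct peptides instead of occurrences.
#' @return Object of class `activity_profile`: `protein_id`, `hits`
#'   (data.frame peptide, activity, start, end ordered by (start, end,
#'   activity)) and `counts` (named integer vector by activity).
#' @export
profile_protein <- function(protein, catalogue, distinct = FALSE) {
  stopifnot(inherits(catalogue, "peptide_catalogue"))
  p <- as_protein(protein)
  n <- nchar(p$sequence)
  ent <- catalogue$entries
  hit_list <- list()
  for (len in unique(nchar(ent$peptide))) {
    if (len > n) next
    starts <- seq_len(n - len + 1L)
    windows <- substring(p$sequence, starts, starts + len - 1L)
    sub <- ent[nchar(ent$peptide) == len, , drop = FALSE]
    idx <- match(windows, sub$peptide)   # first matching entry peptide
    found <- which(!is.na(idx))
    for (i in found) {
      pep <- windows[i]
      acts <- unique(sub$activity[sub$peptide == pep])
      hit_list[[length(hit_list) + 1L]] <- data.frame(
        peptide = pep, activity = acts, start = starts[i],
        end = starts[i] + len - 1L, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(peptide = character(0), activity = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$end, hits$activity), , drop = FALSE]
  rownames(hits) <- NULL
  counted <- if (distinct) hits[!duplicated(hits[c("peptide", "activity")]), ]
             else hits
  counts <- table(factor(counted$activity, levels = catalogue$activities))
  counts <- counts[counts > 0L]
  structure(list(protein_id = p$id, protein_length = n, hits = hits,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 distinct = distinct),
            class = "activity_profile")
}

#' Match released digest fragments against the catalogue
#'
#' Whole-fragment semantics: each released peptide is looked up exactly; a
#' long fragment containing a catalogue peptide internally is not a hit.
#' Counts are per fragment instance (a peptide released twice counts twice).
#'
#' @param fragments Fragment data.frame from [digest()] or
#'   [digest_sequential()].
#' @param catalogue A `peptide_catalogue`.
#' @param enzyme_name Optional enzyme label stamped into the report.
#' @param distinct Count each distinct released peptide once per activity.
#' @return Object of class `digest_report`: `protein_id`, `enzyme`,
#'   `ruleset_version`, `fragments`, `active_hits` (data.frame sequence,
#'   start, end, n_missed, activity) and `counts`.
#' @export
active_fragments <- function(fragments, catalogue, enzyme_name = NA_character_,
                             distinct = FALSE) {
  stopifnot(is.data.frame(fragments), inherits(catalogue, "peptide_catalogue"))
  ent <- catalogue$entries
  rows <- list()
  if (nrow(fragments)) {
    for (i in seq_len(nrow(fragments))) {
      acts <- sort(unique(ent$activity[ent$peptide == fragments$sequence[i]]))
      if (length(acts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = fragments$sequence[i], start = fragments$start[i],
          end = fragments$end[i], n_missed = fragments$n_missed[i],
          activity = acts, stringsAsFactors = FALSE)
      }
    }
  }
  active <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), start = integer(0), end = integer(0),
               n_missed = integer(0), activity = character(0),
               stringsAsFactors = FALSE)
  rownames(active) <- NULL
  counted <- if (distinct) active[!duplicated(active[c("sequence", "activity")]), ]
             else active
  tab <- table(counted$activity)
  structure(list(
    protein_id = if (nrow(fragments)) fragments$parent_id[[1L]] else NA_character_,
    enzyme = enzyme_name, ruleset_version = RULESET_VERSION,
    fragments = fragments, active_hits = active,
    counts = stats::setNames(as.integer(tab), names(tab)),
    distinct = distinct),
    class = "digest_report")
}

#' Rank enzymes by bioactive peptides released in silico
#'
#' Digests every protein completely with every enzyme, matches released
#' fragments against the catalogue, and totals activity counts over
#' proteins. Activities outside `core_activities` are merged under
#' `other_label` (mirroring the usual "other activities" grouping in
#' screening figures). Enzymes are ranked by grand total.
#'
#' @param proteins Protein record data.frame (one row per protein).
#' @param enzymes List of `cleavage_enzyme` objects or registry names.
#' @param catalogue A `peptide_catalogue`.
#' @param core_activities Activities kept as their own rows.
#' @param other_label Label for the merged remainder.
#' @param distinct Count distinct released peptides instead of instances.
#' @return Object of class `enzyme_ranking`: `table` (data.frame enzyme,
#'   activity, count), `totals` (named vector, decreasing), and
#'   `ruleset_version`.
#' @export
rank_enzymes <- function(proteins, enzymes, catalogue,
                         core_activities = c("ACE inhibitor", "DPP-IV inhibitor"),
                         other_label = "other activities", distinct = FALSE) {
  stopifnot(is.data.frame(proteins), inherits(catalogue, "peptide_catalogue"))
  if (inherits(enzymes, "cleavage_enzyme") || is.character(enzymes)) {
    enzymes <- as.list(enzymes)
  }
  registry <- default_enzymes()
  rows <- list()
  totals <- numeric(0)
  for (enz in enzymes) {
    e <- resolve_enzyme(enz, registry)
    agg <- numeric(0)
    for (i in seq_len(nrow(proteins))) {
      rep <- active_fragments(digest(proteins[i, , drop = FALSE], e),
                              catalogue, enzyme_name = e$name,
                              distinct = distinct)
      for (a in names(rep$counts)) {
        key <- if (a %in% core_activities) a else other_label
        agg[key] <- (if (key %in% names(agg)) agg[[key]] else 0L) +
          rep$counts[[a]]
      }
    }
    lvls <- c(core_activities, other_label)
    for (a in lvls) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = e$name, activity = a,
        count = if (a %in% names(agg)) as.integer(agg[[a]]) else 0L,
        stringsAsFactors = FALSE)
    }
    totals[e$name] <- sum(agg)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme = character(0), activity = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  structure(list(table = tab, totals = sort(totals, decreasing = TRUE),
                 ruleset_version = RULESET_VERSION, distinct = distinct),
            class = "enzyme_ranking")
}

#' Frequency of occurrence of bioactive fragments
#'
#' The classic per-activity "A" parameter: occurrence count divided by
#' protein residue count, reported to 4 decimals.
#'
#' @param profile An `activity_profile`.
#' @param protein The protein the profile was computed from (optional; the
#'   profile stores the length).
#' @return Named numeric vector, activity -> count / length.
#' @export
frequency_of_occurrence <- function(profile, protein = NULL) {
  stopifnot(inherits(profile, "activity_profile"))
  n <- profile$protein_length
  if (!is.null(protein)) {
    p <- as_protein(protein)
    if (!identical(p$id, profile$protein_id) && !identical(p$id, "protein")) {
      stop("profile was not computed from this protein", call. = FALSE)
    }
    n <- nchar(p$sequence)
  }
  round(profile$counts / n, 4L)
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile of %s (%d aa): %d hit(s), %s counting\n",
              x$protein_id, x$protein_length, nrow(x$hits),
              if (x$distinct) "distinct-peptide" else "occurrence"))
  for (a in names(x$counts)) cat(sprintf("  %-28s %d\n", a, x$counts[[a]]))
  invisible(x)
}

#' @export
print.digest_report <- function(x, ...) {
  cat(sprintf("Digest report: %s / enzyme %s (rule set v%s)\n",
              x$protein_id, x$enzyme, x$ruleset_version))
  cat(sprintf("  %d fragment(s), %d active hit(s)\n",
              nrow(x$fragments), nrow(x$active_hits)))
  for (a in names(x$counts)) cat(sprintf("  %-28s %d\n", a, x$counts[[a]]))
  invisible(x)
}

#' @export
print.enzyme_ranking <- function(x, ...) {
  cat(sprintf("Enzyme ranking (rule set v%s, %s counting):\n",
              x$ruleset_version,
              if (x$distinct) "distinct-peptide" else "instance"))
  for (nm in names(x$totals)) cat(sprintf("  %-18s %d\n", nm, x$totals[[nm]]))
  invisible(x)
}
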