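# Independent brute-force oracles, implemented directly from the rule and
# matching semantics rather than through the package's engine code paths.

# Per-bond rule evaluation: site i is the bond between residues i and i+1;
# P2 = residue i-1 (absent for i = 1), P1 = residue i, P1' = residue i+1.
oracle_sites <- function(sequence, enz) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  fires <- function(i, r) {
    p1 <- chars[i]; p1p <- chars[i + 1]
    p2 <- if (i > 1) chars[i - 1] else NA
    trig <- p1 %in% r$p1_allow ||
      (length(r$p2_allow) > 0 && !is.na(p2) && p2 %in% r$p2_allow)
    trig &&
      !(p1 %in% r$p1_block) &&
      (length(r$p1prime_allow) == 0 || p1p %in% r$p1prime_allow) &&
      !(p1p %in% r$p1prime_block)
  }
  which(vapply(seq_len(n - 1), function(i) {
    any(vapply(enz$rules, function(r) fires(i, r), logical(1)))
  }, logical(1)))
}

# All (start, end) peptides consistent with complete digestion at `sites`
# and at most `m` internal uncleaved sites, by direct enumeration over all
# substrings.
oracle_fragments <- function(sequence, sites, m) {
  n <- nchar(sequence)
  cuts <- c(0L, sites, n)
  out <- list()
  for (start in 1:n) {
    for (end in start:n) {
      if (!((start - 1L) %in% cuts) || !(end %in% cuts)) next
      internal <- sum(sites > (start - 1L) & sites < end)
      if (internal <= m) {
        out[[length(out) + 1L]] <- data.frame(
          start = start, end = end,
          sequence = substr(sequence, start, end),
          n_missed = internal, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# All-substrings activity scan: every catalogue peptide occurrence.
oracle_profile_hits <- function(sequence, catalogue) {
  ent <- catalogue$entries
  n <- nchar(sequence)
  out <- list()
  for (k in seq_len(nrow(ent))) {
    pep <- ent$peptide[k]
    L <- nchar(pep)
    if (L > n) next
    starts <- seq_len(n - L + 1L)
    hit_at <- starts[substring(sequence, starts, starts + L - 1L) == pep]
    for (s in hit_at) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = pep, activity = ent$activity[k],
        start = s, end = s + L - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(peptide = character(0), activity = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, out))
  df <- df[order(df$start, df$end, df$activity), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

# Random small catalogue of 2-3 residue peptides with random activities.
random_catalogue <- function(n_entries = 20L) {
  peps <- unique(vapply(seq_len(n_entries), function(i) {
    random_sequence(sample(2:3, 1))
  }, character(1)))
  acts <- sample(c("ACE inhibitor", "DPP-IV inhibitor", "antioxidative"),
                 length(peps), replace = TRUE)
  peptide_catalogue(data.frame(id = paste0("r", seq_along(peps)),
                               sequence = peps, activity = acts,
                               stringsAsFactors = FALSE))
}

tiny_catalogue <- function() {
  peptide_catalogue(data.frame(
    id = c("c1", "c2", "c3"),
    sequence = c("AE", "EA", "GP"),
    activity = c("DPP-IV inhibitor", "ACE inhibitor", "DPP-IV inhibitor"),
    stringsAsFactors = FALSE))
}
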