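# Seeded synthetic-data generators: random proteins with controllable
# residue composition, planted releasable motifs, and noisy assay readouts
# with a known true inhibition fraction.
#
# Every generator draws from R's Mersenne-Twister stream seeded from the
# caller's seed combined with a fixed per-operation offset, inside a local
# RNG scope (the global .Random.seed is saved and restored). Operations
# therefore have independent substreams: adding one never perturbs
# another's draws, and a fixed seed reproduces output exactly.

with_local_seed <- function(seed, offset, expr) {
  seed <- (as.integer(seed) + offset) %% .Machine$integer.max
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Generate random protein records
#'
#' Sequences are drawn residue-by-residue from `composition` (default:
#' uniform over the 20 canonical residues); lengths are uniform over
#' `length_range`. With `exclude` nonempty, sequences containing any of the
#' excluded motifs are rejection-sampled and redrawn, so planted-motif
#' experiments can rely on exact occurrence counts.
#'
#' @param n Number of proteins.
#' @param length_range Integer pair (min, max) residues.
#' @param composition Named numeric vector residue -> probability, summing
#'   to 1 (within 1e-9); default uniform.
#' @param seed Integer seed; fully determines the output.
#' @param exclude Character vector of motifs that must not occur by chance.
#' @param id_prefix Identifier prefix.
#' @return Protein record data.frame.
#' @export
random_proteins <- function(n, length_range = c(100L, 300L),
                            composition = NULL, seed = 1L,
                            exclude = character(0), id_prefix = "synth") {
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1L] >= 1L, length_range[1L] <= length_range[2L])
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET20)
  }
  res <- as_residue_set(names(composition), "composition names")
  if (length(res) != length(composition)) {
    stop("composition names must be distinct canonical residues", call. = FALSE)
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    stop("composition probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  }
  exclude <- vapply(exclude, validate_sequence, character(1), USE.NAMES = FALSE)
  with_local_seed(seed, offset = 101L, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      repeat {
        len <- length_range[1L] - 1L +
          sample.int(length_range[2L] - length_range[1L] + 1L, 1L)
        s <- paste(sample(names(composition), len, replace = TRUE,
                          prob = composition), collapse = "")
        if (!length(exclude) ||
            !any(vapply(exclude, grepl, logical(1), x = s, fixed = TRUE))) {
          break
        }
      }
      seqs[i] <- s
    }
    protein_records(id = sprintf("%s_%03d", id_prefix, seq_len(n)),
                    sequence = seqs,
                    description = "synthetic random protein")
  })
}

#' Plant an enzymatically releasable motif into a protein
#'
#' Inserts `motif` into the protein with flanking residues chosen so that a
#' complete digest with `enzyme` releases the motif intact: a preceding
#' flank residue from the enzyme's P1 allow set sits immediately N-terminal
#' of the motif, and a following residue compatible with the P1' constraints
#' sits immediately C-terminal. Preconditions checked with clear errors:
#' the motif must contain no internal cleavage site, and its last residue
#' must itself fire the enzyme's P1 rule (otherwise the C-terminal boundary
#' bond can never be cut and the motif would never be released intact).
#' The construction is verified by actually digesting the modified protein.
#'
#' @param protein One-row protein record data.frame, or a sequence string.
#' @param motif Peptide to plant (validated).
#' @param enzyme A `cleavage_enzyme` or registry name.
#' @param position Residue index after which the insert is placed
#'   (0 = at the N terminus; default: middle of the protein).
#' @return One-row protein record data.frame with extra columns
#'   `motif_start` and `motif_end` (1-based coordinates of the planted
#'   motif in the returned sequence).
#' @export
plant_releasable <- function(protein, motif, enzyme, position = NULL) {
  p <- as_protein(protein)
  motif <- validate_sequence(motif)
  enz <- resolve_enzyme(enzyme)
  if (length(cleavage_sites(motif, enz)) > 0L) {
    stop(sprintf("motif '%s' contains an internal %s cleavage site and would never be released intact",
                 motif, enz$name), call. = FALSE)
  }
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  first <- chars[1L]
  last <- chars[length(chars)]
  all_p1_allow <- unique(unlist(lapply(enz$rules, `[[`, "p1_allow")))
  all_p1p_block <- unique(unlist(lapply(enz$rules, `[[`, "p1prime_block")))

  # N-side flank: a residue X with a rule firing at X | motif[1].
  flank_ok <- function(x, y) {  # does any rule cut the bond x|y (no P2 context)?
    any(vapply(enz$rules, function(r) rule_fires_at(c(x, y), 1L, r),
               logical(1)))
  }
  candidates <- all_p1_allow[vapply(all_p1_allow, flank_ok, logical(1),
                                    y = first)]
  if (!length(candidates)) {
    stop(sprintf("no flank residue lets %s cleave immediately before motif '%s' (P1' constraints)",
                 enz$name, motif), call. = FALSE)
  }
  flank_n <- candidates[[1L]]
  # C-side: the motif's own last residue must be cleavable before some Y.
  after_ok <- vapply(AA_ALPHABET20, flank_ok, logical(1), x = last)
  if (!any(after_ok)) {
    stop(sprintf("motif '%s' cannot be released at its C terminus: last residue '%s' does not fire %s's P1 rule",
                 motif, last, enz$name), call. = FALSE)
  }
  # Prefer a following residue that is inert (not itself a P1 residue).
  safe <- setdiff(AA_ALPHABET20[after_ok], union(all_p1_allow, all_p1p_block))
  flank_c <- if (length(safe)) safe[[1L]] else AA_ALPHABET20[after_ok][[1L]]

  n <- nchar(p$sequence)
  if (is.null(position)) position <- n %/% 2L
  stopifnot(position >= 0L, position <= n)
  insert <- paste0(flank_n, motif, flank_c)
  new_seq <- paste0(substring(p$sequence, 1L, position), insert,
                    substring(p$sequence, position + 1L, n))
  motif_start <- position + 2L
  motif_end <- motif_start + nchar(motif) - 1L

  frags <- digest(new_seq, enz)
  released <- any(frags$start == motif_start & frags$end == motif_end &
                  frags$sequence == motif)
  if (!released) {
    stop(sprintf("planting failed verification: %s digest of the modified protein does not release '%s' at %d-%d (local sequence context interferes); try another position",
                 enz$name, motif, motif_start, motif_end), call. = FALSE)
  }
  out <- data.frame(id = p$id, description = "synthetic planted-motif protein",
                    sequence = new_seq, motif_start = motif_start,
                    motif_end = motif_end, stringsAsFactors = FALSE)
  out
}

#' Simulate noisy ACE and DPP-IV assay readouts with known truth
#'
#' Generates plate readouts whose noiseless evaluation through
#' [ace_inhibition()] and [dppiv_inhibition()] returns `true_inhibition`
#' exactly. The ACE branch simulates the 30-minute kinetic read at 345 nm
#' (control slope -0.010 absorbance/min; per-read Gaussian noise of sd
#' `noise_sd`; slope re-estimated by least squares), the DPP-IV branch adds
#' the same noise to the four endpoint absorbances (blank 0.05, positive
#' control 1.05, negative control 0.05).
#'
#' @param true_inhibition True inhibition percentage in [0, 100].
#' @param n_replicates Number of replicate wells.
#' @param noise_sd Gaussian absorbance noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with data.frames `ace` (replicate, slope_control,
#'   slope_sample) and `dppiv` (replicate, a_sample, a_blank,
#'   a_pos_control, a_neg_control), plus `true_inhibition`.
#' @export
synthetic_assay <- function(true_inhibition, n_replicates = 3L,
                            noise_sd = 0, seed = 1L) {
  stopifnot(true_inhibition >= 0, true_inhibition <= 100, n_replicates >= 1L)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  f <- true_inhibition / 100
  slope_ctrl_true <- -0.010           # absorbance decrease per minute
  slope_samp_true <- slope_ctrl_true * (1 - f)
  a_b <- 0.05; a_nc <- 0.05; a_pc <- 1.05
  a_s_true <- a_b + (1 - f) * (a_pc - a_nc)
  with_local_seed(seed, offset = 303L, {
    tmin <- 0:30
    fit_slope <- function(true_slope) {
      a <- 1.0 + true_slope * tmin +
        if (noise_sd > 0) stats::rnorm(length(tmin), 0, noise_sd) else 0
      unname(stats::coef(stats::lm(a ~ tmin))[2L])
    }
    ace <- data.frame(
      replicate = seq_len(n_replicates),
      slope_control = vapply(seq_len(n_replicates),
                             function(i) fit_slope(slope_ctrl_true), numeric(1)),
      slope_sample = vapply(seq_len(n_replicates),
                            function(i) fit_slope(slope_samp_true), numeric(1)))
    noise <- function() if (noise_sd > 0) stats::rnorm(n_replicates, 0, noise_sd) else 0
    dppiv <- data.frame(
      replicate = seq_len(n_replicates),
      a_sample = a_s_true + noise(), a_blank = a_b + noise(),
      a_pos_control = a_pc + noise(), a_neg_control = a_nc + noise())
    list(ace = ace, dppiv = dppiv, true_inhibition = true_inhibition)
  })
}
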