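# Peptide mass and m/z arithmetic.
#
# Residue masses are pinned to 6 decimals in the tables below (documented,
# versioned constants) so that last-digit agreement with published 2-decimal
# masses is bit-stable. A peptide's mass is the sum of its residue masses
# plus one water; m/z for charge z adds z protons and divides by z.

#' Monoisotopic residue masses (Da)
#' @format Named numeric vector over the 20 canonical residues.
#' @export
AA_MONO_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)

#' Average residue masses (Da)
#' @format Named numeric vector over the 20 canonical residues.
#' @export
AA_AVG_MASS <- c(
  G = 57.051300, A = 71.078800, S = 87.078200, P = 97.116700,
  V = 99.132600, T = 101.104600, C = 103.143800, L = 113.159400,
  I = 113.159400, N = 114.103800, D = 115.088600, Q = 128.130700,
  K = 128.174100, E = 129.115500, M = 131.196600, H = 137.141100,
  F = 147.176600, R = 156.187500, Y = 163.176000, W = 186.213200)

#' Mass constants (Da)
#' @name mass-constants
#' @export
WATER_MONO <- 18.010565
#' @rdname mass-constants
#' @export
WATER_AVG <- 18.015280
#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.007276

#' Peptide mass and m/z
#'
#' Monoisotopic and average masses of a linear, unmodified peptide, and m/z
#' values for the requested positive charge states:
#' `m/z(z) = (M + z * 1.007276) / z`.
#'
#' @param peptide Peptide sequence (validated).
#' @param charges Integer vector of charge states (>= 1).
#' @return Object of class `mass_result`: `peptide`, `monoisotopic_mass`,
#'   `average_mass`, `mz_by_charge` (named numeric, names are charges).
#' @examples
#' peptide_mass("IDSLEGSVSR", charges = 2)
#' @export
peptide_mass <- function(peptide, charges = c(1L, 2L, 3L)) {
  p <- validate_sequence(peptide)
  charges <- as.integer(charges)
  if (any(is.na(charges)) || any(charges < 1L)) {
    stop("charges must be integers >= 1", call. = FALSE)
  }
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  mono <- sum(AA_MONO_MASS[chars]) + WATER_MONO
  avg <- sum(AA_AVG_MASS[chars]) + WATER_AVG
  mz <- (mono + charges * PROTON_MASS) / charges
  structure(list(peptide = p, monoisotopic_mass = mono, average_mass = avg,
                 mz_by_charge = stats::setNames(mz, charges)),
            class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("%s\n  monoisotopic %.5f Da, average %.4f Da\n",
              x$peptide, x$monoisotopic_mass, x$average_mass))
  for (z in names(x$mz_by_charge)) {
    cat(sprintf("  [M+%sH]%s+  m/z %.5f\n", z, z, x$mz_by_charge[[z]]))
  }
  invisible(x)
}
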