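# Declarative enzyme cleavage-specificity rules (Schechter-Berger positions).
#
# A cleavage site i is the peptide bond between residues i and i+1 (1-based).
# Positions around the scissile bond: P2 = residue i-1, P1 = residue i,
# P1' = residue i+1. A rule fires at site i iff
#   (P1 in p1_allow  OR  (p2_allow nonempty AND P2 in p2_allow))
#   AND P1 not in p1_block
#   AND (p1prime_allow empty OR P1' in p1prime_allow)
#   AND P1' not in p1prime_block
# An enzyme cleaves at a site iff any of its rules fires there.
#
# The bundled defaults are a documented editorial choice following standard
# Keil / PeptideCutter-style conventions (proteases are usually described in
# prose, not machine rules); every default can be overridden via
# parse_enzyme_config() and the rule-set version is stamped into all reports.

#' Version of the bundled cleavage rule set
#' @export
RULESET_VERSION <- "1.0.0"

#' Construct a cleavage rule
#'
#' Residue sets may be given as character vectors or compact strings
#' (`"KR"`). Allow and block sets for the same position must be disjoint.
#'
#' @param p1_allow Residues allowed at P1 (N-terminal side of the bond).
#' @param p1_block Residues vetoing cleavage when at P1.
#' @param p1prime_allow Residues allowed at P1' (empty = any residue).
#' @param p1prime_block Residues vetoing cleavage when at P1'.
#' @param p2_allow Optional residues at P2 that fire the rule regardless of
#'   P1 (used e.g. for papain's preference for Phe at P2).
#' @return An object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(p1_allow = character(0), p1_block = character(0),
                          p1prime_allow = character(0),
                          p1prime_block = character(0),
                          p2_allow = character(0)) {
  r <- list(p1_allow = as_residue_set(p1_allow, "p1_allow"),
            p1_block = as_residue_set(p1_block, "p1_block"),
            p1prime_allow = as_residue_set(p1prime_allow, "p1prime_allow"),
            p1prime_block = as_residue_set(p1prime_block, "p1prime_block"),
            p2_allow = as_residue_set(p2_allow, "p2_allow"))
  if (length(intersect(r$p1_allow, r$p1_block))) {
    stop(sprintf("p1_allow and p1_block overlap: %s",
                 paste(intersect(r$p1_allow, r$p1_block), collapse = ", ")),
         call. = FALSE)
  }
  if (length(intersect(r$p1prime_allow, r$p1prime_block))) {
    stop(sprintf("p1prime_allow and p1prime_block overlap: %s",
                 paste(intersect(r$p1prime_allow, r$p1prime_block),
                       collapse = ", ")), call. = FALSE)
  }
  # A rule with empty p1_allow and p2_allow is legal and never fires.
  structure(r, class = "cleavage_rule")
}

#' Construct an enzyme from cleavage rules
#'
#' @param name Registry name (unique).
#' @param ec EC number string.
#' @param rules A `cleavage_rule` or list of them; a site cleaves if any
#'   rule fires.
#' @return An object of class `cleavage_enzyme`.
#' @export
enzyme <- function(name, ec = "", rules) {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  stopifnot(length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "cleavage_rule")))
  structure(list(name = as.character(name), ec = as.character(ec),
                 rules = rules),
            class = "cleavage_enzyme")
}

#' Bundled enzyme registry
#'
#' Default specificity rules, Keil/PeptideCutter-style:
#' \describe{
#'   \item{pepsin_ph_gt2 (EC 3.4.23.1)}{P1 in F, L, W, Y, E; blocked when
#'     P1' = P. Ala, Val and Gly never fire because they are absent from the
#'     allow set.}
#'   \item{bromelain_stem (EC 3.4.22.32)}{P1 in K, R, A, Y, G; blocked when
#'     P1' = P. Protein-substrate specificity of stem bromelain is poorly
#'     characterised; this default is the lowest-confidence entry and should
#'     be overridden for serious use.}
#'   \item{papain (EC 3.4.22.2)}{P1 in R, K, or P2 = F; blocked when P1' = P.}
#'   \item{trypsin (EC 3.4.21.4)}{P1 in K, R; blocked when P1' = P (the
#'     classic Keil exception).}
#'   \item{chymotrypsin_a (EC 3.4.21.1)}{P1 in F, Y, W; blocked when P1' = P.}
#'   \item{lys_c (EC 3.4.21.50)}{P1 = K (cleaves Lys-Pro bonds).}
#' }
#'
#' @return Named list of `cleavage_enzyme` objects.
#' @export
default_enzymes <- function() {
  reg <- list(
    pepsin_ph_gt2 = enzyme("pepsin_ph_gt2", "3.4.23.1",
      cleavage_rule(p1_allow = "FLWYE", p1prime_block = "P")),
    bromelain_stem = enzyme("bromelain_stem", "3.4.22.32",
      cleavage_rule(p1_allow = "KRAYG", p1prime_block = "P")),
    papain = enzyme("papain", "3.4.22.2",
      cleavage_rule(p1_allow = "RK", p2_allow = "F", p1prime_block = "P")),
    trypsin = enzyme("trypsin", "3.4.21.4",
      cleavage_rule(p1_allow = "KR", p1prime_block = "P")),
    chymotrypsin_a = enzyme("chymotrypsin_a", "3.4.21.1",
      cleavage_rule(p1_allow = "FYW", p1prime_block = "P")),
    lys_c = enzyme("lys_c", "3.4.21.50",
      cleavage_rule(p1_allow = "K"))
  )
  reg
}

#' Parse an enzyme configuration file
#'
#' YAML schema: a top-level `enzymes` mapping (or bare mapping) from enzyme
#' name to a record with optional keys `ec`, `p1_allow`, `p1_block`,
#' `p1prime_allow`, `p1prime_block`, `p2_allow`; residue sets are strings
#' like `"KR"` or lists. User definitions are merged over the bundled
#' defaults and override them by name. Unknown keys, residues outside the
#' canonical alphabet, and overlapping allow/block sets are errors.
#'
#' @param path Path to a YAML config, or NULL for the bundled defaults only.
#' @return Named list of `cleavage_enzyme` objects.
#' @export
parse_enzyme_config <- function(path = NULL) {
  reg <- default_enzymes()
  if (is.null(path)) return(reg)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$enzymes)) cfg <- cfg$enzymes
  if (is.null(cfg) || length(cfg) == 0L) return(reg)
  if (is.null(names(cfg)) || any(!nzchar(names(cfg)))) {
    stop("enzyme config must map enzyme names to rule records", call. = FALSE)
  }
  rule_keys <- c("p1_allow", "p1_block", "p1prime_allow", "p1prime_block",
                 "p2_allow")
  for (nm in names(cfg)) {
    rec <- cfg[[nm]]
    unknown <- setdiff(names(rec), c("ec", rule_keys))
    if (length(unknown)) {
      stop(sprintf("enzyme '%s': unknown key(s) %s", nm,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    rule <- tryCatch(
      cleavage_rule(p1_allow = rec$p1_allow, p1_block = rec$p1_block,
                    p1prime_allow = rec$p1prime_allow,
                    p1prime_block = rec$p1prime_block,
                    p2_allow = rec$p2_allow),
      error = function(e) stop(sprintf("enzyme '%s': %s", nm,
                                       conditionMessage(e)), call. = FALSE))
    reg[[nm]] <- enzyme(nm, ec = if (is.null(rec$ec)) "" else rec$ec, rule)
  }
  reg
}

# Internal: resolve an enzyme argument (object or registry name).
resolve_enzyme <- function(enz, registry = default_enzymes()) {
  if (inherits(enz, "cleavage_enzyme")) return(enz)
  if (is.character(enz) && length(enz) == 1L) {
    if (!enz %in% names(registry)) {
      stop(sprintf("unknown enzyme '%s'; registered: %s", enz,
                   paste(names(registry), collapse = ", ")), call. = FALSE)
    }
    return(registry[[enz]])
  }
  stop("`enzyme` must be a cleavage_enzyme or a registry name", call. = FALSE)
}

#' @export
print.cleavage_enzyme <- function(x, ...) {
  cat(sprintf("Enzyme %s (EC %s), %d rule(s):\n", x$name,
              if (nzchar(x$ec)) x$ec else "?", length(x$rules)))
  fmt <- function(s) if (length(s)) paste(s, collapse = "") else "-"
  for (r in x$rules) {
    cat(sprintf("  P1 allow {%s} block {%s}; P1' allow {%s} block {%s}; P2 allow {%s}\n",
                fmt(r$p1_allow), fmt(r$p1_block), fmt(r$p1prime_allow),
                fmt(r$p1prime_block), fmt(r$p2_allow)))
  }
  invisible(x)
}
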