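# Hydrolysate assay arithmetic: degree of hydrolysis (OPA free amino
# groups), ACE and DPP-IV inhibition percentages, inhibition efficiency
# ratio, and OPA standard-curve quantification. All functions are
# vectorised over replicates.

#' Degree of hydrolysis (%)
#'
#' `DH = (NH2_tx - NH2_t0) / (NH2_total - NH2_t0) * 100`, where the NH2
#' terms are free amino group amounts (Gly-Gly-Gly equivalents; units must
#' match across arguments): at hydrolysis time x, at time 0, and after
#' complete acid hydrolysis. Values outside the expected ordering
#' (t0 <= tx <= total) are flagged with a warning, not an error.
#'
#' @param nh2_tx Free amino groups at time x (vectorised).
#' @param nh2_t0 Free amino groups at time 0.
#' @param nh2_total Total amino groups after complete acid hydrolysis.
#' @return DH percentage(s).
#' @export
degree_of_hydrolysis <- function(nh2_tx, nh2_t0, nh2_total) {
  if (any(nh2_total == nh2_t0)) {
    stop("nh2_total equals nh2_t0: degree of hydrolysis is undefined",
         call. = FALSE)
  }
  if (any(nh2_total < nh2_t0)) {
    warning("nh2_total < nh2_t0: check readout units", call. = FALSE)
  }
  if (any(nh2_tx < nh2_t0) || any(nh2_tx > nh2_total)) {
    warning("nh2_tx outside [nh2_t0, nh2_total]: DH outside [0, 100]",
            call. = FALSE)
  }
  (nh2_tx - nh2_t0) / (nh2_total - nh2_t0) * 100
}

#' ACE inhibitory activity (%)
#'
#' From the FAPGG kinetic assay at 345 nm:
#' `(slope_control - slope_sample) / slope_control * 100`, with slopes the
#' absorbance change per minute without and with inhibitor. Negative
#' computed inhibition is returned as-is with a warning (clamping would hide
#' assay problems).
#'
#' @param slope_control Control absorbance slope (per minute), nonzero.
#' @param slope_sample Sample absorbance slope (vectorised).
#' @return Inhibition percentage(s).
#' @export
ace_inhibition <- function(slope_control, slope_sample) {
  if (any(slope_control == 0)) {
    stop("zero control slope: ACE inhibition undefined", call. = FALSE)
  }
  out <- (slope_control - slope_sample) / slope_control * 100
  if (any(out < 0)) {
    warning("negative ACE inhibition (sample slope exceeds control); returned unclamped",
            call. = FALSE)
  }
  out
}

#' DPP-IV inhibitory activity (%)
#'
#' From the Gly-Pro p-nitroanilide endpoint assay:
#' `[1 - (A_s - A_b) / (A_pc - A_nc)] * 100`, with sample, blank, positive
#' control (uninhibited enzyme) and negative control (no enzyme)
#' absorbances. Negative computed inhibition is returned unclamped with a
#' warning.
#'
#' @param a_sample,a_blank,a_pos_control,a_neg_control Absorbances
#'   (vectorised).
#' @return Inhibition percentage(s).
#' @export
dppiv_inhibition <- function(a_sample, a_blank, a_pos_control, a_neg_control) {
  if (any(a_pos_control == a_neg_control)) {
    stop("positive and negative control absorbances are equal: DPP-IV inhibition undefined",
         call. = FALSE)
  }
  out <- (1 - (a_sample - a_blank) / (a_pos_control - a_neg_control)) * 100
  if (any(out < 0)) {
    warning("negative DPP-IV inhibition; returned unclamped", call. = FALSE)
  }
  out
}

#' Inhibition efficiency ratio (% per mg/mL)
#'
#' Inhibition percentage normalised by peptide content:
#' `IER = inhibition / peptide_content`.
#'
#' @param inhibition Inhibition percentage(s).
#' @param peptide_content Peptide content (mg/mL), > 0.
#' @return IER value(s).
#' @export
inhibition_efficiency_ratio <- function(inhibition, peptide_content) {
  if (any(peptide_content <= 0)) {
    stop("peptide_content must be positive", call. = FALSE)
  }
  inhibition / peptide_content
}

#' OPA standard-curve quantification (Gly-Gly-Gly equivalents)
#'
#' Fits an unweighted ordinary least-squares line absorbance ~ concentration
#' to the standards and inverts sample absorbances through it. Samples
#' outside the standard absorbance range are still returned but flagged with
#' an extrapolation warning.
#'
#' @param standards data.frame with columns `concentration` and `absorbance`
#'   (>= 2 distinct concentrations).
#' @param samples Numeric vector of sample absorbances.
#' @return Object of class `opa_quantification`: `concentrations`, `slope`,
#'   `intercept`, `r_squared`, `extrapolated` (logical per sample).
#' @export
opa_quantify <- function(standards, samples) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "absorbance") %in% names(standards)))
  if (length(unique(standards$concentration)) < 2L) {
    stop("need >= 2 distinct standard concentrations for a calibration line",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration, data = standards)
  slope <- unname(stats::coef(fit)["concentration"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  if (slope == 0) stop("singular calibration: zero slope", call. = FALSE)
  conc <- (samples - intercept) / slope
  rng <- range(standards$absorbance)
  extrap <- samples < rng[1L] | samples > rng[2L]
  if (any(extrap)) {
    warning(sprintf("%d sample absorbance(s) outside the standard range: extrapolated",
                    sum(extrap)), call. = FALSE)
  }
  ss_tot <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(concentrations = conc, slope = slope, intercept = intercept,
                 r_squared = r2, extrapolated = extrap),
            class = "opa_quantification")
}

#' @export
print.opa_quantification <- function(x, ...) {
  cat(sprintf("OPA calibration: A = %.5f * c + %.5f (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat("sample concentrations (Gly-Gly-Gly equivalents):\n")
  print(round(x$concentrations, 4L))
  if (any(x$extrapolated)) cat("(values outside the standard range were extrapolated)\n")
  invisible(x)
}
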