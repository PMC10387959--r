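#' Gibbs free energy of binding from a binding constant
#'
#' \deqn{\Delta G = -R T \ln K,} with R = 8.314 J/mol/K.
#'
#' @param k binding constant, L/mol (positive).
#' @param temperature temperature, K (positive).
#' @return Gibbs energy in J/mol (negative for K > 1).
#' @examples
#' gibbs_from_k(4.57e6, 298) / 1000  # about -38.0 kJ/mol
#' @export
gibbs_from_k <- function(k, temperature) {
  if (any(k <= 0)) stop("k must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  -.gas_constant * temperature * log(k)
}

.gas_constant <- 8.314  # J/mol/K

#' Van't Hoff enthalpy from binding constants at two temperatures
#'
#' \deqn{\ln(K_2/K_1) = \frac{\Delta H}{R}\left(\frac{1}{T_1} -
#' \frac{1}{T_2}\right)} solved for the (temperature-independent) binding
#' enthalpy. The sign of the result equals the sign of ln(K2/K1) when
#' T2 > T1: a binding constant that grows with temperature implies an
#' endothermic (positive-enthalpy) association.
#'
#' @param k1,k2 binding constants (L/mol) at temperatures `t1`, `t2` (K).
#' @param t1,t2 the two temperatures, K, distinct.
#' @return Enthalpy change in J/mol.
#' @examples
#' vant_hoff_enthalpy(4.57e6, 298, 5.01e6, 310) / 1000  # about +5.9 kJ/mol
#' @export
vant_hoff_enthalpy <- function(k1, t1, k2, t2) {
  if (any(c(k1, k2) <= 0)) stop("binding constants must be positive")
  if (any(c(t1, t2) <= 0)) stop("temperatures must be positive")
  if (t1 == t2) stop("temperatures must differ")
  .gas_constant * log(k2 / k1) / (1 / t1 - 1 / t2)
}

#' Entropy change from enthalpy and Gibbs energy
#'
#' \deqn{\Delta S = (\Delta H - \Delta G) / T} (rearranged from
#' \eqn{\Delta G = \Delta H - T \Delta S}).
#'
#' @param delta_h enthalpy change, J/mol.
#' @param delta_g Gibbs energy change, J/mol.
#' @param temperature temperature, K (positive).
#' @return Entropy change in J/mol/K.
#' @export
entropy_change <- function(delta_h, delta_g, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  (delta_h - delta_g) / temperature
}

#' Classify the dominant interaction forces from the signs of dH and dS
#'
#' The sign pattern of the binding enthalpy and entropy indicates the
#' dominant non-covalent forces of a ligand-protein association:
#' positive dH and dS imply hydrophobic interaction; negative dH and dS
#' imply hydrogen bonding and van der Waals forces; positive dS with
#' non-positive dH implies hydrophobic plus electrostatic forces; negative
#' dS with non-negative dH again implies hydrogen bonding and van der
#' Waals. If either quantity is exactly zero the pattern is unclassifiable
#' and `"unclassified"` is returned.
#'
#' @param delta_h enthalpy change, J/mol.
#' @param delta_s entropy change, J/mol/K.
#' @return Character vector of force labels, or `"unclassified"`.
#' @examples
#' classify_forces(-14450, -21.36)  # hydrogen bond + van der Waals
#' classify_forces(10, 50)          # hydrophobic
#' @export
classify_forces <- function(delta_h, delta_s) {
  if (delta_h == 0 || delta_s == 0) return("unclassified")
  if (delta_s > 0) {
    if (delta_h > 0) "hydrophobic" else c("hydrophobic", "electrostatic")
  } else {
    c("hydrogen bond", "van der Waals")
  }
}

#' Full Van't Hoff thermodynamic profile from binding constants
#'
#' Composes the Van't Hoff enthalpy, per-temperature Gibbs energies, and
#' per-temperature entropies into one profile, and classifies the dominant
#' interaction forces from dH and the mean dS. With exactly two
#' temperatures dH comes from the two-point Van't Hoff relation; with more,
#' from an ordinary least-squares fit of ln K against 1/T
#' (dH = -R * slope), flagged as an extension beyond the two-point design.
#' By construction \eqn{\Delta G(T) = \Delta H - T\,\Delta S(T)} holds
#' exactly at every temperature.
#'
#' Reported literature values of dH and dS may be supplied; if they
#' disagree with the computed ones by more than 1% a consistency warning is
#' recorded (both sets are kept; neither is silently preferred).
#'
#' @param k_by_temperature named numeric vector of binding constants
#'   (L/mol); names are temperatures in K. At least two temperatures.
#' @param reported_delta_h,reported_delta_s optional reported values
#'   (J/mol and J/mol/K) to check against.
#' @return An object of class `thermo_profile` with elements `delta_h`
#'   (J/mol), `delta_g_by_T` and `delta_s_by_T` (named by temperature,
#'   J/mol and J/mol/K), `forces`, `reported_forces` (the classification of
#'   the supplied reported values, when given), `gas_constant`, `warnings`,
#'   and `k_by_temperature`.
#' @examples
#' tp <- thermo_profile(c("298" = 4.57e6, "310" = 5.01e6))
#' tp$delta_h / 1000
#' @export
thermo_profile <- function(k_by_temperature,
                           reported_delta_h = NULL,
                           reported_delta_s = NULL) {
  temps <- as.numeric(names(k_by_temperature))
  if (anyNA(temps)) stop("k_by_temperature must be named by temperatures in K")
  if (length(temps) < 2) stop("at least two temperatures required")
  ord <- order(temps)
  temps <- temps[ord]
  k <- unname(k_by_temperature)[ord]

  warnings <- character(0)
  if (length(temps) == 2) {
    dh <- vant_hoff_enthalpy(k[1], temps[1], k[2], temps[2])
  } else {
    slope <- unname(stats::coef(stats::lm(log(k) ~ I(1 / temps)))[2])
    dh <- -.gas_constant * slope
    warnings <- c(warnings,
                  "more than two temperatures: dH from OLS of ln K vs 1/T (beyond the two-point design)")
  }
  dg <- gibbs_from_k(k, temps)
  ds <- entropy_change(dh, dg, temps)
  names(dg) <- names(ds) <- as.character(temps)

  if (!is.null(reported_delta_h) &&
      abs(reported_delta_h - dh) > 0.01 * max(abs(dh), 1))
    warnings <- c(warnings, sprintf(
      "reported dH (%.4g J/mol) inconsistent with Van't Hoff dH computed from the binding constants (%.4g J/mol)",
      reported_delta_h, dh))
  if (!is.null(reported_delta_s) &&
      abs(reported_delta_s - mean(ds)) > 0.01 * max(abs(mean(ds)), 1))
    warnings <- c(warnings, sprintf(
      "reported dS (%.4g J/mol/K) inconsistent with computed mean dS (%.4g J/mol/K)",
      reported_delta_s, mean(ds)))

  structure(
    list(delta_h = dh, delta_g_by_T = dg, delta_s_by_T = ds,
         forces = classify_forces(dh, mean(ds)),
         gas_constant = .gas_constant,
         reported_delta_h = reported_delta_h,
         reported_delta_s = reported_delta_s,
         reported_forces = if (!is.null(reported_delta_h) &&
                               !is.null(reported_delta_s))
           classify_forces(reported_delta_h, reported_delta_s),
         warnings = warnings,
         k_by_temperature = stats::setNames(k, as.character(temps))),
    class = "thermo_profile"
  )
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat("Van't Hoff thermodynamic profile\n")
  cat(sprintf("  dH = %.2f kJ/mol\n", x$delta_h / 1000))
  for (tt in names(x$delta_g_by_T)) {
    cat(sprintf("  T = %s K: dG = %.2f kJ/mol, dS = %.2f J/mol/K\n",
                tt, x$delta_g_by_T[[tt]] / 1000, x$delta_s_by_T[[tt]]))
  }
  cat("  forces:", paste(x$forces, collapse = ", "), "\n")
  if (!is.null(x$reported_forces))
    cat("  forces from reported dH/dS:",
        paste(x$reported_forces, collapse = ", "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
summary.thermo_profile <- function(object, ...) {
  print(object)
  invisible(object)
}
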