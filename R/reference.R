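#' Reference constants for the apigenin-nicotinamide cocrystal / HSA system
#'
#' Bundled literature-derived constants for the 1:1 apigenin-nicotinamide
#' pharmaceutical cocrystal (AP-Nico) and its interaction with human serum
#' albumin, used by the examples, the vignette and the validation scripts:
#' molecular formulas and measured CHN fractions, apparent solubilities,
#' Stern-Volmer constants at two temperatures, double-log binding
#' parameters, site-marker competition constants, reported thermodynamic
#' parameters, and PXRD characteristic peak positions.
#'
#' Two temperatures (298 K and 310 K) cover ambient and physiological
#' conditions. Solubilities are apparent solubilities after 72 h of
#' suspension stirring. The reported thermodynamic table is intentionally
#' carried verbatim, including its internal inconsistencies, so that the
#' package's consistency checks can flag them (the reported binding
#' constants of AP-Nico increase with temperature, which implies a positive
#' Van't Hoff enthalpy, while the reported enthalpy is negative).
#'
#' @return A nested list with components `formulas`, `elemental` (measured
#'   CHN percentages), `solubility` (mol/L by temperature and compound),
#'   `quenching` (Ksv on the 1e5 L/mol scale by compound and temperature),
#'   `binding` (K_b in L/mol and n by compound and temperature),
#'   `competition` (marker constants, L/mol), `thermo_reported` (kJ/mol and
#'   J/mol/K), `pxrd` (characteristic peaks, degrees 2-theta), and
#'   `dissolution` (headline 4-h cumulative release fractions at pH 4.5).
#' @examples
#' ref <- apnico_reference()
#' ref$quenching$ap_nico
#' @export
apnico_reference <- function() {
  list(
    formulas = list(
      ap = "C15H10O5",        # apigenin
      nico = "C6H6N2O",       # nicotinamide
      ap_nico = "C21H16N2O6"  # 1:1 cocrystal
    ),
    elemental = list(
      ap = c(C = 64.68, H = 3.85),
      nico = c(C = 58.50, H = 5.02, N = 22.94),
      ap_nico = c(C = 64.47, H = 3.98, N = 6.93)
    ),
    solubility = list(
      # apparent solubility, mol/L; first row reported at 298 K (see
      # package vignette on the temperature-label ambiguity)
      "298" = c(ap = 0.23e-5, ap_nico = 0.57e-5),
      "310" = c(ap = 0.28e-5, ap_nico = 0.81e-5)
    ),
    quenching = list(
      # Stern-Volmer constants, L/mol
      ap = c("298" = 0.27e5, "310" = 0.13e5),
      ap_nico = c("298" = 5.54e5, "310" = 3.82e5),
      tau0 = 1e-8
    ),
    binding = list(
      # double-log binding constants (L/mol) and site numbers
      ap = list(k_b = c("298" = 0.67e6, "310" = 2.39e6),
                n = c("298" = 1.36, "310" = 1.46)),
      ap_nico = list(k_b = c("298" = 4.57e6, "310" = 5.01e6),
                     n = c("298" = 1.48, "310" = 1.93))
    ),
    competition = list(
      # binding constants at 298 K in the presence of site markers, L/mol
      ap = c(warfarin = 0.57e5, ibuprofen = 1.89e5),
      ap_nico = c(warfarin = 1.05e5, ibuprofen = 1.73e5)
    ),
    thermo_reported = list(
      # reported thermodynamic parameters (kJ/mol, J/mol/K)
      ap = list(delta_h = -47.34, delta_s = -59.91,
                delta_g = c("298" = -33.28, "310" = -34.34)),
      ap_nico = list(delta_h = -14.45, delta_s = -21.36,
                     delta_g = c("298" = -38.47, "310" = -36.56))
    ),
    pxrd = list(
      ap = c(11.08, 14.08, 15.86),
      nico = c(14.92, 25.84, 27.71),
      ap_nico_new = c(7.31, 10.36, 20.68)
    ),
    dissolution = list(
      # 4-h cumulative release fractions at pH 4.5
      ap = 0.43, ap_nico = 0.71, t_final = 240
    )
  )
}
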