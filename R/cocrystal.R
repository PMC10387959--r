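# IUPAC 2021 conventional standard atomic weights, elements common in
# small-molecule pharmaceuticals.
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Br = 79.904, I = 126.904
)

#' Parse a molecular formula string
#'
#' Hill-style formulas such as `"C21H16N2O6"`; an omitted count means 1.
#'
#' @param formula a formula string, or an already-parsed named integer
#'   vector (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C15H10O5")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1)
    toks <- regmatches(formula,
                       gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
    if (!length(toks) || sum(nchar(toks)) != nchar(formula))
      stop("cannot parse formula: ", formula)
    elems <- sub("[0-9]*$", "", toks)
    nums <- sub("^[A-Z][a-z]?", "", toks)
    counts <- ifelse(nzchar(nums), as.integer(nums), 1L)
    names(counts) <- elems
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (any(counts < 1)) stop("element counts must be >= 1")
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts
}

#' Theoretical mass fractions of a molecular formula
#'
#' Percent by mass of each element, from IUPAC standard atomic weights.
#' Fractions always sum to 100 (within 0.01) and are invariant under
#' multiplying the whole formula by an integer.
#'
#' @param formula formula string or parsed counts, see [parse_formula()].
#' @return Named numeric vector of mass percentages.
#' @examples
#' mass_fractions("C15H10O5")["C"]    # 66.67 (apigenin)
#' mass_fractions("C21H16N2O6")["N"]  # 7.14 (1:1 apigenin-nicotinamide)
#' @export
mass_fractions <- function(formula) {
  counts <- parse_formula(formula)
  masses <- counts * .atomic_weights[names(counts)]
  100 * masses / sum(masses)
}

#' Check measured elemental composition against a formula
#'
#' Compares measured C/H/N (or other) mass percentages against the
#' theoretical mass fractions of a formula. The per-element relative error
#' is |measured - theoretical| / theoretical * 100; the check passes when
#' every error is within the tolerance (default 5%), the usual acceptance
#' bound for confirming a synthesized stoichiometry by elemental analysis.
#'
#' @param formula formula string or parsed counts.
#' @param measured named numeric vector of measured mass percentages; its
#'   elements must all occur in the formula.
#' @param tolerance maximum admissible relative error, percent (default 5).
#' @return An object of class `composition_report`: a data frame with
#'   columns `element`, `theoretical`, `measured`, `relative_error`, `pass`,
#'   plus attributes `overall_pass` and `tolerance`.
#' @examples
#' composition_check("C15H10O5", c(C = 64.68, H = 3.85))
#' @export
composition_check <- function(formula, measured, tolerance = 5) {
  if (tolerance <= 0) stop("tolerance must be positive")
  theo <- mass_fractions(formula)
  extra <- setdiff(names(measured), names(theo))
  if (length(extra))
    stop("measured element(s) absent from formula: ",
         paste(extra, collapse = ", "))
  theo <- theo[names(measured)]
  rel <- abs(measured - theo) / theo * 100
  rep <- data.frame(element = names(measured),
                    theoretical = unname(theo),
                    measured = unname(measured),
                    relative_error = unname(rel),
                    pass = unname(rel <= tolerance),
                    stringsAsFactors = FALSE)
  structure(rep, class = c("composition_report", "data.frame"),
            overall_pass = all(rep$pass), tolerance = tolerance)
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("Elemental composition check (tolerance %.3g%%)\n",
              attr(x, "tolerance")))
  y <- as.data.frame(x)
  y$theoretical <- round(y$theoretical, 2)
  y$measured <- round(y$measured, 2)
  y$relative_error <- round(y$relative_error, 2)
  print(y, row.names = FALSE)
  cat("overall:", if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Construct a dissolution sampling series
#'
#' Holds the per-draw released fractions of a dissolution experiment with
#' volume replacement: at each sampling time a volume `v_sample` is drawn
#' from the `v_medium` vessel (and replaced with fresh medium), so material
#' removed at earlier draws must be credited back when computing cumulative
#' release.
#'
#' @param times sampling times, min, strictly increasing.
#' @param fractions fraction of the dose measured in the vessel at each
#'   draw (dimensionless, non-negative).
#' @param v_sample sampled volume per draw, mL.
#' @param v_medium total medium volume, mL (>= `v_sample`).
#' @return An object of class `dissolution_series`.
#' @export
dissolution_series <- function(times, fractions, v_sample, v_medium) {
  if (length(times) != length(fractions))
    stop("times and fractions must have the same length")
  if (!length(times)) stop("empty series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (v_sample < 0 || v_medium <= 0 || v_sample > v_medium)
    stop("require 0 <= v_sample <= v_medium and v_medium > 0")
  structure(list(times = as.numeric(times), fractions = as.numeric(fractions),
                 v_sample = v_sample, v_medium = v_medium),
            class = "dissolution_series")
}

#' Volume-corrected cumulative dissolution release
#'
#' At draw n the vessel concentration reflects only material still in
#' solution; the fractions removed in earlier draws must be added back,
#' scaled by the sampled-to-total volume ratio:
#' \deqn{Q_n = \left(A_n + \frac{V_1}{V_2}\sum_{i<n} A_i\right) \times 100,}
#' where A_i is the fraction of the dose measured at draw i, V_1 the
#' sampled volume and V_2 the medium volume. With V_1 = 0 the profile is
#' just the raw fraction series in percent.
#'
#' @param series a [dissolution_series()].
#' @return An object of class `release_profile`: a data frame with columns
#'   `time` (min) and `q_percent` (cumulative release, %).
#' @examples
#' ds <- dissolution_series(c(5, 10, 15), c(0.10, 0.20, 0.30), 4, 100)
#' cumulative_release(ds)  # Q3 = 31.2%
#' @export
cumulative_release <- function(series) {
  stopifnot(inherits(series, "dissolution_series"))
  a <- series$fractions
  ratio <- series$v_sample / series$v_medium
  prior <- c(0, cumsum(a)[-length(a)])
  q <- (a + ratio * prior) * 100
  structure(data.frame(time = series$times, q_percent = q),
            class = c("release_profile", "data.frame"),
            v_ratio = ratio)
}

#' @export
print.release_profile <- function(x, ...) {
  cat("Cumulative dissolution release (volume-corrected)\n")
  y <- as.data.frame(x)
  y$q_percent <- round(y$q_percent, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Apparent solubility enhancement ratio
#'
#' Ratio of the apparent solubility of a product (e.g. a cocrystal) to its
#' parent compound, with the nearest-integer fold label used in headline
#' statements ("about 3 times higher").
#'
#' @param s_product,s_parent apparent solubilities, mol/L (positive).
#' @return A list with `ratio` (dimensionless) and `fold_label` (nearest
#'   integer).
#' @examples
#' solubility_ratio(0.81e-5, 0.28e-5)  # ratio 2.89, fold 3
#' @export
solubility_ratio <- function(s_product, s_parent) {
  if (any(c(s_product, s_parent) <= 0)) stop("solubilities must be positive")
  ratio <- s_product / s_parent
  list(ratio = ratio, fold_label = as.integer(round(ratio)))
}

#' Construct a PXRD peak set
#'
#' A sorted, deduplicated list of diffraction peak positions in degrees 2-theta.
#'
#' @param angles peak positions, degrees 2-theta, each in (0, 90).
#' @param dedup_tol peaks closer than this are merged (degrees; default 1e-6).
#' @return An object of class `peak_set` (numeric vector, sorted ascending).
#' @export
peak_set <- function(angles, dedup_tol = 1e-6) {
  if (!length(angles)) stop("empty peak set")
  if (any(angles <= 0 | angles >= 90))
    stop("peak angles must lie in (0, 90) degrees 2-theta")
  angles <- sort(as.numeric(angles))
  keep <- c(TRUE, diff(angles) > dedup_tol)
  structure(angles[keep], class = "peak_set")
}

#' Detect a new crystalline phase from PXRD peak lists
#'
#' A product peak with no peak of any parent pattern within the angular
#' tolerance cannot come from a physical mixture of the parents; one or
#' more such peaks indicate a new crystalline phase (e.g. cocrystal
#' formation). A product whose every peak matches a parent peak is a
#' superposition. Increasing the tolerance can only remove new peaks,
#' never create them.
#'
#' @param product a [peak_set()] (or numeric vector) of product peaks.
#' @param parents list of parent peak sets.
#' @param tolerance matching tolerance, degrees 2-theta (default 0.2).
#' @return A list with `new_peaks` (a `peak_set`, possibly empty numeric)
#'   and `verdict` (`"new_phase"` or `"superposition"`).
#' @examples
#' pxrd_new_phase(c(7.31, 10.36, 20.68, 11.08),
#'                list(c(11.08, 14.08, 15.86), c(14.92, 25.84, 27.71)))
#' @export
pxrd_new_phase <- function(product, parents, tolerance = 0.2) {
  if (tolerance <= 0) stop("tolerance must be positive")
  product <- if (inherits(product, "peak_set")) product else peak_set(product)
  parent_angles <- sort(unlist(lapply(parents, function(p)
    as.numeric(if (inherits(p, "peak_set")) p else peak_set(p)))))
  if (!length(parent_angles)) stop("empty parent peak sets")
  is_new <- vapply(as.numeric(product), function(a)
    min(abs(parent_angles - a)) > tolerance, logical(1))
  new_angles <- as.numeric(product)[is_new]
  list(
    new_peaks = if (length(new_angles)) peak_set(new_angles) else numeric(0),
    verdict = if (any(is_new)) "new_phase" else "superposition"
  )
}

#' Read a single-column PXRD peak list or a dissolution table from CSV
#'
#' Peak lists: one column `angle` (degrees 2-theta). Dissolution tables:
#' columns `time` (min) and `fraction`. Comment lines start with `#`.
#'
#' @param path file path.
#' @return For `read_peaks`, a [peak_set()].
#' @export
read_peaks <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  if (!"angle" %in% names(tab)) stop("missing 'angle' column in ", path)
  peak_set(tab$angle)
}

#' @rdname read_peaks
#' @param v_sample,v_medium sampling and medium volumes, mL (see
#'   [dissolution_series()]).
#' @return For `read_dissolution`, a [dissolution_series()].
#' @export
read_dissolution <- function(path, v_sample, v_medium) {
  tab <- utils::read.csv(path, comment.char = "#")
  for (col in c("time", "fraction"))
    if (!col %in% names(tab)) stop("missing '", col, "' column in ", path)
  dissolution_series(tab$time, tab$fraction, v_sample, v_medium)
}
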