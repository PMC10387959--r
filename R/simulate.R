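#' Default titration concentration grid
#'
#' Eight quencher levels, 0 and 0.4-4.0 x 1e-5 mol/L, matching the standard
#' eight-point titration design used throughout the package.
#'
#' @return Numeric vector of 8 concentrations in mol/L.
#' @export
default_q_grid <- function() {
  c(0, 0.40, 0.80, 1.00, 1.60, 2.40, 3.20, 4.00) * 1e-5
}

#' Simulate a fluorescence quenching titration with known ground truth
#'
#' Forward model for the two analysis regressions. Under the Stern-Volmer
#' model the noiseless intensity is F(Q) = f0 / (1 + Ksv Q); under the
#' double-log binding model F(Q) = f0 / (1 + K Q^n). Multiplicative
#' Gaussian noise of relative standard deviation `noise_sd` is applied to
#' every intensity (fluorescence error scales with intensity; volumetric
#' concentration preparation is treated as exact). With the same seed the
#' output is bit-identical.
#'
#' Optional inner-filter attenuation (`ife`) distorts the measured
#' intensities after noise, recording per-point absorbances proportional to
#' the quencher concentration so that [correct_inner_filter()] can undo the
#' distortion exactly.
#'
#' @param model `"stern_volmer"` or `"double_log"`.
#' @param ksv true Stern-Volmer constant, L/mol (`stern_volmer` model).
#' @param k,n true binding constant (L/mol) and site number (`double_log`
#'   model).
#' @param f0 reference intensity, arbitrary units (default 1000; all
#'   analyses are invariant to this scale).
#' @param q_grid concentration grid, mol/L, including 0 (default
#'   [default_q_grid()]).
#' @param noise_sd relative SD of the multiplicative Gaussian noise
#'   (default 0 = noiseless).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param temperature temperature in K attached to the series (default 298).
#' @param ife optional list `list(eps_ex =, eps_em =, base =)` of effective
#'   absorbance-per-concentration coefficients (L/mol) and correction base,
#'   applied via [distort_inner_filter()].
#' @return A [titration_series()].
#' @examples
#' ts <- simulate_titration(model = "double_log", k = 4.57e6, n = 1.48,
#'                          noise_sd = 0.01, seed = 42)
#' dlog_fit(ts)
#' @export
simulate_titration <- function(model = c("stern_volmer", "double_log"),
                               ksv = NULL, k = NULL, n = NULL, f0 = 1000,
                               q_grid = default_q_grid(), noise_sd = 0,
                               seed = NULL, temperature = 298, ife = NULL) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!0 %in% q_grid) stop("q_grid must include the zero reference point")
  f_true <- switch(model,
    stern_volmer = {
      if (is.null(ksv) || ksv <= 0) stop("stern_volmer model requires ksv > 0")
      f0 / (1 + ksv * q_grid)
    },
    double_log = {
      if (is.null(k) || is.null(n) || k <= 0 || n <= 0)
        stop("double_log model requires k > 0 and n > 0")
      f0 / (1 + k * q_grid^n)
    }
  )
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f_obs <- f_true * (1 + stats::rnorm(length(f_true), 0, noise_sd))
    f_obs <- pmax(f_obs, .Machine$double.eps * f0)
  } else {
    f_obs <- f_true
  }
  series <- titration_series(q_grid, f_obs, temperature = temperature)
  if (!is.null(ife))
    series <- distort_inner_filter(series, eps_ex = ife$eps_ex,
                                   eps_em = ife$eps_em,
                                   base = if (is.null(ife$base)) "ten"
                                          else ife$base)
  series
}

#' Apply a synthetic inner-filter distortion to a titration series
#'
#' Sets per-point absorbances proportional to the quencher concentration
#' (a_ex = eps_ex * Q, a_em = eps_em * Q) and attenuates each measured
#' intensity by base^(-(a_ex + a_em)/2) — the exact inverse of
#' [correct_inner_filter()], so distorting and then correcting with the
#' same base recovers the original intensities.
#'
#' @param series a [titration_series()].
#' @param eps_ex,eps_em effective absorbance-per-concentration coefficients,
#'   L/mol, non-negative.
#' @param base `"ten"` or `"e"`.
#' @return A new [titration_series()] with absorbance columns set and
#'   attenuated measured intensities; its corrected intensities equal the
#'   input's.
#' @export
distort_inner_filter <- function(series, eps_ex, eps_em,
                                 base = c("ten", "e")) {
  base <- match.arg(base)
  stopifnot(inherits(series, "titration_series"))
  if (eps_ex < 0 || eps_em < 0) stop("coefficients must be non-negative")
  pts <- series$points
  a_ex <- eps_ex * pts$q_conc
  a_em <- eps_em * pts$q_conc
  b <- if (base == "ten") 10 else exp(1)
  f_att <- pts$f_measured * b^(-(a_ex + a_em) / 2)
  titration_series(pts$q_conc, f_att, a_ex = a_ex, a_em = a_em,
                   temperature = series$temperature,
                   excitation_nm = series$excitation_nm, ife_base = base)
}

#' Simulate a site-marker competition experiment with a planted site
#'
#' Generates marker-presence binding constants from a free binding constant
#' and per-site displacement fractions: K_marker = k_free * (1 -
#' displacement). The marker with the larger displacement marks the planted
#' true site, which [site_competition()] should recover.
#'
#' @param k_free binding constant without marker, L/mol.
#' @param displacement_site1 displacement fraction in [0, 1) for the site-I
#'   marker (warfarin).
#' @param displacement_site2 displacement fraction in [0, 1) for the
#'   site-II marker (ibuprofen).
#' @return A list with `marker_k` (named constants for `warfarin` and
#'   `ibuprofen`) and `planted_site`.
#' @export
simulate_competition_pair <- function(k_free, displacement_site1,
                                      displacement_site2) {
  d <- c(displacement_site1, displacement_site2)
  if (any(d < 0 | d >= 1)) stop("displacements must lie in [0, 1)")
  marker_k <- c(warfarin = k_free * (1 - displacement_site1),
                ibuprofen = k_free * (1 - displacement_site2))
  planted <- if (displacement_site1 == displacement_site2) "indeterminate"
             else if (displacement_site1 > displacement_site2) "Sudlow site I"
             else "Sudlow site II"
  list(marker_k = marker_k, planted_site = planted)
}

#' Simulate a dissolution experiment with volume replacement
#'
#' The planted cumulative-release truth is first-order,
#' C(t) = q_inf (1 - exp(-rate_k t)). Per-draw fractions A_i are
#' constructed so that the volume-corrected cumulative release formula
#' applied to the series recovers C(t_i) exactly in the noiseless case:
#' A_n = C(t_n) - (V1/V2) * sum of earlier A_i. Optional seeded
#' multiplicative noise perturbs the per-draw fractions.
#'
#' @param q_inf asymptotic released fraction, in (0, 1].
#' @param rate_k first-order rate constant, 1/min.
#' @param times sampling times, min, strictly increasing.
#' @param v_sample,v_medium sampled and total volumes, mL.
#' @param noise_sd relative SD of multiplicative noise on per-draw
#'   fractions (default 0).
#' @param seed integer seed.
#' @return A [dissolution_series()] with attribute `truth`, the planted
#'   cumulative fractions C(t).
#' @examples
#' ds <- simulate_dissolution(0.75, 0.012, c(30, 60, 120, 240), 5, 100)
#' cumulative_release(ds)
#' @export
simulate_dissolution <- function(q_inf, rate_k, times, v_sample, v_medium,
                                 noise_sd = 0, seed = NULL) {
  if (q_inf <= 0 || q_inf > 1) stop("q_inf must lie in (0, 1]")
  if (rate_k <= 0) stop("rate_k must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  truth <- q_inf * (1 - exp(-rate_k * times))
  ratio <- v_sample / v_medium
  a <- numeric(length(times))
  for (i in seq_along(times)) {
    a[i] <- truth[i] - ratio * sum(a[seq_len(i - 1)])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    a <- pmax(a * (1 + stats::rnorm(length(a), 0, noise_sd)), 0)
  }
  out <- dissolution_series(times, a, v_sample, v_medium)
  attr(out, "truth") <- truth
  out
}
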