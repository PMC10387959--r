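#' Fit the Stern-Volmer quenching model
#'
#' Regresses the intensity ratio F0/F of a titration on the quencher
#' concentration. Under the Stern-Volmer model
#' \deqn{F_0/F = 1 + K_{SV}[Q] = 1 + K_q \tau_0 [Q],}
#' the slope is the Stern-Volmer constant (L/mol), and dividing it by the
#' unquenched fluorophore lifetime `tau0` gives the bimolecular quenching
#' rate constant Kq. A Kq far above the diffusion-controlled limit
#' (about 2e10 L/mol/s) indicates static quenching through ground-state
#' complex formation rather than collisional deactivation; the fit classifies
#' the mechanism accordingly.
#'
#' Corrected intensities are used throughout. The default free-intercept fit
#' tolerates a small experimental offset from the theoretical intercept of 1;
#' an intercept deviating from 1 by more than 10% is flagged in the fit's
#' warnings. The `fixed_at_one` mode instead regresses F0/F - 1 on [Q]
#' through the origin.
#'
#' @param series a [titration_series()].
#' @param intercept_mode `"free"` (default) or `"fixed_at_one"`.
#' @param tau0 unquenched fluorophore lifetime in seconds; default 1e-8 s,
#'   the typical intrinsic lifetime of the tryptophan fluorophore.
#' @param kq_threshold mechanism threshold in L/mol/s; Kq strictly above it
#'   classifies as static. Default 2e10 (diffusion-controlled limit).
#' @return An object of class `sv_fit` with elements `ksv` (L/mol), `kq`
#'   (L/mol/s), `tau0`, `mechanism` (`"static"` or `"dynamic"`), `fit` (a
#'   list with `slope`, `intercept`, `r_squared`, `n_points`, `residuals`),
#'   `intercept_mode`, `warnings`, `temperature`, `ife_base`, and `data`
#'   (data frame of `q` and the regressed ratio).
#' @examples
#' ts <- simulate_titration(model = "stern_volmer", ksv = 5.54e5)
#' fit <- sv_fit(ts)
#' coef(fit)
#' fit$mechanism
#' @export
sv_fit <- function(series, intercept_mode = c("free", "fixed_at_one"),
                   tau0 = 1e-8, kq_threshold = 2e10) {
  intercept_mode <- match.arg(intercept_mode)
  stopifnot(inherits(series, "titration_series"))
  if (tau0 <= 0) stop("tau0 must be positive")
  pts <- series$points
  if (any(pts$f_corrected <= 0)) stop("non-positive corrected intensity")
  q <- pts$q_conc
  if (length(unique(q[q > 0])) < 1 || length(unique(q)) < 2)
    stop("degenerate design: no spread in quencher concentration")
  ratio <- series$f0 / pts$f_corrected

  warnings <- character(0)
  if (intercept_mode == "free") {
    lmfit <- stats::lm(ratio ~ q)
    slope <- unname(stats::coef(lmfit)[2])
    intercept <- unname(stats::coef(lmfit)[1])
    res <- unname(stats::residuals(lmfit))
    r2 <- r_squared_about_mean(ratio, res)
    if (abs(intercept - 1) > 0.10)
      warnings <- c(warnings, sprintf(
        "intercept %.4g deviates from 1 by more than 10%%", intercept))
  } else {
    y <- ratio - 1
    lmfit <- stats::lm(y ~ 0 + q)
    slope <- unname(stats::coef(lmfit)[1])
    intercept <- 1
    res <- unname(stats::residuals(lmfit))
    r2 <- r_squared_about_mean(y, res)
  }

  kq <- slope / tau0
  structure(
    list(
      ksv = slope, kq = kq, tau0 = tau0,
      mechanism = classify_mechanism(max(kq, 0), threshold = kq_threshold),
      fit = list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = length(q), residuals = res),
      intercept_mode = intercept_mode, kq_threshold = kq_threshold,
      warnings = warnings, temperature = series$temperature,
      ife_base = series$ife_base,
      data = data.frame(q = q, ratio = ratio)
    ),
    class = "sv_fit"
  )
}

# R^2 = 1 - SS_res/SS_tot on the regressed variable, SS_tot about the mean.
r_squared_about_mean <- function(y, res) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (sum(res^2) == 0) 1 else 0)
  1 - sum(res^2) / ss_tot
}

#' Bimolecular quenching rate constant
#'
#' Converts a Stern-Volmer constant to the bimolecular quenching rate
#' constant Kq = Ksv / tau0.
#'
#' @param ksv Stern-Volmer constant, L/mol.
#' @param tau0 unquenched fluorophore lifetime, s (default 1e-8).
#' @return Kq in L/mol/s.
#' @examples
#' bimolecular_rate(5.54e5)  # 5.54e13
#' @export
bimolecular_rate <- function(ksv, tau0 = 1e-8) {
  if (any(tau0 <= 0)) stop("tau0 must be positive")
  ksv / tau0
}

#' Classify the quenching mechanism from Kq
#'
#' A bimolecular quenching rate constant significantly greater than the
#' diffusion-controlled limit cannot arise from collisional (dynamic)
#' quenching and indicates static quenching via a ground-state complex. The
#' rule is strict: Kq exactly at the threshold classifies as dynamic.
#'
#' @param kq bimolecular quenching rate constant, L/mol/s (non-negative).
#' @param threshold classification threshold, L/mol/s (default 2e10).
#' @return `"static"` or `"dynamic"`.
#' @export
classify_mechanism <- function(kq, threshold = 2e10) {
  if (any(kq < 0)) stop("negative kq")
  ifelse(kq > threshold, "static", "dynamic")
}

#' Corroborate the quenching mechanism from the temperature trend of Ksv
#'
#' Static quenching weakens with temperature (complexes dissociate), so Ksv
#' decreases as T rises; dynamic quenching strengthens (faster diffusion), so
#' Ksv increases. Given Stern-Volmer fits at two or more temperatures this
#' reports whether the trend corroborates a single mechanism.
#'
#' @param fits a list of [sv_fit()] objects, each carrying its temperature.
#' @return `"consistent_static"`, `"consistent_dynamic"`, or `"mixed"`.
#' @examples
#' t1 <- sv_fit(simulate_titration(ksv = 5.54e5, temperature = 298))
#' t2 <- sv_fit(simulate_titration(ksv = 3.82e5, temperature = 310))
#' temperature_trend(list(t1, t2))  # "consistent_static"
#' @export
temperature_trend <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "sv_fit")))
  temps <- vapply(fits, `[[`, numeric(1), "temperature")
  if (length(unique(temps)) < 2)
    stop("temperature trend requires fits at two or more temperatures")
  ord <- order(temps)
  ksv <- vapply(fits, `[[`, numeric(1), "ksv")[ord]
  d <- diff(ksv)
  if (all(d < 0)) "consistent_static"
  else if (all(d > 0)) "consistent_dynamic"
  else "mixed"
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("Stern-Volmer quenching fit\n")
  cat(sprintf("  T = %g K, %d points, intercept mode: %s\n",
              x$temperature, x$fit$n_points, x$intercept_mode))
  cat(sprintf("  Ksv = %.4g L/mol   Kq = %.4g L/mol/s (tau0 = %g s)\n",
              x$ksv, x$kq, x$tau0))
  cat(sprintf("  intercept = %.4f   R^2 = %.4f\n",
              x$fit$intercept, x$fit$r_squared))
  cat(sprintf("  mechanism: %s quenching\n", x$mechanism))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.sv_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual SD (on F0/F): %.3g\n", stats::sd(object$fit$residuals)))
  invisible(object)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(intercept = object$fit$intercept, ksv = object$ksv)
}

#' @export
residuals.sv_fit <- function(object, ...) object$fit$residuals

#' Predict the intensity ratio F0/F at new quencher concentrations
#'
#' @param object an [sv_fit()].
#' @param newdata numeric vector of quencher concentrations, mol/L; defaults
#'   to the fitted concentrations.
#' @param ... unused.
#' @return Predicted F0/F values.
#' @export
predict.sv_fit <- function(object, newdata = NULL, ...) {
  q <- if (is.null(newdata)) object$data$q else newdata
  object$fit$intercept + object$ksv * q
}

#' @export
plot.sv_fit <- function(x, ...) {
  plot(x$data$q, x$data$ratio, xlab = "[Q] (mol/L)",
       ylab = expression(F[0] / F),
       main = sprintf("Stern-Volmer plot (T = %g K)", x$temperature), ...)
  graphics::abline(x$fit$intercept, x$ksv, lty = 2)
  invisible(x)
}

#' Simulate a titration from a fitted Stern-Volmer model
#'
#' Generates `nsim` synthetic titration series from the fitted Ksv on the
#' fitted concentration grid, via [simulate_titration()].
#'
#' @param object an [sv_fit()].
#' @param nsim number of series to generate.
#' @param seed integer seed for reproducibility.
#' @param noise_sd relative multiplicative noise SD (default 0.01).
#' @param f0 reference intensity of the simulated series.
#' @param ... unused.
#' @return A list of [titration_series()] objects.
#' @export
simulate.sv_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0.01,
                            f0 = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s)
    simulate_titration(model = "stern_volmer", ksv = object$ksv, f0 = f0,
                       q_grid = object$data$q, noise_sd = noise_sd, seed = s,
                       temperature = object$temperature))
}
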