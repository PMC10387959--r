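#' Run the full interaction-analysis pipeline
#'
#' Orchestrates the analysis stages over a structured configuration:
#' inner-filter-corrected titrations are fitted per temperature with the
#' Stern-Volmer model (quenching mechanism), then with the double-log
#' binding model (binding constant, site number, affinity); binding
#' constants across temperatures feed the Van't Hoff thermodynamic profile
#' and force classification; optional competition, elemental-composition,
#' dissolution-release and PXRD stages run independently. Stages are
#' independent: a failed stage is recorded as an error in the report and
#' does not abort the others. Given the same configuration (including
#' seeds) the report is deterministic.
#'
#' @param config a list with any subset of:
#' \describe{
#'   \item{series}{list of [titration_series()] objects (or file paths read
#'     via [read_titration()], in which case each entry is
#'     `list(path =, temperature =)`), one per temperature.}
#'   \item{tau0}{fluorophore lifetime for the Stern-Volmer stage (default
#'     1e-8 s).}
#'   \item{competition}{list with `k_free`, `marker_k`, and optionally
#'     `tie_margin` for [site_competition()].}
#'   \item{composition}{list with `formula`, `measured`, and optionally
#'     `tolerance` for [composition_check()].}
#'   \item{dissolution}{a [dissolution_series()] for [cumulative_release()].}
#'   \item{pxrd}{list with `product` and `parents` for [pxrd_new_phase()].}
#'   \item{thermo_reported}{optional list with `delta_h`, `delta_s` (J/mol,
#'     J/mol/K) checked against the computed profile.}
#' }
#' @return An object of class `analysis_report`: a list with per-stage
#'   results (`quenching`, `trend`, `binding`, `thermo`, `competition`,
#'   `composition`, `release`, `pxrd`), collected `warnings` and `errors`
#'   (each named by source stage), and `provenance` (software version and
#'   units).
#' @examples
#' s298 <- simulate_titration(model = "double_log", k = 4.57e6, n = 1.48)
#' s310 <- simulate_titration(model = "double_log", k = 5.01e6, n = 1.93,
#'                            temperature = 310)
#' rep <- run_pipeline(list(series = list(s298, s310)))
#' rep$thermo$forces
#' @export
run_pipeline <- function(config) {
  if (!length(config)) stop("no stages requested: empty configuration")
  report <- list(quenching = NULL, trend = NULL, binding = NULL,
                 thermo = NULL, competition = NULL, composition = NULL,
                 release = NULL, pxrd = NULL,
                 warnings = list(), errors = list(),
                 provenance = list(
                   package = "quenchbind",
                   version = as.character(utils::packageVersion("quenchbind")),
                   units = c(k = "L/mol", kq = "L/mol/s", dh_dg = "J/mol",
                             ds = "J/mol/K", q_conc = "mol/L")))
  note_warning <- function(stage, msg) {
    report$warnings[[length(report$warnings) + 1]] <<-
      list(stage = stage, message = msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note_warning(stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      report$errors[[length(report$errors) + 1]] <<-
        list(stage = stage, message = conditionMessage(e))
      NULL
    })
  }

  if (!is.null(config$series)) {
    series <- lapply(config$series, function(s) {
      if (inherits(s, "titration_series")) s
      else read_titration(s$path, temperature = s$temperature)
    })
    tau0 <- if (is.null(config$tau0)) 1e-8 else config$tau0
    report$quenching <- run_stage("quenching", {
      fits <- lapply(series, sv_fit, tau0 = tau0)
      names(fits) <- vapply(series, function(s) as.character(s$temperature),
                            character(1))
      for (f in fits)
        for (w in f$warnings) note_warning("quenching", w)
      fits
    })
    if (!is.null(report$quenching) && length(report$quenching) >= 2)
      report$trend <- run_stage("quenching",
                                temperature_trend(report$quenching))
    report$binding <- run_stage("binding", {
      fits <- lapply(series, dlog_fit)
      names(fits) <- names(report$quenching)
      for (f in fits)
        for (note in f$notes) note_warning("binding", note)
      fits
    })
    if (!is.null(report$binding) && length(report$binding) >= 2) {
      report$thermo <- run_stage("thermodynamics", {
        k_by_t <- vapply(report$binding, `[[`, numeric(1), "k_b")
        tp <- thermo_profile(
          k_by_t,
          reported_delta_h = config$thermo_reported$delta_h,
          reported_delta_s = config$thermo_reported$delta_s)
        for (w in tp$warnings) note_warning("thermodynamics", w)
        tp
      })
    }
  }

  if (!is.null(config$competition)) {
    report$competition <- run_stage("competition", {
      cc <- config$competition
      res <- site_competition(
        cc$k_free, cc$marker_k,
        tie_margin = if (is.null(cc$tie_margin)) 0.02 else cc$tie_margin)
      if (res$near_tie)
        note_warning("competition",
                     "top two marker displacements within the tie margin")
      res
    })
  }
  if (!is.null(config$composition)) {
    report$composition <- run_stage("composition", {
      cc <- config$composition
      composition_check(cc$formula, cc$measured,
                        tolerance = if (is.null(cc$tolerance)) 5
                                    else cc$tolerance)
    })
  }
  if (!is.null(config$dissolution)) {
    report$release <- run_stage("release",
                                cumulative_release(config$dissolution))
  }
  if (!is.null(config$pxrd)) {
    report$pxrd <- run_stage("pxrd", {
      pxrd_new_phase(config$pxrd$product, config$pxrd$parents,
                     tolerance = if (is.null(config$pxrd$tolerance)) 0.2
                                 else config$pxrd$tolerance)
    })
  }

  ran <- !vapply(report[c("quenching", "binding", "thermo", "competition",
                          "composition", "release", "pxrd")], is.null,
                 logical(1))
  if (!any(ran) && !length(report$errors))
    stop("no stages requested: configuration matched no stage")
  structure(report, class = "analysis_report")
}

#' Write an analysis report to JSON or formatted text
#'
#' JSON output is schema-stable and round-trippable through
#' [jsonlite::fromJSON()]; text output mirrors the tabular layout of a lab
#' report, with a WARNINGS section when any stage raised one. Stages absent
#' from the report are omitted from the output.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path output file path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "analysis_report"))
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else {
    writeLines(utils::capture.output(print(report)), path)
  }
  invisible(path)
}

# Flatten the S3 report into plain lists for stable JSON serialization.
report_to_list <- function(report) {
  out <- list(schema_version = 1L)
  if (!is.null(report$quenching))
    out$quenching <- lapply(report$quenching, function(f)
      list(temperature = f$temperature, ksv = f$ksv, kq = f$kq,
           tau0 = f$tau0, mechanism = f$mechanism,
           fit = f$fit[c("slope", "intercept", "r_squared", "n_points")]))
  if (!is.null(report$trend)) out$temperature_trend <- report$trend
  if (!is.null(report$binding))
    out$binding <- lapply(report$binding, function(f)
      list(temperature = f$temperature, log_k = f$log_k,
           n_sites = f$n_sites, k_b = f$k_b,
           affinity_class = f$affinity_class,
           fit = f$fit[c("slope", "intercept", "r_squared", "n_points")]))
  if (!is.null(report$thermo))
    out$thermo <- list(delta_h = report$thermo$delta_h,
                       delta_g_by_T = as.list(report$thermo$delta_g_by_T),
                       delta_s_by_T = as.list(report$thermo$delta_s_by_T),
                       forces = I(report$thermo$forces),
                       reported_forces = if (!is.null(report$thermo$reported_forces))
                         I(report$thermo$reported_forces))
  if (!is.null(report$competition))
    out$competition <- list(k_free = report$competition$k_free,
                            assigned_site = report$competition$assigned_site,
                            near_tie = report$competition$near_tie,
                            table = report$competition$table)
  if (!is.null(report$composition))
    out$composition <- list(
      table = as.data.frame(report$composition),
      overall_pass = attr(report$composition, "overall_pass"),
      tolerance = attr(report$composition, "tolerance"))
  if (!is.null(report$release))
    out$release <- as.data.frame(report$release)
  if (!is.null(report$pxrd))
    out$pxrd <- list(new_peaks = as.numeric(report$pxrd$new_peaks),
                     verdict = report$pxrd$verdict)
  out$warnings <- report$warnings
  out$errors <- report$errors
  out$provenance <- report$provenance
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Interaction analysis report ==\n")
  if (!is.null(x$quenching)) {
    cat("\n-- Quenching (Stern-Volmer) --\n")
    for (f in x$quenching) print(f)
    if (!is.null(x$trend)) cat("temperature trend:", x$trend, "\n")
  }
  if (!is.null(x$binding)) {
    cat("\n-- Binding (double-log) --\n")
    for (f in x$binding) print(f)
  }
  if (!is.null(x$thermo)) {
    cat("\n-- Thermodynamics (Van't Hoff) --\n")
    print(x$thermo)
  }
  if (!is.null(x$competition)) {
    cat("\n-- Site competition --\n")
    print(x$competition)
  }
  if (!is.null(x$composition)) {
    cat("\n-- Elemental composition --\n")
    print(x$composition)
  }
  if (!is.null(x$release)) {
    cat("\n-- Dissolution release --\n")
    print(x$release)
  }
  if (!is.null(x$pxrd)) {
    cat("\n-- PXRD phase comparison --\n")
    cat("verdict:", x$pxrd$verdict, "\n")
    if (length(x$pxrd$new_peaks))
      cat("new peaks (deg 2-theta):",
          paste(as.numeric(x$pxrd$new_peaks), collapse = ", "), "\n")
  }
  if (length(x$warnings)) {
    cat("\n-- WARNINGS --\n")
    for (w in x$warnings) cat(sprintf("[%s] %s\n", w$stage, w$message))
  }
  if (length(x$errors)) {
    cat("\n-- ERRORS --\n")
    for (e in x$errors) cat(sprintf("[%s] %s\n", e$stage, e$message))
  }
  invisible(x)
}
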