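#' Construct a fluorescence titration series
#'
#' A titration series holds one temperature's quencher-concentration /
#' fluorescence curve: the intensity of the protein alone (the zero-quencher
#' reference point) followed by intensities at increasing quencher
#' concentrations. Optional absorbances at the excitation and maximum emission
#' wavelengths allow inner-filter correction of each measured intensity; all
#' downstream fits use the corrected intensities.
#'
#' @param q_conc numeric vector of quencher concentrations in mol/L. Must
#'   contain exactly one zero (the reference point) and no duplicates.
#' @param f numeric vector of measured fluorescence intensities (arbitrary
#'   units), strictly positive, same length as `q_conc`.
#' @param a_ex,a_em optional numeric vectors of absorbances at the excitation
#'   and maximum emission wavelengths (dimensionless, non-negative). Supply
#'   both or neither.
#' @param temperature temperature of the titration in K.
#' @param excitation_nm optional excitation wavelength in nm (metadata only).
#' @param ife_base base of the inner-filter correction, `"ten"` (the
#'   conventional correction) or `"e"`. Recorded on the object and used to
#'   compute corrected intensities when absorbances are present.
#' @return An object of class `titration_series`: a list with elements
#'   `points` (data frame with columns `q_conc`, `f_measured`, `a_ex`, `a_em`,
#'   `f_corrected`, sorted by increasing `q_conc`), `temperature`, `f0` (the
#'   corrected intensity of the zero-quencher point), `ife_base`, `corrected`
#'   (logical: were absorbances available), and `excitation_nm`.
#' @examples
#' q <- c(0, 0.4, 0.8, 1.0, 1.6, 2.4, 3.2, 4.0) * 1e-5
#' f <- 1000 / (1 + 5.54e5 * q)
#' ts <- titration_series(q, f, temperature = 298)
#' ts$f0
#' @seealso [correct_inner_filter()], [read_titration()], [sv_fit()],
#'   [dlog_fit()]
#' @export
titration_series <- function(q_conc, f, a_ex = NULL, a_em = NULL,
                             temperature, excitation_nm = NULL,
                             ife_base = c("ten", "e")) {
  ife_base <- match.arg(ife_base)
  if (length(q_conc) != length(f))
    stop("q_conc and f must have the same length")
  if (xor(is.null(a_ex), is.null(a_em)))
    stop("supply both a_ex and a_em, or neither")
  has_abs <- !is.null(a_ex)
  if (has_abs && (length(a_ex) != length(q_conc) ||
                  length(a_em) != length(q_conc)))
    stop("absorbance vectors must match the concentration vector in length")

  ord <- order(q_conc)
  pts <- data.frame(
    q_conc = as.numeric(q_conc)[ord],
    f_measured = as.numeric(f)[ord],
    a_ex = if (has_abs) as.numeric(a_ex)[ord] else NA_real_,
    a_em = if (has_abs) as.numeric(a_em)[ord] else NA_real_
  )
  pts$f_corrected <- if (has_abs) {
    correct_inner_filter(pts$f_measured, pts$a_ex, pts$a_em, base = ife_base)
  } else {
    pts$f_measured
  }

  obj <- structure(
    list(points = pts, temperature = as.numeric(temperature),
         f0 = NA_real_, ife_base = ife_base, corrected = has_abs,
         excitation_nm = excitation_nm),
    class = "titration_series"
  )
  problems <- validate_titration(obj)
  if (length(problems))
    stop("invalid titration series: ", paste(problems, collapse = "; "))
  obj$f0 <- pts$f_corrected[pts$q_conc == 0]
  obj
}

#' Validate a titration series
#'
#' Checks the structural invariants of a [titration_series()]: at least three
#' points, exactly one zero-concentration reference point, strictly increasing
#' non-negative concentrations, strictly positive measured intensities, and
#' non-negative absorbances where present. Returns the violations rather than
#' erroring, so malformed input can be reported in full.
#'
#' @param series a `titration_series`, or any list with a compatible `points`
#'   data frame.
#' @return A character vector of violation messages; `character(0)` if the
#'   series is valid.
#' @export
validate_titration <- function(series) {
  pts <- series$points
  problems <- character(0)
  if (nrow(pts) < 3)
    problems <- c(problems, "fewer than 3 points")
  if (any(pts$q_conc < 0))
    problems <- c(problems, "negative quencher concentration")
  nzero <- sum(pts$q_conc == 0)
  if (nzero == 0)
    problems <- c(problems, "no reference point (q_conc = 0 row required)")
  if (nzero > 1)
    problems <- c(problems, "multiple q_conc = 0 rows")
  if (anyDuplicated(pts$q_conc))
    problems <- c(problems, "duplicate quencher concentrations")
  bad_f <- which(pts$f_measured <= 0 | !is.finite(pts$f_measured))
  if (length(bad_f))
    problems <- c(problems, paste0(
      "non-positive intensity at point ", paste(bad_f, collapse = ", ")))
  for (col in c("a_ex", "a_em")) {
    bad <- which(!is.na(pts[[col]]) & pts[[col]] < 0)
    if (length(bad))
      problems <- c(problems, paste0(
        "negative ", col, " at point ", paste(bad, collapse = ", ")))
  }
  problems
}

#' Inner-filter correction of measured fluorescence
#'
#' Attenuation of the excitation beam and of the emitted light by sample
#' absorbance (the inner-filter effect) depresses measured intensities. The
#' correction multiplies each measured intensity by
#' `base^((a_ex + a_em)/2)`, where `a_ex` and `a_em` are the absorbances at
#' the excitation and maximum emission wavelengths. The conventional
#' correction uses base 10 (absorbances are decadic); a base-e variant is
#' provided as an explicit option. With both absorbances zero the correction
#' is the identity, and it is strictly increasing in `a_ex + a_em`, so
#' corrected intensities never fall below measured ones.
#'
#' @param f measured intensity (arbitrary units); vectorized.
#' @param a_ex,a_em absorbances at the excitation and emission wavelengths
#'   (dimensionless, non-negative). If either is `NA` the intensity is
#'   returned uncorrected with attribute `uncorrected = TRUE`.
#' @param base `"ten"` (default) or `"e"`.
#' @return Corrected intensities, same length as `f`.
#' @examples
#' correct_inner_filter(100, 0.10, 0.10)              # 125.89
#' correct_inner_filter(100, 0.10, 0.10, base = "e")  # 110.52
#' @export
correct_inner_filter <- function(f, a_ex, a_em, base = c("ten", "e")) {
  base <- match.arg(base)
  if (any(stats::na.omit(c(a_ex, a_em)) < 0))
    stop("negative absorbance")
  if (any(is.na(a_ex)) || any(is.na(a_em))) {
    out <- f
    attr(out, "uncorrected") <- TRUE
    return(out)
  }
  b <- if (base == "ten") 10 else exp(1)
  f * b^((a_ex + a_em) / 2)
}

#' Read a titration series from a delimited text file
#'
#' Expects a CSV or TSV file with a header containing columns `q_conc` and
#' `f`, and optionally `a_ex` and `a_em`. Lines starting with `#` are
#' comments. Concentrations may be declared in a different unit and are
#' normalized to mol/L on load. Rows are sorted by concentration, so row
#' order in the file is immaterial.
#'
#' @param path path to the file. Tab- or comma-delimited (sniffed from the
#'   header line).
#' @param temperature temperature in K attached to the series.
#' @param unit unit of the `q_conc` column: `"mol/L"` (default), `"umol/L"`,
#'   or `"1e-5 mol/L"`.
#' @param ife_base inner-filter correction base, see [titration_series()].
#' @return A [titration_series()].
#' @export
read_titration <- function(path, temperature,
                           unit = c("mol/L", "umol/L", "1e-5 mol/L"),
                           ife_base = c("ten", "e")) {
  unit <- match.arg(unit)
  ife_base <- match.arg(ife_base)
  header <- readLines(path, n = 50L)
  header <- header[!startsWith(trimws(header), "#") & nzchar(trimws(header))]
  if (!length(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header[1])) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           strip.white = TRUE, stringsAsFactors = FALSE)
  for (col in c("q_conc", "f"))
    if (!col %in% names(tab))
      stop("missing required column '", col, "' in ", path)
  num_cols <- intersect(c("q_conc", "f", "a_ex", "a_em"), names(tab))
  for (col in num_cols) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !all(is.na(v) == is.na(v2)))
        stop("non-numeric value in column '", col, "'")
      tab[[col]] <- v2
    }
  }
  scale <- switch(unit, "mol/L" = 1, "umol/L" = 1e-6, "1e-5 mol/L" = 1e-5)
  has_abs <- all(c("a_ex", "a_em") %in% names(tab))
  titration_series(
    q_conc = tab$q_conc * scale, f = tab$f,
    a_ex = if (has_abs) tab$a_ex else NULL,
    a_em = if (has_abs) tab$a_em else NULL,
    temperature = temperature, ife_base = ife_base
  )
}

#' Write a titration series to CSV
#'
#' Writes the measured columns (`q_conc`, `f`, and the absorbance columns if
#' present) in mol/L, so that [read_titration()] reproduces the series
#' exactly.
#'
#' @param series a [titration_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  pts <- series$points
  out <- data.frame(q_conc = pts$q_conc, f = pts$f_measured)
  if (series$corrected) {
    out$a_ex <- pts$a_ex
    out$a_em <- pts$a_em
  }
  utils::write.csv(format(out, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "Fluorescence titration series: %d points, T = %g K, F0 = %.4g\n",
    nrow(x$points), x$temperature, x$f0))
  cat(sprintf("Inner-filter correction: %s (base %s)\n",
              if (x$corrected) "applied" else "not applied (no absorbances)",
              x$ife_base))
  print(x$points, ...)
  invisible(x)
}
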