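# Independent oracles for the regression fits: brute-force grid minimizers
# refined iteratively, no calls to lm() or to the package's fitting code.

# Least-squares straight line by grid search over slope (closed-form
# intercept per slope), refined until the slope grid step is below
# rel_tol * |slope|.
grid_line_fit <- function(x, y, slope_range = NULL, rel_tol = 1e-8) {
  if (is.null(slope_range)) {
    rough <- (max(y) - min(y)) / (max(x) - min(x))
    span <- max(abs(rough), 1e-12)
    slope_range <- c(-4 * span, 4 * span)
  }
  sse <- function(s) {
    b <- mean(y) - s * mean(x)
    sum((y - (b + s * x))^2)
  }
  lo <- slope_range[1]; hi <- slope_range[2]
  for (iter in 1:60) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, sse, numeric(1))
    i <- which.min(vals)
    step <- grid[2] - grid[1]
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    if (step < rel_tol * max(abs(grid[i]), 1e-12)) break
  }
  s <- (lo + hi) / 2
  list(slope = s, intercept = mean(y) - s * mean(x))
}

# Two-parameter grid search over (intercept, slope) minimizing squared
# residuals, refined iteratively. Used as the double-log oracle.
grid_plane_fit <- function(x, y, rel_tol = 1e-8) {
  start <- grid_line_fit(x, y)
  a0 <- start$intercept; s0 <- start$slope
  wa <- max(abs(a0), 1) * 0.5; ws <- max(abs(s0), 1) * 0.5
  best <- c(a0, s0)
  for (iter in 1:60) {
    as <- seq(best[1] - wa, best[1] + wa, length.out = 21)
    ss <- seq(best[2] - ws, best[2] + ws, length.out = 21)
    sse <- outer(as, ss, function(a, s)
      vapply(seq_along(a), function(i)
        sum((y - (a[i] + s[i] * x))^2), numeric(1)))
    idx <- arrayInd(which.min(sse), dim(sse))
    best <- c(as[idx[1]], ss[idx[2]])
    wa <- wa / 5; ws <- ws / 5
    if (wa < rel_tol * max(abs(best[1]), 1e-12) &&
        ws < rel_tol * max(abs(best[2]), 1e-12)) break
  }
  list(intercept = best[1], slope = best[2])
}

# Noiseless titration intensities for a given model, independent of
# simulate_titration().
oracle_intensities <- function(q, model, f0 = 1000, ksv = NULL, k = NULL,
                               n = NULL) {
  if (model == "stern_volmer") f0 / (1 + ksv * q) else f0 / (1 + k * q^n)
}

write_titration_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
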