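test_that("noiseless double-log data invert exactly", {
  q <- default_q_grid()

  ts <- titration_series(q, oracle_intensities(q, "double_log", k = 1e6, n = 1),
                         temperature = 298)
  fit <- dlog_fit(ts)
  expect_equal(fit$log_k, 6, tolerance = 1e-9)
  expect_equal(fit$n_sites, 1, tolerance = 1e-9)

  ts2 <- titration_series(q, oracle_intensities(q, "double_log",
                                                k = 4.57e6, n = 1.48),
                          temperature = 298)
  fit2 <- dlog_fit(ts2)
  expect_equal(signif(fit2$k_b, 4), 4.57e6)
  expect_equal(signif(fit2$n_sites, 4), 1.48)
  expect_identical(fit2$affinity_class, "strong")

  ts3 <- titration_series(q, oracle_intensities(q, "double_log", k = 1e5, n = 2),
                          temperature = 298)
  expect_equal(dlog_fit(ts3)$n_sites, 2, tolerance = 1e-9)
})

test_that("noiseless recovery holds over random (K, n) parameters", {
  set.seed(202)
  for (i in 1:20) {
    k <- 10^stats::runif(1, 4, 7)
    n <- stats::runif(1, 0.5, 2.5)
    ts <- simulate_titration(model = "double_log", k = k, n = n)
    fit <- dlog_fit(ts)
    expect_equal(fit$k_b, k, tolerance = 1e-6)
    expect_equal(fit$n_sites, n, tolerance = 1e-6)
  }
})

test_that("double-log fit matches the two-parameter grid oracle on noisy series", {
  set.seed(303)
  for (i in 1:8) {
    # parameterize by the quenched ratio at the top concentration so the
    # titration always spans a detectable quenching range
    n <- stats::runif(1, 1, 2)
    z_max <- stats::runif(1, 1, 5)
    ts <- simulate_titration(model = "double_log",
                             k = z_max / (4e-5)^n, n = n,
                             noise_sd = 0.01,
                             seed = sample.int(1e6, 1))
    fit <- suppressWarnings(dlog_fit(ts))
    oracle <- grid_plane_fit(fit$data$log_q, fit$data$log_ratio)
    expect_equal(fit$log_k, oracle$intercept, tolerance = 1e-5)
    expect_equal(fit$n_sites, oracle$slope, tolerance = 1e-5)
  }
})

test_that("affinity classification uses inclusive good-range boundaries and is monotone", {
  expect_identical(affinity_class(4.57e6), "strong")
  expect_identical(affinity_class(5e5), "good")
  expect_identical(affinity_class(1e5), "good")
  expect_identical(affinity_class(1e6), "good")
  expect_identical(affinity_class(9.99e4), "weak")
  expect_error(affinity_class(0), "positive")

  ks <- 10^seq(3, 8, by = 0.1)
  ranks <- match(affinity_class(ks), c("weak", "good", "strong"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("non-quenching points are dropped with a warning, too few points error", {
  q <- default_q_grid()
  f <- oracle_intensities(q, "double_log", k = 4.57e6, n = 1.48)
  f[2] <- f[1] * 1.001  # low-concentration point above F0
  ts <- titration_series(q, f, temperature = 298)
  expect_warning(fit <- dlog_fit(ts), "non-quenching")
  expect_equal(fit$fit$n_points, 6)
  expect_identical(fit$dropped, 1L)
  expect_equal(fit$k_b, 4.57e6, tolerance = 1e-5)

  few <- titration_series(q[1:4], c(f[1], f[1] * 1.01, f[1] * 1.02, f[1] * 1.03),
                          temperature = 298)
  expect_error(suppressWarnings(dlog_fit(few)), "fewer than 3 usable")
})

test_that("k_b always equals 10^log_k (the intercept is authoritative)", {
  set.seed(404)
  for (i in 1:5) {
    n <- stats::runif(1, 1, 2)
    ts <- simulate_titration(model = "double_log",
                             k = stats::runif(1, 1, 5) / (4e-5)^n, n = n,
                             noise_sd = 0.02, seed = sample.int(1e6, 1))
    fit <- suppressWarnings(dlog_fit(ts))
    expect_identical(fit$k_b, 10^fit$log_k)
  }
})

test_that("site competition assigns the marker with the larger displacement", {
  res <- site_competition(4.57e6, c(warfarin = 1.05e5, ibuprofen = 1.73e5),
                          tie_margin = 0.01)
  expect_identical(res$assigned_site, "Sudlow site I")
  expect_equal(sort(res$table$relative_change), c(0.962, 0.977),
               tolerance = 1e-3)

  # the same constants sit within the default margin: flagged indeterminate
  near <- site_competition(4.57e6, c(warfarin = 1.05e5, ibuprofen = 1.73e5))
  expect_identical(near$assigned_site, "indeterminate")
  expect_true(near$near_tie)

  tie <- site_competition(1e6, c(warfarin = 1e6, ibuprofen = 1e6))
  expect_identical(tie$assigned_site, "indeterminate")

  neg <- site_competition(1e5, c(warfarin = 2e5, ibuprofen = 9e4),
                          tie_margin = 0.01)
  expect_match(neg$table$flag[neg$table$marker == "warfarin"],
               "negative displacement")

  expect_error(site_competition(1e5, c(quercetin = 5e4)), "no site mapping")
  expect_error(site_competition(0, c(warfarin = 1e5)), "positive")
})
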