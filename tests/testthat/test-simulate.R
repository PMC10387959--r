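test_that("simulators are seed-deterministic", {
  a <- simulate_titration(model = "double_log", k = 4.57e6, n = 1.48,
                          noise_sd = 0.01, seed = 42)
  b <- simulate_titration(model = "double_log", k = 4.57e6, n = 1.48,
                          noise_sd = 0.01, seed = 42)
  expect_identical(a$points, b$points)
  c_ <- simulate_titration(model = "double_log", k = 4.57e6, n = 1.48,
                           noise_sd = 0.01, seed = 43)
  expect_false(identical(a$points$f_measured, c_$points$f_measured))

  d1 <- simulate_dissolution(0.75, 0.012, c(30, 60, 120), 5, 100,
                             noise_sd = 0.05, seed = 7)
  d2 <- simulate_dissolution(0.75, 0.012, c(30, 60, 120), 5, 100,
                             noise_sd = 0.05, seed = 7)
  expect_identical(d1$fractions, d2$fractions)
})

test_that("noiseless Stern-Volmer simulation satisfies the model identity", {
  ts <- simulate_titration(model = "stern_volmer", ksv = 5.54e5)
  q <- ts$points$q_conc
  expect_equal(ts$f0 / ts$points$f_corrected - 1, 5.54e5 * q,
               tolerance = 1e-12)
})

test_that("noiseless pipeline simulate -> distort -> correct -> fit is the identity", {
  set.seed(505)
  for (i in 1:10) {
    ksv <- 10^stats::runif(1, 4.5, 6)
    k <- 10^stats::runif(1, 5, 7)
    n <- stats::runif(1, 0.8, 2)
    base <- sample(c("ten", "e"), 1)
    ife <- list(eps_ex = stats::runif(1, 0, 4000),
                eps_em = stats::runif(1, 0, 4000), base = base)

    sv <- simulate_titration(model = "stern_volmer", ksv = ksv, ife = ife)
    expect_equal(sv_fit(sv)$ksv, ksv, tolerance = 1e-6)

    dl <- simulate_titration(model = "double_log", k = k, n = n, ife = ife)
    fit <- dlog_fit(dl)
    expect_equal(fit$k_b, k, tolerance = 1e-6)
    expect_equal(fit$n_sites, n, tolerance = 1e-6)
  }
})

test_that("inner-filter distortion attenuates by the expected factor", {
  ts <- simulate_titration(model = "stern_volmer", ksv = 1e5)
  distorted <- distort_inner_filter(ts, eps_ex = 2500, eps_em = 2500)
  i <- which(ts$points$q_conc == 4e-5)
  expect_equal(distorted$points$f_measured[i] / ts$points$f_measured[i],
               10^(-0.1), tolerance = 1e-12)
  unchanged <- distort_inner_filter(ts, 0, 0)
  expect_equal(unchanged$points$f_measured, ts$points$f_measured)
  expect_error(distort_inner_filter(ts, -1, 0), "non-negative")
})

test_that("competition simulator plants a recoverable dominant site", {
  pair <- simulate_competition_pair(4.57e6, 0.977, 0.962)
  expect_equal(unname(pair$marker_k),
               c(4.57e6 * 0.023, 4.57e6 * 0.038), tolerance = 1e-12)
  res <- site_competition(4.57e6, pair$marker_k, tie_margin = 0.01)
  expect_identical(res$assigned_site, pair$planted_site)
  expect_identical(pair$planted_site, "Sudlow site I")

  none <- simulate_competition_pair(1e6, 0, 0)
  expect_identical(site_competition(1e6, none$marker_k)$assigned_site,
                   "indeterminate")

  site2 <- simulate_competition_pair(1e6, 0.2, 0.8)
  expect_identical(site_competition(1e6, site2$marker_k)$assigned_site,
                   "Sudlow site II")
  expect_error(simulate_competition_pair(1e6, 1, 0.5), "\\[0, 1\\)")
})

test_that("dissolution simulator plants an exactly recoverable release curve", {
  times <- c(5, 10, 15, 20, 30, 45, 60, 90, 120, 150, 180, 240)
  ds <- simulate_dissolution(0.75, 0.01, times, 5, 100)
  prof <- cumulative_release(ds)
  truth <- 0.75 * (1 - exp(-0.01 * times))
  expect_equal(prof$q_percent, truth * 100, tolerance = 1e-9)

  # zero-time draw releases nothing
  ds0 <- simulate_dissolution(0.5, 0.02, c(0, 10, 20), 5, 100)
  expect_equal(ds0$fractions[1], 0)
  expect_equal(cumulative_release(ds0)$q_percent[1], 0)

  # rate chosen so the curve reads 71% at 240 min
  rate <- -log(1 - 0.71 / 0.75) / 240
  ds71 <- simulate_dissolution(0.75, rate, times, 5, 100)
  expect_equal(cumulative_release(ds71)$q_percent[length(times)], 71,
               tolerance = 1e-9)

  expect_error(simulate_dissolution(0.75, 0.01, c(10, 5), 5, 100),
               "strictly increasing")
  expect_error(simulate_dissolution(1.5, 0.01, times, 5, 100), "q_inf")
})

test_that("noisy double-log replicates recover the generating parameters", {
  # Statistical note: the double-log intercept sits several decades outside
  # the concentration window, so single-replicate K estimates are
  # lognormally spread (sd(log10 K) ~ 0.6 at 1% intensity noise); with 1000
  # replicates the median's sampling error is ~6% on K, so a 20% band is a
  # sound (>3 sigma) check of central recovery. n is far tighter.
  k_true <- 4.57e6; n_true <- 1.48
  set.seed(42)
  seeds <- sample.int(2^31 - 1, 1000)
  fits <- vapply(seeds, function(s) {
    ts <- simulate_titration(model = "double_log", k = k_true, n = n_true,
                             noise_sd = 0.01, seed = s)
    fit <- suppressWarnings(dlog_fit(ts))
    c(fit$k_b, fit$n_sites)
  }, numeric(2))
  expect_lt(abs(stats::median(fits[1, ]) - k_true) / k_true, 0.20)
  expect_lt(abs(stats::median(fits[2, ]) - n_true) / n_true, 0.025)
})
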