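test_that("formula parsing handles counts, repeats and bad symbols", {
  expect_identical(parse_formula("C15H10O5"), c(C = 15L, H = 10L, O = 5L))
  expect_identical(parse_formula("CH4")[["H"]], 4L)
  expect_identical(parse_formula("CHCl3")[["Cl"]], 3L)
  expect_error(parse_formula("C2Xx4"), "unknown element")
  expect_error(parse_formula("c2h4"), "cannot parse|unknown element")
})

test_that("mass fractions reproduce hand-computed apigenin and cocrystal values", {
  ap <- mass_fractions("C15H10O5")
  expect_equal(round(ap[["C"]], 2), 66.67)
  expect_equal(mass_fractions("C")[["C"]], 100)
  apn <- mass_fractions("C21H16N2O6")
  expect_equal(round(apn[["N"]], 2), 7.14)
  expect_equal(round(apn[["H"]], 2), 4.11)
  expect_equal(round(apn[["C"]], 2), 64.28)
})

test_that("mass fractions sum to 100 and are invariant under formula multiples", {
  formulas <- c("C15H10O5", "C6H6N2O", "C21H16N2O6", "NaCl", "C6H12O6")
  for (fo in formulas) {
    fr <- mass_fractions(fo)
    expect_lt(abs(sum(fr) - 100), 0.01)
    tripled <- parse_formula(fo) * 3L
    expect_equal(mass_fractions(tripled), fr, tolerance = 1e-12)
  }
})

test_that("composition check computes relative errors against theory", {
  rep1 <- composition_check("C15H10O5", c(C = 64.68))
  expect_equal(round(rep1$relative_error, 2), 2.98)
  expect_true(attr(rep1, "overall_pass"))

  theo <- mass_fractions("C6H6N2O")
  exact <- composition_check("C6H6N2O", theo[c("C", "H", "N")])
  expect_equal(exact$relative_error, rep(0, 3))
  expect_true(attr(exact, "overall_pass"))

  off <- composition_check("C15H10O5", c(C = 66.67 * 0.9, H = 3.73))
  expect_false(attr(off, "overall_pass"))
  expect_identical(off$element[!off$pass], "C")

  expect_error(composition_check("C15H10O5", c(N = 5)), "absent from formula")
})

test_that("cumulative release applies the sampled-volume correction", {
  one <- dissolution_series(10, 0.37, 5, 100)
  expect_equal(cumulative_release(one)$q_percent, 37)

  ds <- dissolution_series(c(5, 10, 15), c(0.10, 0.20, 0.30), 4, 100)
  expect_equal(cumulative_release(ds)$q_percent, c(10, 20.4, 31.2))

  no_loss <- dissolution_series(c(5, 10, 15), c(0.10, 0.20, 0.30), 0, 100)
  expect_equal(cumulative_release(no_loss)$q_percent, c(10, 20, 30))

  # non-decreasing draws give a non-decreasing profile
  set.seed(55)
  for (i in 1:5) {
    a <- sort(stats::runif(6, 0, 0.2))
    prof <- cumulative_release(dissolution_series(1:6, a, 5, 100))
    expect_true(all(diff(prof$q_percent) >= 0))
  }

  expect_error(dissolution_series(c(1, 1), c(0.1, 0.2), 5, 100),
               "strictly increasing")
  expect_error(dissolution_series(1:2, c(0.1, 0.2), 200, 100), "v_sample")
})

test_that("solubility enhancement ratio and fold label", {
  r <- solubility_ratio(0.81e-5, 0.28e-5)
  expect_equal(round(r$ratio, 2), 2.89)
  expect_identical(r$fold_label, 3L)
  expect_equal(solubility_ratio(1e-5, 1e-5)$ratio, 1)
  expect_equal(round(solubility_ratio(0.57e-5, 0.23e-5)$ratio, 2), 2.48)
  expect_error(solubility_ratio(0, 1e-5), "positive")
})

test_that("PXRD comparison separates new-phase peaks from parent superpositions", {
  ap <- c(11.08, 14.08, 15.86)
  nico <- c(14.92, 25.84, 27.71)
  res <- pxrd_new_phase(c(7.31, 10.36, 20.68, 11.08), list(ap, nico))
  expect_identical(res$verdict, "new_phase")
  expect_equal(as.numeric(res$new_peaks), c(7.31, 10.36, 20.68))

  mixture <- pxrd_new_phase(sort(c(ap, nico)), list(ap, nico))
  expect_identical(mixture$verdict, "superposition")
  expect_length(mixture$new_peaks, 0)

  # |11.15 - 11.08| = 0.07 < 0.2: matched, not new
  near <- pxrd_new_phase(11.15, list(ap, nico))
  expect_identical(near$verdict, "superposition")

  expect_error(peak_set(numeric(0)), "empty")
  expect_error(peak_set(95), "0, 90")
})

test_that("widening the PXRD tolerance never creates new peaks", {
  set.seed(66)
  parents <- list(sort(stats::runif(5, 5, 40)), sort(stats::runif(5, 5, 40)))
  product <- sort(stats::runif(8, 5, 40))
  tols <- c(0.05, 0.1, 0.2, 0.5, 1, 2)
  counts <- vapply(tols, function(tol)
    length(pxrd_new_phase(product, parents, tolerance = tol)$new_peaks),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak-list and dissolution CSV readers round-trip simple files", {
  pk <- tempfile(fileext = ".csv")
  writeLines(c("# product peaks", "angle", "7.31", "10.36", "20.68"), pk)
  expect_equal(as.numeric(read_peaks(pk)), c(7.31, 10.36, 20.68))

  dl <- tempfile(fileext = ".csv")
  writeLines(c("time,fraction", "5,0.10", "10,0.20", "15,0.30"), dl)
  ds <- read_dissolution(dl, v_sample = 4, v_medium = 100)
  expect_equal(cumulative_release(ds)$q_percent, c(10, 20.4, 31.2))
})
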