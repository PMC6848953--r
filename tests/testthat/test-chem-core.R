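test_that("monoisotopic masses agree with hand-computed and published values", {
  # oleic acid: printed neutral mass 282.25602 is a measurement; the
  # theoretical value must sit within the instrument's 1 ppm
  expect_equal(monoisotopic_mass("C18H34O2"), 282.255880, tolerance = 1e-8)
  expect_lt(abs(ppm_error(282.25602, monoisotopic_mass("C18H34O2"))), 1)
  # glucose, summed by hand from the atomic-mass table
  expect_equal(monoisotopic_mass("C6H12O6"), 180.063388, tolerance = 1e-6)
  # empty formula is the additive identity
  expect_identical(monoisotopic_mass(""), 0)
  expect_error(monoisotopic_mass("C2Si3"), "outside the supported set")
})

test_that("formula parsing round-trips and rejects junk", {
  m <- parse_formula(c("C18H34O2", "CH4O", "C6H12O6"))
  expect_identical(unname(m[2, c("C", "H", "O")]), c(1L, 4L, 1L))
  expect_identical(formula_string(m)[1], "C18H34O2")
  expect_identical(formula_string(parse_formula("C1H4O1")), "CH4O")
  expect_error(parse_formula("C6H12o6"), "unparseable")
  expect_error(parse_formula("XeF4"), "outside the supported set")
})

test_that("mass additivity holds element-wise", {
  set.seed(42)
  for (i in 1:20) {
    a <- c(C = sample(1:30, 1), H = sample(0:60, 1), O = sample(0:20, 1),
           N = sample(0:3, 1))
    b <- c(C = sample(1:30, 1), H = sample(0:60, 1), S = sample(0:2, 1))
    expect_equal(
      monoisotopic_mass(formula_add(a, b)),
      monoisotopic_mass(formula_string(a)) + monoisotopic_mass(formula_string(b)),
      tolerance = 1e-9)
  }
})

test_that("ion/neutral conversions are exact mutual inverses", {
  # glucose deprotonated: 180.063388 - 1.00727646688
  expect_equal(mz_from_neutral(180.063388), 179.056112, tolerance = 1e-6)
  # adenosine protonated, cf. its published MW of 267
  expect_equal(mz_from_neutral(267.096754, "pos"), 268.104030,
               tolerance = 1e-6)
  # oleic acid ion back to neutral, against the printed 282.25602
  expect_lt(abs(ppm_error(282.25602, neutral_from_mz(281.24860))), 1)
  for (mode in c("neg", "pos")) {
    x <- c(100.5, 341.2, 1199.9)
    expect_equal(neutral_from_mz(mz_from_neutral(x, mode), mode), x,
                 tolerance = 1e-10)
  }
  expect_error(neutral_from_mz(0.5, "pos"), "non-positive")
  expect_error(mz_from_neutral(-1), "positive")
})

test_that("ppm error is signed, zero iff equal, and rejects bad input", {
  expect_identical(ppm_error(100, 100), 0)
  expect_equal(ppm_error(100.0001, 100), 1, tolerance = 1e-9)
  expect_equal(ppm_error(282.25602, 282.25588), 0.496, tolerance = 1e-2)
  expect_lt(ppm_error(99.9999, 100), 0)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("dbe and heteroatom counts follow their definitions", {
  expect_equal(dbe("C6H12O6"), 1)
  expect_equal(dbe("C15H10O6"), 11)
  expect_equal(dbe("C10H13N5O4"), 10 - 6.5 + 2.5 + 1)
  expect_identical(heteroatom_count("C20H32N6O12S2"), 8L)
  expect_identical(heteroatom_count("C6H12O6"), 0L)
})
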