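small_bounds <- element_bounds(C = c(1, 15), H = c(0, 30), O = c(0, 10),
                               N = c(0, 2), S = c(0, 1), P = c(0, 1))

test_that("enumeration matches the brute-force oracle on random masses", {
  set.seed(101)
  masses <- runif(100, 80, 320)
  for (m in masses) {
    got <- sort(enumerate_formulas(m, 5, small_bounds)$formula)
    want <- brute_force_formulas(m, 5, small_bounds)
    expect_identical(got, want)
  }
})

test_that("known compounds are recovered at 1 ppm with default bounds", {
  top <- enumerate_formulas(180.063388, 1)
  expect_identical(top$formula[1], "C6H12O6")
  cand <- enumerate_formulas(282.255880, 1)
  expect_true("C18H34O2" %in% cand$formula)
  # vanishing tolerance leaves only an exact hit, or nothing
  expect_identical(nrow(enumerate_formulas(180.0639, 0.001)), 0L)
  expect_error(enumerate_formulas(2500, 1), "2000")
})

test_that("validity rules hold for every candidate", {
  set.seed(7)
  for (m in runif(25, 150, 900)) {
    cand <- enumerate_formulas(m, 10)
    if (nrow(cand) == 0L) next
    expect_true(all(cand$P == 0 | cand$O >= 4))
    expect_true(all(cand$dbe >= 0))
    expect_true(all(abs(cand$error_ppm) < 10))
  }
})

test_that("enlarging the tolerance never removes candidates", {
  set.seed(11)
  for (m in runif(10, 150, 600)) {
    narrow <- enumerate_formulas(m, 1)$formula
    wide <- enumerate_formulas(m, 4)$formula
    expect_true(all(narrow %in% wide))
  }
})

test_that("selection prefers lowest error, then fewest heteroatoms", {
  cand <- data.frame(formula = c("A", "B"), error_ppm = c(0.6, 0.2),
                     heteroatoms = c(0L, 2L), stringsAsFactors = FALSE)
  expect_identical(select_formula(cand)$formula, "B")
  tie <- data.frame(formula = c("C10H20N2O2", "C11H24O2"),
                    error_ppm = c(0.3, -0.3), heteroatoms = c(2L, 0L),
                    stringsAsFactors = FALSE)
  expect_identical(select_formula(tie)$formula, "C11H24O2")
  expect_null(select_formula(tie[0, ]))
})

test_that("assignment flags unknowns and reports candidate multiplicity", {
  # glutathione disulfide at its deprotonated m/z, printed mass 612.15245
  # glutathione disulfide carries six nitrogens, so the bounds must
  # admit N = 6 (the shipped default stops at N = 5)
  obs <- mz_from_neutral(612.151962)
  a <- assign_formulas(pk(obs), tol_ppm = 1,
                       bounds = element_bounds(N = c(0, 6)))
  expect_identical(a$formula[1], "C20H32N6O12S2")
  # and the printed (measured) mass is within 1 ppm of that formula
  expect_lt(abs(ppm_error(612.15245, monoisotopic_mass("C20H32N6O12S2"))), 1)
  # a mass far from any CHONSP composition stays unknown
  u <- assign_formulas(pk(200.5))
  expect_identical(u$status, "unknown")
  expect_identical(u$n_candidates, 0L)
})

test_that("dropping ambiguous peaks leaves only unique assignments", {
  s <- generate_sample(synthetic_spec(seed = 5, n_compounds = 40,
                                      mass_range = c(150, 400),
                                      contaminant_frac = 0))
  a <- assign_formulas(s$peaks, ambiguous = "drop")
  assigned <- a$status == "assigned"
  expect_true(all(a$n_candidates[assigned] == 1L))
  expect_true(all(a$formula[assigned] == s$truth$formula[assigned]))
})
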