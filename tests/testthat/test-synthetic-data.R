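test_that("the same spec yields byte-identical output", {
  spec <- synthetic_spec(seed = 12, n_compounds = 60)
  s1 <- generate_sample(spec)
  s2 <- generate_sample(spec)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth, s2$truth)
  # a different seed yields a different sample
  s3 <- generate_sample(synthetic_spec(seed = 13, n_compounds = 60))
  expect_false(identical(s1$peaks$mz, s3$peaks$mz))
})

test_that("zero-noise output sits exactly on the ionized true masses", {
  s <- generate_sample(synthetic_spec(seed = 6, n_compounds = 50,
                                      jitter_ppm = 0, drift = c(0, 0)))
  ok <- !s$truth$contaminant
  expect_equal(s$peaks$mz[ok], s$truth$true_mz[ok], tolerance = 1e-12)
  expect_equal(s$truth$true_mz[ok],
               mz_from_neutral(monoisotopic_mass(s$truth$formula[ok])),
               tolerance = 1e-9)
  expect_false(is.unsorted(s$peaks$mz))
})

test_that("the error model applies exactly the drawn drift plus jitter", {
  s <- generate_sample(synthetic_spec(seed = 8, n_compounds = 50,
                                      jitter_ppm = 0, drift = c(2, 0.001)))
  ok <- !s$truth$contaminant
  err <- ppm_error(s$peaks$mz[ok], s$truth$true_mz[ok])
  expect_equal(err, 2 + 0.001 * s$truth$true_mz[ok], tolerance = 1e-6)
})

test_that("contaminants have no CHONSP formula within 2 ppm", {
  s <- generate_sample(synthetic_spec(seed = 14, n_compounds = 40,
                                      contaminant_frac = 0.2))
  cont <- s$truth$contaminant
  expect_gte(sum(cont), 5L)
  for (mz in s$peaks$mz[cont]) {
    expect_identical(nrow(enumerate_formulas(neutral_from_mz(mz), 2)), 0L)
  }
})

test_that("planted CH2 ladders are recovered by series detection", {
  spec <- synthetic_spec(seed = 16, n_compounds = 80, jitter_ppm = 0.1,
                         series = list(n = 4, length = 6))
  s <- generate_sample(spec)
  found <- find_homologous_series(s$peaks, tol_ppm = 1)
  planted <- s$truth[!is.na(s$truth$series_id), ]
  hits <- vapply(planted$mz, function(m) {
    any(abs(found$mz - m) < 1e-9)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("chemical validity of drawn compounds: integer non-negative DBE", {
  s <- generate_sample(synthetic_spec(seed = 18, n_compounds = 120))
  forms <- s$truth$formula[!s$truth$contaminant]
  d <- dbe(forms)
  expect_true(all(d >= 0))
  expect_true(all(abs(d - round(d)) < 1e-9))
  # masses stay within the configured window
  m <- monoisotopic_mass(forms)
  expect_true(all(m >= 150 & m <= 800))
})

test_that("synthetic concentration tables honor totals and the 1 uM floor", {
  tab <- generate_concentration_table(c(Acids = 1000, Sugars = 3000),
                                      n_per_class = 6, seed = 3)
  ct <- class_totals(tab)
  expect_equal(ct$total[ct$class == "Acids"], 1000, tolerance = 1e-9)
  expect_equal(ct$total[ct$class == "Sugars"], 3000, tolerance = 1e-9)
  expect_true(all(tab$concentration >= 1))
  empty <- generate_concentration_table(setNames(numeric(0), character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("synthetic lipid counts are consistent by construction", {
  tab <- generate_lipid_counts(total = 152, n_subclasses = 19, seed = 2)
  expect_identical(nrow(tab), 19L)
  tot <- subclass_total(tab)
  expect_identical(as.integer(tot), 152L)
  expect_true(attr(tot, "consistent"))
  one <- generate_lipid_counts(total = 9, n_subclasses = 1, seed = 1)
  expect_identical(one$count, 9L)
  zero <- generate_lipid_counts(total = 0, n_subclasses = 4, seed = 1)
  expect_true(all(zero$count == 0L))
})
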