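test_that("coordinates are exact molar ratios, undefined without carbon", {
  xy <- vk_coordinates(c("C18H34O2", "C6H12O6", "C15H10O6"))
  expect_equal(xy$oc, c(2 / 18, 1, 0.4))
  expect_equal(xy$hc, c(34 / 18, 2, 10 / 15))
  expect_true(all(is.na(vk_coordinates("H2O1")[1, ])))  # no carbon
})

test_that("the seven printed class ranges classify worked examples", {
  expect_identical(vk_classify("C18H34O2"), "lipid")
  expect_identical(vk_classify("C20H32N6O12S2"), "amino_sugar")
  expect_identical(vk_classify("C15H10O6"), "condensed_aromatic")
  expect_identical(vk_classify("C18H24O9"), "lignin")       # oc 0.50, hc 1.33
  expect_identical(vk_classify("C10H20N2O4"), "protein")    # oc 0.40, hc 2.00
  expect_identical(vk_classify("C10H13N5O4"), "lignin")     # oc 0.40, hc 1.30
})

test_that("bin edges follow the printed open/closed conventions", {
  # O:C = 0 is excluded from lipids but included in unsaturated HC
  expect_identical(vk_classify("C10H20"), "unsaturated_hydrocarbon")
  # the lipid/unsaturated-HC overlap resolves to lipid (listed first)
  expect_identical(vk_classify("C10H20O"), "lipid")         # oc 0.1 hc 2.0
  # H:C = 1.5 belongs to lipid (closed), not lignin (open above)
  expect_identical(vk_classify("C20H30O2"), "lipid")
  # H:C just below 0.8 with low O:C is condensed aromatic
  expect_identical(vk_classify("C20H15O4"), "condensed_aromatic")
  # glucose (oc 1, hc 2) is unclassified under the printed bins...
  expect_identical(vk_classify("C6H12O6"), "unclassified")
  # ...and carbohydrate once the opt-in bin is enabled
  expect_identical(vk_classify("C6H12O6", vk_classes(carbohydrate = TRUE)),
                   "carbohydrate")
})

test_that("classification is scale-invariant and single-valued", {
  set.seed(3)
  base <- c("C12H18O4", "C5H10N2O3", "C9H8O4", "C16H30O2")
  for (f in base) {
    cnt <- parse_formula(f)
    for (k in c(2L, 5L)) {
      expect_identical(vk_classify(formula_string(cnt * k)), vk_classify(f))
    }
  }
})

test_that("class abundances are count fractions summing to one", {
  forms <- c(rep("C18H34O2", 10), rep("C5H11NO2", 10))  # 10 lipid, 10 protein
  fr <- class_abundance(forms)
  expect_equal(unname(fr[c("lipid", "protein")]), c(0.5, 0.5))
  expect_equal(sum(fr), 1)
  one <- class_abundance("C18H34O2")
  expect_equal(unname(one["lipid"]), 1)
  expect_error(class_abundance(character(0)), "no assigned")
  # NA formulas (unassigned peaks) are excluded, not counted
  df <- data.frame(formula = c("C18H34O2", NA, NA))
  expect_equal(unname(class_abundance(df)["lipid"]), 1)
})

test_that("generated class mixtures are recovered within sampling error", {
  mix <- c(lipid = 0.3, lignin = 0.5, condensed_aromatic = 0.2)
  s <- generate_sample(synthetic_spec(seed = 23, n_compounds = 300,
                                      class_mixture = mix,
                                      contaminant_frac = 0,
                                      series = list(n = 0, length = 0),
                                      chains = list(n = 0, length = 0,
                                                    transformations = "CH2")))
  fr <- class_abundance(s$truth$formula)
  for (cl in names(mix)) {
    sd3 <- 3 * sqrt(mix[[cl]] * (1 - mix[[cl]]) / 300)
    expect_lt(abs(fr[[cl]] - mix[[cl]]), sd3 + 1e-9)
  }
})
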