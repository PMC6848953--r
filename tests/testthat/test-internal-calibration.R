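test_that("exact CH2 ladders are detected as one series", {
  mz <- c(200.00000, 214.01565, 228.03130, 242.04695)
  s <- find_homologous_series(mz)
  expect_identical(length(unique(s$series_id)), 1L)
  expect_identical(nrow(s), 4L)
  expect_identical(s$position, 0:3)
  # wrong spacings give nothing
  expect_identical(nrow(find_homologous_series(c(200, 215, 231))), 0L)
  # chains shorter than 3 are discarded
  expect_identical(nrow(find_homologous_series(c(200, 214.01565))), 0L)
})

test_that("a perturbed rung splits the chain and the longer piece survives", {
  ladder <- 300 + monoisotopic_mass("CH2") * (0:5)
  ladder[3] <- ladder[3] * (1 + 5e-6)  # +5 ppm on one member
  s <- find_homologous_series(ladder, tol_ppm = 1)
  expect_identical(length(unique(s$series_id)), 1L)
  expect_identical(nrow(s), 3L)                 # rungs 4..6 survive
  expect_equal(min(s$mz), ladder[4], tolerance = 1e-9)
})

test_that("calibration fitting recovers planted linear error models", {
  # uniform +3 ppm offset
  theo <- seq(200, 900, by = 50)
  m <- fit_calibration(data.frame(observed = theo * (1 + 3e-6),
                                  theoretical = theo))
  expect_equal(m$intercept, 3, tolerance = 1e-3)
  expect_equal(m$slope, 0, tolerance = 1e-6)
  expect_lt(m$rms_post, 1e-6)
  # already exact: identity model
  m0 <- fit_calibration(data.frame(observed = theo, theoretical = theo))
  expect_equal(m0$intercept, 0, tolerance = 1e-9)
  expect_equal(m0$slope, 0, tolerance = 1e-12)
  # 2 ppm at 200 rising to 6 ppm at 1000
  obs <- c(200 * (1 + 2e-6), 1000 * (1 + 6e-6))
  m2 <- fit_calibration(data.frame(observed = obs, theoretical = c(200, 1000)))
  expect_equal(m2$intercept + m2$slope * 200, 2, tolerance = 0.1)
  expect_equal(m2$intercept + m2$slope * 1000, 6, tolerance = 0.1)
  expect_error(fit_calibration(data.frame(observed = 1, theoretical = 1)),
               "at least 2")
  expect_error(fit_calibration(data.frame(observed = c(5, 5),
                                          theoretical = c(5, 5.1))),
               "degenerate")
})

test_that("applying a model corrects m/z and preserves everything else", {
  p <- pk(c(150.5, 300.000000, 700.2), intensity = c(1, 2, 3), sn = 7:9)
  flat3 <- structure(list(intercept = 3, slope = 0, rms_pre = 3,
                          rms_post = 0, n_calibrants = 9L, n_dropped = 0L),
                     class = "mass_calibration")
  out <- apply_calibration(p, flat3)
  expect_equal(out$mz[2], 300 / (1 + 3e-6), tolerance = 1e-9)
  expect_identical(out$intensity, p$intensity)
  expect_identical(out$sn, p$sn)
  expect_false(is.unsorted(out$mz))
  expect_identical(apply_calibration(p, identity_calibration()), p)
})

test_that("a perfectly accurate sample calibrates to the identity", {
  s <- generate_sample(synthetic_spec(seed = 2, n_compounds = 120,
                                      jitter_ppm = 0, drift = c(0, 0),
                                      series = list(n = 4, length = 6)))
  cal <- calibrate_peaklist(s$peaks)
  expect_lt(abs(cal$model$intercept), 1e-4)
  expect_lt(abs(cal$model$slope) * 800, 1e-4)
  expect_lt(cal$model$rms_post, 1e-4)
  # and never reorders peaks
  expect_false(is.unsorted(cal$peaks$mz))
})

test_that("synthetic drift up to 5 ppm is reduced below 0.5 ppm RMS", {
  for (drift in list(c(5, 0), c(0.5, 0.0045))) {
    spec <- synthetic_spec(seed = 31, n_compounds = 150, drift = drift,
                           jitter_ppm = 0.2, series = list(n = 6, length = 8))
    s <- generate_sample(spec)
    cal <- calibrate_peaklist(s$peaks)
    ok <- !s$truth$contaminant
    err <- ppm_error(cal$peaks$mz[ok], s$truth$true_mz[ok])
    expect_lt(sqrt(mean(err^2)), 0.5)
    expect_lt(median(abs(err)), 0.5)
    expect_lt(cal$model$rms_post, cal$model$rms_pre + 1e-12)
  }
})
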