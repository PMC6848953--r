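#' Detect homologous series in a peak list
#'
#' Finds maximal chains of peaks whose successive members differ by the
#' exact mass of a repeat unit (CH2, 14.015650 Da, by default) within
#' `tol_ppm` evaluated at the larger m/z. Each peak joins at most one
#' chain; chains shorter than `min_length` are discarded. Within-spectrum
#' CH2 ladders of natural organic matter are the classic internal
#' calibrant set for FTICR spectra.
#'
#' @param peaks Peak `data.frame` (`mz` column) or numeric m/z vector.
#' @param repeat_unit Formula string of the repeat unit, default `"CH2"`.
#' @param tol_ppm Spacing tolerance in ppm, default 1.
#' @param min_length Minimum chain length, default 3.
#' @return `data.frame` with columns `mz`, `series_id`, `position`
#'   (0-based rung within the chain); empty when no series found.
#' @export
find_homologous_series <- function(peaks, repeat_unit = "CH2", tol_ppm = 1,
                                   min_length = 3) {
  stopifnot(tol_ppm > 0, min_length >= 2)
  mz <- if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks)
  mz <- sort(unique(mz))
  delta <- monoisotopic_mass(repeat_unit)
  n <- length(mz)
  empty <- data.frame(mz = numeric(0), series_id = integer(0),
                      position = integer(0))
  if (n < min_length) return(empty)
  # successor of i: nearest peak to mz[i] + delta within tolerance
  succ <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    target <- mz[i] + delta
    tol <- tol_ppm * 1e-6 * target
    j0 <- findInterval(target - tol, mz) + 1L
    j1 <- findInterval(target + tol, mz)
    if (j1 >= j0) {
      cand <- j0:j1
      succ[i] <- cand[which.min(abs(mz[cand] - target))]
    }
  }
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  used <- rep(FALSE, n)
  series <- list()
  for (s in which(!has_pred)) {
    if (used[s] || is.na(succ[s])) next
    chain <- s
    while (!is.na(succ[chain[length(chain)]]) &&
           !used[succ[chain[length(chain)]]]) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    if (length(chain) >= min_length) {
      used[chain] <- TRUE
      series[[length(series) + 1L]] <- chain
    }
  }
  if (!length(series)) return(empty)
  do.call(rbind, lapply(seq_along(series), function(k) {
    data.frame(mz = mz[series[[k]]], series_id = k,
               position = seq_along(series[[k]]) - 1L)
  }))
}

#' Fit a linear internal-calibration model
#'
#' Least-squares fit of ppm error versus m/z over calibrant peaks. A
#' single robust refit pass drops calibrants whose residual exceeds three
#' times the residual RMS (but at least 1 ppm), so an occasional
#' mis-anchored series does not corrupt the model.
#'
#' @param calibrants `data.frame` with columns `observed` and
#'   `theoretical` (m/z, Da); at least 2 rows with distinct observed m/z.
#' @return A `mass_calibration` object: list with `intercept` (ppm),
#'   `slope` (ppm per Da), `rms_pre`, `rms_post` (ppm), `n_calibrants`,
#'   `n_dropped`.
#' @export
fit_calibration <- function(calibrants) {
  stopifnot(is.data.frame(calibrants),
            all(c("observed", "theoretical") %in% names(calibrants)))
  calibrants <- calibrants[stats::complete.cases(calibrants), , drop = FALSE]
  if (nrow(calibrants) < 2L) stop("need at least 2 calibrant points")
  if (length(unique(calibrants$observed)) < 2L) {
    stop("calibrant m/z values are degenerate (all identical)")
  }
  ppm <- ppm_error(calibrants$observed, calibrants$theoretical)
  fit <- stats::lm(ppm ~ observed, data = calibrants)
  res <- stats::residuals(fit)
  rms <- sqrt(mean(res^2))
  drop <- abs(res) > max(1, 3 * rms)
  n_dropped <- 0L
  if (any(drop) && sum(!drop) >= 2L &&
      length(unique(calibrants$observed[!drop])) >= 2L) {
    n_dropped <- sum(drop)
    calibrants <- calibrants[!drop, , drop = FALSE]
    ppm <- ppm[!drop]
    fit <- stats::lm(ppm ~ observed, data = calibrants)
    res <- stats::residuals(fit)
  }
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    rms_pre = sqrt(mean(ppm^2)),
    rms_post = sqrt(mean(res^2)),
    n_calibrants = nrow(calibrants),
    n_dropped = n_dropped
  ), class = "mass_calibration")
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat("Linear mass calibration (ppm vs m/z)\n")
  cat(sprintf("  intercept: %+.4f ppm   slope: %+.3e ppm/Da\n",
              x$intercept, x$slope))
  cat(sprintf("  calibrants: %d (%d dropped)   RMS pre: %.3f ppm   post: %.3f ppm\n",
              x$n_calibrants, x$n_dropped, x$rms_pre, x$rms_post))
  invisible(x)
}

#' Identity calibration model
#'
#' @return A `mass_calibration` with zero intercept and slope.
#' @export
identity_calibration <- function() {
  structure(list(intercept = 0, slope = 0, rms_pre = 0, rms_post = 0,
                 n_calibrants = 0L, n_dropped = 0L),
            class = "mass_calibration")
}

#' Apply a calibration model to a peak list
#'
#' Each m/z is corrected by its modeled ppm error:
#' `mz / (1 + predicted_ppm * 1e-6)`. Intensities and S/N are untouched
#' and peak order is preserved.
#'
#' @param peaks Peak `data.frame` (`mz` column) or numeric vector.
#' @param model A `mass_calibration` object.
#' @return Same shape as `peaks`, with corrected m/z.
#' @export
apply_calibration <- function(peaks, model) {
  stopifnot(inherits(model, "mass_calibration"))
  mz <- if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks)
  pred <- model$intercept + model$slope * mz
  corrected <- mz / (1 + pred * 1e-6)
  if (is.data.frame(peaks)) {
    peaks$mz <- corrected
    peaks
  } else {
    corrected
  }
}

#' Internally calibrate a peak list on its CH2 homologous series
#'
#' End-to-end internal recalibration: detect CH2 series, anchor each
#' series by assigning a formula to its lowest-mass member at a relaxed
#' tolerance, derive theoretical ladder m/z values from the anchor
#' formula's exact mass, pool calibrants across series, fit the linear
#' model, and apply it.
#'
#' @param peaks Peak `data.frame` (filtered).
#' @param mode Ion mode for anchoring, default `"neg"`.
#' @param tol_ppm Series-spacing tolerance in ppm (default 1).
#' @param anchor_tol_ppm Relaxed assignment tolerance for anchoring
#'   series, default 3 ppm, so pre-calibration drift does not defeat the
#'   bootstrap.
#' @param bounds [element_bounds()] used for anchoring.
#' @param min_length Minimum series length (default 3).
#' @return List with `peaks` (calibrated), `model`
#'   (`mass_calibration`), and `report` (`data.frame`: series and
#'   calibrant counts, pre/post RMS ppm).
#' @export
calibrate_peaklist <- function(peaks, mode = c("neg", "pos"), tol_ppm = 1,
                               anchor_tol_ppm = 3,
                               bounds = element_bounds(), min_length = 3) {
  mode <- match.arg(mode)
  series <- find_homologous_series(peaks, "CH2", tol_ppm = tol_ppm,
                                   min_length = min_length)
  delta <- monoisotopic_mass("CH2")

  # Anchor every series: assign a formula to its lowest-mass member and
  # derive the theoretical ladder. CH2 series of natural organic matter
  # are overwhelmingly CHO ladders, so anchoring prefers the
  # heteroatom-poorest candidate; inside the relaxed window the
  # lowest-error rule would latch onto near-degenerate heteroatom-rich
  # alternatives under drift.
  anchor_pass <- function(anchor_model, window_ppm) {
    cal <- list()
    for (k in unique(series$series_id)) {
      s <- series[series$series_id == k, , drop = FALSE]
      anchor_mz <- apply_calibration(s$mz[1L], anchor_model)
      cand <- enumerate_formulas(neutral_from_mz(anchor_mz, mode),
                                 window_ppm, bounds)
      if (nrow(cand) == 0L) next
      cand <- cand[order(cand$heteroatoms, abs(cand$error_ppm),
                         cand$formula), , drop = FALSE]
      # an anchor is trusted only when the heteroatom-poorest level of
      # the window holds a single candidate; two CHO candidates in one
      # window (possible above ~600 Da, where CHO compositions can sit
      # a few mDa apart) make the ladder identity a coin flip
      hmin <- cand$heteroatoms[1L]
      if (sum(cand$heteroatoms == hmin) > 1L) next
      theo_anchor <- mz_from_neutral(cand$mass[1L], mode)
      k_step <- round((s$mz - s$mz[1L]) / delta)
      cal[[length(cal) + 1L]] <- data.frame(
        observed = s$mz, theoretical = theo_anchor + k_step * delta,
        series = k)
    }
    if (length(cal)) do.call(rbind, cal) else
      data.frame(observed = numeric(0), theoretical = numeric(0),
                 series = integer(0))
  }

  # Siegel repeated-median line: 50% breakdown, so a misanchored half of
  # the series cannot drag the trimming reference
  siegel_line <- function(x, y) {
    n <- length(x)
    slopes_i <- vapply(seq_len(n), function(i) {
      dx <- x - x[i]
      ok <- abs(dx) > 1e-9
      if (!any(ok)) return(NA_real_)
      stats::median((y[ok] - y[i]) / dx[ok])
    }, numeric(1))
    slope <- stats::median(slopes_i, na.rm = TRUE)
    intercept <- stats::median(y - slope * x)
    c(intercept, slope)
  }

  # drop whole series whose median |residual| (against the robust line)
  # marks a wrong anchor, then least-squares refit on the survivors
  fit_trimmed <- function(cal) {
    ppm <- ppm_error(cal$observed, cal$theoretical)
    line <- siegel_line(cal$observed, ppm)
    resid <- ppm - (line[1] + line[2] * cal$observed)
    med <- tapply(abs(resid), cal$series, stats::median)
    bad <- names(med)[med > 0.75]
    keep <- !(cal$series %in% as.integer(bad))
    if (sum(keep) < 4L || length(unique(cal$observed[keep])) < 2L) {
      keep <- rep(TRUE, nrow(cal))
    }
    fit_calibration(cal[keep, , drop = FALSE])
  }

  n_series <- length(unique(series$series_id))
  # The first pass must see the true ladder formula despite uncorrected
  # drift, so its window is opened to the drift scale the instrument can
  # plausibly accumulate; the CHO prior plus series-level trimming keeps
  # the wide window from admitting wrong anchors into the fit. The second
  # pass re-anchors at the configured tolerance once round-1 drift is
  # removed and refits against the original observed m/z, giving one
  # final model.
  cal1 <- if (n_series) {
    anchor_pass(identity_calibration(), max(8, anchor_tol_ppm))
  } else {
    data.frame(observed = numeric(0), theoretical = numeric(0),
               series = integer(0))
  }
  if (nrow(cal1) < 2L) {
    warning("fewer than 2 usable calibrants; returning peaks uncalibrated")
    model <- identity_calibration()
  } else {
    model1 <- fit_trimmed(cal1)
    cal2 <- anchor_pass(model1, anchor_tol_ppm)
    model <- if (nrow(cal2) >= 2L) fit_trimmed(cal2) else model1
  }
  out <- apply_calibration(peaks, model)
  report <- data.frame(
    n_series = n_series,
    n_calibrants = model$n_calibrants,
    rms_pre_ppm = model$rms_pre,
    rms_post_ppm = model$rms_post
  )
  list(peaks = out, model = model, report = report)
}
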