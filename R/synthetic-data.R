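#' Specification for a synthetic FTICR-MS peak list
#'
#' Bundles every knob of the synthetic negative-mode direct-injection
#' peak-list generator: the compound count and neutral-mass range, the
#' target van Krevelen class mixture, the mass-error model (systematic
#' ppm drift linear in m/z plus Gaussian ppm jitter), log-normal
#' intensity and S/N models, the contaminant fraction, planted CH2
#' homologous ladders, planted transformation chains, and optional
#' reference spike-ins. The defaults emulate a plant-extract spectrum:
#' a few hundred singly charged deprotonated CHONSP ions between 150 and
#' 800 Da dominated by lignin-like formulas, sub-ppm random mass error,
#' and a small formula-less contaminant fraction.
#'
#' @param seed Integer seed; the same spec (including seed) always
#'   yields identical output.
#' @param n_compounds Number of core (non-planted) compounds.
#' @param mass_range Neutral monoisotopic mass range, Da.
#' @param mode Ion mode (`"neg"` default).
#' @param class_mixture Named fractions over van Krevelen classes
#'   (must sum to <= 1; remainder spread uniformly over the named
#'   classes).
#' @param drift Length-2 numeric `c(a, b)`: systematic error in ppm is
#'   `a + b * mz`. Default no drift.
#' @param jitter_ppm SD of the Gaussian random ppm error, default 0.2.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param sn_meanlog,sn_sdlog Log-normal signal-to-noise model.
#' @param contaminant_frac Fraction of peaks (relative to compound
#'   count) added at random m/z with no CHONSP formula within 2 ppm.
#' @param series List `(n, length)`: planted CH2 ladders.
#' @param chains List `(n, length, transformations)`: planted chains of
#'   named transformations from [default_transformations()].
#' @param spike_in Optional reference `data.frame` (`name`, `formula`)
#'   whose ions are spiked into the sample.
#' @param bounds [element_bounds()] used to validate contaminants.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_compounds = 500L,
                           mass_range = c(150, 800),
                           mode = "neg",
                           class_mixture = c(
                             lipid = 0.12,
                             unsaturated_hydrocarbon = 0.05,
                             protein = 0.15,
                             amino_sugar = 0.08,
                             lignin = 0.30,
                             tannin = 0.18,
                             condensed_aromatic = 0.12),
                           drift = c(0, 0),
                           jitter_ppm = 0.2,
                           intensity_meanlog = log(1e4),
                           intensity_sdlog = 1,
                           sn_meanlog = log(40),
                           sn_sdlog = 0.7,
                           contaminant_frac = 0.05,
                           series = list(n = 3L, length = 6L),
                           chains = list(n = 3L, length = 4L,
                                         transformations = c("CO2", "H2O",
                                                             "CH2", "O")),
                           spike_in = NULL,
                           bounds = element_bounds()) {
  stopifnot(seed == round(seed), n_compounds >= 0,
            length(mass_range) == 2L, mass_range[1] > 0,
            mass_range[1] < mass_range[2],
            all(class_mixture >= 0), sum(class_mixture) <= 1 + 1e-9,
            length(drift) == 2L, jitter_ppm >= 0,
            contaminant_frac >= 0, contaminant_frac <= 1)
  structure(list(
    seed = as.integer(seed), n_compounds = as.integer(n_compounds),
    mass_range = mass_range, mode = mode, class_mixture = class_mixture,
    drift = drift, jitter_ppm = jitter_ppm,
    intensity_meanlog = intensity_meanlog, intensity_sdlog = intensity_sdlog,
    sn_meanlog = sn_meanlog, sn_sdlog = sn_sdlog,
    contaminant_frac = contaminant_frac, series = series, chains = chains,
    spike_in = spike_in, bounds = bounds
  ), class = "synthetic_spec")
}

# sampling windows per class, slightly inset from the bin edges so that
# integer rounding of element counts rarely crosses a boundary
.class_windows <- list(
  lipid = c(0.02, 0.28, 1.55, 2.45),
  unsaturated_hydrocarbon = c(0.0, 0.12, 0.85, 1.40),
  protein = c(0.32, 0.53, 1.55, 2.25),
  amino_sugar = c(0.57, 0.68, 1.55, 2.15),
  lignin = c(0.15, 0.63, 0.85, 1.45),
  tannin = c(0.67, 1.05, 0.85, 1.45),
  condensed_aromatic = c(0.05, 0.9, 0.25, 0.75),
  carbohydrate = c(0.67, 1.05, 1.55, 2.45)
)

.draw_formula <- function(class, mass_range, used, classes = vk_classes(TRUE),
                          max_tries = 400L) {
  win <- .class_windows[[class]]
  if (is.null(win)) stop("no sampling window for class '", class, "'")
  for (t in seq_len(max_tries)) {
    target <- stats::runif(1, mass_range[1], mass_range[2])
    oc <- stats::runif(1, win[1], win[2])
    hc <- stats::runif(1, win[3], win[4])
    am <- atomic_masses()
    C <- max(4L, as.integer(round(target /
      (12 + hc * am[["H"]] + oc * am[["O"]]))))
    O <- as.integer(round(oc * C))
    H <- as.integer(round(hc * C))
    cnt <- c(C = C, H = H, N = 0L, O = O, P = 0L, S = 0L)
    # heteroatoms leave O:C and H:C untouched
    if (stats::runif(1) < 0.25) cnt["N"] <- sample(1:3, 1)
    if (stats::runif(1) < 0.05) cnt["S"] <- 1L
    if (stats::runif(1) < 0.04 && O >= 4L) cnt["P"] <- 1L
    # even-electron neutral molecules have integer DBE: H = N + P (mod 2)
    if ((cnt["H"] - cnt["N"] - cnt["P"]) %% 2L == 1L) {
      cnt["H"] <- cnt["H"] - 1L
    }
    f <- formula_string(cnt)
    if (f %in% used) next
    if (dbe(f) < 0) next  # chemically invalid; would defeat assignment
    m <- monoisotopic_mass(f)
    if (m < mass_range[1] || m > mass_range[2]) next
    realized <- vk_classify(f, classes)
    if (realized != class) next
    return(list(formula = f, mass = m, class = realized))
  }
  stop("could not draw a formula for class '", class,
       "' within the mass range; mixture unreachable under bounds")
}

#' Generate a synthetic peak list with ground truth
#'
#' Draws CHONSP formulas by rejection sampling within the van Krevelen
#' class bins to hit the target mixture, appends planted CH2 ladders,
#' transformation chains, and spike-ins, ionizes everything
#' (deprotonation by default), applies the systematic drift and random
#' jitter of the error model, draws log-normal intensities and S/N, and
#' appends contaminant peaks verified (by running the formula enumerator
#' at generation time, 2 ppm window) to have no valid CHONSP formula.
#' Output is sorted by observed m/z.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `peaks` (`data.frame`: `mz`, `intensity`, `sn`) and
#'   `truth` (`data.frame`, row-aligned with `peaks`: `mz`, `true_mz`,
#'   `formula`, `neutral_mass`, `class`, `series_id`, `chain_id`,
#'   `reference`, `contaminant`).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes_all <- vk_classes(TRUE)
  mix <- spec$class_mixture
  rest <- 1 - sum(mix)
  prob <- mix + rest / length(mix)

  # -- core compounds ------------------------------------------------
  set.seed(spec$seed)
  used <- character(0)
  rows <- list()
  if (spec$n_compounds > 0L) {
    draw_class <- sample(names(prob), spec$n_compounds, replace = TRUE,
                         prob = prob)
    for (i in seq_len(spec$n_compounds)) {
      d <- .draw_formula(draw_class[i], spec$mass_range, used, classes_all)
      used <- c(used, d$formula)
      rows[[length(rows) + 1L]] <- data.frame(
        formula = d$formula, neutral_mass = d$mass, class = d$class,
        series_id = NA_integer_, chain_id = NA_integer_,
        reference = NA_character_, stringsAsFactors = FALSE)
    }
  }

  # -- planted CH2 homologous ladders --------------------------------
  set.seed(spec$seed + 1L)
  if (!is.null(spec$series) && spec$series$n > 0L) {
    # ladder bases spread across the acquired range, as in real organic
    # matter spectra, so series-derived calibrants span the mass axis
    ch2 <- monoisotopic_mass("CH2")
    base_range <- c(spec$mass_range[1],
                    max(spec$mass_range[1] + 50,
                        spec$mass_range[2] - spec$series$length * ch2 - 5))
    for (s in seq_len(spec$series$n)) {
      base <- .draw_formula("lignin", base_range, used, classes_all)
      f <- base$formula
      for (k in seq_len(spec$series$length) - 1L) {
        if (k > 0L) f <- formula_add(f, "CH2")
        if (f %in% used) next
        used <- c(used, f)
        rows[[length(rows) + 1L]] <- data.frame(
          formula = f, neutral_mass = monoisotopic_mass(f),
          class = vk_classify(f, classes_all),
          series_id = s, chain_id = NA_integer_,
          reference = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }

  # -- planted transformation chains ---------------------------------
  set.seed(spec$seed + 2L)
  if (!is.null(spec$chains) && spec$chains$n > 0L) {
    tr <- default_transformations()
    steps <- spec$chains$transformations
    bad <- setdiff(steps, tr$name)
    if (length(bad)) stop("unknown chain transformation(s): ",
                          paste(bad, collapse = ", "))
    half <- c(spec$mass_range[1],
              spec$mass_range[1] + diff(spec$mass_range) / 2)
    for (cid in seq_len(spec$chains$n)) {
      base <- .draw_formula("lignin", half, used, classes_all)
      f <- base$formula
      for (k in seq_len(spec$chains$length) - 1L) {
        if (k > 0L) {
          step <- steps[(k - 1L) %% length(steps) + 1L]
          f <- formula_add(f, tr$formula[tr$name == step])
        }
        if (f %in% used) next
        used <- c(used, f)
        rows[[length(rows) + 1L]] <- data.frame(
          formula = f, neutral_mass = monoisotopic_mass(f),
          class = vk_classify(f, classes_all),
          series_id = NA_integer_, chain_id = cid,
          reference = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }

  # -- reference spike-ins -------------------------------------------
  if (!is.null(spec$spike_in) && nrow(spec$spike_in) > 0L) {
    sp <- spec$spike_in
    for (i in seq_len(nrow(sp))) {
      f <- formula_string(parse_formula(sp$formula[i]))  # canonical form
      if (f %in% used) next
      used <- c(used, f)
      rows[[length(rows) + 1L]] <- data.frame(
        formula = f, neutral_mass = monoisotopic_mass(f),
        class = vk_classify(f, classes_all),
        series_id = NA_integer_, chain_id = NA_integer_,
        reference = sp$name[i], stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, rows)
  truth$true_mz <- mz_from_neutral(truth$neutral_mass, spec$mode)
  truth$contaminant <- FALSE

  # -- contaminants: no CHONSP formula within 2 ppm ------------------
  set.seed(spec$seed + 3L)
  n_cont <- round(spec$contaminant_frac * nrow(truth))
  if (n_cont > 0L) {
    ion_range <- mz_from_neutral(spec$mass_range, spec$mode)
    cont_mz <- numeric(0)
    tries <- 0L
    while (length(cont_mz) < n_cont && tries < 200L * n_cont) {
      tries <- tries + 1L
      mz <- stats::runif(1, ion_range[1], ion_range[2])
      cand <- enumerate_formulas(neutral_from_mz(mz, spec$mode), 2,
                                 spec$bounds)
      if (nrow(cand) == 0L) cont_mz <- c(cont_mz, mz)
    }
    if (length(cont_mz)) {
      truth <- rbind(truth, data.frame(
        formula = NA_character_, neutral_mass = NA_real_,
        class = NA_character_, series_id = NA_integer_,
        chain_id = NA_integer_, reference = NA_character_,
        true_mz = cont_mz, contaminant = TRUE, stringsAsFactors = FALSE))
    }
  }

  # -- error model, intensities, S/N ---------------------------------
  set.seed(spec$seed + 4L)
  n <- nrow(truth)
  err_ppm <- spec$drift[1] + spec$drift[2] * truth$true_mz +
    stats::rnorm(n, 0, spec$jitter_ppm)
  err_ppm[truth$contaminant] <- 0  # contaminant m/z is already arbitrary
  mz_obs <- truth$true_mz * (1 + err_ppm * 1e-6)
  peaks <- data.frame(
    mz = mz_obs,
    intensity = stats::rlnorm(n, spec$intensity_meanlog,
                              spec$intensity_sdlog),
    sn = stats::rlnorm(n, spec$sn_meanlog, spec$sn_sdlog)
  )
  ord <- order(peaks$mz)
  peaks <- peaks[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  truth <- data.frame(mz = peaks$mz, truth[, c(
    "true_mz", "formula", "neutral_mass", "class", "series_id",
    "chain_id", "reference", "contaminant")], stringsAsFactors = FALSE)
  rownames(peaks) <- rownames(truth) <- NULL
  attr(peaks, "sample_id") <- paste0("synthetic_seed", spec$seed)
  list(peaks = peaks, truth = truth)
}

#' Generate a synthetic metabolite-concentration table
#'
#' Class-structured micromolar concentrations: log-normal draws per
#' class rescaled so each class sums exactly to its target total, with
#' every value at or above the 1 uM detection floor.
#'
#' @param class_totals Named numeric vector of per-class totals (uM).
#' @param n_per_class Metabolites per class (single integer or named
#'   vector).
#' @param seed Integer seed.
#' @return Concentration `data.frame` (`name`, `concentration`, `class`)
#'   compatible with [class_totals()].
#' @export
generate_concentration_table <- function(class_totals =
                                           c(Sugars = 3360, Acids = 1010,
                                             `Amino Acids` = 790,
                                             Polyols = 256),
                                         n_per_class = 5L, seed = 1L) {
  stopifnot(all(class_totals > 0))
  if (length(class_totals) == 0L) {
    return(data.frame(name = character(0), concentration = numeric(0),
                      class = character(0)))
  }
  if (length(n_per_class) == 1L) {
    n_per_class <- stats::setNames(rep(as.integer(n_per_class),
                                       length(class_totals)),
                                   names(class_totals))
  }
  set.seed(seed)
  rows <- lapply(names(class_totals), function(cl) {
    n <- n_per_class[[cl]]
    repeat {
      w <- stats::rlnorm(n, 0, 1)
      conc <- w / sum(w) * class_totals[[cl]]
      if (all(conc >= 1)) break  # detection floor of the emulated assay
    }
    data.frame(name = paste0(cl, "_", seq_len(n)), concentration = conc,
               class = cl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic lipid-subclass count table
#'
#' Multinomial split of a fixed identification total over subclasses;
#' the embedded total is consistent by construction.
#'
#' @param total Total identifications, default 152.
#' @param n_subclasses Number of subclasses, default 19.
#' @param seed Integer seed.
#' @return Count `data.frame` (`category`, `subclass`, `count`) with
#'   attribute `embedded_total = total`, compatible with
#'   [subclass_total()].
#' @export
generate_lipid_counts <- function(total = 152L, n_subclasses = 19L,
                                  seed = 1L) {
  stopifnot(total >= 0, n_subclasses >= 1L)
  set.seed(seed)
  prob <- stats::runif(n_subclasses, 0.2, 1)
  counts <- as.integer(stats::rmultinom(1, total, prob))
  out <- data.frame(
    category = paste0("category_", rep(seq_len(ceiling(n_subclasses / 5)),
                                       each = 5)[seq_len(n_subclasses)]),
    subclass = paste0("subclass_", sprintf("%02d", seq_len(n_subclasses))),
    count = counts, stringsAsFactors = FALSE)
  attr(out, "embedded_total") <- as.integer(total)
  out
}
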