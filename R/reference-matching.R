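#' Read a reference compound list
#'
#' Delimited text with columns `name`, `formula`, `source` (plant of
#' origin; optional `notes`). Rows whose formula does not parse are
#' rejected with a warning.
#'
#' @param path CSV/TSV path.
#' @return `data.frame` with `name`, `formula`, `source`, `notes`,
#'   `neutral_mass`.
#' @export
read_reference_compounds <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "\"")
  need <- c("name", "formula")
  if (length(setdiff(need, names(raw)))) {
    stop("reference list needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(raw$source)) raw$source <- rep(NA_character_, nrow(raw))
  if (is.null(raw$notes)) raw$notes <- rep(NA_character_, nrow(raw))
  mass <- vapply(raw$formula, function(f) {
    tryCatch(monoisotopic_mass(f), error = function(e) NA_real_)
  }, numeric(1))
  bad <- is.na(mass)
  if (any(bad)) {
    warning(sum(bad), " reference row(s) rejected (unparseable formula): ",
            paste(raw$name[bad], collapse = "; "))
  }
  out <- data.frame(name = raw$name[!bad], formula = raw$formula[!bad],
                    source = raw$source[!bad], notes = raw$notes[!bad],
                    neutral_mass = unname(mass[!bad]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Packaged antimicrobial reference compounds
#'
#' The 17 known antimicrobial compounds confirmed by FTICR-MS in the
#' medicinal-plant comparison panel, transcribed into a packaged fixture
#' (name, molecular formula, source plant). Two formulas are shared by
#' isomer pairs, so the 17 compounds collapse to 15 distinct deprotonated
#' m/z values.
#'
#' @return `data.frame` as from [read_reference_compounds()].
#' @examples
#' nrow(antimicrobial_reference())  # 17
#' @export
antimicrobial_reference <- function() {
  read_reference_compounds(
    system.file("extdata", "antimicrobial_reference.csv",
                package = "fticrms", mustWork = TRUE))
}

#' Distinct theoretical m/z values with isomer groups
#'
#' Direct-injection FTICR-MS cannot separate isomers: compounds sharing a
#' molecular formula share one exact m/z. This collapses a reference list
#' to its distinct theoretical m/z values and enumerates the compounds
#' behind each (the isomer group).
#'
#' @param compounds Reference `data.frame`
#'   (from [read_reference_compounds()]).
#' @param mode Ion mode, default `"neg"` (`[M-H]-`).
#' @return `data.frame` with one row per distinct formula: `formula`,
#'   `theoretical_mz`, `isomer_group` (integer id), `n_compounds`,
#'   `compounds` (names collapsed with `"; "`), sorted by m/z.
#' @export
distinct_mz <- function(compounds, mode = c("neg", "pos")) {
  mode <- match.arg(mode)
  stopifnot(nrow(compounds) >= 1L)
  if (is.null(compounds$neutral_mass)) {
    compounds$neutral_mass <- monoisotopic_mass(compounds$formula)
  }
  groups <- split(seq_len(nrow(compounds)), compounds$formula)
  out <- do.call(rbind, lapply(names(groups), function(f) {
    ix <- groups[[f]]
    data.frame(
      formula = f,
      theoretical_mz = mz_from_neutral(compounds$neutral_mass[ix[1]], mode),
      n_compounds = length(ix),
      compounds = paste(sort(compounds$name[ix]), collapse = "; "),
      stringsAsFactors = FALSE)
  }))
  out <- out[order(out$theoretical_mz), , drop = FALSE]
  out$isomer_group <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("formula", "theoretical_mz", "isomer_group", "n_compounds",
          "compounds")]
}

#' Match observed peaks against a reference compound list
#'
#' Cross-checks every distinct theoretical m/z (after isomer collapse)
#' against the observed peak list in m/z space. All peaks within
#' `tol_ppm` of a theoretical m/z are reported; the nearest is flagged
#' primary. References with no peak in tolerance appear with `matched =
#' FALSE`.
#'
#' @param peaks Peak `data.frame` (`mz`) or numeric m/z vector
#'   (calibrated).
#' @param compounds Reference `data.frame`.
#' @param mode Ion mode, default `"neg"`.
#' @param tol_ppm Match tolerance in ppm, default 1.
#' @return `data.frame` sorted by reference formula m/z: `formula`,
#'   `theoretical_mz`, `isomer_group`, `compounds`, `observed_mz`,
#'   `error_ppm`, `primary`, `matched`.
#' @export
match_reference <- function(peaks, compounds, mode = c("neg", "pos"),
                            tol_ppm = 1) {
  mode <- match.arg(mode)
  stopifnot(tol_ppm > 0)
  mz <- sort(if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks))
  refs <- distinct_mz(compounds, mode)
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    theo <- refs$theoretical_mz[i]
    tol <- tol_ppm * 1e-6 * theo
    j0 <- findInterval(theo - tol, mz) + 1L
    j1 <- findInterval(theo + tol, mz)
    base <- refs[i, c("formula", "theoretical_mz", "isomer_group",
                      "compounds")]
    if (j1 < j0) {
      return(cbind(base, data.frame(observed_mz = NA_real_,
                                    error_ppm = NA_real_,
                                    primary = FALSE, matched = FALSE)))
    }
    obs <- mz[j0:j1]
    err <- ppm_error(obs, theo)
    cbind(base[rep(1L, length(obs)), , drop = FALSE],
          data.frame(observed_mz = obs, error_ppm = err,
                     primary = seq_along(obs) == which.min(abs(err)),
                     matched = TRUE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$theoretical_mz, !out$primary), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Name-token class tallies of a reference list
#'
#' Counts reference compounds whose names contain the token `"acid"` and
#' those containing `"glycoside"` or `"glucoside"` (case-insensitive).
#' These name-level tallies summarise the acid / sugar-derivative
#' character of a compound panel.
#'
#' @param compounds Reference `data.frame` with a `name` column.
#' @return Named integer vector `c(acid = ..., glycoside = ...)`.
#' @examples
#' name_token_counts(antimicrobial_reference())  # 9 acids, 7 glycosides
#' @export
name_token_counts <- function(compounds) {
  nm <- tolower(compounds$name)
  c(acid = sum(grepl("acid", nm)),
    glycoside = sum(grepl("glycoside|glucoside", nm)))
}
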