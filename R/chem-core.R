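#' Monoisotopic atomic masses
#'
#' Reference monoisotopic masses (Da) of the six elements considered during
#' formula assignment (C, H, N, O, P, S), together with the proton and
#' electron masses. Carbon is exactly 12 by definition of the unified atomic
#' mass unit; the remaining values are standard CODATA/AME monoisotopic
#' masses carried to >= 9 significant digits, as required for sub-ppm mass
#' arithmetic.
#'
#' @return Named numeric vector with elements `C`, `H`, `N`, `O`, `P`, `S`,
#'   `proton`, `electron` (all in Da).
#' @examples
#' atomic_masses()[["C"]]
#' @export
atomic_masses <- function() {
  c(
    C = 12,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    P = 30.97376163,
    S = 31.97207100,
    proton = 1.00727646688,
    electron = 0.000548579909
  )
}

.elements <- c("C", "H", "N", "O", "P", "S")

#' Parse molecular formula strings
#'
#' Parses Hill-style formula strings over the element set C, H, N, O, P, S
#' ("CHONSP"). A count of 1 may be written explicitly or omitted
#' (`"CH4O"` is `C1H4O1`). Elements outside the set are rejected.
#'
#' @param x Character vector of formula strings.
#' @return Integer matrix with one row per formula and columns
#'   `C`, `H`, `N`, `O`, `P`, `S`; row names are the input strings.
#' @examples
#' parse_formula("C18H34O2")
#' parse_formula(c("CH4O", "C6H12O6"))
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  out <- matrix(0L, nrow = length(x), ncol = length(.elements),
                dimnames = list(x, .elements))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || !nzchar(s)) {
      next  # empty formula: all-zero counts
    }
    parts <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
    if (paste(parts, collapse = "") != s) {
      stop("unparseable formula string: '", s, "'")
    }
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      if (!el %in% .elements) {
        stop("element '", el, "' in '", s,
             "' is outside the supported set {C,H,O,N,S,P}")
      }
      n <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(n)) as.integer(n) else 1L
      out[i, el] <- out[i, el] + n
    }
  }
  out
}

.as_counts <- function(formula) {
  if (is.character(formula)) return(parse_formula(formula))
  if (is.matrix(formula)) {
    stopifnot(all(colnames(formula) %in% .elements))
    m <- matrix(0L, nrow = nrow(formula), ncol = length(.elements),
                dimnames = list(rownames(formula), .elements))
    m[, colnames(formula)] <- as.integer(formula)
    return(m)
  }
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(.as_counts(matrix(formula, nrow = 1,
                             dimnames = list(NULL, names(formula)))))
  }
  stop("formula must be a character vector, named count vector, or count matrix")
}

#' Write element counts as a Hill-style formula string
#'
#' @param counts Integer matrix (columns among C,H,N,O,P,S) or named vector.
#' @return Character vector of formula strings in Hill order (C, H, then
#'   alphabetical); counts of 1 are omitted, empty formulas give `""`.
#' @examples
#' formula_string(c(C = 6, H = 12, O = 6))
#' @export
formula_string <- function(counts) {
  m <- .as_counts(counts)
  unname(apply(m, 1L, function(v) {
    paste0(vapply(.elements[v > 0], function(el) {
      if (v[el] == 1L) el else paste0(el, v[el])
    }, character(1)), collapse = "")
  }))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times monoisotopic atomic masses. The empty
#' formula has mass 0.
#'
#' @param formula Character vector of formula strings, a named count
#'   vector, or a count matrix as returned by [parse_formula()].
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C18H34O2")  # oleic acid, 282.25588
#' @export
monoisotopic_mass <- function(formula) {
  m <- .as_counts(formula)
  if (any(m < 0)) stop("negative element counts are not a valid formula")
  am <- atomic_masses()[.elements]
  as.numeric(m %*% am)
}

#' Add two molecular formulas element-wise
#'
#' @param a,b Formulas (strings, named vectors, or single-row matrices).
#' @return Hill-style formula string of the element-wise sum.
#' @examples
#' formula_add("C6H12O6", "CH2")
#' @export
formula_add <- function(a, b) {
  formula_string(.as_counts(a) + .as_counts(b))
}

#' Convert neutral mass to ion m/z
#'
#' For singly charged ions only: deprotonation (`[M-H]-`, negative mode)
#' subtracts one proton mass; protonation (`[M+H]+`, positive mode) adds
#' one. The electron mass is folded into the proton-mass convention, which
#' keeps computed neutral masses of deprotonated ions within the sub-ppm
#' regime of the instrument.
#'
#' @param mass Neutral monoisotopic mass (Da), positive.
#' @param mode `"neg"` for `[M-H]-` (default) or `"pos"` for `[M+H]+`.
#' @return m/z of the singly charged ion.
#' @seealso [neutral_from_mz()] for the exact inverse.
#' @examples
#' mz_from_neutral(180.063388)          # glucose [M-H]-
#' mz_from_neutral(267.096754, "pos")   # adenosine [M+H]+
#' @export
mz_from_neutral <- function(mass, mode = c("neg", "pos")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mass))
  if (any(mass <= 0)) stop("neutral mass must be positive")
  p <- atomic_masses()[["proton"]]
  if (mode == "neg") mass - p else mass + p
}

#' Convert ion m/z to neutral mass
#'
#' Exact inverse of [mz_from_neutral()] for singly charged `[M-H]-` /
#' `[M+H]+` species.
#'
#' @param mz Observed m/z of the singly charged ion.
#' @param mode `"neg"` (default) or `"pos"`.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_from_mz <- function(mz, mode = c("neg", "pos")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mz))
  p <- atomic_masses()[["proton"]]
  mass <- if (mode == "neg") mz + p else mz - p
  if (any(mass <= 0)) {
    stop("m/z implies a non-positive neutral mass")
  }
  mass
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical Masses in Da; `theoretical` must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`, signed.
#' @examples
#' ppm_error(282.25602, 282.25588)  # +0.50 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(is.numeric(observed), is.numeric(theoretical))
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Double-bond equivalents of a formula
#'
#' DBE = C - H/2 + N/2 + P/2 + 1 (rings plus double bonds); negative values
#' are chemically invalid and are rejected during formula assignment.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector of DBE values (may be half-integer).
#' @export
dbe <- function(formula) {
  m <- .as_counts(formula)
  m[, "C"] - m[, "H"] / 2 + m[, "N"] / 2 + m[, "P"] / 2 + 1
}

#' Heteroatom count (N + S + P) of a formula
#'
#' @inheritParams monoisotopic_mass
#' @return Integer vector of N + S + P counts.
#' @export
heteroatom_count <- function(formula) {
  m <- .as_counts(formula)
  as.integer(m[, "N"] + m[, "S"] + m[, "P"])
}
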