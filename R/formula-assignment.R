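#' Element count bounds for formula enumeration
#'
#' Default bounds span the CHONSP composition space of plant-extract
#' dissolved organic matter at desk-scale enumeration cost.
#'
#' @param C,H,O,N,S,P Length-2 integer vectors `c(min, max)`.
#' @return A named list of bounds with class `element_bounds`.
#' @examples
#' element_bounds()                       # defaults
#' element_bounds(C = c(1, 15), N = c(0, 2))
#' @export
element_bounds <- function(C = c(1, 100), H = c(0, 200), O = c(0, 50),
                           N = c(0, 5), S = c(0, 2), P = c(0, 2)) {
  b <- list(C = C, H = H, O = O, N = N, S = S, P = P)
  for (el in names(b)) {
    v <- b[[el]]
    if (length(v) != 2L || any(v < 0) || v[1] > v[2]) {
      stop("bounds for ", el, " must be c(min, max) with 0 <= min <= max")
    }
    b[[el]] <- as.integer(v)
  }
  # H is solved per query mass, so the search grid spans C, O, N, S, P only
  n_raw <- prod(vapply(b[c("C", "O", "N", "S", "P")],
                       function(v) v[2] - v[1] + 1, numeric(1)))
  if (n_raw > 1e7) {
    stop("bounds produce ", format(n_raw, big.mark = ","),
         " search-grid combinations (> 1e7); tighten element ranges")
  }
  structure(b, class = "element_bounds")
}

# Candidate grid over (C, O, N, S, P); H is solved per query mass.
# Cached per bounds signature: building it is the expensive step, querying
# one mass is a vectorized window scan.
.grid_cache <- new.env(parent = emptyenv())

.candidate_grid <- function(bounds) {
  key <- paste(unlist(bounds), collapse = "_")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  g <- expand.grid(C = bounds$C[1]:bounds$C[2],
                   O = bounds$O[1]:bounds$O[2],
                   N = bounds$N[1]:bounds$N[2],
                   S = bounds$S[1]:bounds$S[2],
                   P = bounds$P[1]:bounds$P[2],
                   KEEP.OUT.ATTRS = FALSE)
  # one P atom requires at least four O atoms
  g <- g[g$P == 0L | g$O >= 4L, , drop = FALSE]
  am <- atomic_masses()
  base <- 12 * g$C + am[["O"]] * g$O + am[["N"]] * g$N +
    am[["S"]] * g$S + am[["P"]] * g$P
  ord <- order(base)
  grid <- list(C = g$C[ord], O = g$O[ord], N = g$N[ord], S = g$S[ord],
               P = g$P[ord], base = base[ord])
  .grid_cache[[key]] <- grid
  grid
}

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Finds every CHONSP formula within `bounds` whose monoisotopic mass lies
#' strictly within `tol_ppm` of `neutral_mass`, subject to the validity
#' rules: one or more phosphorus atoms require at least four oxygens, and
#' DBE (C - H/2 + N/2 + P/2 + 1) must be non-negative. Candidates are
#' sorted by absolute ppm error, then heteroatom count (N+S+P), then
#' formula string, which makes downstream selection deterministic.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da, in (0, 2000].
#' @param tol_ppm Mass tolerance in ppm (strict `<`), default 1.
#' @param bounds An [element_bounds()] object.
#' @return `data.frame` with columns `formula`, `mass`, `error_ppm`,
#'   `heteroatoms`, `dbe`, `C`, `H`, `N`, `O`, `P`, `S`.
#' @examples
#' enumerate_formulas(180.063388)$formula[1]  # "C6H12O6"
#' @export
enumerate_formulas <- function(neutral_mass, tol_ppm = 1,
                               bounds = element_bounds()) {
  stopifnot(length(neutral_mass) == 1L, is.numeric(neutral_mass),
            tol_ppm > 0)
  if (neutral_mass <= 0 || neutral_mass > 2000) {
    stop("neutral mass must be in (0, 2000] Da")
  }
  if (!inherits(bounds, "element_bounds")) bounds <- do.call(element_bounds, bounds)
  grid <- .candidate_grid(bounds)
  am <- atomic_masses()
  mh <- am[["H"]]
  w <- neutral_mass * tol_ppm * 1e-6
  # base mass window implied by H in [Hmin, Hmax]
  lo <- neutral_mass - bounds$H[2] * mh - w
  hi <- neutral_mass - bounds$H[1] * mh + w
  i0 <- findInterval(lo, grid$base) + 1L
  i1 <- findInterval(hi, grid$base)
  empty <- data.frame(formula = character(0), mass = numeric(0),
                      error_ppm = numeric(0), heteroatoms = integer(0),
                      dbe = numeric(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0), P = integer(0),
                      S = integer(0))
  if (i1 < i0) return(empty)
  ix <- i0:i1
  H <- as.integer(round((neutral_mass - grid$base[ix]) / mh))
  mass <- grid$base[ix] + H * mh
  err <- (mass - neutral_mass) / neutral_mass * 1e6
  d <- grid$C[ix] - H / 2 + grid$N[ix] / 2 + grid$P[ix] / 2 + 1
  keep <- H >= bounds$H[1] & H <= bounds$H[2] & abs(err) < tol_ppm & d >= 0
  if (!any(keep)) return(empty)
  ix <- ix[keep]
  out <- data.frame(
    formula = NA_character_,
    mass = mass[keep],
    error_ppm = -err[keep],  # observed - theoretical convention
    heteroatoms = as.integer(grid$N[ix] + grid$S[ix] + grid$P[ix]),
    dbe = d[keep],
    C = grid$C[ix], H = H[keep], N = grid$N[ix], O = grid$O[ix],
    P = grid$P[ix], S = grid$S[ix]
  )
  cnt <- as.matrix(out[, c("C", "H", "N", "O", "P", "S")])
  colnames(cnt) <- c("C", "H", "N", "O", "P", "S")
  out$formula <- formula_string(cnt)
  ord <- order(abs(out$error_ppm), out$heteroatoms, out$formula)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the best formula from a candidate set
#'
#' Applies the selection rule used throughout the pipeline: lowest
#' absolute mass error, then lowest heteroatom count, with the formula
#' string as a final deterministic tie-break. Candidates from
#' [enumerate_formulas()] are already in this order, so the first row is
#' returned.
#'
#' @param candidates `data.frame` from [enumerate_formulas()].
#' @return One-row `data.frame`, or `NULL` when the set is empty.
#' @export
select_formula <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  ord <- order(abs(candidates$error_ppm), candidates$heteroatoms,
               candidates$formula)
  candidates[ord[1L], , drop = FALSE]
}

#' Assign molecular formulas to a peak list
#'
#' Converts each observed m/z to a neutral mass for the configured ion
#' mode, enumerates CHONSP candidates, and selects one formula per peak by
#' the lowest-error / fewest-heteroatoms rule. Peaks with no candidate
#' within tolerance are reported with status `"unknown"`.
#'
#' Exact-mass formula assignment above a few hundred Da is not always
#' unique: CHONSP composition space contains near-degenerate pairs (for
#' example exchanging C7 + N + S against H2 + O8 shifts the mass by only
#' 0.18 mDa), so several candidates can fall inside a sub-ppm window.
#' The `n_candidates` column reports the window population per peak;
#' rows with `n_candidates == 1` are unique, confidently interpretable
#' assignments. With `ambiguous = "drop"`, multi-candidate peaks are
#' reported as status `"ambiguous"` instead of receiving the
#' best-ranked formula.
#'
#' @param peaks Peak `data.frame` (`mz` column required), already filtered
#'   and calibrated.
#' @param mode Ion mode: `"neg"` (`[M-H]-`, default) or `"pos"`.
#' @param tol_ppm Assignment tolerance in ppm (strict `<`), default 1.
#' @param bounds An [element_bounds()] object.
#' @param ambiguous `"select"` (default): resolve multi-candidate peaks
#'   by the selection rule; `"drop"`: leave them unassigned with status
#'   `"ambiguous"`.
#' @return `data.frame` with one row per peak: `mz`, `neutral_mass`,
#'   `formula`, `error_ppm`, `heteroatoms`, `dbe`, `n_candidates`,
#'   `status` (`"assigned"` / `"unknown"` / `"ambiguous"`).
#' @export
assign_formulas <- function(peaks, mode = c("neg", "pos"), tol_ppm = 1,
                            bounds = element_bounds(),
                            ambiguous = c("select", "drop")) {
  mode <- match.arg(mode)
  ambiguous <- match.arg(ambiguous)
  mz <- if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks)
  n <- length(mz)
  out <- data.frame(
    mz = mz,
    neutral_mass = neutral_from_mz(mz, mode),
    formula = NA_character_,
    error_ppm = NA_real_,
    heteroatoms = NA_integer_,
    dbe = NA_real_,
    n_candidates = 0L,
    status = "unknown",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    cand <- enumerate_formulas(out$neutral_mass[i], tol_ppm, bounds)
    out$n_candidates[i] <- nrow(cand)
    if (nrow(cand) > 1L && ambiguous == "drop") {
      out$status[i] <- "ambiguous"
      next
    }
    best <- select_formula(cand)
    if (!is.null(best)) {
      out$formula[i] <- best$formula
      out$error_ppm[i] <- best$error_ppm
      out$heteroatoms[i] <- best$heteroatoms
      out$dbe[i] <- best$dbe
      out$status[i] <- "assigned"
    }
  }
  sid <- attr(peaks, "sample_id")
  if (!is.null(sid)) attr(out, "sample_id") <- sid
  out
}
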