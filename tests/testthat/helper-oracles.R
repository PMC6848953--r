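# Independent oracles kept deliberately naive: full grids and double
# loops, no shared code with the implementation paths they check.

# Brute-force formula enumeration over a full element grid (H included).
brute_force_formulas <- function(neutral_mass, tol_ppm, bounds) {
  am <- fticrms::atomic_masses()
  g <- expand.grid(C = bounds$C[1]:bounds$C[2],
                   H = bounds$H[1]:bounds$H[2],
                   O = bounds$O[1]:bounds$O[2],
                   N = bounds$N[1]:bounds$N[2],
                   S = bounds$S[1]:bounds$S[2],
                   P = bounds$P[1]:bounds$P[2])
  mass <- 12 * g$C + am[["H"]] * g$H + am[["O"]] * g$O +
    am[["N"]] * g$N + am[["S"]] * g$S + am[["P"]] * g$P
  keep <- abs(mass - neutral_mass) / neutral_mass * 1e6 < tol_ppm
  keep <- keep & (g$P == 0 | g$O >= 4)
  keep <- keep & (g$C - g$H / 2 + g$N / 2 + g$P / 2 + 1 >= 0)
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  cnt <- as.matrix(g[, c("C", "H", "N", "O", "P", "S")])
  sort(unname(fticrms::formula_string(cnt)))
}

# All-pairs edge finder for mass-difference networks.
all_pairs_edges <- function(mz, transformations, tol_da) {
  mz <- sort(unique(mz))
  rows <- list()
  for (i in seq_along(mz)) {
    for (j in seq_along(mz)) {
      if (mz[j] <= mz[i]) next
      for (t in seq_len(nrow(transformations))) {
        if (abs((mz[j] - mz[i]) - transformations$delta_mass[t]) <= tol_da) {
          rows[[length(rows) + 1L]] <- data.frame(
            low_mz = mz[i], high_mz = mz[j],
            transformation = transformations$name[t])
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(low_mz = numeric(0), high_mz = numeric(0),
                      transformation = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$low_mz, out$high_mz, out$transformation), , drop = FALSE]
}

# PCA oracle: eigendecomposition of the sample covariance matrix.
eigen_pca <- function(x, k) {
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  loadings <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  list(scores = xc %*% loadings, loadings = loadings,
       explained = ev$values / sum(ev$values))
}

# Small peak-list data frame builder for terse test bodies.
pk <- function(mz, intensity = 1000, sn = 20) {
  data.frame(mz = mz,
             intensity = rep_len(intensity, length(mz)),
             sn = rep_len(sn, length(mz)))
}
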