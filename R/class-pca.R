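#' Principal component analysis of class-abundance profiles
#'
#' Column-mean-centered PCA (singular value decomposition via
#' [stats::prcomp()]) of a samples-by-classes relative-abundance matrix.
#' Compositional fractions share a scale, so unit-variance scaling is off
#' by default. A deterministic sign convention is applied: within each
#' component, the largest-magnitude loading is made positive, so results
#' are unique and reproducible across platforms.
#'
#' @param x Numeric matrix or data.frame, samples (rows) x classes
#'   (columns).
#' @param n_components Number of components to keep; must not exceed
#'   `min(nrow - 1, ncol)`. Default 2.
#' @param scale. Divide columns by their standard deviation before
#'   decomposition (default `FALSE`).
#' @return A `class_pca` object: list with `scores` (samples x
#'   components), `loadings` (classes x components), `explained`
#'   (variance fractions, non-increasing), `center`, `n_components`.
#' @export
class_pca <- function(x, n_components = 2, scale. = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    stop("n_components must be <= min(n_samples - 1, n_classes)")
  }
  sds <- apply(x, 2L, stats::sd)
  if (all(sds < 1e-12)) stop("matrix is constant: zero variance to decompose")
  if (scale. && any(sds < 1e-12)) {
    stop("cannot scale: some classes have zero variance")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- n_components
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = scores,
    loadings = loadings,
    explained = p$sdev^2 / sum(p$sdev^2),
    center = p$center,
    n_components = k
  ), class = "class_pca")
}

#' @export
print.class_pca <- function(x, ...) {
  cat("PCA of class abundances:", nrow(x$scores), "samples,",
      nrow(x$loadings), "classes\n")
  ev <- x$explained[seq_len(x$n_components)]
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_along(ev), 100 * ev),
            collapse = ", "), "\n")
  invisible(x)
}

#' Ranked between-group centroid distances in score space
#'
#' Computes group centroids over the retained components and the
#' Euclidean distances between them, ranked from closest to farthest --
#' a quantitative reading of which groups cluster together on the PCA
#' plot.
#'
#' @param pca A `class_pca` object.
#' @param groups Group label per sample (length `nrow(scores)`).
#' @param n_components Components to use, default all retained.
#' @return `data.frame` with `group_a`, `group_b`, `distance`, `rank`,
#'   sorted by distance.
#' @export
group_distances <- function(pca, groups, n_components = pca$n_components) {
  stopifnot(inherits(pca, "class_pca"),
            length(groups) == nrow(pca$scores),
            n_components <= pca$n_components)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  sc <- pca$scores[, seq_len(n_components), drop = FALSE]
  cent <- do.call(rbind, lapply(split(seq_along(groups), groups),
                                function(ix) colMeans(sc[ix, , drop = FALSE])))
  g <- rownames(cent)
  pairs <- utils::combn(seq_along(g), 2)
  out <- data.frame(
    group_a = g[pairs[1, ]],
    group_b = g[pairs[2, ]],
    distance = apply(pairs, 2L, function(p) {
      sqrt(sum((cent[p[1], ] - cent[p[2], ])^2))
    }),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$distance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Scatter plot of the first two components
#'
#' @param x A `class_pca` object.
#' @param groups Optional group labels for coloring.
#' @param ... Unused.
#' @return A ggplot object when ggplot2 is available, else the score
#'   `data.frame` invisibly.
#' @export
plot.class_pca <- function(x, groups = NULL, ...) {
  df <- data.frame(PC1 = x$scores[, 1],
                   PC2 = if (ncol(x$scores) >= 2) x$scores[, 2] else 0)
  if (!is.null(groups)) df$group <- as.character(groups)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    aes <- if (is.null(groups)) {
      ggplot2::aes(x = .data$PC1, y = .data$PC2)
    } else {
      ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
    }
    return(ggplot2::ggplot(df, aes) + ggplot2::geom_point(size = 2) +
             ggplot2::labs(
               x = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
               y = sprintf("PC2 (%.1f%%)", 100 * x$explained[2])))
  }
  invisible(df)
}
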