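#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end analysis with their defaults:
#' peak filtering (S/N > 7, intensity >= 100), internal CH2 calibration,
#' 1 ppm cross-sample alignment, CHONSP formula assignment (< 1 ppm),
#' van Krevelen classification, the mass-difference network (1 mDa),
#' reference matching, and class-abundance PCA. Stages can be toggled;
#' unknown keys are rejected.
#'
#' @param ... Name-value overrides of the defaults.
#' @return Named list of resolved parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sn_min = 7, intensity_min = 100, mz_range = c(100, 1200),
    mode = "neg", align_tol_ppm = 1, assign_tol_ppm = 1,
    anchor_tol_ppm = 3, network_tol_da = 0.001, match_tol_ppm = 1,
    bounds = element_bounds(), classes = vk_classes(),
    transformations = default_transformations(),
    reference = NULL, n_components = 2,
    calibrate = TRUE, align = TRUE, assign = TRUE, classify = TRUE,
    network = TRUE, match = TRUE, pca = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order on a set of per-sample
#' peak lists: filter, per-sample internal calibration, cross-sample
#' alignment, per-sample formula assignment, class annotation and
#' abundance, transformation network on the consensus m/z set (with
#' first neighbors of reference seeds when a reference list is
#' configured), reference matching, and class-abundance PCA. Outputs are
#' written with stable file names when `out_dir` is given.
#'
#' @param peaklists Named list of peak `data.frame`s (or a single peak
#'   `data.frame`).
#' @param groups Optional group label per sample (for PCA distances).
#' @param config List from [pipeline_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return A run report: list with per-stage results (`filtered`,
#'   `calibration`, `aligned`, `assignments`, `abundance`, `network`,
#'   `neighbors`, `matches`, `pca`, `distances`) and a `counts` summary
#'   `data.frame`.
#' @export
run_pipeline <- function(peaklists, groups = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.data.frame(peaklists)) peaklists <- list(peaklists)
  ids <- .sample_ids(peaklists)
  names(peaklists) <- ids
  if (!is.null(groups)) stopifnot(length(groups) == length(peaklists))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()

  # filter
  filtered <- lapply(peaklists, filter_peaks, sn_min = config$sn_min,
                     intensity_min = config$intensity_min,
                     mz_range = config$mz_range)
  res$filtered <- filtered

  # per-sample internal calibration
  if (isTRUE(config$calibrate)) {
    cals <- lapply(filtered, function(p) {
      calibrate_peaklist(p, mode = config$mode,
                         tol_ppm = config$align_tol_ppm,
                         anchor_tol_ppm = config$anchor_tol_ppm,
                         bounds = config$bounds)
    })
    filtered <- lapply(cals, `[[`, "peaks")
    for (i in seq_along(filtered)) {
      attr(filtered[[i]], "sample_id") <- ids[i]
    }
    res$calibration <- do.call(rbind, lapply(cals, `[[`, "report"))
    res$calibration$sample <- ids
  }

  # alignment
  if (isTRUE(config$align)) {
    res$aligned <- align_samples(filtered, tol_ppm = config$align_tol_ppm)
    consensus_mz <- res$aligned$consensus_mz
  } else {
    consensus_mz <- sort(unique(unlist(lapply(filtered, `[[`, "mz"))))
  }

  # per-sample formula assignment
  if (isTRUE(config$assign)) {
    res$assignments <- lapply(filtered, assign_formulas,
                              mode = config$mode,
                              tol_ppm = config$assign_tol_ppm,
                              bounds = config$bounds)
    names(res$assignments) <- ids
  }

  # class abundances
  if (isTRUE(config$classify) && isTRUE(config$assign)) {
    res$abundance <- class_abundance_matrix(res$assignments,
                                            classes = config$classes)
  }

  # transformation network on the consensus m/z set
  if (isTRUE(config$network)) {
    net <- build_network(consensus_mz,
                         transformations = config$transformations,
                         tol_da = config$network_tol_da)
    if (isTRUE(config$assign)) {
      pooled <- do.call(rbind, lapply(res$assignments, function(a) {
        a[, c("mz", "formula")]
      }))
      net <- annotate_network(net, pooled, classes = config$classes,
                              tol = config$network_tol_da)
    }
    res$network <- net
    if (!is.null(config$reference)) {
      seeds <- match_reference(consensus_mz, config$reference,
                               mode = config$mode,
                               tol_ppm = config$match_tol_ppm)
      seed_mz <- seeds$observed_mz[seeds$matched & seeds$primary]
      if (length(seed_mz)) {
        res$neighbors <- first_neighbors(net, seed_mz)
      }
    }
  }

  # reference matching on the consensus list
  if (isTRUE(config$match) && !is.null(config$reference)) {
    res$matches <- match_reference(consensus_mz, config$reference,
                                   mode = config$mode,
                                   tol_ppm = config$match_tol_ppm)
  }

  # PCA of class abundances
  if (isTRUE(config$pca) && !is.null(res$abundance) &&
      nrow(res$abundance) >= 3L) {
    k <- min(config$n_components, nrow(res$abundance) - 1L,
             ncol(res$abundance))
    res$pca <- tryCatch(class_pca(res$abundance, n_components = k),
                        error = function(e) NULL)
    if (!is.null(res$pca) && !is.null(groups) &&
        length(unique(groups)) >= 2L) {
      res$distances <- group_distances(res$pca, groups)
    }
  }

  res$counts <- data.frame(
    sample = ids,
    peaks_in = vapply(peaklists, nrow, integer(1)),
    peaks_kept = vapply(filtered, nrow, integer(1)),
    assigned = if (!is.null(res$assignments)) {
      vapply(res$assignments, function(a) sum(a$status == "assigned"),
             integer(1))
    } else NA_integer_,
    unknown = if (!is.null(res$assignments)) {
      vapply(res$assignments, function(a) sum(a$status == "unknown"),
             integer(1))
    } else NA_integer_
  )
  rownames(res$counts) <- NULL

  if (!is.null(out_dir)) {
    utils::write.csv(res$counts, file.path(out_dir, "run_counts.csv"),
                     row.names = FALSE)
    if (!is.null(res$aligned)) {
      utils::write.csv(res$aligned, file.path(out_dir, "aligned_matrix.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$assignments)) {
      all_assign <- do.call(rbind, lapply(ids, function(s) {
        cbind(sample = s, res$assignments[[s]])
      }))
      utils::write.csv(all_assign, file.path(out_dir, "assignments.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$abundance)) {
      utils::write.csv(data.frame(sample = rownames(res$abundance),
                                  res$abundance, check.names = FALSE),
                       file.path(out_dir, "class_abundance.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$network)) {
      write_network(res$network, file.path(out_dir, "network"))
    }
    if (!is.null(res$matches)) {
      utils::write.csv(res$matches, file.path(out_dir, "reference_matches.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$pca)) {
      utils::write.csv(data.frame(sample = rownames(res$pca$scores),
                                  res$pca$scores),
                       file.path(out_dir, "pca_scores.csv"),
                       row.names = FALSE)
    }
  }
  res
}
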