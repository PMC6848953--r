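#' Read a per-sample peak list from delimited text
#'
#' Expects a header with columns `mz`, `intensity`, `sn` (any order; extra
#' columns ignored). Comma- or tab-delimited is auto-detected from the file
#' extension (`.tsv`/`.txt` read as tab, everything else as comma). Rows
#' with missing or non-numeric fields, non-positive m/z, or negative
#' intensity/S/N are dropped with a warning naming their line numbers.
#'
#' @param path Path to the delimited file.
#' @param sample_id Sample label; defaults to the file name without
#'   extension.
#' @return A `data.frame` with columns `mz`, `intensity`, `sn`, sorted by
#'   increasing m/z, with attributes `sample_id` and `n_rejected`.
#' @export
read_peaklist <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("peak list file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("mz", "intensity", "sn")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("peak list ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    mz = suppressWarnings(as.numeric(raw$mz)),
    intensity = suppressWarnings(as.numeric(raw$intensity)),
    sn = suppressWarnings(as.numeric(raw$sn))
  )
  bad <- !stats::complete.cases(df) | df$mz <= 0 | df$intensity < 0 | df$sn < 0
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) rejected in ", basename(path),
            " (lines ", paste(which(bad) + 1L, collapse = ", "), ")")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) warning("peak list ", basename(path), " has no valid peaks")
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Write a peak list to CSV
#'
#' @param peaks Peak `data.frame` with columns `mz`, `intensity`, `sn`.
#' @param path Output path.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.csv(peaks[, c("mz", "intensity", "sn")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter peaks by signal-to-noise and absolute intensity
#'
#' Retains peaks with `sn > sn_min` (strict, following the assignment
#' criterion S/N > 7) and `intensity >= intensity_min` (the picker's
#' absolute intensity threshold, default 100). Optionally restricts to the
#' acquired m/z range. Filtering preserves order and is idempotent.
#'
#' @param peaks Peak `data.frame` (`mz`, `intensity`, `sn`).
#' @param sn_min Signal-to-noise threshold, default 7 (strict `>`).
#' @param intensity_min Absolute intensity threshold, default 100 (`>=`).
#' @param mz_range Optional length-2 numeric; peaks outside are dropped.
#'   Default `c(100, 1200)`, the acquired window.
#' @return The filtered peak `data.frame` (attributes preserved).
#' @export
filter_peaks <- function(peaks, sn_min = 7, intensity_min = 100,
                         mz_range = c(100, 1200)) {
  stopifnot(sn_min >= 0, intensity_min >= 0)
  keep <- peaks$sn > sn_min & peaks$intensity >= intensity_min
  if (!is.null(mz_range)) {
    stopifnot(length(mz_range) == 2L)
    keep <- keep & peaks$mz >= mz_range[1] & peaks$mz <= mz_range[2]
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(peaks, "sample_id")
  out
}

.sample_ids <- function(peaklists) {
  ids <- names(peaklists)
  if (is.null(ids)) ids <- rep(NA_character_, length(peaklists))
  for (i in seq_along(peaklists)) {
    if (is.na(ids[i]) || !nzchar(ids[i])) {
      sid <- attr(peaklists[[i]], "sample_id")
      ids[i] <- if (is.null(sid)) paste0("sample_", i) else sid
    }
  }
  ids
}

#' Align peak lists across samples
#'
#' Single-linkage clustering of m/z values over the merged, sorted peak
#' set: a new cluster starts whenever the gap to the previous m/z exceeds
#' `tol_ppm` (evaluated at the current m/z). The consensus m/z of a cluster
#' is the intensity-weighted mean of its members. Each sample contributes
#' at most one peak per cluster; when a cluster contains two or more peaks
#' of one sample, the peak nearest the consensus wins and the conflict is
#' logged.
#'
#' @param peaklists List of peak `data.frame`s (named by sample, or
#'   carrying `sample_id` attributes).
#' @param tol_ppm Linkage tolerance in ppm (default 1, the instrument's
#'   stated mass accuracy).
#' @return A `data.frame` with column `consensus_mz` followed by one
#'   intensity column per sample (`NA` = absent), ordered by m/z.
#'   Attribute `conflicts` is a `data.frame` of dropped duplicate-sample
#'   peaks (`consensus_mz`, `sample`, `mz`).
#' @export
align_samples <- function(peaklists, tol_ppm = 1) {
  stopifnot(length(peaklists) >= 1L, tol_ppm > 0)
  ids <- .sample_ids(peaklists)
  merged <- do.call(rbind, lapply(seq_along(peaklists), function(i) {
    p <- peaklists[[i]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(mz = p$mz, intensity = p$intensity, sample = ids[i])
  }))
  if (is.null(merged) || nrow(merged) == 0L) {
    out <- data.frame(consensus_mz = numeric(0))
    for (s in ids) out[[s]] <- numeric(0)
    attr(out, "conflicts") <- data.frame(consensus_mz = numeric(0),
                                         sample = character(0),
                                         mz = numeric(0))
    return(out)
  }
  merged <- merged[order(merged$mz), , drop = FALSE]
  gap <- c(Inf, diff(merged$mz))
  new_cluster <- gap > tol_ppm * 1e-6 * merged$mz
  cl <- cumsum(new_cluster)
  consensus <- vapply(split(seq_len(nrow(merged)), cl), function(ix) {
    stats::weighted.mean(merged$mz[ix], merged$intensity[ix] + 1e-12)
  }, numeric(1))

  n_cl <- max(cl)
  out <- data.frame(consensus_mz = as.numeric(consensus))
  for (s in ids) out[[s]] <- NA_real_
  conflicts <- list()
  for (k in seq_len(n_cl)) {
    ix <- which(cl == k)
    for (s in unique(merged$sample[ix])) {
      jx <- ix[merged$sample[ix] == s]
      if (length(jx) > 1L) {
        best <- jx[which.min(abs(merged$mz[jx] - consensus[k]))]
        dropped <- setdiff(jx, best)
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          consensus_mz = consensus[k], sample = s, mz = merged$mz[dropped])
        jx <- best
      }
      out[[s]][k] <- merged$intensity[jx]
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(consensus_mz = numeric(0), sample = character(0),
               mz = numeric(0))
  if (nrow(conflicts)) {
    message(nrow(conflicts), " within-sample alignment conflict(s) resolved ",
            "by keeping the peak nearest the consensus m/z")
  }
  attr(out, "conflicts") <- conflicts
  out
}
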