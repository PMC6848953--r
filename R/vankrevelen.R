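#' Default van Krevelen compound-class bins
#'
#' The seven rectangular H:C versus O:C regions used to annotate assigned
#' formulas with biochemical compound classes, in priority order (first
#' match wins; the lipid and unsaturated-hydrocarbon regions overlap and
#' are resolved by listing order). Interval endpoints follow the published
#' inequalities: `oc_min_open`/`hc_max_open` flag which side of each
#' interval is open. An eighth carbohydrate bin
#' (`0.65 < O:C <= 1.1`, `1.5 <= H:C <= 2.5`) is shipped but off by
#' default, since the published method names carbohydrate-like compounds
#' without printing a range for them; pass `carbohydrate = TRUE` to give
#' high-O:C sugars like glucose (O:C 1, H:C 2) a class of their own.
#'
#' @param carbohydrate Include and enable the carbohydrate bin
#'   (default `FALSE`).
#' @return `data.frame` with columns `class`, `oc_min`, `oc_max`, `hc_min`,
#'   `hc_max`, `oc_min_open`, `oc_max_open`, `hc_min_open`, `hc_max_open`,
#'   `priority`, `enabled`.
#' @export
vk_classes <- function(carbohydrate = FALSE) {
  b <- data.frame(
    class = c("lipid", "unsaturated_hydrocarbon", "protein", "amino_sugar",
              "lignin", "tannin", "condensed_aromatic", "carbohydrate"),
    oc_min = c(0, 0, 0.3, 0.55, 0.125, 0.65, 0, 0.65),
    oc_max = c(0.3, 0.125, 0.55, 0.7, 0.65, 1.1, 0.95, 1.1),
    hc_min = c(1.5, 0.8, 1.5, 1.5, 0.8, 0.8, 0.2, 1.5),
    hc_max = c(2.5, 2.5, 2.3, 2.2, 1.5, 1.5, 0.8, 2.5),
    oc_min_open = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    oc_max_open = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hc_min_open = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hc_max_open = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    priority = 1:8,
    enabled = TRUE,
    stringsAsFactors = FALSE
  )
  if (!carbohydrate) b <- b[b$class != "carbohydrate", , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Read van Krevelen class bins from a config CSV
#'
#' The file must carry the columns of [vk_classes()]. Bins are validated
#' (non-empty intervals, unique priorities) and returned sorted by
#' priority.
#'
#' @param path CSV path.
#' @return Bin `data.frame` as for [vk_classes()].
#' @export
read_vk_classes <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "oc_min", "oc_max", "hc_min", "hc_max", "priority")
  if (length(setdiff(need, names(b)))) {
    stop("class-bin file must have columns: ", paste(need, collapse = ", "))
  }
  for (fl in c("oc_min_open", "oc_max_open", "hc_min_open", "hc_max_open")) {
    if (is.null(b[[fl]])) b[[fl]] <- FALSE else b[[fl]] <- as.logical(b[[fl]])
  }
  if (is.null(b$enabled)) b$enabled <- TRUE
  if (any(b$oc_min > b$oc_max) || any(b$hc_min > b$hc_max)) {
    stop("class-bin file contains an empty interval")
  }
  if (anyDuplicated(b$priority)) stop("bin priorities must be unique")
  b <- b[order(b$priority), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Van Krevelen coordinates of a formula
#'
#' Molar O:C and H:C ratios; defined only for carbon-containing formulas.
#'
#' @inheritParams monoisotopic_mass
#' @return `data.frame` with columns `oc` and `hc` (NA where C = 0).
#' @examples
#' vk_coordinates("C18H34O2")  # oc 0.111, hc 1.889
#' @export
vk_coordinates <- function(formula) {
  m <- .as_counts(formula)
  oc <- ifelse(m[, "C"] > 0, m[, "O"] / m[, "C"], NA_real_)
  hc <- ifelse(m[, "C"] > 0, m[, "H"] / m[, "C"], NA_real_)
  data.frame(oc = oc, hc = hc)
}

.in_interval <- function(x, lo, hi, lo_open, hi_open) {
  above <- if (lo_open) x > lo else x >= lo
  below <- if (hi_open) x < hi else x <= hi
  above & below
}

#' Classify formulas into van Krevelen compound classes
#'
#' Assigns each formula to the first enabled bin (by priority) whose O:C
#' and H:C intervals contain its coordinates; `"unclassified"` when no bin
#' matches or the formula contains no carbon.
#'
#' @inheritParams monoisotopic_mass
#' @param classes Bin table from [vk_classes()] or [read_vk_classes()].
#' @return Character vector of class labels.
#' @examples
#' vk_classify("C18H34O2")        # "lipid"
#' vk_classify("C15H10O6")        # "condensed_aromatic"
#' @export
vk_classify <- function(formula, classes = vk_classes()) {
  xy <- vk_coordinates(formula)
  if (!is.null(classes$enabled)) {
    classes <- classes[classes$enabled, , drop = FALSE]
  }
  classes <- classes[order(classes$priority), , drop = FALSE]
  out <- rep("unclassified", nrow(xy))
  for (k in seq_len(nrow(classes))) {
    hit <- !is.na(xy$oc) & out == "unclassified" &
      .in_interval(xy$oc, classes$oc_min[k], classes$oc_max[k],
                   classes$oc_min_open[k], classes$oc_max_open[k]) &
      .in_interval(xy$hc, classes$hc_min[k], classes$hc_max[k],
                   classes$hc_min_open[k], classes$hc_max_open[k])
    out[hit] <- classes$class[k]
  }
  out
}

#' Count-based compound-class relative abundances
#'
#' Fraction of assigned formulas in each van Krevelen class (counts, not
#' intensities). Unassigned peaks are excluded; formulas matching no bin
#' count toward `"unclassified"`, so the returned fractions sum to 1.
#'
#' @param assignments Assignment `data.frame` from [assign_formulas()]
#'   (or any data.frame with a `formula` column; NA formulas are dropped),
#'   or a character vector of formulas.
#' @param classes Bin table, default [vk_classes()].
#' @return Named numeric vector of fractions over
#'   `c(<enabled classes>, "unclassified")`, summing to 1.
#' @export
class_abundance <- function(assignments, classes = vk_classes()) {
  formulas <- if (is.data.frame(assignments)) assignments$formula else
    as.character(assignments)
  formulas <- formulas[!is.na(formulas)]
  if (length(formulas) == 0L) {
    stop("no assigned formulas: class abundances are undefined")
  }
  enabled <- if (is.null(classes$enabled)) classes else
    classes[classes$enabled, , drop = FALSE]
  lv <- c(enabled$class[order(enabled$priority)], "unclassified")
  cls <- factor(vk_classify(formulas, classes), levels = lv)
  tab <- table(cls)
  fr <- as.numeric(tab) / length(formulas)
  names(fr) <- names(tab)
  fr
}

#' Per-sample class-abundance matrix
#'
#' @param assignment_list Named list of per-sample assignment data.frames.
#' @param classes Bin table, default [vk_classes()].
#' @return Numeric matrix, samples x classes (incl. `unclassified`); each
#'   row sums to 1.
#' @export
class_abundance_matrix <- function(assignment_list, classes = vk_classes()) {
  stopifnot(is.list(assignment_list), length(assignment_list) >= 1L)
  ids <- .sample_ids(assignment_list)
  rows <- lapply(assignment_list, class_abundance, classes = classes)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Scatter data (and optional plot) for a van Krevelen diagram
#'
#' Returns the per-formula coordinates and classes; if ggplot2 is
#' installed and `plot = TRUE`, also draws the diagram.
#'
#' @param assignments Assignment `data.frame` with a `formula` column.
#' @param classes Bin table.
#' @param plot Draw with ggplot2 when available (default `FALSE`).
#' @return `data.frame` with `formula`, `oc`, `hc`, `class` (invisibly
#'   when plotted).
#' @export
vk_diagram <- function(assignments, classes = vk_classes(), plot = FALSE) {
  formulas <- assignments$formula[!is.na(assignments$formula)]
  xy <- vk_coordinates(formulas)
  df <- data.frame(formula = formulas, oc = xy$oc, hc = xy$hc,
                   class = vk_classify(formulas, classes),
                   stringsAsFactors = FALSE)
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$oc, y = .data$hc,
                                          colour = .data$class)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "O:C", y = "H:C")
    print(p)
    return(invisible(df))
  }
  df
}
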