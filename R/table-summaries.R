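#' Round to three significant figures for display
#'
#' Concentration totals are reported to 3 significant figures, matching
#' the precision convention of NMR quantitation; the full-precision value
#' is never altered, only its display form.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded to 3 significant figures.
#' @examples
#' signif3(1009.3)  # 1010
#' @export
signif3 <- function(x) signif(x, 3)

#' Read a metabolite-concentration table
#'
#' Delimited text with columns `name`, `concentration` (micromolar per
#' 50 mg sample), `class`; optional `formula` and `kegg_id` are carried
#' through. Non-numeric or negative concentrations reject the row.
#'
#' @param path CSV/TSV path.
#' @return `data.frame` of validated rows.
#' @export
read_concentration_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "\"")
  need <- c("name", "concentration", "class")
  if (length(setdiff(need, names(raw)))) {
    stop("concentration table needs columns: ", paste(need, collapse = ", "))
  }
  raw$concentration <- suppressWarnings(as.numeric(raw$concentration))
  bad <- is.na(raw$concentration) | raw$concentration < 0
  if (any(bad)) {
    warning(sum(bad), " concentration row(s) rejected")
    raw <- raw[!bad, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' Packaged primary-metabolite concentration fixture
#'
#' Twenty-nine primary metabolites of a *Sphagnum fallax* extract
#' quantified by 1H NMR (micromolar per 50 mg plant in 1 ml water),
#' grouped into eight compound classes, transcribed into a packaged
#' fixture.
#'
#' @return `data.frame` with `name`, `kegg_id`, `formula`,
#'   `concentration`, `class`.
#' @export
sphagnum_metabolites <- function() {
  read_concentration_table(
    system.file("extdata", "sphagnum_metabolites.csv",
                package = "fticrms", mustWork = TRUE))
}

#' Per-class concentration totals
#'
#' Sums concentrations within each class, ranks classes by total, and
#' reports the 3-significant-figure display value alongside the exact
#' sum.
#'
#' @param table Concentration `data.frame`
#'   (from [read_concentration_table()]).
#' @return `data.frame` with `class`, `total`, `total_3sf`, `rank`
#'   (1 = most abundant), plus attribute `grand_total`.
#' @examples
#' totals <- class_totals(sphagnum_metabolites())
#' totals[totals$class == "Acids", ]  # exact 1009.3, display 1010
#' @export
class_totals <- function(table) {
  if (nrow(table) == 0L) {
    out <- data.frame(class = character(0), total = numeric(0),
                      total_3sf = numeric(0), rank = integer(0))
    attr(out, "grand_total") <- 0
    return(out)
  }
  sums <- tapply(table$concentration, table$class, sum)
  out <- data.frame(class = names(sums), total = as.numeric(sums),
                    stringsAsFactors = FALSE)
  out$total_3sf <- signif3(out$total)
  out <- out[order(-out$total), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "grand_total") <- sum(table$concentration)
  out
}

#' Read a category/subclass count table
#'
#' Delimited text with columns `category`, `subclass`, `count`. An
#' embedded total row (subclass equal to `"Total identifications"` or
#' `"Total"`, case-insensitive) is split off into the `embedded_total`
#' attribute.
#'
#' @param path CSV/TSV path.
#' @return `data.frame` of subclass rows with integer counts; attribute
#'   `embedded_total` (or `NA` when absent).
#' @export
read_count_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "\"")
  need <- c("category", "subclass", "count")
  if (length(setdiff(need, names(raw)))) {
    stop("count table needs columns: ", paste(need, collapse = ", "))
  }
  raw$count <- suppressWarnings(as.integer(raw$count))
  if (any(is.na(raw$count)) || any(raw$count < 0)) {
    stop("counts must be non-negative integers")
  }
  is_total <- grepl("^total", trimws(raw$subclass), ignore.case = TRUE)
  embedded <- if (any(is_total)) raw$count[which(is_total)[1]] else NA_integer_
  out <- raw[!is_total, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "embedded_total") <- embedded
  out
}

#' Packaged lipid subclass count fixture
#'
#' Lipid profile of *Sphagnum fallax* by category and subclass (LC-MS/MS,
#' positive and negative modes, triplicate samples): 19 subclasses whose
#' identifications sum to the embedded total of 152, transcribed into a
#' packaged fixture.
#'
#' @return Count `data.frame` as from [read_count_table()].
#' @export
sphagnum_lipid_counts <- function() {
  read_count_table(
    system.file("extdata", "sphagnum_lipid_counts.csv",
                package = "fticrms", mustWork = TRUE))
}

#' Total identifications across subclasses
#'
#' Sums subclass counts using integer arithmetic. When the table carries
#' an embedded total row, a mismatch is flagged with a warning and in the
#' `consistent` attribute.
#'
#' @param table Count `data.frame` (from [read_count_table()]).
#' @return Integer total with attributes `embedded_total` and
#'   `consistent`.
#' @examples
#' subclass_total(sphagnum_lipid_counts())  # 152
#' @export
subclass_total <- function(table) {
  total <- sum(as.integer(table$count))
  embedded <- attr(table, "embedded_total")
  consistent <- NA
  if (!is.null(embedded) && !is.na(embedded)) {
    consistent <- embedded == total
    if (!consistent) {
      warning("subclass counts sum to ", total,
              " but the embedded total row says ", embedded)
    }
  }
  structure(total, embedded_total = embedded, consistent = consistent)
}

#' Total detections across analytical platforms
#'
#' @param counts Named non-negative integer vector (platform -> count).
#' @return Integer sum across platforms (0 for an empty vector).
#' @examples
#' platform_total(c(nmr = 29, lc_pos = 234, lc_neg = 240, lipids = 152))
#' @export
platform_total <- function(counts) {
  if (length(counts) == 0L) return(0L)
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("platform counts must be non-negative integers")
  }
  sum(counts)
}
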