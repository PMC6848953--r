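#' Default chemical-transformation dictionary
#'
#' Common biochemical mass-difference transformations (homologation,
#' (de)hydration, (de)carboxylation, redox, amination, sulfation,
#' phosphorylation, glycosylation, amino-acid residue gains, ...). Every
#' entry is defined by a molecular formula and its exact mass difference
#' is recomputed from the atomic-mass table, never hard-coded, so the
#' dictionary stays consistent with the package's mass arithmetic.
#'
#' @return `data.frame` with columns `name`, `formula`, `delta_mass` (Da).
#' @examples
#' tr <- default_transformations()
#' tr[tr$name == "CO2", ]
#' @export
default_transformations <- function() {
  formulas <- c(
    "H2", "CH2", "O", "NH3", "H2O", "C2H2", "CO", "CH2O", "CH4O",
    "S", "H2S", "C2H4", "C3H6", "C4H8", "C2H2O", "CO2", "C2H4O",
    "CH2O2", "C2H2O2", "C2H4O2", "C3H4O2", "C3H6O2", "C3H4O3",
    "C2H3NO", "C3H5NO", "C3H5NO2", "C3H5NOS", "C4H5NO3", "C5H7NO3",
    "C5H9NO", "C6H11NO", "C9H9NO",
    "C5H8", "C10H16",
    "HPO3", "H3PO4", "SO3", "H2SO4",
    "C5H8O4", "C6H10O4", "C6H10O5", "C6H8O6"
  )
  names_ <- formulas
  data.frame(
    name = names_,
    formula = formulas,
    delta_mass = monoisotopic_mass(formulas),
    stringsAsFactors = FALSE
  )
}

#' Read a transformation dictionary from delimited text
#'
#' Expects columns `name` and `formula` and/or `delta_mass`. When a
#' formula is given its exact mass is recomputed; a supplied `delta_mass`
#' inconsistent with its formula by more than 1e-4 Da rejects the row.
#' Rows with neither a parseable formula nor a positive mass are rejected.
#'
#' @param path CSV/TSV path (delimiter auto-detected by extension).
#' @return `data.frame` with `name`, `formula`, `delta_mass`.
#' @export
read_transformations <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(raw$name)) stop("transformation file needs a 'name' column")
  if (is.null(raw$formula)) raw$formula <- rep(NA_character_, nrow(raw))
  if (is.null(raw$delta_mass)) raw$delta_mass <- rep(NA_real_, nrow(raw))
  raw$delta_mass <- suppressWarnings(as.numeric(raw$delta_mass))
  keep <- rep(TRUE, nrow(raw))
  delta <- raw$delta_mass
  for (i in seq_len(nrow(raw))) {
    f <- raw$formula[i]
    has_f <- !is.na(f) && nzchar(f)
    m <- if (has_f) tryCatch(monoisotopic_mass(f), error = function(e) NA_real_)
         else NA_real_
    if (has_f && is.na(m)) { keep[i] <- FALSE; next }
    if (!is.na(m)) {
      if (!is.na(delta[i]) && abs(delta[i] - m) > 1e-4) {
        keep[i] <- FALSE  # inconsistent mass/formula pair
        next
      }
      delta[i] <- m
    }
    if (is.na(delta[i]) || delta[i] <= 0) keep[i] <- FALSE
  }
  if (any(!keep)) {
    warning(sum(!keep), " transformation row(s) rejected ",
            "(unparseable formula, inconsistent mass, or non-positive mass)")
  }
  out <- data.frame(name = raw$name[keep], formula = raw$formula[keep],
                    delta_mass = delta[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a mass-difference transformation network
#'
#' Nodes are the (deduplicated) m/z values; for every ordered pair
#' `a < b` and every transformation `t` with `|b - a - delta_t| <=
#' tol_da`, an undirected edge `(a, b, t)` is added, stored low-to-high
#' for reproducible serialization. A node may join many edges, and two
#' nodes may be linked by several differently named transformations.
#'
#' @param mz Numeric vector of m/z values (duplicates collapsed).
#' @param transformations Dictionary `data.frame` (`name`, `delta_mass`),
#'   default [default_transformations()].
#' @param tol_da Absolute matching tolerance in Da, default 0.001 (mass
#'   differences call for an absolute window; 1 mDa is the conventional
#'   molecular-network threshold).
#' @return A `transformation_network` object: list with `nodes`
#'   (`data.frame`: `mz`), `edges` (`data.frame`: `low_mz`, `high_mz`,
#'   `transformation`, `delta_mass`, `residual_da`), and `tol_da`.
#' @export
build_network <- function(mz, transformations = default_transformations(),
                          tol_da = 0.001) {
  stopifnot(is.numeric(mz), tol_da > 0)
  mz <- sort(unique(mz))
  edges <- list()
  if (length(mz) >= 2L && nrow(transformations) > 0L) {
    for (t in seq_len(nrow(transformations))) {
      delta <- transformations$delta_mass[t]
      targets <- mz + delta
      j0 <- findInterval(targets - tol_da, mz) + 1L
      j1 <- findInterval(targets + tol_da, mz)
      for (i in which(j1 >= j0)) {
        js <- j0[i]:j1[i]
        js <- js[js != i]
        if (length(js)) {
          edges[[length(edges) + 1L]] <- data.frame(
            low_mz = mz[i], high_mz = mz[js],
            transformation = transformations$name[t],
            delta_mass = delta,
            residual_da = (mz[js] - mz[i]) - delta,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(low_mz = numeric(0), high_mz = numeric(0),
               transformation = character(0), delta_mass = numeric(0),
               residual_da = numeric(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$low_mz, edges$high_mz, edges$transformation), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(mz = mz), edges = edges,
                 tol_da = tol_da),
            class = "transformation_network")
}

#' @export
print.transformation_network <- function(x, ...) {
  cat("Transformation network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges (tol", x$tol_da, "Da)\n")
  if (!is.null(x$seeds)) {
    cat("  seeds:", length(x$seeds), "  first neighbors:",
        x$n_neighbors, "\n")
  }
  invisible(x)
}

.match_nodes <- function(node_mz, query, tol = 1e-6) {
  idx <- rep(NA_integer_, length(query))
  for (i in seq_along(query)) {
    d <- abs(node_mz - query[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tol) idx[i] <- j
  }
  idx
}

#' Extract the first-neighbor subnetwork of seed nodes
#'
#' Induces the subnetwork on the seeds plus every node adjacent to any
#' seed (one chemical transformation away). Seeds absent from the network
#' are logged and skipped. Neighbors shared by several seeds are counted
#' once (unique-node semantics).
#'
#' @param network A `transformation_network`.
#' @param seeds Numeric m/z values of seed nodes.
#' @param seed_tol Absolute tolerance (Da) for matching seeds to nodes,
#'   default 1e-6.
#' @return A `transformation_network` restricted to seeds and neighbors,
#'   with extra fields `seeds` (matched seed m/z), `n_neighbors`
#'   (neighbor count excluding seeds), and `unmatched_seeds`.
#' @export
first_neighbors <- function(network, seeds, seed_tol = 1e-6) {
  stopifnot(inherits(network, "transformation_network"))
  node_mz <- network$nodes$mz
  idx <- .match_nodes(node_mz, seeds, seed_tol)
  unmatched <- seeds[is.na(idx)]
  if (length(unmatched)) {
    message(length(unmatched), " seed(s) not present as network nodes; skipped")
  }
  seed_mz <- node_mz[idx[!is.na(idx)]]
  e <- network$edges
  touch_low <- e$low_mz %in% seed_mz
  touch_high <- e$high_mz %in% seed_mz
  nb <- unique(c(e$high_mz[touch_low], e$low_mz[touch_high]))
  nb <- setdiff(nb, seed_mz)
  keep_nodes <- sort(unique(c(seed_mz, nb)))
  sub_e <- e[(e$low_mz %in% keep_nodes) & (e$high_mz %in% keep_nodes), ,
             drop = FALSE]
  rownames(sub_e) <- NULL
  out <- structure(list(
    nodes = data.frame(mz = keep_nodes),
    edges = sub_e,
    tol_da = network$tol_da,
    seeds = seed_mz,
    n_neighbors = length(nb),
    unmatched_seeds = unmatched
  ), class = "transformation_network")
  if (!is.null(network$nodes$formula)) {
    out$nodes <- merge(out$nodes, network$nodes, by = "mz", all.x = TRUE,
                       sort = TRUE)
  }
  out$nodes$is_seed <- out$nodes$mz %in% seed_mz
  out
}

#' Annotate network nodes with formulas and compound classes
#'
#' Joins a formula-assignment table onto the node set (nearest match
#' within `tol`); nodes with no assignment carry class `"unknown"`.
#'
#' @param network A `transformation_network`.
#' @param assignments Assignment `data.frame` from [assign_formulas()].
#' @param classes Van Krevelen bin table, default [vk_classes()].
#' @param tol Absolute m/z match tolerance (Da), default 1e-6.
#' @return The network with node columns `formula` and `class` added.
#' @export
annotate_network <- function(network, assignments, classes = vk_classes(),
                             tol = 1e-6) {
  stopifnot(inherits(network, "transformation_network"))
  idx <- .match_nodes(assignments$mz, network$nodes$mz, tol)
  formula <- rep(NA_character_, nrow(network$nodes))
  ok <- !is.na(idx)
  formula[ok] <- assignments$formula[idx[ok]]
  cls <- rep("unknown", nrow(network$nodes))
  has_f <- !is.na(formula)
  if (any(has_f)) cls[has_f] <- vk_classify(formula[has_f], classes)
  network$nodes$formula <- formula
  network$nodes$class <- cls
  network
}

#' Tally node classes of a network (or neighbor set)
#'
#' @param network An annotated `transformation_network`.
#' @param neighbors_only Restrict to non-seed nodes when seed information
#'   is present (default `FALSE`).
#' @return Named integer vector of class counts (including `"unknown"`).
#' @export
class_tally <- function(network, neighbors_only = FALSE) {
  stopifnot(inherits(network, "transformation_network"))
  if (is.null(network$nodes$class)) {
    stop("network is not annotated; run annotate_network() first")
  }
  nodes <- network$nodes
  if (neighbors_only && !is.null(nodes$is_seed)) {
    nodes <- nodes[!nodes$is_seed, , drop = FALSE]
  }
  tab <- table(nodes$class)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Convert a transformation network to an igraph graph
#'
#' @param network A `transformation_network`.
#' @return An undirected `igraph` graph; vertex names are m/z printed to
#'   6 decimals, edge attribute `transformation` names the mass
#'   difference.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "transformation_network"))
  vname <- sprintf("%.6f", network$nodes$mz)
  vdf <- data.frame(name = vname, mz = network$nodes$mz,
                    stringsAsFactors = FALSE)
  for (col in c("formula", "class", "is_seed")) {
    if (!is.null(network$nodes[[col]])) {
      v <- network$nodes[[col]]
      if (is.character(v)) v[is.na(v)] <- ""
      vdf[[col]] <- v
    }
  }
  e <- network$edges
  edf <- data.frame(from = sprintf("%.6f", e$low_mz),
                    to = sprintf("%.6f", e$high_mz),
                    transformation = e$transformation,
                    residual_da = e$residual_da,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Write a network as GraphML plus edge/node CSV tables
#'
#' @param network A `transformation_network`.
#' @param basename Output path prefix; writes `<basename>.graphml`,
#'   `<basename>_edges.csv`, `<basename>_nodes.csv`.
#' @return Invisibly, the three paths written.
#' @export
write_network <- function(network, basename) {
  g <- as_igraph(network)
  paths <- paste0(basename, c(".graphml", "_edges.csv", "_nodes.csv"))
  igraph::write_graph(g, paths[1], format = "graphml")
  utils::write.csv(network$edges, paths[2], row.names = FALSE)
  utils::write.csv(network$nodes, paths[3], row.names = FALSE)
  invisible(paths)
}
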