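#' Construct a multiset cytometry dataset
#'
#' The canonical container for multi-sample list-mode data: one stacked
#' cells x markers matrix together with the nesting structure (which cell
#' belongs to which individual, which individual to which clinical group).
#' All downstream stages operate on this structure so that statistics can
#' weight individuals, not cells, equally.
#'
#' @param values Numeric matrix, total cells x J markers.
#' @param cell_to_individual Integer vector (length `nrow(values)`) giving
#'   each cell's individual index (1-based, referring to `individual_ids`).
#' @param individual_ids Character vector of unique sample identifiers.
#' @param group_labels Factor (or vector coercible to factor) of length
#'   `length(individual_ids)` assigning each individual to a group. The
#'   first factor level is treated as the control group downstream.
#' @param marker_names Optional marker names; defaults to column names of
#'   `values`.
#' @return An object of class `mfc_dataset`.
#' @export
mfc_dataset <- function(values, cell_to_individual, individual_ids,
                        group_labels, marker_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cell_to_individual <- as.integer(cell_to_individual)
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) stop("individual_ids must be unique")
  n_ind <- length(individual_ids)
  if (length(group_labels) != n_ind) {
    stop("group_labels must have one label per individual")
  }
  group_labels <- as.factor(group_labels)
  if (length(cell_to_individual) != nrow(values)) {
    stop("cell_to_individual must have one entry per cell")
  }
  if (any(cell_to_individual < 1L | cell_to_individual > n_ind)) {
    stop("cell_to_individual refers to a non-existent individual")
  }
  counts <- tabulate(cell_to_individual, nbins = n_ind)
  if (any(counts == 0L)) {
    stop("every individual must have at least one cell; empty: ",
         paste(individual_ids[counts == 0L], collapse = ", "))
  }
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(values)))
  colnames(values) <- marker_names
  structure(
    list(values = values,
         cell_to_individual = cell_to_individual,
         individual_ids = individual_ids,
         group_labels = group_labels),
    class = "mfc_dataset")
}

#' @export
print.mfc_dataset <- function(x, ...) {
  cat("Multiset cytometry dataset\n")
  cat("  cells:       ", nrow(x$values), "\n")
  cat("  markers:     ", ncol(x$values), " (",
      paste(colnames(x$values), collapse = ", "), ")\n", sep = "")
  cat("  individuals: ", length(x$individual_ids), "\n")
  cat("  groups:      ", paste(sprintf("%s (n=%d)", levels(x$group_labels),
                                       tabulate(x$group_labels)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Per-individual cell counts
#' @param dataset An `mfc_dataset`.
#' @return Named integer vector of cell counts, one per individual.
#' @export
cell_counts <- function(dataset) {
  stats::setNames(
    tabulate(dataset$cell_to_individual, nbins = length(dataset$individual_ids)),
    dataset$individual_ids)
}

#' Subset a dataset to selected individuals
#'
#' Keeps every cell of the selected individuals, in the requested order.
#' Used by the cross-validation folds, which always partition individuals,
#' never cells.
#'
#' @param dataset An `mfc_dataset`.
#' @param idx Integer indices or identifiers of the individuals to keep.
#' @param drop_levels Drop unused group levels (default `FALSE`, so that the
#'   control/challenged coding survives subsetting).
#' @return An `mfc_dataset`.
#' @export
subset_individuals <- function(dataset, idx, drop_levels = FALSE) {
  if (is.character(idx)) idx <- match(idx, dataset$individual_ids)
  if (anyNA(idx)) stop("unknown individual id in subset")
  blocks <- split(seq_along(dataset$cell_to_individual), dataset$cell_to_individual)
  rows <- unlist(blocks[as.character(idx)], use.names = FALSE)
  new_map <- rep(seq_along(idx), times = lengths(blocks[as.character(idx)]))
  g <- dataset$group_labels[idx]
  if (drop_levels) g <- droplevels(g)
  mfc_dataset(dataset$values[rows, , drop = FALSE], new_map,
              dataset$individual_ids[idx], g)
}

#' Read a per-sample CSV cell matrix
#'
#' CSV fallback format: one file per individual, a header row of marker
#' names, one row per cell.
#'
#' @inheritParams read_fcs
#' @return Numeric matrix, cells x markers.
#' @export
read_sample_csv <- function(path, markers = NULL) {
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  storage.mode(x) <- "double"
  if (!is.null(markers)) x <- select_markers(x, markers, context = path)
  x
}

#' Read a sample manifest
#'
#' A manifest is a CSV with columns `file`, `individual`, `group`; one row
#' per sample file.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with columns `file`, `individual`, `group`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("file", "individual", "group")
  if (!all(required %in% names(m))) {
    stop("manifest must have columns: ", paste(required, collapse = ", "))
  }
  m
}

#' Assemble a multiset dataset from a sample manifest
#'
#' Reads each sample file (FCS by `.fcs` extension, CSV otherwise) and
#' stacks the cell matrices in manifest order. Identity is defined by the
#' `individual` column, not by file paths: the same file listed twice under
#' different ids yields two individuals.
#'
#' @param manifest Data frame with columns `file`, `individual`, `group`
#'   (as returned by [read_manifest()]), or a path to such a CSV.
#' @param markers Optional marker subset applied to every file; when `NULL`
#'   all files must share an identical panel.
#' @param base_dir Directory that relative file paths are resolved against.
#' @return An [mfc_dataset()].
#' @export
assemble_dataset <- function(manifest, markers = NULL, base_dir = NULL) {
  if (is.character(manifest)) {
    # relative sample paths resolve against the manifest's own directory
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (anyDuplicated(manifest$individual)) {
    stop("duplicate individual id in manifest: ",
         paste(unique(manifest$individual[duplicated(manifest$individual)]),
               collapse = ", "))
  }
  paths <- manifest$file
  if (!is.null(base_dir)) paths <- file.path(base_dir, paths)
  mats <- lapply(paths, function(p) {
    if (grepl("\\.fcs$", p, ignore.case = TRUE)) read_fcs(p, markers)
    else read_sample_csv(p, markers)
  })
  panel <- colnames(mats[[1L]])
  for (i in seq_along(mats)) {
    if (!identical(colnames(mats[[i]]), panel)) {
      stop("marker panel mismatch in ", paths[i],
           ": expected (", paste(panel, collapse = ", "),
           "), found (", paste(colnames(mats[[i]]), collapse = ", "), ")")
    }
  }
  counts <- vapply(mats, nrow, integer(1L))
  # group level order follows first appearance in the manifest, so the
  # first-listed group is the control (negative-score) side downstream
  mfc_dataset(do.call(rbind, mats),
              rep(seq_along(mats), times = counts),
              manifest$individual,
              factor(manifest$group, levels = unique(manifest$group)),
              marker_names = panel)
}
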