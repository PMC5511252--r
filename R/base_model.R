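#' Fit the cell-level principal component base model
#'
#' PCA of the preprocessed cell matrix describing marker co-expression
#' variability across all cells. To prevent individuals with many acquired
#' cells from dominating the loadings, each individual's block of rows is
#' divided by its own cell count before the decomposition; the loadings are
#' the top right singular vectors of that cell-count-normalized matrix.
#' Scores of the *unnormalized* data on these loadings are obtained with
#' [project_cells()].
#'
#' The sign of each component is fixed so that its largest-magnitude loading
#' element is positive, making runs reproducible.
#'
#' @param dataset Preprocessed [mfc_dataset()] (`X_cs`).
#' @param k Number of components to retain (`K_base`), at most the number
#'   of markers. Default 2.
#' @return An object of class `base_model` with elements `loadings`
#'   (J x k, orthonormal columns), `singular_values` (all `J` of them),
#'   `explained_variance` (per-PC fraction of the normalized fit, length J),
#'   `k`, and `marker_names`.
#' @export
fit_base_model <- function(dataset, k = 2L) {
  J <- ncol(dataset$values)
  if (k < 1L || k > J) {
    stop("k must be between 1 and the number of markers (", J, ")")
  }
  if (length(dataset$individual_ids) < 2L) {
    stop("base model requires at least 2 individuals")
  }
  counts <- tabulate(dataset$cell_to_individual,
                     nbins = length(dataset$individual_ids))
  x_n <- dataset$values / counts[dataset$cell_to_individual]
  sv <- svd(x_n, nu = 0L, nv = J)
  P <- sv$v
  # deterministic sign: largest-|loading| element of each PC made positive
  for (j in seq_len(J)) {
    i_max <- which.max(abs(P[, j]))
    if (P[i_max, j] < 0) P[, j] <- -P[, j]
  }
  rownames(P) <- colnames(dataset$values)
  colnames(P) <- paste0("PC", seq_len(J))
  structure(
    list(loadings = P[, seq_len(k), drop = FALSE],
         singular_values = sv$d,
         explained_variance = sv$d^2 / sum(sv$d^2),
         k = as.integer(k),
         marker_names = colnames(dataset$values)),
    class = "base_model")
}

#' @export
print.base_model <- function(x, ...) {
  cat("Base model:", x$k, "component(s) over", length(x$marker_names), "markers\n")
  ev <- x$explained_variance[seq_len(x$k)]
  cat("  explained variance (normalized fit):",
      paste(sprintf("PC%d %.1f%%", seq_along(ev), 100 * ev), collapse = ", "), "\n")
  invisible(x)
}

#' Project cells onto the base model
#'
#' Linear projection `T = X P`; applies identically to training and
#' held-out data.
#'
#' @param dataset Preprocessed [mfc_dataset()] or a bare numeric matrix on
#'   the preprocessed scale.
#' @param model A [fit_base_model()] fit.
#' @return Score matrix, cells x `k`.
#' @export
project_cells <- function(dataset, model) {
  x <- if (inherits(dataset, "mfc_dataset")) dataset$values else as.matrix(dataset)
  if (ncol(x) != length(model$marker_names)) {
    stop("marker panel mismatch: model expects ",
         length(model$marker_names), " markers")
  }
  x %*% model$loadings
}

#' Per-individual explained variance of the base model
#'
#' For individual i and component k: the variance of that individual's
#' scores on component k divided by the total variance of the individual's
#' preprocessed rows (the trace of its own centred covariance). With the
#' full set of J components the fractions of an individual sum to one.
#' Individuals with a single cell have no variance; their row is zero and is
#' flagged in `attr(, "degenerate")`.
#'
#' @param dataset Preprocessed [mfc_dataset()].
#' @param model A [fit_base_model()] fit.
#' @return Matrix (individuals x k) of explained-variance fractions.
#' @export
explained_variance_by_individual <- function(dataset, model) {
  scores <- project_cells(dataset, model)
  n_ind <- length(dataset$individual_ids)
  map <- dataset$cell_to_individual
  counts <- tabulate(map, nbins = n_ind)
  out <- matrix(0, n_ind, model$k,
                dimnames = list(dataset$individual_ids,
                                colnames(model$loadings)[seq_len(model$k)]))
  sample_var_by <- function(v) {
    # per-individual sample variance (n-1) of each column
    m1 <- rowsum(v, map, reorder = TRUE) / counts
    ss <- rowsum(v^2, map, reorder = TRUE) - counts * m1^2
    ss / pmax(counts - 1L, 1L)
  }
  num <- sample_var_by(scores)
  den <- rowSums(sample_var_by(dataset$values))
  ok <- counts > 1L & den > 0
  out[ok, ] <- num[ok, , drop = FALSE] / den[ok]
  attr(out, "degenerate") <- dataset$individual_ids[!ok]
  out
}

#' Biplot data for one individual
#'
#' Returns an individual's 2-D cell scores on a chosen component pair
#' together with the marker loading vectors rescaled for co-plotting.
#'
#' @param model A [fit_base_model()] fit with at least two components.
#' @param scores Score matrix from [project_cells()] (all individuals).
#' @param dataset The [mfc_dataset()] the scores belong to.
#' @param individual Individual id or index.
#' @param pcs Length-2 integer vector of components to plot (default `c(1, 2)`).
#' @return List with `scores` (cells x 2), `loadings` (J x 2, rescaled),
#'   `scale` (the positive factor applied to the loadings) and `pcs`.
#' @export
biplot_data <- function(model, scores, dataset, individual, pcs = c(1L, 2L)) {
  if (model$k < 2L) stop("biplot requires at least 2 components")
  if (length(pcs) != 2L || any(pcs < 1L) || any(pcs > model$k)) {
    stop("pcs must be two component indices within 1..", model$k)
  }
  if (is.character(individual)) {
    individual <- match(individual, dataset$individual_ids)
  }
  if (is.na(individual) || individual < 1L ||
      individual > length(dataset$individual_ids)) {
    stop("unknown individual")
  }
  rows <- dataset$cell_to_individual == individual
  if (!any(rows)) stop("individual has no cells")
  sc <- scores[rows, pcs, drop = FALSE]
  ld <- model$loadings[, pcs, drop = FALSE]
  scale <- max(abs(sc)) / max(abs(ld))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  list(scores = sc, loadings = ld * scale, scale = scale, pcs = pcs)
}
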