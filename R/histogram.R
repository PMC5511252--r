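#' Fit the shared histogram bin grid
#'
#' The grid is fitted once on the pooled base-model scores of all training
#' individuals and then shared by every histogram of the study. Per
#' component the bin width is `(P99.95 - P0.05) / F`: the range of the
#' scores without the 0.1% most extreme values, divided by the number of
#' bins. Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) so grids are bit-reproducible.
#'
#' @param scores Pooled score matrix (all training cells) with one column
#'   per histogram dimension.
#' @param bins Number of bins `F` per dimension (default 500).
#' @param clip_policy How cells outside the trimmed range are treated when
#'   histograms are built; only `"clip"` (assign to the boundary bin) is
#'   implemented, so every cell contributes and histograms keep total mass 1.
#' @return An object of class `bin_grid` with elements `bins`, `k`, `lower`
#'   (per-dimension anchor, the 0.05th percentile), `delta` (per-dimension
#'   bin width) and `clip_policy`.
#' @export
fit_bin_grid <- function(scores, bins = 500L, clip_policy = "clip") {
  scores <- as.matrix(scores)
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1")
  clip_policy <- match.arg(clip_policy, "clip")
  qs <- apply(scores, 2L, stats::quantile, probs = c(0.0005, 0.9995),
              names = FALSE, type = 7L)
  lower <- qs[1L, ]
  upper <- qs[2L, ]
  if (any(upper <= lower)) {
    stop("degenerate score axis: trimmed range is empty on dimension ",
         paste(which(upper <= lower), collapse = ", "))
  }
  structure(
    list(bins = bins,
         k = ncol(scores),
         lower = lower,
         delta = (upper - lower) / bins,
         clip_policy = clip_policy),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("Bin grid:", x$bins, "bins x", x$k, "dimension(s);",
      "bin widths:", paste(signif(x$delta, 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Bin centre coordinates of a grid
#' @param grid A [fit_bin_grid()] grid.
#' @param dim Dimension index.
#' @return Numeric vector of `bins` centre coordinates.
#' @export
bin_centers <- function(grid, dim = 1L) {
  grid$lower[dim] + (seq_len(grid$bins) - 0.5) * grid$delta[dim]
}

# bin index per cell and dimension; half-open [edge_f, edge_{f+1}) intervals,
# out-of-range cells clipped into the boundary bins
bin_index <- function(scores, grid) {
  idx <- floor(sweep(sweep(as.matrix(scores), 2L, grid$lower), 2L,
                     grid$delta, "/")) + 1
  idx[idx < 1] <- 1
  idx[idx > grid$bins] <- grid$bins
  storage.mode(idx) <- "integer"
  idx
}

#' Build one individual's normalized score histogram
#'
#' Counts the individual's cells on the shared grid and divides by the
#' individual's cell count, so that the histogram sums to one and carries no
#' information about how many cells were acquired. Cells falling outside the
#' trimmed grid range are clipped into the first/last bin. A cell exactly on
#' an interior bin edge belongs to the upper bin.
#'
#' @param scores Score matrix of one individual's cells (columns = grid
#'   dimensions).
#' @param grid A [fit_bin_grid()] grid.
#' @param individual_id Optional identifier carried along.
#' @return An object of class `sample_histogram`: list with `values`
#'   (a K-dimensional array with `bins` entries per dimension, summing to 1),
#'   `grid`, `n_cells`, `smoothed = FALSE` and `individual_id`.
#' @export
build_histogram <- function(scores, grid, individual_id = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("cannot build a histogram from zero cells")
  if (ncol(scores) != grid$k) {
    stop("scores have ", ncol(scores), " columns but the grid has ",
         grid$k, " dimensions")
  }
  idx <- bin_index(scores, grid)
  mult <- grid$bins^(seq_len(grid$k) - 1L)
  lin <- as.vector((idx - 1L) %*% mult) + 1L
  counts <- tabulate(lin, nbins = grid$bins^grid$k)
  h <- array(counts / nrow(scores), dim = rep(grid$bins, grid$k))
  structure(
    list(values = h, grid = grid, n_cells = nrow(scores),
         smoothed = FALSE, individual_id = individual_id),
    class = "sample_histogram")
}

#' @export
print.sample_histogram <- function(x, ...) {
  cat("Sample histogram", if (!is.null(x$individual_id)) paste0("[", x$individual_id, "]"),
      ":", paste(dim(x$values), collapse = " x "),
      if (x$smoothed) "(smoothed)" else "(raw)",
      "from", x$n_cells, "cells\n")
  invisible(x)
}

# cache of Gaussian boundary-reflecting smoothing matrices
.kernel_cache <- new.env(parent = emptyenv())

#' Gaussian smoothing matrix with reflective boundaries
#'
#' Dense `F x F` matrix applying a truncated, normalized 1-D Gaussian kernel
#' with half-sample-symmetric ("reflect") boundary handling. The matrix is
#' symmetric and doubly stochastic, so convolution conserves total mass
#' exactly.
#'
#' @param bins Grid size `F`.
#' @param sigma Kernel standard deviation in bin units.
#' @param truncate Kernel support half-width in units of `sigma` (default 4).
#' @return `F x F` numeric matrix.
#' @keywords internal
smoothing_matrix <- function(bins, sigma, truncate = 4) {
  key <- paste(bins, sigma, truncate, sep = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- ceiling(truncate * sigma)
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  M <- matrix(0, bins, bins)
  i <- seq_len(bins)
  for (o in seq(-r, r)) {
    src <- i + o
    src[src < 1L] <- 1L - src[src < 1L]
    src[src > bins] <- 2L * bins + 1L - src[src > bins]
    ij <- cbind(i, src)
    M[ij] <- M[ij] + w[o + r + 1L]
  }
  .kernel_cache[[key]] <- M
  M
}

#' Smooth a normalized histogram with a separable Gaussian kernel
#'
#' Applies a 1-D Gaussian convolution (standard deviation `sigma` in bin
#' units, truncated at `truncate * sigma`, reflective boundaries) along each
#' axis in turn, which for a separable kernel equals the full K-dimensional
#' Gaussian convolution. The result is renormalized to total mass one
#' (the reflective boundary already conserves mass exactly; renormalization
#' guards against floating-point drift). Smoothing compensates for the
#' biological and instrumental shifts that place equivalent cells of
#' different samples into adjacent bins.
#'
#' @param histogram A [build_histogram()] result, or a bare numeric array.
#' @param sigma Gaussian standard deviation in bin units; `0` is the
#'   identity. See [sigma_from_factor()] for the conversion from the
#'   pipeline's `smoothing_factor` setting.
#' @param truncate Kernel truncation radius in units of `sigma` (default 4).
#' @param renormalize Rescale the result to sum to one (default `TRUE`).
#' @return Same type as the input, smoothed.
#' @export
smooth_histogram <- function(histogram, sigma, truncate = 4, renormalize = TRUE) {
  if (sigma < 0) stop("sigma must be non-negative")
  is_obj <- inherits(histogram, "sample_histogram")
  h <- if (is_obj) histogram$values else histogram
  if (sigma > 0) {
    dims <- dim(h)
    if (is.null(dims)) dims <- length(h)
    k <- length(dims)
    bins <- dims[1L]
    if (any(dims != bins)) stop("histogram must have equal extent per dimension")
    M <- smoothing_matrix(bins, sigma, truncate)
    if (k == 1L) {
      h <- as.vector(M %*% h)
    } else if (k == 2L) {
      h <- M %*% h %*% t(M)
    } else {
      for (axis in seq_len(k)) {
        perm <- c(axis, setdiff(seq_len(k), axis))
        hp <- aperm(h, perm)
        hp <- array(M %*% matrix(hp, nrow = bins), dim = dims[perm])
        h <- aperm(hp, order(perm))
      }
    }
    if (renormalize) h <- h / sum(h)
  }
  if (is_obj) {
    histogram$values <- h
    histogram$smoothed <- sigma > 0
    histogram
  } else {
    h
  }
}

#' Convert a smoothing factor to a kernel standard deviation
#'
#' The pipeline exposes one smoothing strength setting. Under the default
#' `"sigma"` convention the factor is the kernel standard deviation in bin
#' units (the working value 5 gives `sigma = 5` bins); under `"fwhm"` it is
#' the kernel's full width at half maximum
#' (`sigma = factor / (2 * sqrt(2 * log(2)))`).
#'
#' @param factor Non-negative smoothing factor.
#' @param bandwidth `"sigma"` (default) or `"fwhm"`.
#' @return Kernel standard deviation in bin units.
#' @export
sigma_from_factor <- function(factor, bandwidth = c("sigma", "fwhm")) {
  bandwidth <- match.arg(bandwidth)
  if (factor < 0) stop("smoothing factor must be non-negative")
  if (bandwidth == "fwhm") factor / (2 * sqrt(2 * log(2))) else factor
}

#' Export a 1-D or 2-D histogram as a CSV grid
#'
#' @param histogram A `sample_histogram` (K = 1 or 2).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_histogram_csv <- function(histogram, path) {
  h <- histogram$values
  k <- length(dim(h))
  if (k > 2L) stop("CSV export supports 1- or 2-dimensional histograms")
  utils::write.table(as.matrix(h), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
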