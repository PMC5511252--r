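#' Vectorize sample histograms into a design matrix
#'
#' Flattens each individual's K-dimensional histogram into a row vector in
#' R's column-major order (the first grid dimension varies fastest), and
#' stacks the rows into the design matrix `C` of size samples x `F^K`. The
#' unfold order is fixed so that [refold_weights()] is an exact inverse.
#'
#' @param histograms List of [build_histogram()] objects sharing one grid.
#' @return Object of class `histogram_design`: list with `C`, `grid`,
#'   `individual_ids`, `mask` (`NULL` until [filter_low_variance_bins()] is
#'   applied) and `unfold_order = "column-major"`.
#' @export
vectorize_histograms <- function(histograms) {
  if (length(histograms) == 0L) stop("no histograms to vectorize")
  grid <- histograms[[1L]]$grid
  for (h in histograms) {
    if (!identical(h$grid, grid)) {
      stop("all histograms must share the same bin grid")
    }
  }
  C <- do.call(rbind, lapply(histograms, function(h) as.vector(h$values)))
  ids <- vapply(histograms, function(h) {
    if (is.null(h$individual_id)) NA_character_ else as.character(h$individual_id)
  }, character(1L))
  rownames(C) <- if (all(!is.na(ids))) ids else NULL
  structure(
    list(C = C, grid = grid, individual_ids = ids, mask = NULL,
         unfold_order = "column-major"),
    class = "histogram_design")
}

#' @export
print.histogram_design <- function(x, ...) {
  cat("Histogram design matrix:", nrow(x$C), "samples x", ncol(x$C), "bins")
  if (!is.null(x$mask)) cat(";", sum(x$mask), "bins retained after variance filter")
  cat("\n")
  invisible(x)
}

#' Drop near-constant histogram bins
#'
#' Bins whose across-sample variance is below `threshold` carry essentially
#' no between-sample information and are removed before the discriminant
#' model is fitted. The variance is computed on the *density* scale (bin
#' fraction divided by the bin volume `prod(delta_k)`): a fixed absolute
#' threshold is only meaningful on that scale, because bin densities -- and
#' hence their across-sample variances -- converge to a resolution-
#' independent limit as the grid is refined, whereas the variance of raw
#' bin fractions shrinks towards zero with the bin volume and would make any
#' absolute cutoff depend on `F`. The retained-bin mask is stored and later
#' applied unchanged to held-out samples, so the filter never sees test
#' data.
#'
#' @param design A [vectorize_histograms()] design.
#' @param threshold Density-variance threshold (default `1e-6`); bins whose
#'   across-sample density variance (n-1 denominator) is below it are
#'   omitted.
#' @return The design with `mask` set (logical, length `F^K`).
#' @export
filter_low_variance_bins <- function(design, threshold = 1e-6) {
  C <- design$C
  n <- nrow(C)
  if (n < 2L) stop("variance filtering requires at least 2 samples")
  bin_volume <- prod(design$grid$delta)
  m <- colMeans(C)
  v <- (colSums(C^2) - n * m^2) / (n - 1L)
  v[v < 0] <- 0
  mask <- v / bin_volume^2 >= threshold
  if (!any(mask)) {
    stop("degenerate design: the variance filter removed every bin ",
         "(threshold ", format(threshold), ")")
  }
  design$mask <- mask
  design
}

#' Masked design matrix of a filtered design
#' @param design A filtered `histogram_design`.
#' @return Matrix of retained columns.
#' @export
masked_design <- function(design) {
  if (is.null(design$mask)) stop("design has not been variance-filtered")
  design$C[, design$mask, drop = FALSE]
}

code_response <- function(y, levels = NULL) {
  y <- as.factor(y)
  if (!is.null(levels)) y <- factor(as.character(y), levels = levels)
  if (nlevels(y) != 2L || any(table(y) == 0L)) {
    stop("OPLS-DA requires exactly two non-empty classes")
  }
  list(numeric = ifelse(y == levels(y)[2L], 1, -1), levels = levels(y))
}

#' Fit a two-class OPLS-DA model on vectorized histograms
#'
#' Orthogonal partial least squares discriminant analysis: an orthogonal
#' signal correction (OSC) filter first removes `n_ortho` components of
#' between-sample variation that are uncorrelated with the class response,
#' then a single predictive PLS component is fitted on the deflated matrix.
#' With `n_ortho = 0` the model coincides with single-component PLS-DA.
#'
#' The response is coded -1 (first level, control) / +1 (second level,
#' challenged) and centred; the columns of `C` are mean-centred and the
#' centring vector is stored for prediction. The predictive weight vector
#' `w_top` has unit length, so the sign and magnitude of each entry tell
#' whether cells in that bin are over- (+) or under- (-) represented in the
#' challenged group.
#'
#' @param C Numeric matrix, samples x retained bins (see [masked_design()]).
#' @param y Two-level factor (or vector coercible to one) of group labels.
#' @param n_ortho Number of orthogonal components to remove (default 1).
#' @param levels Optional explicit level order (control first).
#' @return Object of class `oplsda` with the predictive weights `w_top`,
#'   loadings `p_top`, scores `t_top`, orthogonal parts `W_o`, `P_o`, `T_o`,
#'   the column-centring vector `mu`, `y_levels` and `threshold = 0`.
#' @export
fit_oplsda <- function(C, y, n_ortho = 1L, levels = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n < 4L) stop("OPLS-DA requires at least 4 samples")
  resp <- code_response(y, levels)
  yc <- resp$numeric - mean(resp$numeric)
  if (n_ortho < 0L) stop("n_ortho must be >= 0")
  mu <- colMeans(C)
  Xc <- sweep(C, 2L, mu)

  p <- ncol(C)
  W_o <- matrix(0, p, 0L)
  P_o <- matrix(0, p, 0L)
  T_o <- matrix(0, n, 0L)
  tol <- 1e-12
  for (a in seq_len(n_ortho)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < tol) stop("rank error: response direction vanished during OSC")
    w <- w / wn
    t_p <- Xc %*% w
    p_p <- crossprod(Xc, t_p) / sum(t_p^2)
    w_o <- p_p - as.numeric(crossprod(w, p_p)) * w
    w_on <- sqrt(sum(w_o^2))
    if (w_on < tol) {
      stop("rank error: no orthogonal variation left for component ", a)
    }
    w_o <- w_o / w_on
    t_o <- Xc %*% w_o
    p_o <- crossprod(Xc, t_o) / sum(t_o^2)
    Xc <- Xc - t_o %*% t(p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }
  w_top <- crossprod(Xc, yc)
  wn <- sqrt(sum(w_top^2))
  if (wn < tol) stop("rank error: no predictive variation left")
  w_top <- as.vector(w_top / wn)
  t_top <- as.vector(Xc %*% w_top)
  p_top <- as.vector(crossprod(Xc, t_top) / sum(t_top^2))
  structure(
    list(w_top = w_top, p_top = p_top, t_top = t_top,
         W_o = W_o, P_o = P_o, T_o = T_o,
         n_ortho = as.integer(n_ortho), mu = mu,
         y_levels = resp$levels, threshold = 0),
    class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat("OPLS-DA: 1 predictive +", x$n_ortho, "orthogonal component(s) on",
      length(x$w_top), "bins\n")
  cat("  classes:", x$y_levels[1L], "(-) vs", x$y_levels[2L], "(+)\n")
  invisible(x)
}

#' Prediction scores of an OPLS-DA model for new histogram rows
#'
#' Applies the stored column centring, deflates the orthogonal components,
#' and projects on the predictive weights. Positive scores classify as the
#' second (challenged) level, negative as the first (control) level.
#'
#' @param model A [fit_oplsda()] fit.
#' @param C New rows (samples x retained bins), already masked.
#' @return Numeric vector of prediction scores.
#' @export
predict_oplsda <- function(model, C) {
  C <- matrix(C, ncol = length(model$mu))
  Xc <- sweep(C, 2L, model$mu)
  for (a in seq_len(model$n_ortho)) {
    t_o <- Xc %*% model$W_o[, a]
    Xc <- Xc - t_o %*% t(model$P_o[, a])
  }
  as.vector(Xc %*% model$w_top)
}

#' Refold predictive weights into the leukocyte map
#'
#' Scatters the masked predictive weight vector back onto the `F x F` score
#' grid (filtered bins carry weight zero, being non-discriminative by
#' construction). Rows of the map index the first histogram dimension and
#' columns the second, matching the biplot axes. Positive entries mark cell
#' regions over-represented in the challenged group, negative entries
#' regions over-represented in controls.
#'
#' @param model A [fit_oplsda()] fit.
#' @param design The filtered [histogram_design] the model was fitted on
#'   (provides the grid and the bin mask).
#' @return Object of class `leukocyte_map`: list with `weights` (`F x F`
#'   matrix), `grid` and `mask`.
#' @export
refold_weights <- function(model, design) {
  grid <- design$grid
  if (grid$k != 2L) {
    stop("the leukocyte map is defined for 2-dimensional histograms (k = ",
         grid$k, ")")
  }
  if (is.null(design$mask)) stop("design has not been variance-filtered")
  w_full <- numeric(length(design$mask))
  w_full[design$mask] <- model$w_top
  structure(
    list(weights = matrix(w_full, grid$bins, grid$bins),
         grid = grid, mask = design$mask),
    class = "leukocyte_map")
}

#' @export
print.leukocyte_map <- function(x, ...) {
  cat("Leukocyte map:", x$grid$bins, "x", x$grid$bins, "bins;",
      sum(x$mask), "carry weight\n")
  invisible(x)
}
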