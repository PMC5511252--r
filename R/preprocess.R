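#' Log-transform raw marker intensities
#'
#' Fluorescence intensities are log10-transformed before any multivariate
#' modelling. When the global minimum of the data is below 1 (including
#' negative values, which occur in uncompensated acquisitions), a constant
#' shift of `1 - min(values)` is added first so that the minimum maps to
#' `log10(1) = 0` and the transform is defined everywhere. The shift is
#' monotone and is stored so that held-out samples are transformed with the
#' training shift.
#'
#' @param dataset An [mfc_dataset()] on the raw intensity scale.
#' @param shift Optional fixed shift (used when applying a fitted
#'   preprocessing model to new data). When `NULL` the shift is determined
#'   from the data as described above.
#' @return The transformed dataset, with the shift used stored in
#'   `attr(, "log_shift")`.
#' @export
log_transform <- function(dataset, shift = NULL) {
  v <- dataset$values
  if (any(!is.finite(v))) stop("non-finite marker values; cannot log-transform")
  if (is.null(shift)) {
    v_min <- min(v)
    shift <- if (v_min < 1) 1 - v_min else 0
  }
  v <- v + shift
  # held-out values below the training minimum are floored at 1 (-> log10 0)
  v[v < 1] <- 1
  dataset$values <- log10(v)
  attr(dataset, "log_shift") <- shift
  dataset
}

row_means_by <- function(values, map, n_ind, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  if (fun == "mean") {
    sums <- rowsum(values, map, reorder = TRUE)
    sums / tabulate(map, nbins = n_ind)
  } else {
    t(vapply(seq_len(n_ind), function(i) {
      apply(values[map == i, , drop = FALSE], 2L, stats::median)
    }, numeric(ncol(values))))
  }
}

# per-individual population variance (divide by N) of each marker column
individual_variances <- function(values, map, n_ind) {
  counts <- tabulate(map, nbins = n_ind)
  m1 <- rowsum(values, map, reorder = TRUE) / counts
  m2 <- rowsum(values^2, map, reorder = TRUE) / counts
  v <- m2 - m1^2
  v[v < 0] <- 0  # numeric guard
  v
}

#' Fit multiset centring
#'
#' Computes the reference point that is subtracted from every cell. Under
#' the default `overall` mode the per-individual marker means `m_i` are
#' computed first and the overall mean `m` is their unweighted average over
#' individuals -- not the grand mean over cells -- so that every individual
#' contributes equally regardless of how many cells were acquired for it.
#' `median_overall` replaces means by medians at both levels. `per_group`
#' stores one reference per clinical group; `per_individual` centres each
#' sample on itself at application time.
#'
#' @param dataset A log-transformed [mfc_dataset()].
#' @param center_mode One of `"overall"`, `"per_individual"`, `"per_group"`,
#'   `"median_overall"`.
#' @return A `preprocess_model` with the centring parameters populated.
#' @export
fit_centring <- function(dataset,
                         center_mode = c("overall", "per_individual",
                                         "per_group", "median_overall")) {
  center_mode <- match.arg(center_mode)
  n_ind <- length(dataset$individual_ids)
  fun <- if (center_mode == "median_overall") "median" else "mean"
  m_i <- row_means_by(dataset$values, dataset$cell_to_individual, n_ind, fun)
  rownames(m_i) <- dataset$individual_ids
  m <- if (center_mode == "median_overall") {
    apply(m_i, 2L, stats::median)
  } else {
    colMeans(m_i)
  }
  group_means <- rowsum(m_i, dataset$group_labels, reorder = TRUE) /
    as.vector(table(dataset$group_labels))
  structure(
    list(center_mode = center_mode,
         scale_mode = NULL,
         log_shift = attr(dataset, "log_shift"),
         individual_means = m_i,
         overall_mean = m,
         group_means = group_means,
         group_levels = levels(dataset$group_labels),
         marker_names = colnames(dataset$values),
         scale = NULL,
         group_scales = NULL),
    class = "preprocess_model")
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat("Preprocessing model: centring =", x$center_mode,
      "| scaling =", if (is.null(x$scale_mode)) "<unfitted>" else x$scale_mode, "\n")
  cat("  markers:", paste(x$marker_names, collapse = ", "), "\n")
  if (!is.null(x$log_shift)) cat("  log shift:", format(x$log_shift), "\n")
  invisible(x)
}

check_panel <- function(dataset, model) {
  if (!identical(colnames(dataset$values), model$marker_names)) {
    stop("marker panel mismatch: model was fitted on (",
         paste(model$marker_names, collapse = ", "), ")")
  }
}

#' Apply fitted centring to a dataset
#'
#' Held-out samples under the `overall` and `median_overall` modes are
#' shifted by the training reference unchanged; `per_individual` recomputes
#' each sample's own mean; `per_group` requires the sample's group to be one
#' of the training groups.
#'
#' @param dataset A log-transformed [mfc_dataset()].
#' @param model A `preprocess_model` from [fit_centring()].
#' @return The mean-centred dataset.
#' @export
apply_centring <- function(dataset, model) {
  check_panel(dataset, model)
  v <- dataset$values
  mode <- model$center_mode
  if (mode %in% c("overall", "median_overall")) {
    v <- sweep(v, 2L, model$overall_mean)
  } else if (mode == "per_individual") {
    n_ind <- length(dataset$individual_ids)
    fun <- "mean"
    m_i <- row_means_by(v, dataset$cell_to_individual, n_ind, fun)
    v <- v - m_i[dataset$cell_to_individual, , drop = FALSE]
  } else { # per_group
    g <- as.character(dataset$group_labels)
    if (!all(g %in% rownames(model$group_means))) {
      stop("per_group centring cannot be applied to samples from a group ",
           "absent at fit time: ",
           paste(setdiff(g, rownames(model$group_means)), collapse = ", "))
    }
    centre <- model$group_means[g[dataset$cell_to_individual], , drop = FALSE]
    v <- v - centre
  }
  dataset$values <- v
  dataset
}

#' Fit multiset scaling
#'
#' Under the default `pooled` mode the scale of marker `j` is the square
#' root of the *mean over individuals* of that individual's (population)
#' variance of marker `j`, so that each sample determines the resulting
#' standard deviation equally, independent of its cell count. `per_group`
#' averages within each group; `per_individual` rescales each sample by its
#' own standard deviations at application time; `none` is the identity.
#'
#' @param dataset A centred [mfc_dataset()].
#' @param scale_mode One of `"pooled"`, `"per_individual"`, `"per_group"`,
#'   `"none"`.
#' @param model Optional `preprocess_model` (from [fit_centring()]) that the
#'   scale parameters are added to; a bare model is created otherwise.
#' @return A `preprocess_model` with the scale populated.
#' @export
fit_scaling <- function(dataset,
                        scale_mode = c("pooled", "per_individual",
                                       "per_group", "none"),
                        model = NULL) {
  scale_mode <- match.arg(scale_mode)
  n_ind <- length(dataset$individual_ids)
  v_i <- individual_variances(dataset$values, dataset$cell_to_individual, n_ind)
  s <- sqrt(colMeans(v_i))
  gv <- rowsum(v_i, dataset$group_labels, reorder = TRUE) /
    as.vector(table(dataset$group_labels))
  group_scales <- sqrt(gv)
  if (scale_mode %in% c("pooled", "per_group")) {
    bad <- if (scale_mode == "pooled") s == 0 else apply(group_scales == 0, 2L, any)
    if (any(bad)) {
      stop("degenerate marker(s) with zero variance: ",
           paste(colnames(dataset$values)[bad], collapse = ", "))
    }
  }
  if (is.null(model)) {
    model <- structure(
      list(center_mode = NULL, scale_mode = NULL, log_shift = NULL,
           individual_means = NULL, overall_mean = NULL, group_means = NULL,
           group_levels = levels(dataset$group_labels),
           marker_names = colnames(dataset$values),
           scale = NULL, group_scales = NULL),
      class = "preprocess_model")
  }
  model$scale_mode <- scale_mode
  model$scale <- stats::setNames(s, colnames(dataset$values))
  model$group_scales <- group_scales
  model
}

#' Apply fitted scaling to a centred dataset
#'
#' @param dataset A centred [mfc_dataset()].
#' @param model A `preprocess_model` with the scale fitted.
#' @return The centred-and-scaled dataset (`X_cs`).
#' @export
apply_scaling <- function(dataset, model) {
  check_panel(dataset, model)
  mode <- model$scale_mode
  if (is.null(mode)) stop("scaling has not been fitted")
  if (mode == "none") return(dataset)
  v <- dataset$values
  if (mode == "pooled") {
    v <- sweep(v, 2L, model$scale, "/")
  } else if (mode == "per_individual") {
    n_ind <- length(dataset$individual_ids)
    v_i <- individual_variances(v, dataset$cell_to_individual, n_ind)
    if (any(v_i == 0)) {
      stop("per_individual scaling: an individual has a zero-variance marker")
    }
    v <- v / sqrt(v_i)[dataset$cell_to_individual, , drop = FALSE]
  } else { # per_group
    g <- as.character(dataset$group_labels)
    if (!all(g %in% rownames(model$group_scales))) {
      stop("per_group scaling cannot be applied to samples from a group ",
           "absent at fit time")
    }
    v <- v / model$group_scales[g[dataset$cell_to_individual], , drop = FALSE]
  }
  dataset$values <- v
  dataset
}

#' Fit the full preprocessing stage
#'
#' Convenience wrapper: log-transform, fit + apply centring, fit + apply
#' scaling. Returns both the fitted model (applicable to held-out samples
#' via [apply_preprocess()]) and the transformed training data.
#'
#' @param dataset Raw-scale [mfc_dataset()].
#' @param center_mode,scale_mode See [fit_centring()] and [fit_scaling()].
#' @param log Apply the log10 transform first (default `TRUE`).
#' @return List with elements `model` (a `preprocess_model`) and `data`
#'   (the transformed dataset, `X_cs`).
#' @export
fit_preprocess <- function(dataset, center_mode = "overall",
                           scale_mode = "pooled", log = TRUE) {
  if (log) dataset <- log_transform(dataset)
  model <- fit_centring(dataset, center_mode)
  model$log_applied <- log
  centred <- apply_centring(dataset, model)
  model <- fit_scaling(centred, scale_mode, model)
  list(model = model, data = apply_scaling(centred, model))
}

#' Apply a fitted preprocessing model to (held-out) data
#'
#' @param dataset Raw-scale [mfc_dataset()].
#' @param model A fitted `preprocess_model` from [fit_preprocess()].
#' @return The transformed dataset on the training scale.
#' @export
apply_preprocess <- function(dataset, model) {
  if (isTRUE(model$log_applied)) {
    dataset <- log_transform(dataset, shift = model$log_shift)
  }
  apply_scaling(apply_centring(dataset, model), model)
}
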