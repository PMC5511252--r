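#' Pipeline configuration
#'
#' Collects every tunable stage parameter with the method's working defaults:
#' 500 bins per histogram dimension, smoothing factor 5, bin variance
#' threshold 1e-6, two base components, overall multiset centring and pooled
#' multiset scaling.
#'
#' @param center_mode,scale_mode Preprocessing modes; see [fit_centring()],
#'   [fit_scaling()].
#' @param k_base Number of base-model components fitted.
#' @param hist_pcs Components used as histogram dimensions (default: all
#'   `k_base`). A subset such as `c(1, 3)` selects a component pair from a
#'   larger base model; see [rank_pc_pairs()].
#' @param bins_f Histogram bins per dimension.
#' @param smoothing_factor Gaussian smoothing strength; interpreted per
#'   `smoothing_bandwidth` by [sigma_from_factor()].
#' @param smoothing_bandwidth `"sigma"` (default: the factor is the kernel
#'   standard deviation in bins) or `"fwhm"`.
#' @param variance_threshold Bin variance filter threshold of the top model.
#' @param n_ortho Orthogonal components of the OPLS-DA model when no grid
#'   search is requested.
#' @param n_ortho_grid Optional candidate set (e.g. `c(0, 1, 2)`); when it
#'   has more than one value, [fit_pipeline()] selects `n_ortho` by inner
#'   cross-validation over the training individuals.
#' @param inner_folds Folds of that inner selection (default 3).
#' @param clip_policy Out-of-range cell policy of the histogram stage.
#' @param log Log10-transform raw intensities (default `TRUE`).
#' @return A validated list of class `leukomap_config`.
#' @export
leukomap_config <- function(center_mode = "overall",
                            scale_mode = "pooled",
                            k_base = 2L,
                            hist_pcs = NULL,
                            bins_f = 500L,
                            smoothing_factor = 5,
                            smoothing_bandwidth = "sigma",
                            variance_threshold = 1e-6,
                            n_ortho = 1L,
                            n_ortho_grid = NULL,
                            inner_folds = 3L,
                            clip_policy = "clip",
                            log = TRUE) {
  cfg <- list(center_mode = center_mode, scale_mode = scale_mode,
              k_base = as.integer(k_base), hist_pcs = hist_pcs,
              bins_f = as.integer(bins_f),
              smoothing_factor = smoothing_factor,
              smoothing_bandwidth = smoothing_bandwidth,
              variance_threshold = variance_threshold,
              n_ortho = as.integer(n_ortho), n_ortho_grid = n_ortho_grid,
              inner_folds = as.integer(inner_folds),
              clip_policy = clip_policy, log = isTRUE(log))
  if (cfg$k_base < 1L) stop("k_base must be >= 1")
  if (cfg$bins_f < 1L) stop("bins_f must be >= 1")
  if (cfg$smoothing_factor < 0) stop("smoothing_factor must be >= 0")
  if (cfg$variance_threshold < 0) stop("variance_threshold must be >= 0")
  if (!is.null(cfg$hist_pcs)) {
    cfg$hist_pcs <- as.integer(cfg$hist_pcs)
    if (any(cfg$hist_pcs < 1L) || any(cfg$hist_pcs > cfg$k_base)) {
      stop("hist_pcs must index fitted base components (1..k_base)")
    }
  }
  structure(cfg, class = "leukomap_config")
}

#' Coerce a plain list into a pipeline configuration
#'
#' Unknown keys raise an error; missing keys take the defaults of
#' [leukomap_config()] (useful for configurations read from JSON/YAML files).
#'
#' @param x A named list or an existing `leukomap_config`.
#' @return A `leukomap_config`.
#' @export
as_leukomap_config <- function(x) {
  if (inherits(x, "leukomap_config")) return(x)
  known <- names(formals(leukomap_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(leukomap_config, x)
}

smoothing_sigma <- function(config) {
  sigma_from_factor(config$smoothing_factor, config$smoothing_bandwidth)
}

# histograms of each individual in a (preprocessed) dataset on a fixed grid
sample_histograms <- function(scores, dataset, grid, sigma) {
  lapply(seq_along(dataset$individual_ids), function(i) {
    h <- build_histogram(scores[dataset$cell_to_individual == i, , drop = FALSE],
                         grid, individual_id = dataset$individual_ids[i])
    smooth_histogram(h, sigma)
  })
}

# stages 1-2 plus histogram design: everything up to (but excluding) OPLS-DA
fit_stages <- function(dataset, config) {
  pp <- fit_preprocess(dataset, config$center_mode, config$scale_mode,
                       log = config$log)
  base <- fit_base_model(pp$data, config$k_base)
  pcs <- if (is.null(config$hist_pcs)) seq_len(config$k_base) else config$hist_pcs
  scores <- project_cells(pp$data, base)[, pcs, drop = FALSE]
  grid <- fit_bin_grid(scores, config$bins_f, config$clip_policy)
  sigma <- smoothing_sigma(config)
  hists <- sample_histograms(scores, dataset, grid, sigma)
  design <- filter_low_variance_bins(vectorize_histograms(hists),
                                     config$variance_threshold)
  list(preprocess = pp$model, base = base, pcs = pcs, grid = grid,
       sigma = sigma, design = design,
       group_labels = dataset$group_labels,
       group_levels = levels(dataset$group_labels))
}

#' Fit the full discriminant pipeline
#'
#' Runs all stages on the training dataset: log/centre/scale preprocessing,
#' cell-count-balanced PCA base model, shared bin grid, per-sample smoothed
#' histograms, bin variance filter and the OPLS-DA top model. When the
#' configuration carries an `n_ortho_grid` with more than one candidate, the
#' number of orthogonal components is chosen by a small inner
#' cross-validation over the training individuals (ties resolved towards
#' fewer components); the whole pipeline is then refitted with the winner.
#'
#' @param dataset Raw-scale training [mfc_dataset()] with exactly two group
#'   levels.
#' @param config A [leukomap_config()] (or a list coercible to one).
#' @param seed Optional seed controlling the inner-selection folds.
#' @return Object of class `leukomap_model` bundling every fitted stage.
#' @export
fit_pipeline <- function(dataset, config = leukomap_config(), seed = NULL) {
  config <- as_leukomap_config(config)
  if (nlevels(dataset$group_labels) != 2L) {
    stop("supervised fitting requires exactly two group levels")
  }
  n_ortho <- config$n_ortho
  selection <- NULL
  grid_cand <- sort(unique(as.integer(config$n_ortho_grid)))
  if (length(grid_cand) > 1L) {
    selection <- select_n_ortho(dataset, config, grid_cand,
                                config$inner_folds, seed)
    n_ortho <- selection$n_ortho
  }
  stages <- fit_stages(dataset, config)
  top <- fit_oplsda(masked_design(stages$design), stages$group_labels,
                    n_ortho, levels = stages$group_levels)
  structure(
    c(stages,
      list(top = top, n_ortho = n_ortho, selection = selection,
           config = config, individual_ids = dataset$individual_ids,
           version = 1L)),
    class = "leukomap_model")
}

#' @export
print.leukomap_model <- function(x, ...) {
  cat("Leukocyte-map discriminant model\n")
  cat("  individuals:", length(x$individual_ids),
      "| groups:", paste(x$group_levels, collapse = " vs "), "\n")
  cat("  base components:", x$config$k_base,
      "| histogram dims:", paste(x$pcs, collapse = ","),
      "x", x$grid$bins, "bins\n")
  cat("  smoothing sigma:", signif(x$sigma, 4), "bins",
      "| retained bins:", sum(x$design$mask), "\n")
  cat("  orthogonal components:", x$n_ortho,
      if (!is.null(x$selection)) "(inner-CV selected)", "\n")
  invisible(x)
}

# inner cross-validated accuracy per n_ortho candidate
select_n_ortho <- function(dataset, config, candidates, inner_folds, seed) {
  n_ind <- length(dataset$individual_ids)
  inner_folds <- min(inner_folds, min(table(dataset$group_labels)))
  if (inner_folds < 2L) {
    return(list(n_ortho = config$n_ortho, accuracy = NULL,
                note = "too few samples for inner selection"))
  }
  folds <- make_folds(dataset$group_labels, inner_folds, seed = seed)
  hits <- stats::setNames(numeric(length(candidates)), candidates)
  total <- 0L
  for (f in seq_len(inner_folds)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    if (nlevels(droplevels(dataset$group_labels[train_idx])) < 2L) next
    train <- subset_individuals(dataset, train_idx)
    test <- subset_individuals(dataset, test_idx)
    stages <- try(fit_stages(train, config), silent = TRUE)
    if (inherits(stages, "try-error")) next
    Cm <- masked_design(stages$design)
    h_test <- pipeline_histogram_rows(stages, test)[, stages$design$mask, drop = FALSE]
    truth <- dataset$group_labels[test_idx]
    for (cand in candidates) {
      top <- try(fit_oplsda(Cm, stages$group_labels, cand,
                            levels = stages$group_levels), silent = TRUE)
      if (inherits(top, "try-error")) next
      sc <- predict_oplsda(top, h_test)
      pred <- ifelse(sc > top$threshold, stages$group_levels[2L],
                     stages$group_levels[1L])
      correct <- pred == as.character(truth) & sc != top$threshold
      hits[as.character(cand)] <- hits[as.character(cand)] + sum(correct)
    }
    total <- total + length(test_idx)
  }
  acc <- if (total > 0L) hits / total else hits
  best <- candidates[which.max(acc)]  # first max -> smallest candidate wins ties
  list(n_ortho = as.integer(best), accuracy = acc)
}

# masked-space histogram rows for new samples under fitted stages
pipeline_histogram_rows <- function(stages, dataset) {
  xcs <- apply_preprocess(dataset, stages$preprocess)
  scores <- project_cells(xcs, stages$base)[, stages$pcs, drop = FALSE]
  hists <- sample_histograms(scores, dataset, stages$grid, stages$sigma)
  do.call(rbind, lapply(hists, function(h) as.vector(h$values)))
}

#' Score new samples with a fitted pipeline
#'
#' Each sample is pushed through every stored stage: training log shift,
#' centring and scaling, projection on the base loadings, histogram on the
#' training grid (out-of-range cells clipped), smoothing, vectorization,
#' training bin mask and column centring, OSC deflation and projection on
#' the predictive weights. A sample whose histogram equals the training mean
#' histogram scores 0; positive scores classify as the challenged (second)
#' level.
#'
#' @param model A [fit_pipeline()] fit.
#' @param newdata An [mfc_dataset()], or a bare cell matrix treated as one
#'   unlabelled sample.
#' @return Data frame with columns `individual`, `group` (NA for unlabelled
#'   input), `score` and `predicted`.
#' @export
predict_pipeline <- function(model, newdata) {
  if (!inherits(newdata, "mfc_dataset")) {
    newdata <- mfc_dataset(as.matrix(newdata),
                           rep(1L, nrow(newdata)), "sample_1",
                           factor(NA_character_, levels = model$group_levels),
                           marker_names = colnames(newdata))
  }
  rows <- pipeline_histogram_rows(model, newdata)[, model$design$mask,
                                                  drop = FALSE]
  sc <- predict_oplsda(model$top, rows)
  data.frame(
    individual = newdata$individual_ids,
    group = as.character(newdata$group_labels),
    score = sc,
    predicted = ifelse(sc > model$top$threshold,
                       model$group_levels[2L], model$group_levels[1L]),
    stringsAsFactors = FALSE)
}

#' Leukocyte map of a fitted pipeline
#'
#' @param model A [fit_pipeline()] fit (2-dimensional histograms).
#' @return A [refold_weights()] `leukocyte_map`.
#' @export
leukocyte_map <- function(model) {
  refold_weights(model$top, model$design)
}

#' Save / load a fitted pipeline
#'
#' The archive is a single self-describing file bundling every fitted stage,
#' so that prediction is impossible without the complete preprocessing state.
#'
#' @param model A `leukomap_model`.
#' @param path Archive path.
#' @return `path` invisibly, resp. the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "leukomap_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "leukomap_model")) {
    stop("not a leukomap model archive: ", path)
  }
  model
}

#' Plot a leukocyte map with base-model loadings overlaid
#'
#' Blue regions mark histogram bins over-represented in the challenged
#' group, red regions bins over-represented in controls; black arrows are
#' the base-model marker loadings, so the marker combination of any region
#' can be read off directly.
#'
#' @param x A `leukocyte_map` (see [leukocyte_map()]).
#' @param base Optional [fit_base_model()] fit supplying loading arrows.
#' @param pcs Component pair of the map axes (for axis labels/arrows).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.leukocyte_map <- function(x, base = NULL, pcs = c(1L, 2L), ...) {
  w <- x$weights
  lim <- max(abs(w))
  if (lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(255L)
  cx <- bin_centers(x$grid, 1L)
  cy <- bin_centers(x$grid, 2L)
  graphics::image(cx, cy, w, zlim = c(-lim, lim), col = pal,
                  xlab = paste0("PC", pcs[1L], " score"),
                  ylab = paste0("PC", pcs[2L], " score"), ...)
  if (!is.null(base)) {
    ld <- base$loadings[, pcs, drop = FALSE]
    scale <- 0.4 * min(diff(range(cx)), diff(range(cy))) / max(abs(ld))
    graphics::arrows(mean(cx), mean(cy),
                     mean(cx) + ld[, 1L] * scale, mean(cy) + ld[, 2L] * scale,
                     length = 0.08)
    graphics::text(mean(cx) + ld[, 1L] * scale * 1.08,
                   mean(cy) + ld[, 2L] * scale * 1.08,
                   rownames(ld), cex = 0.8)
  }
  invisible(x)
}
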