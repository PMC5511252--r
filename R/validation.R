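#' Stratified leave-sample-out fold assignment
#'
#' Partitions *individuals* (never cells) into `n_folds` folds. Under
#' stratification the members of each group are shuffled and dealt
#' round-robin over the folds, so group proportions stay as balanced as the
#' counts allow. Deterministic for a given seed.
#'
#' @param group_labels Factor of group memberships, one entry per individual.
#' @param n_folds Number of folds.
#' @param stratified Balance folds within groups (default `TRUE`).
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per individual.
#' @export
make_folds <- function(group_labels, n_folds, stratified = TRUE, seed = NULL) {
  group_labels <- as.factor(group_labels)
  n <- length(group_labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > n) {
    stop("n_folds must be between 2 and the number of individuals")
  }
  if (stratified && any(table(group_labels) < n_folds)) {
    stop("stratification impossible: every group needs at least ", n_folds,
         " members (or use stratified = FALSE)")
  }
  assign <- function(idx) {
    perm <- sample(idx)
    stats::setNames(rep_len(seq_len(n_folds), length(perm)), perm)
  }
  draw <- function() {
    folds <- integer(n)
    if (stratified) {
      for (g in levels(group_labels)) {
        a <- assign(which(group_labels == g))
        folds[as.integer(names(a))] <- a
      }
    } else {
      a <- assign(seq_len(n))
      folds[as.integer(names(a))] <- a
    }
    folds
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Cross-validation configuration
#'
#' Defaults follow the method's validation recipe: 6 outer folds, 20
#' iterations with reshuffled fold membership, stratified leave-sample-out
#' folds, and inner selection of the number of orthogonal components.
#'
#' @param outer_folds Outer accuracy folds (default 6).
#' @param n_iterations Fold-reshuffling repetitions (default 20).
#' @param inner_folds Folds of the inner hyperparameter selection.
#' @param stratified Stratify folds by group (default `TRUE`).
#' @param seed Base seed; iteration i derives its fold seed as `seed + i`.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 6L, n_iterations = 20L, inner_folds = 3L,
                      stratified = TRUE, seed = 1L) {
  structure(
    list(outer_folds = as.integer(outer_folds),
         n_iterations = as.integer(n_iterations),
         inner_folds = as.integer(inner_folds),
         stratified = isTRUE(stratified),
         seed = as.integer(seed)),
    class = "cv_config")
}

#' Double (nested) cross-validation of the full pipeline
#'
#' For every iteration and outer fold the *entire* pipeline -- preprocessing
#' parameters, base loadings, bin grid, variance mask, column centring and
#' OPLS-DA weights, plus any inner-fold hyperparameter selection -- is
#' refitted on the training individuals only, and the held-out individuals
#' are scored. No fitted statistic ever derives from a test sample.
#' Accuracy counts a held-out prediction as correct when the sign of its
#' score matches its group; a score exactly at the threshold counts as
#' incorrect.
#'
#' @param dataset Raw-scale [mfc_dataset()] with two group levels.
#' @param config Pipeline configuration ([leukomap_config()]).
#' @param cv A [cv_config()].
#' @return Object of class `cv_result`: per-sample score matrix
#'   (`individuals x iterations`, `NA` where a fit failed), per-iteration
#'   accuracies, overall mean accuracy, the fold-assignment log and the
#'   derived seeds.
#' @export
double_cross_validate <- function(dataset, config = leukomap_config(),
                                  cv = cv_config()) {
  config <- as_leukomap_config(config)
  n_ind <- length(dataset$individual_ids)
  if (cv$outer_folds > n_ind) stop("more outer folds than individuals")
  levels2 <- levels(dataset$group_labels)
  if (length(levels2) != 2L) stop("cross-validation requires two groups")
  scores <- matrix(NA_real_, n_ind, cv$n_iterations,
                   dimnames = list(dataset$individual_ids, NULL))
  accuracy <- numeric(cv$n_iterations)
  fold_log <- vector("list", cv$n_iterations)
  seeds <- cv$seed + seq_len(cv$n_iterations)
  for (it in seq_len(cv$n_iterations)) {
    folds <- make_folds(dataset$group_labels, cv$outer_folds,
                        cv$stratified, seed = seeds[it])
    fold_log[[it]] <- folds
    correct <- 0L
    for (f in sort(unique(folds))) {
      train_idx <- which(folds != f)
      test_idx <- which(folds == f)
      train <- subset_individuals(dataset, train_idx)
      test <- subset_individuals(dataset, test_idx)
      model <- tryCatch(
        fit_pipeline(train, config, seed = seeds[it] * 1000L + f),
        error = function(e) {
          stop("pipeline fit failed in iteration ", it, ", fold ", f, ": ",
               conditionMessage(e))
        })
      pred <- predict_pipeline(model, test)
      scores[test_idx, it] <- pred$score
      ok <- pred$predicted == as.character(dataset$group_labels[test_idx]) &
        pred$score != model$top$threshold
      correct <- correct + sum(ok)
    }
    accuracy[it] <- correct / n_ind
  }
  structure(
    list(scores = scores,
         accuracy_per_iteration = accuracy,
         accuracy = mean(accuracy),
         fold_log = fold_log,
         seeds = seeds,
         group_labels = dataset$group_labels,
         individual_ids = dataset$individual_ids,
         config = config, cv = cv),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Double cross-validation:", x$cv$outer_folds, "folds x",
      x$cv$n_iterations, "iterations\n")
  cat(sprintf("  mean accuracy: %.1f%% (per-iteration %.1f-%.1f%%)\n",
              100 * x$accuracy,
              100 * min(x$accuracy_per_iteration),
              100 * max(x$accuracy_per_iteration)))
  invisible(x)
}

#' Summarize a cross-validation result
#'
#' @param result A [double_cross_validate()] result.
#' @return List with `samples` (data frame of per-sample mean and standard
#'   deviation of held-out scores across iterations, group and majority
#'   prediction), `per_iteration` accuracies and `accuracy` (their mean).
#' @export
summarize_cv <- function(result) {
  m <- rowMeans(result$scores, na.rm = TRUE)
  s <- apply(result$scores, 1L, stats::sd, na.rm = TRUE)
  lv <- levels(result$group_labels)
  samples <- data.frame(
    individual = result$individual_ids,
    group = as.character(result$group_labels),
    mean_score = m,
    sd_score = s,
    predicted = ifelse(m > 0, lv[2L], lv[1L]),
    stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  list(samples = samples,
       per_iteration = result$accuracy_per_iteration,
       accuracy = mean(result$accuracy_per_iteration))
}

#' Rank base-component pairs by cross-validated accuracy
#'
#' Fits a larger base model and evaluates every unordered pair of its
#' components as histogram axes by (outer) cross-validated accuracy, so the
#' pair feeding the top model can be chosen explicitly rather than silently.
#'
#' @param dataset Raw-scale [mfc_dataset()].
#' @param config Pipeline configuration; `k_base` sets the pool of
#'   components to pair.
#' @param cv A [cv_config()]; a handful of iterations is usually enough for
#'   a ranking.
#' @return Data frame with columns `pc1`, `pc2`, `accuracy`, sorted by
#'   decreasing accuracy.
#' @export
rank_pc_pairs <- function(dataset, config = leukomap_config(k_base = 3L),
                          cv = cv_config(n_iterations = 5L)) {
  config <- as_leukomap_config(config)
  if (config$k_base < 2L) stop("need k_base >= 2 to form component pairs")
  pairs <- utils::combn(config$k_base, 2L)
  res <- apply(pairs, 2L, function(p) {
    cfg <- config
    cfg$hist_pcs <- as.integer(p)
    double_cross_validate(dataset, cfg, cv)$accuracy
  })
  out <- data.frame(pc1 = pairs[1L, ], pc2 = pairs[2L, ], accuracy = res)
  out[order(-out$accuracy), , drop = FALSE]
}
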