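#' Specify a synthetic cell population
#'
#' Populations are Gaussian clusters in log10 marker space, optionally with a
#' linear drift of the mean across the population (a "continuum" of marker
#' expression rather than a discrete cluster, as seen in activated
#' neutrophil compartments).
#'
#' @param name Population label used in the truth record.
#' @param mean Mean marker vector (log10 units), length J.
#' @param sd Within-population standard deviation: a scalar, a length-J
#'   vector, or a full J x J covariance matrix via `cov`.
#' @param fractions Numeric vector of mixing fractions, one per group.
#' @param drift Optional length-J drift vector (log10 units): a cell at
#'   continuum position `u ~ Uniform(0, 1)` has mean `mean + (u - 0.5) * drift`.
#' @param cov Optional full covariance matrix (overrides `sd`); must be
#'   symmetric positive definite.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(name, mean, sd = 0.05, fractions, drift = NULL,
                            cov = NULL) {
  J <- length(mean)
  if (is.null(cov)) {
    if (length(sd) == 1L) sd <- rep(sd, J)
    if (length(sd) != J) stop("sd must be scalar or length J")
    cov <- diag(sd^2, J)
  }
  if (!isTRUE(all.equal(cov, t(cov)))) stop("covariance must be symmetric")
  eg <- eigen(cov, symmetric = TRUE)
  if (min(eg$values) < -1e-10 * max(abs(eg$values), 1)) {
    stop("covariance of population '", name, "' is not positive definite")
  }
  # square root factor A with t(A) %*% A = cov (accepts semi-definite cov)
  ch <- diag(sqrt(pmax(eg$values, 0)), J) %*% t(eg$vectors)
  if (!is.null(drift) && length(drift) != J) stop("drift must have length J")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  structure(list(name = name, mean = mean, cov = cov, chol = ch,
                 fractions = fractions, drift = drift),
            class = "population_spec")
}

#' Specify a synthetic two-group cytometry cohort
#'
#' Defines the generative law of a multiset cohort: G groups of individuals,
#' per-individual cell counts drawn uniformly from a range (so counts differ
#' between samples), a shared set of Gaussian(-continuum) populations whose
#' mixing fractions differ between groups, and a between-individual jitter
#' that shifts each population's mean per individual to model biological
#' variability. Cells are drawn in log10 space and exponentiated, so the
#' pipeline's log transform recovers the generative scale.
#'
#' @param populations List of [population_spec()]s with consistent J and a
#'   fraction per group; fractions must sum to 1 within each group.
#' @param individuals_per_group Integer vector, individuals per group.
#' @param cells Length-2 integer range from which each individual's cell
#'   count is drawn uniformly.
#' @param jitter_sd Standard deviation (log10 units) of the per-individual,
#'   per-population mean shift.
#' @param marker_names Marker panel names, length J.
#' @param group_names Group labels; the first is the control group.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(populations, individuals_per_group = c(8L, 8L),
                        cells = c(1500L, 2500L), jitter_sd = 0.04,
                        marker_names = NULL,
                        group_names = c("control", "challenged")) {
  G <- length(individuals_per_group)
  J <- length(populations[[1L]]$mean)
  fr <- vapply(populations, function(p) {
    if (length(p$fractions) != G) {
      stop("population '", p$name, "' needs one mixing fraction per group")
    }
    p$fractions
  }, numeric(G))
  fr <- matrix(fr, nrow = G)
  if (any(abs(rowSums(fr) - 1) > 1e-8)) {
    stop("population fractions must sum to 1 within each group")
  }
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(J))
  if (any(cells < 1L)) stop("cell counts must be >= 1")
  structure(
    list(populations = populations,
         individuals_per_group = as.integer(individuals_per_group),
         cells = as.integer(cells), jitter_sd = jitter_sd,
         marker_names = marker_names, group_names = group_names,
         n_markers = J),
    class = "cohort_spec")
}

draw_population <- function(pop, n, jitter) {
  J <- length(pop$mean)
  x <- matrix(stats::rnorm(n * J), n, J) %*% pop$chol
  x <- sweep(x, 2L, pop$mean + jitter, "+")
  if (!is.null(pop$drift)) {
    u <- stats::runif(n) - 0.5
    x <- x + outer(u, pop$drift)
  }
  x
}

#' Simulate a synthetic cytometry cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical seeds give identical cohorts
#'   cell-for-cell.
#' @return List with `dataset` (an [mfc_dataset()] on the raw intensity
#'   scale) and `truth`: per-cell population assignments (in dataset row
#'   order), per-individual realized fractions, per-individual jitter draws
#'   and the generating `spec`.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  run <- function() {
    G <- length(spec$individuals_per_group)
    n_pop <- length(spec$populations)
    J <- spec$n_markers
    blocks <- list()
    assign_all <- list()
    jitters <- list()
    ids <- character(0L)
    groups <- character(0L)
    counts <- integer(0L)
    realized <- NULL
    idx <- 0L
    for (g in seq_len(G)) {
      fr <- vapply(spec$populations, function(p) p$fractions[g], numeric(1L))
      for (i in seq_len(spec$individuals_per_group[g])) {
        idx <- idx + 1L
        n_i <- if (spec$cells[1L] == spec$cells[2L]) spec$cells[1L] else
          sample(spec$cells[1L]:spec$cells[2L], 1L)
        z <- sample.int(n_pop, n_i, replace = TRUE, prob = fr)
        jit <- matrix(stats::rnorm(n_pop * J, sd = spec$jitter_sd), n_pop, J)
        x <- matrix(0, n_i, J)
        for (p in seq_len(n_pop)) {
          rows <- which(z == p)
          if (length(rows)) {
            x[rows, ] <- draw_population(spec$populations[[p]],
                                         length(rows), jit[p, ])
          }
        }
        blocks[[idx]] <- x
        assign_all[[idx]] <- z
        jitters[[idx]] <- jit
        ids <- c(ids, sprintf("%s_%02d", spec$group_names[g], i))
        groups <- c(groups, spec$group_names[g])
        counts <- c(counts, n_i)
        realized <- rbind(realized, tabulate(z, nbins = n_pop) / n_i)
      }
    }
    values <- 10^do.call(rbind, blocks)
    colnames(values) <- spec$marker_names
    dataset <- mfc_dataset(values, rep(seq_along(counts), counts), ids,
                           factor(groups, levels = spec$group_names))
    colnames(realized) <- vapply(spec$populations, `[[`, character(1L), "name")
    rownames(realized) <- ids
    list(dataset = dataset,
         truth = list(population = unlist(assign_all, use.names = FALSE),
                      realized_fractions = realized,
                      jitter = stats::setNames(jitters, ids),
                      spec = spec, seed = seed))
  }
  withr::with_seed(seed, run())
}

#' Write a simulated cohort as FCS fixtures plus a manifest
#'
#' One FCS 3.1 file per individual and a `manifest.csv` with columns
#' `file`, `individual`, `group`, directly consumable by
#' [assemble_dataset()].
#'
#' @param dataset An [mfc_dataset()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_fixture_fcs <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0L)
  for (i in seq_along(dataset$individual_ids)) {
    id <- dataset$individual_ids[i]
    f <- paste0(id, ".fcs")
    write_fcs(dataset$values[dataset$cell_to_individual == i, , drop = FALSE],
              file.path(dir, f))
    files <- c(files, f)
  }
  manifest <- data.frame(file = files,
                         individual = dataset$individual_ids,
                         group = as.character(dataset$group_labels),
                         stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Preset cohort scenarios
#'
#' Named generative scenarios used throughout the tests and examples:
#'
#' * `lps_like` -- an endotoxin-challenge-style neutrophil cohort: 2 groups
#'   of 8 individuals, ~2,000 cells each, 6 markers. A compact resting
#'   population dominates; an "activated" continuum population whose mean
#'   drifts along the CD16/CD62L axis carries 5% of control cells but 30%
#'   of challenged cells.
#' * `null` -- two exchangeable groups of 20 individuals drawn from one law;
#'   any classifier's long-run held-out accuracy is 50%.
#' * `aml_like` -- bone-marrow-style cohort with 8 markers and a blast-like
#'   population shifted along a single marker, 2% of control cells vs 25%
#'   of patient cells.
#'
#' Fraction values and population geometry are test parameters of this
#' package, not measurements; see the methods vignette for how they were
#' chosen.
#'
#' @return Named list of [cohort_spec()]s.
#' @export
preset_scenarios <- function() {
  lps_markers <- c("CD16", "CD62L", "CD11b", "CD11c", "CD32", "CD64")
  lps <- cohort_spec(
    populations = list(
      population_spec("resting",
                      mean = c(2.30, 2.20, 1.80, 1.60, 2.00, 1.20),
                      sd = 0.060, fractions = c(0.95, 0.70)),
      population_spec("activated",
                      mean = c(1.40, 1.60, 2.60, 2.20, 2.00, 1.30),
                      sd = 0.025, fractions = c(0.05, 0.30),
                      drift = c(0.10, -0.10, 0.05, 0.05, 0, 0))),
    individuals_per_group = c(8L, 8L),
    cells = c(1500L, 2500L),
    jitter_sd = 0.015,
    marker_names = lps_markers)

  null <- cohort_spec(
    populations = list(
      population_spec("major",
                      mean = c(2.30, 2.20, 1.80, 1.60, 2.00, 1.20),
                      sd = 0.060, fractions = c(0.80, 0.80)),
      population_spec("minor",
                      mean = c(1.60, 1.70, 2.40, 2.10, 2.00, 1.30),
                      sd = 0.040, fractions = c(0.20, 0.20))),
    individuals_per_group = c(20L, 20L),
    cells = c(800L, 1200L),
    jitter_sd = 0.015,
    marker_names = lps_markers)

  aml_markers <- c("cMPO", "cCD79a", "cCD3", "CD19", "CD34", "CD45",
                   "CD7", "sCD3")
  aml <- cohort_spec(
    populations = list(
      population_spec("myeloid",
                      mean = c(2.40, 1.20, 1.20, 1.30, 1.40, 2.30, 1.30, 1.20),
                      sd = 0.060, fractions = c(0.58, 0.45)),
      population_spec("lymphoid",
                      mean = c(1.30, 1.60, 2.20, 2.00, 1.30, 2.60, 2.20, 2.30),
                      sd = 0.050, fractions = c(0.40, 0.30)),
      population_spec("blast",
                      mean = c(1.50, 1.20, 1.20, 1.30, 2.50, 1.90, 1.30, 1.20),
                      sd = 0.030, fractions = c(0.02, 0.25))),
    individuals_per_group = c(8L, 8L),
    cells = c(2000L, 3000L),
    jitter_sd = 0.015,
    marker_names = aml_markers)

  list(lps_like = lps, null = null, aml_like = aml)
}

#' Score-space footprint of a simulated population
#'
#' Locates where a generated population's cells fall on a fitted model's
#' histogram grid: the bin-coordinate box covering the central mass of that
#' population's cells (pooled over the selected individuals), dilated by the
#' smoothing radius. Used to check that leukocyte-map weight concentrates
#' where a planted group difference truly lives.
#'
#' @param model A [fit_pipeline()] fit.
#' @param cohort A [simulate_cohort()] result (dataset + truth).
#' @param population Population name or index in the generating spec.
#' @param groups Optional group labels to restrict the pooled cells to.
#' @param coverage Central fraction of the population's cells the box must
#'   cover per axis (default 0.99).
#' @return List with `lo` and `hi` (per-axis bin index bounds) and
#'   `in_region(i, j)`-style logical matrix `mask` of size F x F.
#' @export
population_region <- function(model, cohort, population, groups = NULL,
                              coverage = 0.99) {
  spec <- cohort$truth$spec
  pop_names <- vapply(spec$populations, `[[`, character(1L), "name")
  if (is.character(population)) population <- match(population, pop_names)
  if (is.na(population)) stop("unknown population")
  ds <- cohort$dataset
  keep_cells <- cohort$truth$population == population
  if (!is.null(groups)) {
    keep_cells <- keep_cells &
      as.character(ds$group_labels[ds$cell_to_individual]) %in% groups
  }
  if (!any(keep_cells)) stop("population has no cells in the selected groups")
  xcs <- apply_preprocess(ds, model$preprocess)
  scores <- project_cells(xcs, model$base)[, model$pcs, drop = FALSE]
  idx <- bin_index(scores[keep_cells, , drop = FALSE], model$grid)
  alpha <- (1 - coverage) / 2
  qs <- apply(idx, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 1L)
  pad <- ceiling(4 * model$sigma)
  lo <- pmax(1L, as.integer(floor(qs[1L, ])) - pad)
  hi <- pmin(model$grid$bins, as.integer(ceiling(qs[2L, ])) + pad)
  f <- model$grid$bins
  mask <- matrix(FALSE, f, f)
  mask[lo[1L]:hi[1L], lo[2L]:hi[2L]] <- TRUE
  list(lo = lo, hi = hi, mask = mask)
}

#' Leukocyte-map recovery of a planted group difference
#'
#' Quantifies how well the fitted map localizes a simulated group
#' difference: among the bins whose |weight| falls in the top decile of all
#' weight-carrying bins, the fraction of the *positively* weighted ones
#' (over-represented in the challenged group -- the sign under which the
#' planted excess population must appear) that lie inside the population's
#' true score-space region from [population_region()].
#'
#' @param model A fitted [fit_pipeline()] model with a 2-D histogram grid.
#' @param cohort The [simulate_cohort()] result the model was fitted on.
#' @param population Planted population name or index.
#' @param groups Groups whose cells define the true region (default: the
#'   challenged, i.e. second, group).
#' @param decile Quantile of |weight| defining the top bins (default 0.9).
#' @return Fraction in [0, 1].
#' @export
map_recovery <- function(model, cohort, population, groups = NULL,
                         decile = 0.9) {
  if (is.null(groups)) groups <- model$group_levels[2L]
  region <- population_region(model, cohort, population, groups)
  w <- refold_weights(model$top, model$design)$weights
  retained <- w != 0
  if (!any(retained)) stop("model has no weighted bins")
  cutoff <- stats::quantile(abs(w[retained]), decile, names = FALSE)
  top_pos <- retained & abs(w) >= cutoff & w > 0
  if (!any(top_pos)) return(0)
  mean(region$mask[top_pos])
}
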