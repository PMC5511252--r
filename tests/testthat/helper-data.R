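# small datasets built in code for the unit tests

# dataset from a list of per-individual cell matrices
dataset_from_blocks <- function(blocks, groups = NULL, ids = NULL) {
  if (is.null(ids)) ids <- paste0("ind", seq_along(blocks))
  if (is.null(groups)) {
    groups <- rep(c("control", "challenged"), length.out = length(blocks))
  }
  counts <- vapply(blocks, nrow, integer(1L))
  mfc_dataset(do.call(rbind, blocks),
              rep(seq_along(blocks), counts),
              ids,
              factor(groups, levels = c("control", "challenged")))
}

# tiny, strongly separable two-group cohort for fast pipeline tests
tiny_cohort_spec <- function(individuals_per_group = c(6L, 6L),
                             cells = c(300L, 400L)) {
  cohort_spec(
    populations = list(
      population_spec("common", mean = c(2.2, 2.0, 1.6, 1.8),
                      sd = 0.06, fractions = c(0.92, 0.55)),
      population_spec("marked", mean = c(1.3, 2.6, 2.4, 1.8),
                      sd = 0.03, fractions = c(0.08, 0.45))),
    individuals_per_group = individuals_per_group,
    cells = cells,
    jitter_sd = 0.015,
    marker_names = c("A", "B", "C", "D"))
}

# fast pipeline configuration for unit tests (coarser grid than the default)
tiny_config <- function(...) {
  leukomap_config(bins_f = 128L, ...)
}
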