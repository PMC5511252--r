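test_that("rank-1 data gives one component explaining everything", {
  set.seed(2)
  dir <- c(2, -1, 1) / sqrt(6)
  t_vals <- rnorm(60)
  x <- outer(t_vals, dir)
  ds <- dataset_from_blocks(list(x[1:30, ], x[31:60, ]))
  model <- fit_base_model(ds, k = 1L)
  expect_equal(model$explained_variance[1L], 1)
  aligned <- abs(sum(model$loadings[, 1L] * dir))
  expect_gt(aligned, 1 - 1e-10)
  # deterministic sign: largest-magnitude element positive
  expect_gt(model$loadings[which.max(abs(model$loadings[, 1L])), 1L], 0)
})

test_that("loadings match a dense eigendecomposition of the normalized matrix", {
  set.seed(14)
  for (trial in 1:5) {
    blocks <- list(matrix(rnorm(3 * 5), 3, 5), matrix(rnorm(7 * 5), 7, 5))
    ds <- dataset_from_blocks(blocks)
    model <- fit_base_model(ds, k = 5L)
    counts <- unname(cell_counts(ds))
    x_n <- rbind(blocks[[1]] / counts[1], blocks[[2]] / counts[2])
    ev <- oracle_pca_eigen(x_n)
    for (k in 1:5) {
      expect_gt(abs(sum(model$loadings[, k] * ev[, k])), 1 - 1e-8)
    }
  }
})

test_that("cell-count normalization removes acquisition-size bias", {
  set.seed(8)
  # two individuals with identical cell clouds, one acquired 100x deeper:
  # dividing each block by its own cell count leaves the loadings unchanged
  b <- matrix(rnorm(10 * 3), 10, 3)
  small <- dataset_from_blocks(list(b, b))
  big <- dataset_from_blocks(list(b, b[rep(1:10, 100), ]))  # N = 10 vs 1000
  l_small <- fit_base_model(small, 3L)$loadings
  l_big <- fit_base_model(big, 3L)$loadings
  expect_equal(l_big, l_small, tolerance = 1e-6)
})

test_that("loadings are orthonormal and ordered by singular value", {
  set.seed(26)
  ds <- dataset_from_blocks(lapply(1:3, function(i) matrix(rnorm(90), 30, 3)),
                            groups = c("control", "challenged", "control"))
  model <- fit_base_model(ds, 3L)
  expect_lt(max(abs(crossprod(model$loadings) - diag(3))), 1e-8)
  expect_false(is.unsorted(rev(model$singular_values)))
  expect_false(is.unsorted(rev(model$explained_variance)))
  expect_true(all(model$explained_variance >= 0 & model$explained_variance <= 1))
  expect_error(fit_base_model(ds, 4L), "between 1 and")
})

test_that("projection is linear and decomposes the data orthogonally", {
  set.seed(31)
  ds <- dataset_from_blocks(list(matrix(rnorm(40), 10, 4),
                                 matrix(rnorm(40), 10, 4)))
  model <- fit_base_model(ds, 2L)
  scores <- project_cells(ds, model)
  resid <- ds$values - scores %*% t(model$loadings)
  expect_lt(max(abs(resid %*% model$loadings)), 1e-12)
  # zero cell -> zero score; loading column -> unit score
  expect_equal(as.vector(project_cells(matrix(0, 1, 4), model)), c(0, 0))
  e1 <- project_cells(matrix(model$loadings[, 2L], 1), model)
  expect_equal(as.vector(e1), c(0, 1), tolerance = 1e-12)
  # linearity
  x <- matrix(rnorm(8), 2, 4)
  y <- matrix(rnorm(8), 2, 4)
  expect_equal(project_cells(2 * x - 3 * y, model),
               2 * project_cells(x, model) - 3 * project_cells(y, model))
})

test_that("per-individual explained variance behaves as a variance fraction", {
  set.seed(19)
  ds <- dataset_from_blocks(list(matrix(rnorm(200), 50, 4),
                                 matrix(rnorm(200), 50, 4)))
  model <- fit_base_model(ds, 4L)
  # an individual whose cells lie in span(PC1)
  t1 <- rnorm(40)
  in_span <- outer(t1, model$loadings[, 1L])
  ds2 <- dataset_from_blocks(list(in_span, matrix(rnorm(200), 50, 4)))
  model2 <- fit_base_model(ds2, 4L)
  # project the span individual on the original basis instead: use model with
  # known loadings by reusing ds2 fit only for the API, and check sums instead
  ev <- explained_variance_by_individual(ds2, model2)
  expect_true(all(ev >= 0))
  expect_equal(unname(rowSums(ev)), c(1, 1), tolerance = 1e-10)

  # fractions against the defining ratio, computed directly
  scores <- project_cells(ds, model)
  i1 <- ds$cell_to_individual == 1L
  frac <- apply(scores[i1, ], 2, var) / sum(apply(ds$values[i1, ], 2, var))
  expect_equal(unname(explained_variance_by_individual(ds, model)[1L, ]),
               unname(frac))
})

test_that("cells spanning one component give that component fraction one", {
  set.seed(61)
  b_noise <- matrix(rnorm(400), 100, 4)
  ds0 <- dataset_from_blocks(list(b_noise, matrix(rnorm(400), 100, 4)))
  model <- fit_base_model(ds0, 2L)
  t1 <- rnorm(50)
  aligned <- outer(t1, model$loadings[, 1L])
  ds <- dataset_from_blocks(list(aligned, b_noise))
  ev <- explained_variance_by_individual(ds, model)
  expect_equal(unname(ev[1L, ]), c(1, 0), tolerance = 1e-10)
})

test_that("isotropic cells spread explained variance evenly", {
  set.seed(77)
  ds <- dataset_from_blocks(list(matrix(rnorm(50000 * 4), 50000, 4),
                                 matrix(rnorm(1000 * 4), 1000, 4)))
  model <- fit_base_model(ds, 4L)
  ev <- explained_variance_by_individual(ds, model)[1L, ]
  expect_equal(unname(ev), rep(0.25, 4), tolerance = 0.02)
})

test_that("single-cell individuals are flagged with zero variance", {
  set.seed(5)
  ds <- dataset_from_blocks(list(matrix(rnorm(3), 1, 3),
                                 matrix(rnorm(30), 10, 3)))
  model <- fit_base_model(ds, 2L)
  ev <- explained_variance_by_individual(ds, model)
  expect_equal(unname(ev[1L, ]), c(0, 0))
  expect_identical(attr(ev, "degenerate"), "ind1")
})

test_that("biplot export returns matched scores, scaled loadings and errors", {
  set.seed(88)
  ds <- dataset_from_blocks(list(matrix(rnorm(60), 20, 3),
                                 matrix(rnorm(60), 20, 3)))
  model <- fit_base_model(ds, 3L)
  scores <- project_cells(ds, model)
  bp <- biplot_data(model, scores, ds, "ind2", pcs = c(1L, 3L))
  expect_identical(nrow(bp$scores), 20L)
  expect_identical(dim(bp$loadings), c(3L, 2L))
  expect_gt(bp$scale, 0)
  expect_equal(bp$loadings / bp$scale, model$loadings[, c(1L, 3L)])
  expect_error(biplot_data(model, scores, ds, "ind2", pcs = c(1L, 4L)),
               "component indices")
  expect_error(biplot_data(model, scores, ds, "nobody"), "unknown individual")
})
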