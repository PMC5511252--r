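test_that("log transform applies the minimum-shift rule", {
  ds <- dataset_from_blocks(list(matrix(c(1, 10, 100, 1000), 4, 1),
                                 matrix(c(1, 10), 2, 1)))
  out <- log_transform(ds)
  expect_identical(attr(out, "log_shift"), 0)
  expect_equal(out$values[1:4, 1], c(0, 1, 2, 3))

  ds_neg <- dataset_from_blocks(list(matrix(c(-9, 91), 2, 1),
                                     matrix(c(0, 1), 2, 1)))
  out_neg <- log_transform(ds_neg)
  expect_identical(attr(out_neg, "log_shift"), 10)
  expect_equal(out_neg$values[1:2, 1], c(0, log10(101)))

  # monotone: cell order preserved for all-positive input
  set.seed(3)
  v <- matrix(runif(40, 1, 50), 20, 2)
  dsp <- dataset_from_blocks(list(v[1:10, ], v[11:20, ]))
  outp <- log_transform(dsp)
  expect_identical(attr(outp, "log_shift"), 0)
  expect_identical(order(outp$values[, 1]), order(v[, 1]))
  expect_error(log_transform(dataset_from_blocks(list(matrix(c(1, Inf), 2, 1),
                                                      matrix(1, 1, 1)))),
               "non-finite")
})

test_that("overall centring weights individuals, not cells, equally", {
  # individual means [0,2] (10 cells) and [2,4] (1000 cells)
  b1 <- cbind(rep(0, 10), rep(2, 10))
  b2 <- cbind(rep(2, 1000), rep(4, 1000))
  ds <- dataset_from_blocks(list(b1, b2))
  model <- fit_centring(ds, "overall")
  expect_equal(unname(model$overall_mean), c(1, 3))

  centred <- apply_centring(ds, model)
  m1 <- colMeans(centred$values[centred$cell_to_individual == 1L, ])
  m2 <- colMeans(centred$values[centred$cell_to_individual == 2L, ])
  expect_equal(unname(m1), c(-1, -1))
  expect_equal(unname(m2), c(1, 1))

  single <- dataset_from_blocks(list(b1), groups = "control")
  expect_equal(fit_centring(single, "overall")$overall_mean,
               colMeans(b1), ignore_attr = TRUE)
})

test_that("overall mean equals a brute-force two-step loop over individuals", {
  set.seed(21)
  blocks <- lapply(c(5, 17, 40), function(n) matrix(rnorm(n * 3), n, 3))
  ds <- dataset_from_blocks(blocks, groups = c("control", "challenged", "control"))
  model <- fit_centring(ds, "overall")
  manual <- colMeans(do.call(rbind, lapply(blocks, colMeans)))
  expect_equal(unname(model$overall_mean), unname(manual))
  # fitted centred per-individual means average to zero across individuals
  expect_lt(max(abs(colMeans(model$individual_means) - model$overall_mean)), 1e-12)
})

test_that("centring modes behave as declared", {
  set.seed(4)
  blocks <- lapply(1:4, function(i) matrix(rnorm(12, mean = i), 6, 2))
  ds <- dataset_from_blocks(blocks)
  # per-individual: every individual's column means become exactly 0
  model_pi <- fit_centring(ds, "per_individual")
  centred <- apply_centring(ds, model_pi)
  for (i in 1:4) {
    expect_equal(unname(colMeans(centred$values[centred$cell_to_individual == i, ])),
                 c(0, 0), tolerance = 1e-12)
  }
  # applying a fitted overall model twice shifts by 2m
  model_ov <- fit_centring(ds, "overall")
  twice <- apply_centring(apply_centring(ds, model_ov), model_ov)
  manual <- sweep(ds$values, 2L, 2 * model_ov$overall_mean)
  expect_equal(twice$values, manual)
  # per_group on a held-out sample from an unseen group errors
  model_pg <- fit_centring(ds, "per_group")
  ds_new <- ds
  levels(ds_new$group_labels) <- c("control", "other")
  expect_error(apply_centring(ds_new, model_pg), "absent at fit time")
  # median centring: medians at both levels
  model_md <- fit_centring(ds, "median_overall")
  med <- apply(do.call(rbind, lapply(blocks, function(b) apply(b, 2, median))),
               2, median)
  expect_equal(unname(model_md$overall_mean), unname(med))
})

test_that("pooled scaling averages per-individual population variances", {
  # per-marker population variances 1 and 3 -> s = sqrt(2)
  b1 <- matrix(c(-1, 1), 2, 1)           # population variance 1
  b2 <- matrix(c(-sqrt(3), sqrt(3)), 2, 1)  # population variance 3
  ds <- dataset_from_blocks(list(b1, b2))
  model <- fit_scaling(ds, "pooled")
  expect_equal(unname(model$scale), sqrt(2))

  scaled <- apply_scaling(dataset_from_blocks(list(matrix(c(-2, 2), 2, 1),
                                                   matrix(c(-2, 2), 2, 1))),
                          structure(list(scale_mode = "pooled",
                                         scale = 2, marker_names = "M1"),
                                    class = "preprocess_model"))
  expect_equal(scaled$values[, 1], c(-1, 1, -1, 1))

  const <- dataset_from_blocks(list(matrix(5, 3, 1), matrix(5, 4, 1)))
  expect_error(fit_scaling(const, "pooled"), "degenerate marker")
})

test_that("scaling is invariant to duplicating an individual's cells", {
  set.seed(9)
  blocks <- list(matrix(rnorm(30), 10, 3), matrix(rnorm(60), 20, 3))
  ds <- dataset_from_blocks(blocks)
  s0 <- fit_scaling(ds, "pooled")$scale
  dup <- dataset_from_blocks(list(blocks[[1]][rep(1:10, 2), ], blocks[[2]]))
  expect_equal(fit_scaling(dup, "pooled")$scale, s0)
})

test_that("after pooled scaling the pooled standard deviation is one", {
  set.seed(12)
  blocks <- lapply(1:3, function(i) matrix(rnorm(40, sd = i), 20, 2))
  ds <- dataset_from_blocks(blocks, groups = c("control", "challenged", "control"))
  model <- fit_centring(ds, "overall")
  centred <- apply_centring(ds, model)
  model <- fit_scaling(centred, "pooled", model)
  scaled <- apply_scaling(centred, model)
  expect_equal(unname(fit_scaling(scaled, "pooled")$scale), c(1, 1))
  # scale_mode none is the identity
  model_none <- fit_scaling(centred, "none", model)
  expect_identical(apply_scaling(centred, model_none)$values, centred$values)
})

test_that("equal-weighting invariance: replicating one individual changes nothing", {
  set.seed(33)
  blocks <- lapply(1:3, function(i) matrix(rnorm(24, mean = i), 8, 3))
  ds <- dataset_from_blocks(blocks, groups = c("control", "challenged", "control"))
  m0 <- fit_centring(ds, "overall")$overall_mean
  s0 <- fit_scaling(ds, "pooled")$scale
  r3 <- dataset_from_blocks(list(blocks[[1]][rep(1:8, 3), ], blocks[[2]], blocks[[3]]),
                            groups = c("control", "challenged", "control"))
  expect_equal(fit_centring(r3, "overall")$overall_mean, m0)
  expect_equal(fit_scaling(r3, "pooled")$scale, s0)
})

test_that("preprocessing commutes with marker permutation", {
  set.seed(41)
  blocks <- lapply(1:3, function(i) matrix(runif(30, 1, 100), 10, 3))
  ds <- dataset_from_blocks(blocks, groups = c("control", "challenged", "control"))
  colnames(ds$values) <- c("A", "B", "C")
  fit <- fit_preprocess(ds, "overall", "pooled")
  perm <- c(3L, 1L, 2L)
  dsp <- ds
  dsp$values <- ds$values[, perm]
  fitp <- fit_preprocess(dsp, "overall", "pooled")
  expect_equal(fitp$data$values, fit$data$values[, perm])
})

test_that("a held-out sample identical to a training sample transforms identically", {
  set.seed(55)
  blocks <- lapply(1:4, function(i) matrix(runif(40, 1, 500), 20, 2))
  ds <- dataset_from_blocks(blocks)
  fit <- fit_preprocess(ds, "overall", "pooled")
  held <- dataset_from_blocks(blocks[2], groups = "challenged", ids = "copy")
  out <- apply_preprocess(held, fit$model)
  expect_equal(out$values,
               fit$data$values[fit$data$cell_to_individual == 2L, ],
               tolerance = 1e-12)
})
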