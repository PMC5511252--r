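# a small filtered design plus labels, built from real pipeline stages
make_design <- function(seed = 1, n_per_group = 5L, bins = 24L,
                        threshold = 1e-6) {
  co <- simulate_cohort(tiny_cohort_spec(c(n_per_group, n_per_group)), seed = seed)
  pp <- fit_preprocess(co$dataset, "overall", "pooled")
  base <- fit_base_model(pp$data, 2L)
  scores <- project_cells(pp$data, base)
  grid <- fit_bin_grid(scores, bins)
  hists <- lapply(seq_along(co$dataset$individual_ids), function(i) {
    h <- build_histogram(scores[co$dataset$cell_to_individual == i, , drop = FALSE],
                         grid, co$dataset$individual_ids[i])
    smooth_histogram(h, 2)
  })
  design <- filter_low_variance_bins(vectorize_histograms(hists), threshold)
  list(design = design, y = co$dataset$group_labels, cohort = co)
}

test_that("vectorize/refold is an exact round trip under column-major order", {
  grid <- fit_bin_grid(cbind(c(rep(0, 100), rep(1, 100)),
                             c(rep(0, 100), rep(1, 100))), bins = 3L)
  h <- structure(list(values = array(0, c(3, 3)), grid = grid, n_cells = 1L,
                      smoothed = FALSE, individual_id = "a"),
                 class = "sample_histogram")
  h$values[2, 3] <- 1
  design <- vectorize_histograms(list(h))
  expect_equal(which(design$C[1, ] != 0), 2L + (3L - 1L) * 3L)
  # refold through a stand-in model with all bins retained
  design$mask <- rep(TRUE, 9L)
  model <- list(w_top = design$C[1, ])
  class(model) <- "oplsda"
  map <- refold_weights(model, design)
  expect_equal(map$weights, h$values, ignore_attr = TRUE)
})

test_that("vectorized rows keep unit mass and grids must match", {
  d <- make_design(seed = 2)
  expect_equal(unname(rowSums(d$design$C)), rep(1, 10), tolerance = 1e-9)
  g_other <- fit_bin_grid(cbind(rnorm(100), rnorm(100)), bins = 24L)
  h_other <- build_histogram(cbind(rnorm(10), rnorm(10)), g_other)
  hs <- lapply(1:2, function(i) build_histogram(cbind(rnorm(9), rnorm(9)),
                                                d$design$grid))
  expect_error(vectorize_histograms(c(hs, list(h_other))), "same bin grid")
})

test_that("vectorize/refold round-trips random masked weight vectors", {
  set.seed(31)
  d <- make_design(seed = 3)
  mask <- d$design$mask
  w <- rnorm(sum(mask))
  model <- structure(list(w_top = w), class = "oplsda")
  map <- refold_weights(model, d$design)
  expect_equal(as.vector(map$weights)[mask], w)
  expect_true(all(as.vector(map$weights)[!mask] == 0))
})

test_that("variance filter removes constant bins and keeps varying ones", {
  grid <- fit_bin_grid(cbind(c(rep(0, 100), rep(1, 100))), bins = 4L)
  mk <- function(v) structure(list(values = array(v, 4L), grid = grid,
                                   n_cells = 10L, smoothed = FALSE,
                                   individual_id = NULL),
                              class = "sample_histogram")
  hists <- lapply(1:4, function(i) {
    mk(c(0, if (i %% 2) 0.5 else 0, if (i %% 2) 0.5 else 1, 0))
  })
  design <- filter_low_variance_bins(vectorize_histograms(hists), 1e-6)
  expect_identical(design$mask, c(FALSE, TRUE, TRUE, FALSE))

  flat <- lapply(1:3, function(i) mk(c(0.25, 0.25, 0.25, 0.25)))
  expect_error(filter_low_variance_bins(vectorize_histograms(flat), 1e-6),
               "removed every bin")
  expect_error(filter_low_variance_bins(vectorize_histograms(flat[1]), 1e-6),
               "at least 2 samples")
})

test_that("surviving-column count matches a brute-force variance scan", {
  d <- make_design(seed = 4)
  expect_identical(sum(d$design$mask),
                   oracle_surviving_columns(d$design$C,
                                            prod(d$design$grid$delta), 1e-6))
})

test_that("with no orthogonal components OPLS-DA equals NIPALS PLS1", {
  d <- make_design(seed = 5)
  C <- masked_design(d$design)
  model <- fit_oplsda(C, d$y, n_ortho = 0L)
  oracle <- oracle_nipals_pls1(C, ifelse(d$y == levels(d$y)[2L], 1, -1))
  expect_gt(abs(cor(model$t_top, oracle$scores)), 1 - 1e-8)
  # held-out predictions coincide too (up to the same sign)
  new_rows <- C[c(2L, 7L), , drop = FALSE] * 0.9
  sgn <- sign(sum(model$w_top * oracle$w))
  expect_equal(predict_oplsda(model, new_rows),
               sgn * unname(oracle$predict(new_rows)), tolerance = 1e-10)
})

test_that("coding convention fixes the sign of discriminative weights", {
  # group +1 (challenged) systematically high in bin 2
  C <- cbind(c(0.9, 0.8, 0.85, 0.2, 0.1, 0.15),
             c(0.1, 0.2, 0.15, 0.8, 0.9, 0.85))
  y <- factor(rep(c("control", "challenged"), each = 3),
              levels = c("control", "challenged"))
  model <- fit_oplsda(C, y, n_ortho = 0L)
  expect_gt(model$w_top[2L], 0)
  expect_lt(model$w_top[1L], 0)
  expect_true(all(model$t_top[4:6] > 0) && all(model$t_top[1:3] < 0))
})

test_that("orthogonal components are uncorrelated with the response and scores", {
  d <- make_design(seed = 6)
  C <- masked_design(d$design)
  for (n_ortho in 1:2) {
    model <- fit_oplsda(C, d$y, n_ortho)
    yc <- ifelse(d$y == levels(d$y)[2L], 1, -1)
    yc <- yc - mean(yc)
    for (a in seq_len(n_ortho)) {
      expect_lt(abs(cov(model$T_o[, a], yc)), 1e-8)
    }
    expect_lt(max(abs(crossprod(model$t_top, model$T_o))), 1e-8)
  }
})

test_that("training predictions reproduce t_top from undeflated data", {
  d <- make_design(seed = 7)
  C <- masked_design(d$design)
  model <- fit_oplsda(C, d$y, n_ortho = 1L)
  # predict_oplsda receives the raw (not deflated) training rows: the OSC
  # components it removes are exactly those fitted, so t_top is recovered
  expect_equal(predict_oplsda(model, C), model$t_top, tolerance = 1e-10)
})

test_that("swapping class labels negates weights and scores", {
  d <- make_design(seed = 8)
  C <- masked_design(d$design)
  m1 <- fit_oplsda(C, d$y, n_ortho = 1L)
  flipped <- factor(as.character(d$y),
                    levels = rev(levels(d$y)))
  m2 <- fit_oplsda(C, flipped, n_ortho = 1L)
  expect_equal(m2$w_top, -m1$w_top, tolerance = 1e-10)
  expect_equal(m2$t_top, -m1$t_top, tolerance = 1e-10)
})

test_that("degenerate OPLS-DA inputs raise the declared errors", {
  C <- matrix(runif(40), 8, 5)
  expect_error(fit_oplsda(C, rep("a", 8)), "two non-empty classes")
  expect_error(fit_oplsda(C[1:3, ], c("a", "a", "b")), "at least 4")
  y <- rep(c("a", "b"), 4)
  expect_error(fit_oplsda(C, y, n_ortho = -1), "n_ortho")
  expect_error(fit_oplsda(matrix(rep(c(0, 1), 4), 8, 1), y, n_ortho = 3),
               "rank error")
})

test_that("prediction scores are affine in the masked histogram", {
  d <- make_design(seed = 9)
  C <- masked_design(d$design)
  model <- fit_oplsda(C, d$y, n_ortho = 1L)
  # the chain centring -> OSC deflation -> w_top is affine: differences of
  # scores must equal the linear map applied to differences of inputs
  deflate <- diag(ncol(C))
  for (a in seq_len(model$n_ortho)) {
    deflate <- deflate %*% (diag(ncol(C)) -
                              tcrossprod(model$W_o[, a], model$P_o[, a]))
  }
  lin_w <- deflate %*% model$w_top
  h1 <- C[1L, ]
  h2 <- h1
  j <- which(model$w_top > 0)[1L]
  h2[j] <- h2[j] * 2
  h2 <- h2 / sum(h2)
  predicted_delta <- sum((h2 - h1) * lin_w)
  observed_delta <- diff(predict_oplsda(model, rbind(h1, h2)))
  expect_equal(unname(observed_delta), predicted_delta, tolerance = 1e-10)
  # the training-mean histogram row scores exactly zero
  expect_equal(predict_oplsda(model, matrix(model$mu, 1)), 0, tolerance = 1e-12)
})

test_that("the leukocyte map localizes a planted group difference", {
  co <- simulate_cohort(tiny_cohort_spec(), seed = 10)
  model <- fit_pipeline(co$dataset, tiny_config(n_ortho = 1L))
  region <- population_region(model, co, "marked", groups = "challenged")
  map <- leukocyte_map(model)
  peak <- which(abs(map$weights) == max(abs(map$weights)), arr.ind = TRUE)[1, ]
  expect_true(region$mask[peak[1L], peak[2L]] ||
                map$weights[peak[1L], peak[2L]] < 0)
  expect_gte(map_recovery(model, co, "marked"), 0.7)
  bad_design <- model$design
  bad_design$grid$k <- 3L
  expect_error(refold_weights(model$top, bad_design), "2-dimensional")
})
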