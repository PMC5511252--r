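# Independent brute-force oracles. These deliberately share no code with the
# package implementation they check.

# PCA loadings via dense eigendecomposition of the crossproduct
oracle_pca_eigen <- function(x) {
  eg <- eigen(crossprod(x), symmetric = TRUE)
  eg$vectors
}

# first-component NIPALS PLS1 on column-centred x and centred y;
# returns scores, weights and an intercept-free prediction rule
oracle_nipals_pls1 <- function(x, y) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  yc <- y - mean(y)
  w <- drop(crossprod(xc, yc))
  w <- w / sqrt(sum(w^2))
  t_scores <- drop(xc %*% w)
  list(w = w, scores = t_scores, mu = mu,
       predict = function(newx) drop(sweep(newx, 2L, mu) %*% w))
}

# per-cell loop histogram on a fitted grid (clip, half-open bins, /N)
oracle_histogram_loop <- function(scores, grid) {
  f <- grid$bins
  k <- grid$k
  h <- array(0, dim = rep(f, k))
  for (n in seq_len(nrow(scores))) {
    idx <- integer(k)
    for (d in seq_len(k)) {
      b <- floor((scores[n, d] - grid$lower[d]) / grid$delta[d]) + 1
      idx[d] <- min(max(b, 1), f)
    }
    h[matrix(idx, 1L)] <- h[matrix(idx, 1L)] + 1
  }
  h / nrow(scores)
}

# direct K-dimensional Gaussian convolution with 'reflect' boundaries,
# computed by nested loops over target and kernel offsets
oracle_convolve_kd <- function(h, sigma, truncate = 4) {
  dims <- dim(h)
  k <- length(dims)
  f <- dims[1L]
  r <- ceiling(truncate * sigma)
  w1 <- dnorm(seq(-r, r), sd = sigma)
  w1 <- w1 / sum(w1)
  reflect <- function(j) {
    if (j < 1) j <- 1 - j
    if (j > f) j <- 2 * f + 1 - j
    j
  }
  out <- array(0, dim = dims)
  targets <- as.matrix(expand.grid(lapply(dims, seq_len)))
  offsets <- as.matrix(expand.grid(rep(list(seq(-r, r)), k)))
  wk <- apply(offsets, 1L, function(o) prod(w1[o + r + 1L]))
  for (ti in seq_len(nrow(targets))) {
    tgt <- targets[ti, ]
    acc <- 0
    for (oi in seq_len(nrow(offsets))) {
      src <- vapply(seq_len(k), function(d) reflect(tgt[d] + offsets[oi, d]),
                    numeric(1L))
      acc <- acc + wk[oi] * h[matrix(src, 1L)]
    }
    out[matrix(tgt, 1L)] <- acc
  }
  out
}

# explicit loop count of columns surviving the density-variance filter
oracle_surviving_columns <- function(C, bin_volume, threshold = 1e-6) {
  keep <- 0L
  for (j in seq_len(ncol(C))) {
    d <- C[, j] / bin_volume
    v <- sum((d - mean(d))^2) / (length(d) - 1L)
    if (v >= threshold) keep <- keep + 1L
  }
  keep
}
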