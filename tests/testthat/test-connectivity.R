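brute_gfc <- function(X, sigma) {
  C <- nrow(X)
  K <- diag(1, C)
  for (i in seq_len(C - 1)) {
    for (j in (i + 1):C) {
      K[i, j] <- K[j, i] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma^2))
    }
  }
  K
}

test_that("pair_index is the lexicographic strict upper triangle", {
  pm <- pair_index(3)
  expect_equal(pm$c1, c(1, 1, 2))  # (1,2), (1,3), (2,3)
  expect_equal(pm$c2, c(2, 3, 3))
  expect_identical(nrow(pair_index(22)), 231L)
  pm10 <- pair_index(10)
  # index -> pair -> index round trip
  for (p in seq_len(nrow(pm10))) {
    hit <- which(pm10$c1 == pm10$c1[p] & pm10$c2 == pm10$c2[p])
    expect_identical(hit, p)
  }
  expect_error(pair_index(1), "at least 2")
})

test_that("median sigma matches construction and a brute-force oracle", {
  # two identical channels plus one offset by a constant vector of norm d
  L <- 16
  d <- 3.7
  base <- sin(seq_len(L))
  vals <- array(0, dim = c(2, 1, 1, 3, L))
  for (r in 1:2) {
    vals[r, 1, 1, 1, ] <- base
    vals[r, 1, 1, 2, ] <- base
    vals[r, 1, 1, 3, ] <- base + d / sqrt(L)
  }
  expect_equal(median_sigma(make_segments(vals))$sigma, d, tolerance = 1e-12)

  # random segments vs. a two-loop median/mean oracle
  set.seed(9)
  vals <- array(rnorm(4 * 2 * 3 * 6 * 20), dim = c(4, 2, 3, 6, 20))
  seg <- make_segments(vals)
  meds <- c()
  for (r in 1:4) for (b in 1:2) for (w in 1:3) {
    X <- vals[r, b, w, , ]
    dd <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      dd <- c(dd, sqrt(sum((X[i, ] - X[j, ])^2)))
    }
    meds <- c(meds, median(dd))
  }
  expect_equal(median_sigma(seg)$sigma, mean(meds), tolerance = 1e-12)

  # homogeneity: scaling the data scales sigma
  seg2 <- make_segments(2.5 * vals)
  expect_equal(median_sigma(seg2)$sigma, 2.5 * median_sigma(seg)$sigma,
               tolerance = 1e-12)

  # training-mask restriction
  s13 <- median_sigma(seg, trials = c(1, 3))
  meds13 <- meds[rep(1:4, each = 6) %in% c(1, 3)]
  expect_equal(s13$sigma, mean(meds13), tolerance = 1e-12)

  expect_error(median_sigma(make_segments(array(0, c(2, 1, 1, 3, 8)))),
               "degenerate")
})

test_that("Gaussian kernel connectivity matches its closed form and oracle", {
  # zero distance and the exp(-1) point
  x <- rnorm(32)
  X <- rbind(x, x, x + sqrt(2) / sqrt(32))  # ||x1 - x3||^2 = 2, sigma = 1
  K <- gaussian_kernel_fc(X, sigma = 1)
  expect_equal(K[1, 2], 1)
  expect_equal(K[1, 3], exp(-1), tolerance = 1e-12)

  set.seed(13)
  for (rep in 1:5) {
    X <- matrix(rnorm(8 * 64), 8, 64)
    sigma <- runif(1, 0.5, 3)
    expect_equal(gaussian_kernel_fc(X, sigma), brute_gfc(X, sigma),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # monotone decreasing in distance
  base <- rnorm(16)
  offs <- c(0.1, 0.5, 1, 2, 4)
  vals <- sapply(offs, function(d) {
    gaussian_kernel_fc(rbind(base, base + d / 4), sigma = 1)[1, 2]
  })
  expect_true(all(diff(vals) < 0))

  # invariant to adding the same vector to both channels
  shift <- rnorm(16)
  X <- matrix(rnorm(2 * 16), 2, 16)
  expect_equal(gaussian_kernel_fc(X, 1)[1, 2],
               gaussian_kernel_fc(sweep(X, 2, -shift), 1)[1, 2],
               tolerance = 1e-12)

  expect_error(gaussian_kernel_fc(matrix(c(1, NA, 2, 3), 2), 1), "non-finite")
  expect_error(gaussian_kernel_fc(matrix(rnorm(4), 2), 0), "sigma")
})

test_that("cross-correlation connectivity is the Pearson matrix", {
  x <- rnorm(64)
  expect_equal(cross_correlation_fc(rbind(x, x))[1, 2], 1)
  expect_equal(cross_correlation_fc(rbind(x, -x))[1, 2], -1)

  set.seed(17)
  X <- matrix(rnorm(6 * 128), 6, 128)
  R <- cross_correlation_fc(X)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      xi <- X[i, ]; xj <- X[j, ]
      r_oracle <- mean((xi - mean(xi)) * (xj - mean(xj))) /
        (sqrt(mean((xi - mean(xi))^2)) * sqrt(mean((xj - mean(xj))^2)))
      expect_equal(R[i, j], r_oracle, tolerance = 1e-12)
    }
  }

  # invariant to positive-slope affine maps per channel
  X2 <- X
  X2[1, ] <- 3.2 * X2[1, ] + 7
  expect_equal(cross_correlation_fc(X2), R, tolerance = 1e-12)

  expect_error(cross_correlation_fc(rbind(x, rep(1, 64))), "zero-variance")
})

test_that("phase locking is 1 for constant phase shifts and bounded", {
  fs <- 128
  t <- (0:255) / fs
  x1 <- sin(2 * pi * 8 * t)
  x2 <- sin(2 * pi * 8 * t + 0.7)
  P <- phase_locking_fc(rbind(x1, x1, x2))
  expect_equal(P[1, 2], 1, tolerance = 1e-9)
  expect_gt(P[1, 3], 0.99)

  # amplitude-scaling invariance
  expect_equal(phase_locking_fc(rbind(5 * x1, 0.2 * x2))[1, 2], P[1, 3],
               tolerance = 1e-9)

  # independent white noise decorrelates
  set.seed(23)
  plvs <- replicate(50, phase_locking_fc(matrix(rnorm(2 * 512), 2, 512))[1, 2])
  expect_lt(mean(plvs), 0.15)

  expect_error(phase_locking_fc(matrix(rnorm(2 * 4), 2, 4)), "at least 8")
  expect_error(phase_locking_fc(rbind(x1, rep(2, 256))), "constant channel")
})

test_that("analytic signal recovers amplitude and phase of a tone", {
  fs <- 128
  t <- (0:511) / fs
  x <- 2 * cos(2 * pi * 10 * t + 0.4)
  a <- analytic_signal(x)
  expect_equal(Re(a), x, tolerance = 1e-10)
  mid <- 100:400
  expect_lt(max(abs(Mod(a[mid]) - 2)), 0.01)
})

test_that("connectivity tensors have the contracted shape and match loops", {
  set.seed(29)
  vals <- array(rnorm(4 * 2 * 3 * 5 * 32), dim = c(4, 2, 3, 5, 32))
  seg <- make_segments(vals)
  for (meas in c("gfc", "ccf", "plv")) {
    ct <- connectivity_tensor(seg, meas, sigma = if (meas == "gfc") 2)
    expect_identical(dim(ct$values), c(4L, 2L, 3L, 10L))
    # loop oracle over all splits
    fun <- switch(meas,
                  gfc = function(X) gaussian_kernel_fc(X, 2),
                  ccf = cross_correlation_fc,
                  plv = phase_locking_fc)
    pm <- pair_index(5)
    for (r in 1:4) for (b in 1:2) for (w in 1:3) {
      M <- fun(vals[r, b, w, , ])
      expect_equal(ct$values[r, b, w, ], M[cbind(pm$c1, pm$c2)],
                   tolerance = 1e-12)
    }
  }
  expect_error(connectivity_tensor(seg, "gfc"), "sigma is required")
})

test_that("duplicated channels give an all-ones Gaussian tensor", {
  base <- array(rnorm(3 * 1 * 2 * 1 * 16), dim = c(3, 1, 2, 1, 16))
  vals <- array(0, dim = c(3, 1, 2, 4, 16))
  for (ch in 1:4) vals[, , , ch, ] <- base[, , , 1, ]
  ct <- connectivity_tensor(make_segments(vals), "gfc", sigma = 1)
  expect_equal(max(abs(ct$values - 1)), 0)
})

test_that("all three measures respect their bounds on fuzzed windows", {
  set.seed(31)
  for (i in 1:1000) {
    X <- matrix(rnorm(4 * 16, sd = runif(1, 0.01, 100)), 4, 16)
    g <- gaussian_kernel_fc(X, sigma = runif(1, 0.1, 50))
    expect_true(all(g > 0 & g <= 1))
    r <- cross_correlation_fc(X)
    expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
    p <- phase_locking_fc(X)
    expect_true(all(p >= 0 & p <= 1 + 1e-12))
  }
})

test_that("measures are equivariant under channel relabeling", {
  set.seed(37)
  X <- matrix(rnorm(5 * 64), 5, 64)
  perm <- c(3, 1, 5, 2, 4)
  for (fun in list(function(Z) gaussian_kernel_fc(Z, 1.5),
                   cross_correlation_fc, phase_locking_fc)) {
    M <- fun(X)
    Mp <- fun(X[perm, ])
    expect_equal(Mp, M[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("vectorize produces the band-major layout and inverts", {
  set.seed(43)
  vals <- array(rnorm(4 * 2 * 3 * 5 * 16), dim = c(4, 2, 3, 5, 16))
  ct <- connectivity_tensor(make_segments(vals), "ccf")
  X <- vectorize(ct)
  expect_identical(dim(X), c(4L, 60L))
  cm <- attr(X, "colmap")
  # unravel oracle: column k = ((band-1) * W + window - 1) * P + pair
  for (k in sample(60, 20)) {
    band <- (k - 1) %/% (3 * 10) + 1
    win <- ((k - 1) %/% 10) %% 3 + 1
    pair <- (k - 1) %% 10 + 1
    expect_equal(c(cm$band[k], cm$window[k], cm$pair[k]),
                 c(band, win, pair))
    expect_equal(X[, k], ct$values[, band, win, pair])
  }
  ct2 <- devectorize(X, ct)
  expect_equal(ct2$values, ct$values)
  # full matrices carry unit diagonal and symmetry
  M <- fc_matrix(ct, 2, 1, 3)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 5), ignore_attr = TRUE)

  td <- tidy(ct)
  expect_identical(nrow(td), 240L)
  row <- td[td$trial == 2 & td$band == 1 & td$window == 3 & td$pair == 4, ]
  expect_equal(row$value, ct$values[2, 1, 3, 4])
})
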