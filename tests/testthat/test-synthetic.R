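test_that("generation is bit-reproducible given the seed", {
  sp <- synthetic_spec(C = 4, trials_per_class = 5, fs = 128, duration = 1,
                       seed = 21,
                       effects = tibble::tibble(f_low = 8, f_high = 12,
                                                t_start = 0, t_end = 1,
                                                c1 = 1L, c2 = 2L, gain = 0.8))
  g1 <- generate_synthetic(sp)
  g2 <- generate_synthetic(sp)
  expect_identical(g1$epochs$data, g2$epochs$data)
  expect_identical(g1$epochs$labels, g2$epochs$labels)
  g3 <- generate_synthetic(synthetic_spec(C = 4, trials_per_class = 5,
                                          fs = 128, duration = 1, seed = 22))
  expect_false(identical(g1$epochs$data, g3$epochs$data))
})

test_that("spec validation rejects infeasible effects", {
  expect_error(synthetic_spec(fs = 100, effects = tibble::tibble(
    f_low = 40, f_high = 60, t_start = 0, t_end = 1, c1 = 1L, c2 = 2L,
    gain = 0.5)), "Nyquist")
  expect_error(synthetic_spec(duration = 1, effects = tibble::tibble(
    f_low = 8, f_high = 12, t_start = 0, t_end = 2, c1 = 1L, c2 = 2L,
    gain = 0.5)))
  expect_error(synthetic_spec(C = 2, effects = tibble::tibble(
    f_low = 8, f_high = 12, t_start = 0, t_end = 1, c1 = 1L, c2 = 5L,
    gain = 0.5)))
})

test_that("background rhythm energy concentrates in its nominal band", {
  sp <- synthetic_spec(C = 2, trials_per_class = 2, fs = 128, duration = 4,
                       snr_db = 40,  # nearly noiseless
                       effects = tibble::tibble(f_low = numeric(),
                                                f_high = numeric(),
                                                t_start = numeric(),
                                                t_end = numeric(),
                                                c1 = integer(), c2 = integer(),
                                                gain = numeric()),
                       background = tibble::tibble(f_low = 8, f_high = 12),
                       seed = 23)
  g <- generate_synthetic(sp)
  x <- g$epochs$data[1, 1, ]
  banded <- apply_bank(g$epochs, filter_bank(8, 12, 4, 4))
  in_band <- sum(banded$values[1, 1, 1, ]^2)
  expect_gt(in_band / sum(x^2), 0.7)
})

test_that("zero coupling leaves the class GFC distributions indistinguishable", {
  for (seed in c(31, 32, 33)) {
    sp <- synthetic_spec(C = 3, trials_per_class = 200, fs = 128,
                         duration = 1,
                         effects = tibble::tibble(f_low = 8, f_high = 12,
                                                  t_start = 0, t_end = 1,
                                                  c1 = 1L, c2 = 2L, gain = 0),
                         seed = seed)
    g <- generate_synthetic(sp)
    seg <- segment(apply_bank(g$epochs, filter_bank(8, 12, 4, 4)),
                   window_spec(1, 0))
    sig <- median_sigma(seg)
    ct <- connectivity_tensor(seg, "gfc", sigma = sig)
    vals <- ct$values[, 1, 1, 1]  # pair (1,2)
    ks <- suppressWarnings(ks.test(vals[g$epochs$labels == 0],
                                   vals[g$epochs$labels == 1]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("strong coupling separates the target split by many standard errors", {
  g <- generate_synthetic(strong_coupling_spec(seed = 35,
                                               trials_per_class = 50))
  bank <- filter_bank(4, 16, 4, 2)
  seg <- segment(apply_bank(g$epochs, bank), window_spec(1, 0.75))
  sig <- median_sigma(seg)
  ct <- connectivity_tensor(seg, "gfc", sigma = sig)
  y <- g$epochs$labels
  vals <- ct$values[, 3, 5, 1]  # band [8,12], central window, pair (1,2)
  se <- sqrt(var(vals[y == 1]) / sum(y == 1) + var(vals[y == 0]) / sum(y == 0))
  expect_gt((mean(vals[y == 1]) - mean(vals[y == 0])) / se, 3)
})

test_that("ground truth resolves to overlap-consistent feature columns", {
  mk_truth <- function(effects, fs = 128, duration = 2, C = 4) {
    structure(list(effects = tibble::as_tibble(effects), fs = fs,
                   duration = duration, C = C, seed = 1L),
              class = "ground_truth")
  }
  # non-overlapped bank, non-overlapped windows, exactly-aligned effect:
  # exactly one column for the effect pair
  bank <- filter_bank(4, 16, 4, 4)        # [4,8] [8,12] [12,16]
  w <- window_spec(1, 0)                  # [0,1], [1,2]
  tr <- mk_truth(tibble::tibble(f_low = 8, f_high = 12, t_start = 1,
                                t_end = 2, c1 = 1L, c2 = 2L, gain = 1))
  cols <- resolve_truth(tr, bank, w)
  expect_length(cols, 1L)
  P <- 6L; W <- 2L
  expect_identical(cols, (2L - 1L) * W * P + (2L - 1L) * P + 1L)

  # effect spanning two bands gives at least two columns
  tr2 <- mk_truth(tibble::tibble(f_low = 7, f_high = 9, t_start = 0,
                                 t_end = 1, c1 = 2L, c2 = 4L, gain = 1))
  expect_gte(length(resolve_truth(tr2, bank, w)), 2L)

  # membership matches a brute-force interval-overlap scan
  bank2 <- filter_bank(4, 20, 4, 2)
  w2 <- window_spec(0.5, 0.75)
  set.seed(167)
  for (i in 1:20) {
    f_lo <- runif(1, 4, 14)
    t_lo <- runif(1, 0, 1.4)
    ef <- tibble::tibble(f_low = f_lo, f_high = f_lo + runif(1, 0.5, 4),
                         t_start = t_lo, t_end = t_lo + runif(1, 0.1, 0.6),
                         c1 = 1L, c2 = 3L, gain = 1)
    tr3 <- mk_truth(ef)
    got <- tryCatch(resolve_truth(tr3, bank2, w2), error = function(e) integer(0))
    # brute force
    L <- round(0.5 * 128); step <- round(L * 0.25)
    starts <- seq(0, 2 * 128 - L, by = step)
    pm <- pair_index(4)
    p <- pm$pair[pm$c1 == 1 & pm$c2 == 3]
    W3 <- length(starts); P3 <- 6
    want <- integer(0)
    for (b in seq_len(nrow(bank2$bands))) {
      for (wi in seq_len(W3)) {
        band_ov <- min(bank2$bands$f_high[b], ef$f_high) -
          max(bank2$bands$f_low[b], ef$f_low)
        win_ov <- min((starts[wi] + L) / 128, ef$t_end) -
          max(starts[wi] / 128, ef$t_start)
        if (band_ov > 1e-9 && win_ov > 1e-9) {
          want <- c(want, (b - 1L) * W3 * P3 + (wi - 1L) * P3 + p)
        }
      }
    }
    expect_identical(got, sort(unique(as.integer(want))))
  }

  # an orphan effect is an error naming the effect
  tr4 <- mk_truth(tibble::tibble(f_low = 17, f_high = 18, t_start = 0,
                                 t_end = 1, c1 = 1L, c2 = 2L, gain = 1))
  expect_error(resolve_truth(tr4, bank, w), "overlaps no")
})

test_that("recovery of a truth-supported model is perfect", {
  v <- numeric(30)
  truth <- c(2, 11, 29)
  v[truth] <- c(1, 2, 3)
  m <- make_relmodel(v)
  expect_equal(recovery_score(m, truth, length(truth)), 1)
})
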