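test_that("the embedding is deterministic and validates perplexity", {
  set.seed(137)
  X <- matrix(rnorm(8 * 20), 8, 20)
  e1 <- embed_subjects(X, seed = 5, max_iter = 200)
  e2 <- embed_subjects(X, seed = 5, max_iter = 200)
  expect_identical(e1, e2)
  expect_identical(nrow(e1), 8L)
  expect_error(embed_subjects(X, perplexity = 8), "below the subject count")
  expect_error(embed_subjects(X[1:3, ]), "at least 4")
})

test_that("duplicated subjects embed to near-coincident points", {
  set.seed(139)
  X <- matrix(rnorm(8 * 15), 8, 15)
  X[2, ] <- X[1, ]
  e <- embed_subjects(X, seed = 3, perplexity = 2)
  d <- as.matrix(dist(cbind(e$dim1, e$dim2)))
  expect_lt(d[1, 2], 0.1 * max(d))
})

test_that("orthogonal relevance supports separate in the embedding", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(200 + seed)
    n <- 6
    A <- cbind(matrix(abs(rnorm(n * 10, 1)), n, 10), matrix(0, n, 10))
    B <- cbind(matrix(0, n, 10), matrix(abs(rnorm(n * 10, 1)), n, 10))
    X <- rbind(A, B)
    e <- embed_subjects(X, seed = seed, perplexity = 3)
    d <- as.matrix(dist(cbind(e$dim1, e$dim2)))
    grp <- rep(1:2, each = n)
    within <- mean(d[grp == 1, grp == 1][upper.tri(diag(n))]) / 2 +
      mean(d[grp == 2, grp == 2][upper.tri(diag(n))]) / 2
    between <- mean(d[grp == 1, grp == 2])
    if (between > within) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("planted subject groups are recovered with the right ranking", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    centers <- list(c(0, 0), c(6, 6), c(-6, 6))
    acc_means <- c(0.9, 0.7, 0.5)
    coords <- do.call(rbind, lapply(1:3, function(g) {
      cbind(rnorm(6, centers[[g]][1], 0.5), rnorm(6, centers[[g]][2], 0.5))
    }))
    accs <- rep(acc_means, each = 6) + rnorm(18, sd = 0.02)
    ca <- cluster_subjects(coords, accs, k = 3, seed = seed)
    grp <- as.character(ca$assignments$group)
    ok <- length(unique(grp[1:6])) == 1 &&
      length(unique(grp[7:12])) == 1 &&
      length(unique(grp[13:18])) == 1 &&
      grp[1] == "I" && grp[7] == "II" && grp[13] == "III"
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("group ranking is non-increasing and degenerate input warns", {
  set.seed(149)
  coords <- matrix(rnorm(24), 12, 2)
  accs <- runif(12, 0.4, 0.95)
  ca <- cluster_subjects(coords, accs, k = 3, seed = 2)
  expect_true(all(diff(ca$group_summary$mean_accuracy) <= 0))
  expect_identical(levels(ca$assignments$group), c("I", "II", "III"))
  expect_identical(nrow(ca$assignments), 12L)

  same <- matrix(1, 5, 2)
  expect_warning(ca0 <- cluster_subjects(same, rep(0.7, 5), k = 3, seed = 1),
                 "degenerate")
  expect_identical(nrow(ca0$assignments), 5L)

  expect_error(cluster_subjects(coords[1:2, ], accs[1:2], k = 3), "exceeds")
})

test_that("group switch counts match brute-force adjacent comparison", {
  mk <- function(groups, accs) {
    structure(list(assignments = tibble::tibble(
      subject = paste0("S", 1:4), dim1 = 0, dim2 = 0,
      accuracy = accs, group = factor(groups, levels = c("I", "II", "III"))),
      k = 3, seed = 1), class = "cluster_assignment")
  }
  a1 <- mk(c("I", "II", "III", "I"), c(.9, .7, .5, .9))
  a2 <- mk(c("I", "II", "III", "I"), c(.9, .7, .5, .9))
  a3 <- mk(c("I", "III", "III", "II"), c(.9, .5, .5, .7))
  sw <- group_switch_matrix(list(`0.5` = a1, `1` = a2, `2` = a3))
  expect_equal(sw$switches, c(0L, 1L, 0L, 1L))
  # brute force across adjacent columns
  M <- as.matrix(sw[, c("0.5", "1", "2")])
  expect_equal(sw$switches,
               as.integer(rowSums(M[, -1] != M[, -ncol(M)])))
  sw1 <- group_switch_matrix(list(a1, a2))
  expect_equal(sw1$switches, rep(0L, 4))

  a_bad <- mk(c("I", "II", "III", "I"), c(.9, .7, .5, .9))
  a_bad$assignments$subject <- paste0("T", 1:4)
  expect_error(group_switch_matrix(list(a1, a_bad)), "subject sets differ")
})

test_that("channel relevance accumulates pair mass and conserves totals", {
  C <- 5
  P <- C * (C - 1) / 2
  rel <- numeric(P)
  rel[2] <- 0.8  # pair (1,3)
  ch <- channel_relevance(rel, C = C)
  expect_equal(ch$relevance, c(1, 0, 1, 0, 0))

  # uniform relevance flagged uniform
  chu <- channel_relevance(rep(0.3, P), C = C)
  expect_true(attr(chu, "uniform"))
  expect_true(all(chu$relevance == chu$relevance[1]))

  # random input matches a two-loop oracle; mass conserved pre-normalization
  set.seed(151)
  rel <- runif(choose(8, 2))
  ch8 <- channel_relevance(rel, C = 8)
  pm <- pair_index(8)
  raw <- numeric(8)
  for (c in 1:8) {
    for (p in seq_len(nrow(pm))) {
      if (pm$c1[p] == c || pm$c2[p] == c) raw[c] <- raw[c] + rel[p]
    }
  }
  expect_equal(attr(ch8, "raw"), raw, tolerance = 1e-12)
  expect_equal(sum(raw), 2 * sum(rel), tolerance = 1e-12)
  expect_equal(ch8$relevance, (raw - min(raw)) / (max(raw) - min(raw)),
               tolerance = 1e-12)
})

test_that("top links keep strictly-above-percentile pairs, sorted", {
  rel <- c(1, rep(0, 99))
  # needs C with C(C-1)/2 = 100: use a bare tibble instead
  pr <- tibble::tibble(pair = 1:100, c1 = 1L, c2 = 2L, relevance = rel)
  tl <- top_links(pr, percentile = 99)
  expect_identical(nrow(tl), 1L)
  expect_equal(tl$weight, 1)

  # all-equal weights: nothing strictly above the percentile
  pr$relevance <- 0.5
  expect_identical(nrow(top_links(pr, 99)), 0L)

  # random weights match a sort-and-threshold oracle
  set.seed(157)
  rel <- runif(231)
  pm <- pair_index(22)
  pr <- tibble::tibble(pair = pm$pair, c1 = pm$c1, c2 = pm$c2,
                       relevance = rel)
  tl <- top_links(pr, percentile = 99)
  thr <- quantile(rel, 0.99, type = 7, names = FALSE)
  expect_setequal(tl$weight, rel[rel > thr])
  expect_true(all(diff(tl$weight) <= 0))
  expect_error(top_links(pr, percentile = 0), "strictly between")
  expect_error(top_links(pr, percentile = 100), "strictly between")
})

test_that("the interpretation layer is a pure function of its inputs", {
  set.seed(163)
  X <- matrix(abs(rnorm(10 * 30)), 10, 30)
  accs <- runif(10, 0.5, 0.95)
  e1 <- embed_subjects(X, seed = 9, perplexity = 3, max_iter = 150)
  e2 <- embed_subjects(X, seed = 9, perplexity = 3, max_iter = 150)
  c1 <- cluster_subjects(e1, accs, seed = 4)
  c2 <- cluster_subjects(e2, accs, seed = 4)
  expect_identical(c1$assignments, c2$assignments)
})

test_that("topography reports bundle channels, links and threshold", {
  cm <- make_colmap(2, 2, 6)
  v <- numeric(nrow(cm))
  v[cm$column[cm$pair == 1]] <- 2   # pair (1,2) dominates
  v[cm$column[cm$pair == 4][1]] <- 0.1
  m <- make_relmodel(v, cm)
  topo <- topography_report(m, montage = ring_montage(6), percentile = 90)
  expect_identical(nrow(topo$channels), 6L)
  expect_true(all(c("x", "y") %in% names(topo$channels)))
  expect_true(all(topo$links$weight > topo$threshold))
  expect_identical(topo$links$c1[1], 1L)
  expect_identical(topo$links$c2[1], 2L)
  p <- autoplot(topo)
  expect_s3_class(p, "ggplot")
})
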