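# Exact t-SNE for small cohorts (tens of subjects): perplexity calibration
# by per-point binary search, symmetrized affinities, early exaggeration,
# momentum gradient descent on the KL divergence. Deterministic given the
# seed. O(n^2) per iteration, which is the right trade-off at cohort scale.

perplexity_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 60L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf; beta_max <- Inf
    di <- D2[i, -i]
    for (tr in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { H <- 0; p[] <- 1 / length(p) } else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else { beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

tsne_exact <- function(X, dims = 2L, perplexity = 5, seed = 1L,
                       max_iter = 500L, eta = 100, exaggeration = 4,
                       exaggerate_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- perplexity_affinities(D2, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  inc <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  Pex <- P * exaggeration
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    Puse <- if (iter <= exaggerate_iter) Pex else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    W <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
    if (iter == 250L) momentum <- 0.8
  }
  Y
}
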