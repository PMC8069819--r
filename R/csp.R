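#' Common-spatial-pattern style projection of connectivity matrices
#'
#' Classic CSP solves the generalized eigenproblem
#' `Sigma_1 w = lambda (Sigma_1 + Sigma_2) w` on class-conditional
#' covariance matrices; here the covariance can be replaced by any
#' symmetric per-trial functional-connectivity matrix. Eigenvalues lie in
#' `[0, 1]` and swapping the class labels maps them to `1 - lambda`.
#' The `K` eigenvectors with the largest eigenvalues are kept
#' (`K = 3` by default).
#'
#' @param mats per-trial symmetric matrices: an R x C x C array or a list
#'   of C x C matrices.
#' @param labels per-trial class labels in `{0, 1}`.
#' @param K number of spatial components to keep (default 3).
#' @param ridge ridge added to each class mean (`ridge * I`); default
#'   `1e-6 * trace(mean matrix) / C`, which keeps indefinite FC matrices
#'   (e.g. PLV) numerically safe.
#' @return A `csp_model`: list with `filters` (C x K), `eigenvalues`
#'   (length K, descending, in `[0, 1]`), `class_means`, `ridge`, `K`.
#' @export
fit_csp <- function(mats, labels, K = 3L, ridge = NULL) {
  if (is.list(mats)) {
    mats <- simplify2array(mats)          # C x C x R
    mats <- aperm(mats, c(3L, 1L, 2L))    # R x C x C
  }
  stopifnot(is.array(mats), length(dim(mats)) == 3L,
            dim(mats)[2L] == dim(mats)[3L])
  R <- dim(mats)[1L]; C <- dim(mats)[2L]
  labels <- coerce_labels(labels)
  stopifnot(length(labels) == R)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit CSP", call. = FALSE)
  }
  K <- as.integer(K)
  stopifnot(K >= 1L, K <= C)
  sym_err <- max(abs(mats - aperm(mats, c(1L, 3L, 2L))))
  if (sym_err > 1e-8) {
    stop("per-trial matrices are not symmetric (max asymmetry ",
         format(sym_err), ")", call. = FALSE)
  }
  S1 <- apply(mats[labels == 1L, , , drop = FALSE], c(2L, 3L), mean)
  S0 <- apply(mats[labels == 0L, , , drop = FALSE], c(2L, 3L), mean)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(S1 + S0)) / (2 * C)
  S1 <- S1 + ridge * diag(C)
  S0 <- S0 + ridge * diag(C)
  Sc <- S1 + S0
  ec <- eigen(Sc, symmetric = TRUE)
  if (min(ec$values) <= 1e-12 * max(abs(ec$values))) {
    stop("composite matrix singular even after ridge; increase `ridge`",
         call. = FALSE)
  }
  Wh <- ec$vectors %*% diag(1 / sqrt(ec$values), C) %*% t(ec$vectors)
  M <- Wh %*% S1 %*% Wh
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)       # descending eigenvalues
  lam <- pmin(pmax(em$values, 0), 1)
  filt <- Wh %*% em$vectors
  # deterministic sign: largest-magnitude entry of each filter is positive
  for (k in seq_len(C)) {
    j <- which.max(abs(filt[, k]))
    if (filt[j, k] < 0) filt[, k] <- -filt[, k]
  }
  structure(list(filters = filt[, seq_len(K), drop = FALSE],
                 eigenvalues = lam[seq_len(K)],
                 class_means = list(`0` = S0, `1` = S1),
                 ridge = ridge, K = K, C = C),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat("<csp_model> ", x$C, " channels -> ", x$K, " components; eigenvalues: ",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project a connectivity matrix through a fitted CSP model
#'
#' Computes `M' = W^T M W` (K x K) and returns its upper triangle
#' including the diagonal, a length `K(K+1)/2` pattern vector.
#'
#' @param M symmetric C x C matrix.
#' @param model a `csp_model`.
#' @return Numeric vector of length `K(K+1)/2` (column-major upper
#'   triangle of the projected matrix).
#' @export
project_features <- function(M, model) {
  stopifnot(inherits(model, "csp_model"))
  M <- as.matrix(M)
  if (nrow(M) != model$C || ncol(M) != model$C) {
    stop("matrix dimension ", nrow(M), " does not match model (", model$C, ")",
         call. = FALSE)
  }
  Mp <- t(model$filters) %*% M %*% model$filters
  Mp <- (Mp + t(Mp)) / 2
  Mp[upper.tri(Mp, diag = TRUE)]
}

#' CSP pattern-vector features for every (band, window) split
#'
#' Fits one CSP model per (band, window) split on the training trials'
#' FC matrices and concatenates the projected pattern vectors of all
#' splits into one feature row per trial.
#'
#' @param ct a `connectivity_tensor`.
#' @param train trials used for fitting (indices or logical); default all.
#' @param K components per split.
#' @return A list with `X` (R x `B*W*K(K+1)/2` matrix with a `colmap`
#'   attribute) and `models` (list of fitted `csp_model`s by split).
#' @export
csp_feature_matrix <- function(ct, train = NULL, K = 3L) {
  stopifnot(inherits(ct, "connectivity_tensor"))
  d <- dim(ct$values)
  R <- d[1L]; B <- d[2L]; W <- d[3L]
  train <- if (is.null(train)) seq_len(R) else seq_len(R)[train]
  pk <- K * (K + 1L) / 2L
  X <- matrix(0, R, B * W * pk)
  models <- vector("list", B * W)
  col <- 0L
  for (b in seq_len(B)) {
    for (w in seq_len(W)) {
      mats <- lapply(seq_len(R), function(r) fc_matrix(ct, r, b, w))
      arr <- aperm(simplify2array(mats), c(3L, 1L, 2L))
      m <- fit_csp(arr[train, , , drop = FALSE], ct$labels[train], K = K)
      models[[(b - 1L) * W + w]] <- m
      for (r in seq_len(R)) {
        X[r, col + seq_len(pk)] <- project_features(mats[[r]], m)
      }
      col <- col + pk
    }
  }
  colmap <- tibble::tibble(
    column = seq_len(B * W * pk),
    band = rep(seq_len(B), each = W * pk),
    window = rep(rep(seq_len(W), each = pk), times = B),
    component = rep(seq_len(pk), times = B * W)
  )
  attr(X, "colmap") <- colmap
  list(X = X, models = models)
}
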