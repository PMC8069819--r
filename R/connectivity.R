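#' Channel-pair index map
#'
#' Connectivity matrices are symmetric with a unit diagonal, so only the
#' strict upper triangle is stored: pairs `(c, c')` with `c < c'` in
#' lexicographic order. This map is the single source of truth for
#' vectorized feature layouts.
#'
#' @param C number of channels (>= 2).
#' @param channel_names optional channel names to attach.
#' @return A tibble with columns `pair`, `c1`, `c2` (1-based channel
#'   indices, `c1 < c2`) and, if names were given, `ch1`, `ch2`;
#'   `C * (C - 1) / 2` rows.
#' @export
pair_index <- function(C, channel_names = NULL) {
  if (!is.numeric(C) || C < 2) stop("need at least 2 channels", call. = FALSE)
  C <- as.integer(C)
  c1 <- rep(seq_len(C - 1L), times = (C - 1L):1L)
  c2 <- unlist(lapply(seq_len(C - 1L), function(i) (i + 1L):C))
  out <- tibble::tibble(pair = seq_along(c1), c1 = c1, c2 = c2)
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == C)
    out$ch1 <- channel_names[c1]
    out$ch2 <- channel_names[c2]
  }
  out
}

#' Gaussian-kernel bandwidth by the averaged median heuristic
#'
#' For every (trial, band, window) split the median of the
#' `C(C-1)/2` pairwise Euclidean distances between windowed channel series
#' is taken; sigma is the mean of these medians over the selected splits.
#' Computed on training trials only when a mask is given, so no test
#' information leaks into the kernel bandwidth.
#'
#' @param segments a `tf_segments` from [segment()].
#' @param trials logical or integer vector selecting the (training) trials;
#'   default all.
#' @return A `sigma_estimate`: list with `sigma`, `n_splits` and `scope`.
#' @export
median_sigma <- function(segments, trials = NULL) {
  stopifnot(inherits(segments, "tf_segments"))
  d <- dim(segments$values)
  idx <- if (is.null(trials)) seq_len(d[1L]) else seq_len(d[1L])[trials]
  if (length(idx) < 1L) stop("trial mask selects no trials", call. = FALSE)
  meds <- numeric(0)
  for (r in idx) {
    for (b in seq_len(d[2L])) {
      for (w in seq_len(d[3L])) {
        X <- segments$values[r, b, w, , ]
        meds <- c(meds, stats::median(stats::dist(X)))
      }
    }
  }
  sigma <- mean(meds)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate input: median pairwise distance is zero ",
         "(all-zero or duplicated channels?)", call. = FALSE)
  }
  structure(list(sigma = sigma, n_splits = length(meds),
                 scope = sprintf("%d trials x %d bands x %d windows",
                                 length(idx), d[2L], d[3L])),
            class = "sigma_estimate")
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat("<sigma_estimate> sigma = ", format(x$sigma), " (", x$scope, ")\n",
      sep = "")
  invisible(x)
}

as_sigma <- function(sigma) {
  if (inherits(sigma, "sigma_estimate")) sigma <- sigma$sigma
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a positive finite scalar", call. = FALSE)
  }
  sigma
}

#' Single-window functional connectivity matrices
#'
#' Three pairwise channel dependency measures on one windowed,
#' band-filtered segment (a channels x samples matrix):
#'
#' * `gaussian_kernel_fc()`: Gaussian functional connectivity,
#'   `exp(-||x_c - x_c'||^2 / (2 sigma^2))`, values in `(0, 1]`;
#' * `cross_correlation_fc()`: Pearson correlation of the two windowed
#'   series, values in `[-1, 1]`;
#' * `phase_locking_fc()`: phase-locking value, the modulus of the
#'   time-averaged complex phase difference between the channels'
#'   analytic-signal phases, values in `[0, 1]`.
#'
#' All three return a symmetric C x C matrix with unit diagonal.
#'
#' @param X numeric matrix, channels x samples.
#' @param sigma Gaussian kernel bandwidth (positive scalar or a
#'   `sigma_estimate`).
#' @return A symmetric C x C matrix.
#' @export
gaussian_kernel_fc <- function(X, sigma) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite input window", call. = FALSE)
  if (ncol(X) < 2L) stop("window needs at least 2 samples", call. = FALSE)
  sigma <- as_sigma(sigma)
  D2 <- as.matrix(stats::dist(X))^2
  # clamp underflow so the open-interval bound (0, 1] survives numerically
  K <- pmax(exp(-D2 / (2 * sigma^2)), .Machine$double.xmin)
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' @rdname gaussian_kernel_fc
#' @export
cross_correlation_fc <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite input window", call. = FALSE)
  v <- apply(X, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance channel(s) in window: ",
         paste(which(v == 0), collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(t(X))
  diag(R) <- 1
  R
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric vector.
#' @return Complex vector of the same length whose real part is `x` and
#'   whose argument is the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' @rdname gaussian_kernel_fc
#' @export
phase_locking_fc <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite input window", call. = FALSE)
  L <- ncol(X)
  if (L < 8L) stop("PLV needs at least 8 samples", call. = FALSE)
  if (any(apply(X, 1L, stats::sd) == 0)) {
    stop("constant channel: instantaneous phase undefined", call. = FALSE)
  }
  Z <- t(apply(X, 1L, function(x) {
    a <- analytic_signal(x)
    exp(1i * Arg(a))
  }))
  P <- Mod(Z %*% Conj(t(Z))) / L
  P <- (P + t(P)) / 2
  diag(P) <- 1
  pmin(P, 1)
}

measure_tags <- c("gfc", "ccf", "plv")

#' Pairwise squared-distance tensor
#'
#' Precomputes `||x_c - x_c'||^2` for every (trial, band, window, pair)
#' split. The Gaussian connectivity tensor is then an elementwise
#' `exp(-d2 / (2 sigma^2))`, which makes refitting sigma per
#' cross-validation fold cheap and leak-free.
#'
#' @param segments a `tf_segments`.
#' @return An R x B x W x P array with the pair axis ordered as in
#'   [pair_index()].
#' @export
distance_tensor <- function(segments) {
  stopifnot(inherits(segments, "tf_segments"))
  d <- dim(segments$values)
  R <- d[1L]; B <- d[2L]; W <- d[3L]; C <- d[4L]
  P <- C * (C - 1L) / 2L
  out <- array(0, dim = c(R, B, W, P))
  for (r in seq_len(R)) {
    for (b in seq_len(B)) {
      for (w in seq_len(W)) {
        out[r, b, w, ] <- as.numeric(stats::dist(segments$values[r, b, w, , ]))^2
      }
    }
  }
  out
}

new_connectivity_tensor <- function(values, measure, segments, sigma = NULL) {
  C <- length(segments$channel_names)
  structure(list(values = values, measure = measure,
                 pairs = pair_index(C, segments$channel_names),
                 bands = segments$bands, windows = segments$windows,
                 tau = segments$tau, sigma = sigma,
                 labels = segments$labels,
                 channel_names = segments$channel_names,
                 montage = segments$montage, subject_id = segments$subject_id),
            class = "connectivity_tensor")
}

#' Single-trial connectivity tensor over all time-frequency splits
#'
#' Applies one connectivity measure to every (trial, band, window) segment
#' and stores the strict upper triangle (see [pair_index()]), yielding an
#' R x bands x windows x pairs tensor.
#'
#' @param segments a `tf_segments` from [segment()].
#' @param measure `"gfc"`, `"ccf"` or `"plv"`.
#' @param sigma Gaussian kernel bandwidth; required iff `measure = "gfc"`
#'   (see [median_sigma()]).
#' @return A `connectivity_tensor`: list with `values` (R x B x W x P
#'   array), `measure`, `pairs`, `bands`, `windows`, `labels` and metadata.
#' @export
connectivity_tensor <- function(segments, measure = c("gfc", "ccf", "plv"),
                                sigma = NULL) {
  stopifnot(inherits(segments, "tf_segments"))
  measure <- match.arg(measure)
  d <- dim(segments$values)
  R <- d[1L]; B <- d[2L]; W <- d[3L]; C <- d[4L]
  P <- C * (C - 1L) / 2L
  if (measure == "gfc") {
    sigma <- as_sigma(sigma %||% stop("sigma is required for measure 'gfc'",
                                      call. = FALSE))
    d2 <- distance_tensor(segments)
    vals <- pmax(exp(-d2 / (2 * sigma^2)), .Machine$double.xmin)
    return(new_connectivity_tensor(vals, "gfc", segments, sigma))
  }
  fc_fun <- if (measure == "ccf") cross_correlation_fc else phase_locking_fc
  ut <- upper.tri(matrix(0, C, C))
  vals <- array(0, dim = c(R, B, W, P))
  for (r in seq_len(R)) {
    for (b in seq_len(B)) {
      for (w in seq_len(W)) {
        M <- tryCatch(fc_fun(segments$values[r, b, w, , ]),
                      error = function(e) {
                        stop(sprintf("%s failed at trial %d, band %d, window %d: %s",
                                     measure, r, b, w, conditionMessage(e)),
                             call. = FALSE)
                      })
        vals[r, b, w, ] <- t(M)[t(ut)]  # row-major upper triangle = pair order
      }
    }
  }
  new_connectivity_tensor(vals, measure, segments)
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<connectivity_tensor> ", toupper(x$measure), ": ", d[1], " trials x ",
      d[2], " bands x ", d[3], " windows x ", d[4], " pairs\n", sep = "")
  invisible(x)
}

#' Vectorize a connectivity tensor into a trial x feature matrix
#'
#' Columns are ordered band-major, then window, then pair, and the layout
#' is recorded in the `colmap` attribute so every feature can be traced
#' back to its (band, window, channel pair) split. `devectorize()` inverts
#' the operation.
#'
#' @param ct a `connectivity_tensor`.
#' @return A numeric R x D matrix (`D = bands * windows * pairs`) with
#'   attribute `colmap`, a tibble with columns `column`, `band`, `window`,
#'   `pair`, `c1`, `c2`.
#' @export
vectorize <- function(ct) {
  stopifnot(inherits(ct, "connectivity_tensor"))
  d <- dim(ct$values)
  R <- d[1L]; B <- d[2L]; W <- d[3L]; P <- d[4L]
  X <- matrix(aperm(ct$values, c(1L, 4L, 3L, 2L)), nrow = R)  # pair fastest
  colmap <- tibble::tibble(
    column = seq_len(B * W * P),
    band = rep(seq_len(B), each = W * P),
    window = rep(rep(seq_len(W), each = P), times = B),
    pair = rep(seq_len(P), times = B * W)
  )
  colmap$c1 <- ct$pairs$c1[colmap$pair]
  colmap$c2 <- ct$pairs$c2[colmap$pair]
  attr(X, "colmap") <- colmap
  attr(X, "measure") <- ct$measure
  X
}

#' @param X a matrix produced by [vectorize()].
#' @param template the original `connectivity_tensor` (for its metadata).
#' @rdname vectorize
#' @export
devectorize <- function(X, template) {
  stopifnot(inherits(template, "connectivity_tensor"))
  d <- dim(template$values)
  vals <- aperm(array(X, dim = c(nrow(X), d[4L], d[3L], d[2L])),
                c(1L, 4L, 3L, 2L))
  out <- template
  out$values <- vals
  out
}

#' Rebuild full symmetric connectivity matrices from a tensor
#'
#' @param ct a `connectivity_tensor`.
#' @param trial,band,window split indices.
#' @return A symmetric C x C matrix with unit diagonal.
#' @export
fc_matrix <- function(ct, trial, band, window) {
  stopifnot(inherits(ct, "connectivity_tensor"))
  C <- length(ct$channel_names)
  M <- diag(1, C)
  v <- ct$values[trial, band, window, ]
  M[cbind(ct$pairs$c1, ct$pairs$c2)] <- v
  M[cbind(ct$pairs$c2, ct$pairs$c1)] <- v
  dimnames(M) <- list(ct$channel_names, ct$channel_names)
  M
}

#' Long-format view of a connectivity tensor
#'
#' @param x a `connectivity_tensor`.
#' @param ... unused.
#' @return A tibble with one row per (trial, band, window, pair) value.
#' @exportS3Method generics::tidy
tidy.connectivity_tensor <- function(x, ...) {
  d <- dim(x$values)
  out <- tidyr::expand_grid(trial = seq_len(d[1L]), band = seq_len(d[2L]),
                            window = seq_len(d[3L]), pair = seq_len(d[4L]))
  out$value <- as.numeric(aperm(x$values, c(4L, 3L, 2L, 1L)))
  out$label <- x$labels[out$trial]
  out$c1 <- x$pairs$c1[out$pair]
  out$c2 <- x$pairs$c2[out$pair]
  out$measure <- x$measure
  out
}
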