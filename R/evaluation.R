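#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_from_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all counts are zero", call. = FALSE)
  (TP + TN) / total
}

#' Stratified fold assignment
#'
#' Shuffles each class with the given seed and deals trials round-robin
#' into `k` folds, so per-fold class proportions are within one trial of
#' exact stratification.
#'
#' @param y labels in `{0, 1}`.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer fold id (1..k) per trial.
#' @export
make_stratified_folds <- function(y, k, seed = 1L) {
  y <- coerce_labels(y)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  tab <- table(y)
  if (any(tab < k)) {
    stop("class with ", min(tab), " member(s) cannot be split into ", k,
         " folds; reduce k", call. = FALSE)
  }
  set.seed(seed)
  foldid <- integer(length(y))
  offset <- 0L
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    # rotate the round-robin start per class so remainder trials spread
    # over different folds and overall fold sizes stay within one trial
    foldid[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  foldid
}

#' Stratified k-fold cross-validated decoding accuracy
#'
#' For every fold: (optionally) rebuild the feature matrix with
#' training-fold-only parameters, fit the sparse relevance model and the
#' classifier on the training rows, predict the held-out rows, and score
#' the accuracy. All fitting -- standardization, elastic net, classifier
#' -- happens strictly inside the training folds.
#'
#' @param X trial x feature matrix (ignored per fold when
#'   `feature_builder` is given).
#' @param y labels in `{0, 1}`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment and inner-CV seed.
#' @param classifier `"lda"` (linear discriminant on the selected
#'   features, the default) or `"enet"` (thresholded elastic-net
#'   prediction).
#' @param feature_builder optional function of the training-row indices
#'   returning the full trial x feature matrix built with
#'   training-only parameters (e.g. the kernel bandwidth sigma); used to
#'   keep data-driven feature parameters leak-free.
#' @param config optional named list recorded with the result.
#' @param keep_models if `TRUE`, keep each fold's fitted relevance model
#'   (useful for leakage audits).
#' @param ... passed to [fit_relevance()] (e.g. `mixing`, `nlambda`).
#' @return A `subject_result`: list with `folds` (tibble: `fold`,
#'   `n_test`, `accuracy`), `mean_accuracy`, `sd_accuracy`, `config`,
#'   `support_sizes`.
#' @export
cross_validate <- function(X, y, k = 10L, seed = 1L,
                           classifier = c("lda", "enet"),
                           feature_builder = NULL, config = list(),
                           keep_models = FALSE, ...) {
  classifier <- match.arg(classifier)
  y <- coerce_labels(y)
  if (!is.null(X)) X <- as.matrix(X)
  n <- length(y)
  foldid <- make_stratified_folds(y, k, seed = seed)
  folds <- vector("list", k)
  models <- if (keep_models) vector("list", k)
  supports <- integer(k)
  for (f in seq_len(k)) {
    test <- which(foldid == f)
    train <- which(foldid != f)
    Xf <- if (is.null(feature_builder)) X else feature_builder(train)
    m <- fit_relevance(Xf[train, , drop = FALSE], y[train], seed = seed, ...)
    supports[f] <- sum(m$v != 0)
    if (keep_models) models[[f]] <- m
    if (classifier == "enet") {
      pred <- predict.relevance_model(m, Xf[test, , drop = FALSE],
                                      type = "class")
    } else {
      Xtr <- suppressWarnings(select_features(m, Xf[train, , drop = FALSE]))
      kept <- attr(Xtr, "retained")$column
      Xte <- Xf[test, kept, drop = FALSE]
      # guard LDA against within-class constant columns
      ok <- apply(Xtr, 2L, function(z) stats::sd(z) > 1e-12)
      if (!any(ok)) {
        pred <- rep(as.integer(mean(y[train]) > 0.5), length(test))
      } else {
        ld <- MASS::lda(Xtr[, ok, drop = FALSE], grouping = factor(y[train]))
        pred <- as.integer(as.character(
          stats::predict(ld, Xte[, ok, drop = FALSE])$class))
      }
    }
    folds[[f]] <- tibble::tibble(fold = f, n_test = length(test),
                                 accuracy = mean(pred == y[test]))
  }
  folds <- dplyr::bind_rows(folds)
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy),
                 sd_accuracy = stats::sd(folds$accuracy),
                 support_sizes = supports,
                 fold_models = if (keep_models) models,
                 config = utils::modifyList(
                   list(k = k, seed = seed, classifier = classifier), config)),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat("<subject_result> ", nrow(x$folds), "-fold CV accuracy: ",
      sprintf("%.3f +/- %.3f", x$mean_accuracy, x$sd_accuracy), "\n", sep = "")
  invisible(x)
}

#' Tidy views of a cross-validation result
#'
#' `tidy()` returns the per-fold accuracies; `glance()` a one-row summary
#' with the mean and standard deviation.
#'
#' @param x a `subject_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.subject_result <- function(x, ...) x$folds

#' @rdname tidy.subject_result
#' @exportS3Method generics::glance
glance.subject_result <- function(x, ...) {
  tibble::tibble(folds = nrow(x$folds), mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy,
                 min_accuracy = min(x$folds$accuracy),
                 max_accuracy = max(x$folds$accuracy))
}

#' @exportS3Method ggplot2::autoplot
autoplot.subject_result <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("CV accuracy %.3f +/- %.3f",
                                  object$mean_accuracy, object$sd_accuracy)) +
    ggplot2::ylim(0, 1)
}
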