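#' Embed subjects' relevance vectors in 2D
#'
#' Rows (one relevance vector per subject) are l2-normalized and embedded
#' with exact t-SNE, preserving nearest-neighbour structure of the
#' high-dimensional relevance patterns. Deterministic given the seed.
#'
#' @param relevance numeric subjects x features matrix.
#' @param seed RNG seed for the embedding initialization.
#' @param perplexity t-SNE perplexity (default 5, suited to small
#'   cohorts); must be below the subject count.
#' @param max_iter gradient-descent iterations.
#' @return A tibble with columns `subject`, `dim1`, `dim2`.
#' @export
embed_subjects <- function(relevance, seed = 1L, perplexity = 5,
                           max_iter = 500L) {
  relevance <- as.matrix(relevance)
  n <- nrow(relevance)
  if (n < 4L) stop("need at least 4 subjects to embed", call. = FALSE)
  if (perplexity >= n) {
    stop("perplexity (", perplexity, ") must be below the subject count (",
         n, "); try perplexity = ", max(2, floor((n - 1) / 3)), call. = FALSE)
  }
  nrm <- sqrt(rowSums(relevance^2))
  nrm[nrm == 0] <- 1
  Xn <- relevance / nrm
  Y <- tsne_exact(Xn, dims = 2L, perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  subj <- rownames(relevance) %||% paste0("S", sprintf("%02d", seq_len(n)))
  tibble::tibble(subject = subj, dim1 = Y[, 1L], dim2 = Y[, 2L])
}

#' Cluster subjects into performance groups
#'
#' k-means on the standardized embedding coordinates concatenated with the
#' standardized decoding accuracy (20 seeded restarts, best inertia kept).
#' Clusters are relabelled `I`, `II`, `III`, ... in decreasing order of
#' mean accuracy, so group `I` is always the best-performing ensemble.
#'
#' @param coords tibble from [embed_subjects()] (columns `subject`,
#'   `dim1`, `dim2`) or a subjects x 2 matrix.
#' @param accuracies per-subject decoding accuracy in `[0, 1]`.
#' @param k number of groups (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @return A `cluster_assignment`: list with `assignments` (tibble:
#'   `subject`, `dim1`, `dim2`, `accuracy`, `group`), `group_summary`
#'   (tibble: `group`, `n`, `mean_accuracy`), `k`, `seed`.
#' @export
cluster_subjects <- function(coords, accuracies, k = 3L, seed = 1L) {
  if (is.matrix(coords)) {
    coords <- tibble::tibble(subject = rownames(coords) %||%
                               paste0("S", sprintf("%02d", seq_len(nrow(coords)))),
                             dim1 = coords[, 1L], dim2 = coords[, 2L])
  }
  n <- nrow(coords)
  stopifnot(length(accuracies) == n)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the subject count (", n, ")",
                  call. = FALSE)
  Z <- cbind(scale_safe(coords$dim1), scale_safe(coords$dim2),
             scale_safe(accuracies))
  n_distinct <- nrow(unique(Z))
  if (n_distinct < k) {
    warning("degenerate input: fewer than k distinct subject profiles; ",
            "assigning all subjects to one group", call. = FALSE)
    cl <- rep(1L, n)
  } else {
    set.seed(seed)
    cl <- stats::kmeans(Z, centers = k, nstart = 20L, iter.max = 50L)$cluster
  }
  grp_acc <- tapply(accuracies, cl, mean)
  ord <- order(-grp_acc)  # cluster ids in decreasing mean accuracy
  roman <- as.character(utils::as.roman(seq_along(ord)))
  relabel <- stats::setNames(roman, names(grp_acc)[ord])
  group <- factor(relabel[as.character(cl)], levels = roman)
  assignments <- tibble::tibble(subject = coords$subject,
                                dim1 = coords$dim1, dim2 = coords$dim2,
                                accuracy = accuracies, group = group)
  group_summary <- assignments |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_accuracy = mean(.data$accuracy),
                     .groups = "drop") |>
    dplyr::arrange(.data$group)
  structure(list(assignments = assignments, group_summary = group_summary,
                 k = k, seed = seed),
            class = "cluster_assignment")
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", nrow(x$assignments), " subjects in ", x$k,
      " groups\n", sep = "")
  print(x$group_summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_assignment <- function(x, ...) x$assignments

#' @exportS3Method generics::glance
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(subjects = nrow(x$assignments), k = x$k,
                 best_group_accuracy = max(x$group_summary$mean_accuracy),
                 worst_group_accuracy = min(x$group_summary$mean_accuracy))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cluster_assignment <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data$group,
                               size = .data$accuracy)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2",
                  title = "Subject groups by relevance pattern and accuracy")
}

#' Group-membership switches across window lengths
#'
#' Collects the group labels of the same subject cohort clustered at
#' several window lengths into a subjects x tau matrix and counts, per
#' subject, how often the label changes between adjacent window lengths.
#'
#' @param assignments named list of `cluster_assignment`s, one per window
#'   length (names are the tau values).
#' @return A tibble with one row per subject: the group label per tau
#'   plus a `switches` count.
#' @export
group_switch_matrix <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) >= 1L)
  subj <- lapply(assignments, function(a) sort(a$assignments$subject))
  if (length(unique(subj)) != 1L) {
    stop("subject sets differ across window lengths", call. = FALSE)
  }
  nms <- names(assignments) %||% paste0("tau", seq_along(assignments))
  cols <- lapply(assignments, function(a) {
    as.character(a$assignments$group[order(a$assignments$subject)])
  })
  M <- do.call(cbind, cols)
  colnames(M) <- nms
  switches <- if (ncol(M) < 2L) rep(0L, nrow(M)) else
    rowSums(M[, -1L, drop = FALSE] != M[, -ncol(M), drop = FALSE])
  out <- tibble::as_tibble(M)
  out <- dplyr::bind_cols(tibble::tibble(subject = subj[[1L]]), out)
  out$switches <- as.integer(switches)
  out
}

#' Accumulate pair relevance onto channels
#'
#' Each channel receives the summed relevance of every pair it belongs to
#' (so the pre-normalization total over channels is twice the total pair
#' relevance), then values are min-max normalized to `[0, 1]`. An
#' all-equal result is flagged with attribute `uniform = TRUE`.
#'
#' @param pair_rel tibble from [pair_relevance()] (columns `pair`, `c1`,
#'   `c2`, `relevance`) or a numeric vector of length `C(C-1)/2` in
#'   [pair_index()] order.
#' @param C channel count (required when `pair_rel` is a bare vector).
#' @return A tibble with columns `channel_index`, `relevance` and
#'   attribute `raw` (the pre-normalization accumulations).
#' @export
channel_relevance <- function(pair_rel, C = NULL) {
  if (is.numeric(pair_rel)) {
    stopifnot(!is.null(C))
    pm <- pair_index(C)
    pair_rel <- tibble::tibble(pair = pm$pair, c1 = pm$c1, c2 = pm$c2,
                               relevance = pair_rel)
  }
  C <- C %||% max(pair_rel$c2)
  if (nrow(pair_rel) != C * (C - 1) / 2) {
    stop("expected ", C * (C - 1) / 2, " pairs for ", C, " channels",
         call. = FALSE)
  }
  raw <- numeric(C)
  for (i in seq_len(nrow(pair_rel))) {
    raw[pair_rel$c1[i]] <- raw[pair_rel$c1[i]] + pair_rel$relevance[i]
    raw[pair_rel$c2[i]] <- raw[pair_rel$c2[i]] + pair_rel$relevance[i]
  }
  rng <- range(raw)
  uniform <- diff(rng) == 0
  rel <- if (uniform) rep(1, C) else (raw - rng[1L]) / diff(rng)
  out <- tibble::tibble(channel_index = seq_len(C), relevance = rel)
  attr(out, "raw") <- raw
  attr(out, "uniform") <- uniform
  out
}

#' Extract the top-percentile connectivity links
#'
#' Keeps the channel pairs whose normalized relevance lies strictly above
#' the given percentile of the relevance vector (linear-interpolation
#' percentile), sorted by decreasing weight. With an all-equal relevance
#' vector nothing is strictly above the percentile and the list is empty.
#'
#' @param pair_rel tibble from [pair_relevance()] or numeric vector (with
#'   `C` as in [channel_relevance()]).
#' @param percentile percentile threshold in (0, 100); default 99.
#' @param C channel count when `pair_rel` is a bare vector.
#' @return A tibble with columns `c1`, `c2`, `weight`, plus the threshold
#'   as attribute `threshold`.
#' @export
top_links <- function(pair_rel, percentile = 99, C = NULL) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  if (is.numeric(pair_rel)) {
    stopifnot(!is.null(C))
    pm <- pair_index(C)
    pair_rel <- tibble::tibble(pair = pm$pair, c1 = pm$c1, c2 = pm$c2,
                               relevance = pair_rel)
  }
  thr <- stats::quantile(pair_rel$relevance, percentile / 100, type = 7,
                         names = FALSE)
  keep <- pair_rel$relevance > thr
  out <- pair_rel[keep, c("c1", "c2", "relevance")]
  names(out)[3L] <- "weight"
  out <- out[order(-out$weight), , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Topography report: channel relevance plus top links
#'
#' Bundles the accumulated per-channel relevance, the links above the
#' percentile threshold and the montage into one serializable report.
#'
#' @param m a `relevance_model` fitted on vectorized connectivity
#'   features.
#' @param montage a montage (see [make_montage()]); optional.
#' @param percentile link threshold percentile (default 99).
#' @return A `topography_report`: list with `channels` (tibble:
#'   `channel_index`, `channel`, `x`, `y`, `relevance`), `links` (tibble
#'   with montage coordinates when available), `percentile`, `threshold`.
#' @export
topography_report <- function(m, montage = NULL, percentile = 99) {
  pr <- pair_relevance(m)
  C <- max(pr$c2)
  ch <- channel_relevance(pr, C = C)
  links <- top_links(pr, percentile = percentile)
  channels <- ch
  channels$channel <- paste0("ch", channels$channel_index)
  if (!is.null(montage)) {
    montage <- as_montage(montage)
    stopifnot(nrow(montage) >= C)
    channels$channel <- montage$channel[channels$channel_index]
    channels$x <- montage$x[channels$channel_index]
    channels$y <- montage$y[channels$channel_index]
    if (nrow(links) > 0) {
      links$x1 <- montage$x[links$c1]; links$y1 <- montage$y[links$c1]
      links$x2 <- montage$x[links$c2]; links$y2 <- montage$y[links$c2]
    }
  }
  structure(list(channels = channels, links = links,
                 percentile = percentile,
                 threshold = attr(links, "threshold")),
            class = "topography_report")
}

#' @export
print.topography_report <- function(x, ...) {
  cat("<topography_report> ", nrow(x$channels), " channels, ",
      nrow(x$links), " link(s) above the ", x$percentile,
      "th percentile\n", sep = "")
  invisible(x)
}

#' Scalp map of accumulated channel relevance with top links
#'
#' @param object a `topography_report` whose channels carry montage
#'   coordinates.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.topography_report <- function(object, ...) {
  ch <- object$channels
  if (!all(c("x", "y") %in% names(ch))) {
    stop("topography_report has no montage coordinates to plot", call. = FALSE)
  }
  circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181))
  circ$x <- cos(circ$theta); circ$y <- sin(circ$theta)
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = ch,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$relevance), size = 6) +
    ggplot2::geom_text(data = ch,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$channel),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "relevance")
  if (nrow(object$links) > 0 && all(c("x1", "y1") %in% names(object$links))) {
    p <- p + ggplot2::geom_segment(
      data = object$links,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, linewidth = .data$weight),
      colour = "firebrick", alpha = 0.7) +
      ggplot2::scale_linewidth(range = c(0.3, 1.5))
  }
  p
}
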