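#' Scalp montages
#'
#' A montage maps channel names to 2D positions inside the unit head circle
#' (nose up: +y anterior, +x right). It is only needed for the topographic
#' interpretation layer; the connectivity pipeline itself is montage-free.
#'
#' `make_montage()` builds a montage from explicit coordinates;
#' `ring_montage()` places `n` channels evenly on a ring, a convenient
#' default for synthetic cohorts.
#'
#' @param channel character vector of unique channel names.
#' @param x,y numeric coordinates, `x^2 + y^2 <= 1`.
#' @return A tibble of class `gfconn_montage` with columns `channel`, `x`, `y`.
#' @export
make_montage <- function(channel, x, y) {
  stopifnot(length(channel) == length(x), length(x) == length(y))
  if (anyDuplicated(channel)) stop("montage channel names must be unique", call. = FALSE)
  if (any(x^2 + y^2 > 1 + 1e-9)) {
    stop("montage positions must lie within the unit head circle", call. = FALSE)
  }
  out <- tibble::tibble(channel = as.character(channel),
                        x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("gfconn_montage", class(out))
  out
}

#' @param n number of channels for the ring layout.
#' @param radius ring radius, in (0, 1].
#' @param names optional channel names (default `"ch1" ... "chn"`).
#' @rdname make_montage
#' @export
ring_montage <- function(n, radius = 0.8, names = NULL) {
  stopifnot(n >= 1, radius > 0, radius <= 1)
  if (is.null(names)) names <- paste0("ch", seq_len(n))
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n  # start at vertex-front, clockwise
  make_montage(names, radius * cos(theta), radius * sin(theta))
}

as_montage <- function(m) {
  if (inherits(m, "gfconn_montage")) return(m)
  m <- tibble::as_tibble(m)
  if (!all(c("channel", "x", "y") %in% names(m))) {
    stop("montage needs columns channel, x, y", call. = FALSE)
  }
  make_montage(m$channel, m$x, m$y)
}
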