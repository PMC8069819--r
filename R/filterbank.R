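#' Butterworth band-pass filter banks
#'
#' The pipeline decomposes each trial into a set of band-pass filtered
#' versions before windowing. `filter_bank()` constructs a bank of
#' overlapping bands `[f, f + width]` for `f = f_start, f_start + step, ...`
#' while `f + width <= f_stop`, so the band count is
#' `floor((f_stop - f_start - width) / step) + 1`.
#'
#' @param f_start,f_stop frequency range of the bank in Hz.
#' @param width bandwidth of each band in Hz.
#' @param step spacing between consecutive lower edges in Hz
#'   (`step < width` gives overlapping bands).
#' @param order Butterworth filter order (default 5).
#' @return A `filter_bank_spec`: list with a `bands` tibble
#'   (`band`, `f_low`, `f_high`), `order` and `design`.
#' @examples
#' filter_bank(4, 40, width = 4, step = 2)   # 17 overlapped bands, 4-40 Hz
#' @export
filter_bank <- function(f_start, f_stop, width, step, order = 5L) {
  stopifnot(is.numeric(f_start), is.numeric(f_stop), f_start > 0,
            f_start < f_stop, width > 0, step > 0, step <= width,
            order >= 1)
  f_lows <- seq(f_start, f_stop, by = step)
  f_lows <- f_lows[f_lows + width <= f_stop + 1e-9]
  if (length(f_lows) == 0L) {
    stop("empty filter bank: width (", width, " Hz) exceeds the range ",
         f_stop - f_start, " Hz", call. = FALSE)
  }
  new_filter_bank(tibble::tibble(band = seq_along(f_lows),
                                 f_low = f_lows, f_high = f_lows + width),
                  order)
}

new_filter_bank <- function(bands, order) {
  stopifnot(all(bands$f_low > 0), all(bands$f_low < bands$f_high))
  structure(list(bands = bands, order = as.integer(order),
                 design = "butterworth-bandpass"),
            class = "filter_bank_spec")
}

#' Preset filter banks for motor imagery and motor execution
#'
#' `"MI"` is the motor-imagery bank: 17 five-order Butterworth bands
#' covering 4-40 Hz with 4 Hz bandwidth and 2 Hz overlap step.
#' `"ME"` is the motor-execution bank: 4 non-overlapped bands
#' 8-12 (alpha), 12-30 (beta), 30-50 (low gamma), 50-125 Hz (high gamma);
#' the top band requires a sampling rate above 250 Hz at apply time.
#'
#' @param preset `"MI"` or `"ME"`.
#' @return A `filter_bank_spec`.
#' @export
preset_bank <- function(preset = c("MI", "ME")) {
  preset <- match.arg(preset)
  if (preset == "MI") {
    filter_bank(4, 40, width = 4, step = 2, order = 5L)
  } else {
    new_filter_bank(tibble::tibble(band = 1:4,
                                   f_low = c(8, 12, 30, 50),
                                   f_high = c(12, 30, 50, 125)),
                    order = 5L)
  }
}

#' @export
print.filter_bank_spec <- function(x, ...) {
  cat("<filter_bank_spec> ", nrow(x$bands), " band(s), order-", x$order,
      " ", x$design, "\n", sep = "")
  print(x$bands, n = 6)
  invisible(x)
}

# Zero-phase (forward-backward) Butterworth band-pass of one series.
bandpass_filtfilt <- function(x, f_low, f_high, fs, order) {
  bf <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  if (!all(is.finite(y))) {
    stop(sprintf("band-pass filter unstable for band [%g, %g] Hz at fs = %g",
                 f_low, f_high, fs), call. = FALSE)
  }
  y
}

#' Apply a filter bank to an epochs set
#'
#' Each channel of each trial is band-pass filtered with a zero-phase
#' (forward-backward) Butterworth filter for every band of the bank,
#' giving a trials x bands x channels x samples tensor.
#'
#' @param e an [epochs_set()].
#' @param bank a `filter_bank_spec`.
#' @return A `banded_epochs`: list with `values` (R x B x C x T array),
#'   `fs`, `bands`, `order`, `labels`, `channel_names`, `montage`,
#'   `subject_id`.
#' @export
apply_bank <- function(e, bank) {
  stopifnot(inherits(e, "epochs_set"), inherits(bank, "filter_bank_spec"))
  bad <- bank$bands$f_high >= e$fs / 2
  if (any(bad)) {
    b <- bank$bands[which(bad)[1L], ]
    stop(sprintf("band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
                 b$f_low, b$f_high, e$fs / 2), call. = FALSE)
  }
  d <- dim(e$data)
  R <- d[1L]; C <- d[2L]; T_ <- d[3L]; B <- nrow(bank$bands)
  out <- array(0, dim = c(R, B, C, T_))
  for (b in seq_len(B)) {
    bf <- signal::butter(bank$order,
                         c(bank$bands$f_low[b], bank$bands$f_high[b]) / (e$fs / 2),
                         type = "pass")
    for (r in seq_len(R)) {
      for (ch in seq_len(C)) {
        y <- signal::filtfilt(bf, e$data[r, ch, ])
        out[r, b, ch, ] <- y
      }
    }
  }
  if (!all(is.finite(out))) {
    stop("band-pass filtering produced non-finite output (unstable design)",
         call. = FALSE)
  }
  structure(list(values = out, fs = e$fs, bands = bank$bands,
                 order = bank$order, labels = e$labels,
                 channel_names = e$channel_names, montage = e$montage,
                 subject_id = e$subject_id),
            class = "banded_epochs")
}

#' Sliding-window specification
#'
#' @param tau window length in seconds.
#' @param overlap fraction of overlap between consecutive windows, in `[0, 1)`
#'   (default 0.75).
#' @return A `window_spec` list.
#' @export
window_spec <- function(tau, overlap = 0.75) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
            is.numeric(overlap), length(overlap) == 1L,
            overlap >= 0, overlap < 1)
  structure(list(tau = as.numeric(tau), overlap = as.numeric(overlap)),
            class = "window_spec")
}

#' Segment band-filtered trials into overlapping windows
#'
#' Cuts every (trial, band, channel) series into windows of
#' `L = round(tau * fs)` samples starting at multiples of
#' `round(L * (1 - overlap))`; a trailing partial window is dropped, so the
#' window count is `floor((T - L) / step) + 1`.
#'
#' @param banded a `banded_epochs` from [apply_bank()].
#' @param w a [window_spec()].
#' @return A `tf_segments`: list with `values`
#'   (R x B x W x C x L array), `fs`, `bands`, `windows` tibble
#'   (`window`, `start_sample`, `t_start`, `t_end` in seconds), `tau`,
#'   `overlap`, `labels`, `channel_names`, `montage`, `subject_id`.
#' @export
segment <- function(banded, w) {
  stopifnot(inherits(banded, "banded_epochs"), inherits(w, "window_spec"))
  d <- dim(banded$values)
  R <- d[1L]; B <- d[2L]; C <- d[3L]; T_ <- d[4L]
  L <- as.integer(round(w$tau * banded$fs))
  if (L < 2L) stop("window length must be at least 2 samples", call. = FALSE)
  if (L > T_) {
    stop(sprintf("window of %d samples exceeds trial length %d", L, T_),
         call. = FALSE)
  }
  step <- max(1L, as.integer(round(L * (1 - w$overlap))))
  starts <- seq(0L, T_ - L, by = step)
  W <- length(starts)
  out <- array(0, dim = c(R, B, W, C, L))
  for (wi in seq_len(W)) {
    idx <- (starts[wi] + 1L):(starts[wi] + L)
    out[, , wi, , ] <- banded$values[, , , idx, drop = FALSE]
  }
  windows <- tibble::tibble(window = seq_len(W), start_sample = starts,
                            t_start = starts / banded$fs,
                            t_end = (starts + L) / banded$fs)
  structure(list(values = out, fs = banded$fs, bands = banded$bands,
                 windows = windows, tau = w$tau, overlap = w$overlap,
                 L = L, step = step, labels = banded$labels,
                 channel_names = banded$channel_names,
                 montage = banded$montage, subject_id = banded$subject_id),
            class = "tf_segments")
}

#' @export
print.tf_segments <- function(x, ...) {
  d <- dim(x$values)
  cat("<tf_segments> ", d[1], " trials x ", d[2], " bands x ", d[3],
      " windows x ", d[4], " channels x ", d[5], " samples (tau = ",
      x$tau, " s, overlap = ", x$overlap, ")\n", sep = "")
  invisible(x)
}
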