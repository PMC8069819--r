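#' Specification of a synthetic coupled-oscillator EEG subject
#'
#' Describes labeled multichannel EEG with planted class-dependent
#' coupling: every channel carries independent band-limited background
#' rhythms on top of 1/f-plus-white noise at a given SNR; in class-1
#' trials the channels of each effect pair additionally share a common
#' band-limited source inside the stated band and time window, mixed as
#' `sqrt(1 - g^2) * own + g * shared`. The shared source raises
#' amplitude-profile similarity and phase alignment simultaneously, so
#' Gaussian-kernel, correlation and phase-locking measures can all detect
#' it in principle.
#'
#' @param C number of channels.
#' @param trials_per_class trials per class (labels come out balanced).
#' @param fs sampling rate in Hz.
#' @param duration trial length in seconds.
#' @param snr_db per-channel SNR in dB: background rhythm power over
#'   total (1/f + white) noise power.
#' @param effects tibble with one row per planted effect: columns
#'   `f_low`, `f_high` (Hz), `t_start`, `t_end` (seconds), `c1`, `c2`
#'   (channel indices) and `gain` in `[0, 1]`. Default: one sustained
#'   8-12 Hz coupling between channels 1 and 2 over the whole trial,
#'   gain 0.9. Use a zero-row tibble for no planted effect.
#' @param background tibble of background rhythm bands (`f_low`,
#'   `f_high`); every channel carries one independent rhythm per band.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(C = 8L, trials_per_class = 100L, fs = 128,
                           duration = 3, snr_db = 5,
                           effects = NULL,
                           background = tibble::tibble(
                             f_low = c(8, 16), f_high = c(12, 24)),
                           seed = 1L) {
  if (is.null(effects)) {
    # default: one sustained alpha-band coupling on the first channel pair
    effects <- tibble::tibble(f_low = 8, f_high = 12, t_start = 0,
                              t_end = duration, c1 = 1L, c2 = 2L, gain = 0.9)
  }
  effects <- tibble::as_tibble(effects)
  background <- tibble::as_tibble(background)
  stopifnot(C >= 2, trials_per_class >= 1, fs > 0, duration > 0,
            nrow(background) >= 1)
  if (nrow(effects) > 0) {
    stopifnot(all(effects$f_low > 0), all(effects$f_low < effects$f_high),
              all(effects$t_start >= 0), all(effects$t_start < effects$t_end),
              all(effects$t_end <= duration + 1e-9),
              all(effects$gain >= 0), all(effects$gain <= 1),
              all(effects$c1 < effects$c2), all(effects$c2 <= C))
    if (any(effects$f_high >= fs / 2)) {
      stop("effect band reaches the Nyquist frequency", call. = FALSE)
    }
  }
  if (any(background$f_high >= fs / 2)) {
    stop("background band reaches the Nyquist frequency", call. = FALSE)
  }
  structure(list(C = as.integer(C),
                 trials_per_class = as.integer(trials_per_class),
                 fs = fs, duration = duration, snr_db = snr_db,
                 effects = effects, background = background,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' The strong-coupling study preset
#'
#' Eight channels, 100 trials per class at 128 Hz, 3 s trials, SNR 5 dB,
#' one planted effect: channels 1-2 share a source in the 8-12 Hz band
#' sustained over the whole trial with coupling gain 0.9, so every
#' ground-truth (band, window) split genuinely carries the effect.
#' Paired with the 5-band bank `filter_bank(4, 16, 4, 2)` and
#' `tau = 1` s windows this is the reference condition for recovery and
#' decoding checks.
#'
#' @param seed RNG seed.
#' @param gain coupling gain of the planted effect.
#' @param trials_per_class trials per class.
#' @return A `synthetic_spec`.
#' @export
strong_coupling_spec <- function(seed = 1L, gain = 0.9,
                                 trials_per_class = 100L) {
  synthetic_spec(C = 8L, trials_per_class = trials_per_class, fs = 128,
                 duration = 3, snr_db = 5,
                 effects = tibble::tibble(f_low = 8, f_high = 12,
                                          t_start = 0, t_end = 3,
                                          c1 = 1L, c2 = 2L, gain = gain),
                 seed = seed)
}

# Band-limited unit-power noise: white noise through the bank's own
# zero-phase Butterworth band-pass, rescaled to unit mean-square power.
bandlimited_noise <- function(n, f_low, f_high, fs, order = 5L) {
  x <- stats::rnorm(n)
  y <- bandpass_filtfilt(x, f_low, f_high, fs, order)
  p <- mean(y^2)
  if (p <= 0) stop("degenerate band-limited noise", call. = FALSE)
  y / sqrt(p)
}

# 1/f ("pink") noise by spectral shaping of white noise, exponent 1.
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # fold to two-sided frequency index
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / sqrt(mean(y^2))
}

#' Generate a synthetic subject with planted coupling
#'
#' Class-0 trials contain only independent background rhythms plus noise;
#' class-1 trials additionally mix a shared band-limited source into each
#' effect pair inside the effect window (with a 50 ms linear ramp on the
#' mixing gain to avoid edge discontinuities). Labels come out balanced
#' (first all class 0, then all class 1). Bit-reproducible given the
#' spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `epochs` (an [epochs_set()] with a ring montage)
#'   and `truth` (a `ground_truth`: the effect table plus the generation
#'   parameters needed to resolve feature columns).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  Tn <- as.integer(round(spec$duration * spec$fs))
  R <- 2L * spec$trials_per_class
  labels <- rep(c(0L, 1L), each = spec$trials_per_class)
  nb <- nrow(spec$background)
  snr_lin <- 10^(spec$snr_db / 10)
  data <- array(0, dim = c(R, spec$C, Tn))
  ramp_n <- max(1L, as.integer(round(0.05 * spec$fs)))
  for (r in seq_len(R)) {
    rhythms <- matrix(0, spec$C, Tn)
    for (ch in seq_len(spec$C)) {
      for (b in seq_len(nb)) {
        rhythms[ch, ] <- rhythms[ch, ] +
          bandlimited_noise(Tn, spec$background$f_low[b],
                            spec$background$f_high[b], spec$fs) / sqrt(nb)
      }
    }
    if (labels[r] == 1L && nrow(spec$effects) > 0) {
      for (i in seq_len(nrow(spec$effects))) {
        ef <- spec$effects[i, ]
        shared <- bandlimited_noise(Tn, ef$f_low, ef$f_high, spec$fs)
        i1 <- max(1L, as.integer(round(ef$t_start * spec$fs)) + 1L)
        i2 <- min(Tn, as.integer(round(ef$t_end * spec$fs)))
        g <- numeric(Tn)
        g[i1:i2] <- ef$gain
        rn <- min(ramp_n, (i2 - i1) %/% 2L)
        if (rn > 1L) {
          g[i1:(i1 + rn - 1L)] <- ef$gain * seq(0, 1, length.out = rn)
          g[(i2 - rn + 1L):i2] <- ef$gain * seq(1, 0, length.out = rn)
        }
        for (ch in c(ef$c1, ef$c2)) {
          rhythms[ch, ] <- sqrt(1 - g^2) * rhythms[ch, ] + g * shared
        }
      }
    }
    for (ch in seq_len(spec$C)) {
      noise <- (pink_noise(Tn) + stats::rnorm(Tn)) / sqrt(2)
      data[r, ch, ] <- rhythms[ch, ] + noise / sqrt(snr_lin)
    }
  }
  epochs <- epochs_set(data, spec$fs, labels,
                       channel_names = paste0("ch", seq_len(spec$C)),
                       montage = ring_montage(spec$C),
                       subject_id = sprintf("SYN%03d", spec$seed %% 1000L))
  truth <- structure(list(effects = spec$effects, fs = spec$fs,
                          duration = spec$duration, C = spec$C,
                          seed = spec$seed),
                     class = "ground_truth")
  list(epochs = epochs, truth = truth)
}

#' Resolve planted effects to vectorized feature columns
#'
#' Maps every planted (band, window, pair) effect to the columns of the
#' vectorized connectivity feature matrix whose filter-bank band and
#' sliding window overlap it (positive-length overlap), for the effect's
#' channel pair.
#'
#' @param truth a `ground_truth` from [generate_synthetic()].
#' @param bank the `filter_bank_spec` used for feature extraction.
#' @param w the [window_spec()] used.
#' @return Sorted integer vector of ground-truth feature columns (layout
#'   of [vectorize()]).
#' @export
resolve_truth <- function(truth, bank, w) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(bank, "filter_bank_spec"), inherits(w, "window_spec"))
  fs <- truth$fs
  Tn <- as.integer(round(truth$duration * fs))
  L <- as.integer(round(w$tau * fs))
  step <- max(1L, as.integer(round(L * (1 - w$overlap))))
  starts <- seq(0L, Tn - L, by = step)
  W <- length(starts)
  B <- nrow(bank$bands)
  C <- as.integer(truth$C)
  P <- (C * (C - 1L)) %/% 2L
  pm <- pair_index(C)
  pair_of <- function(c1, c2) pm$pair[pm$c1 == c1 & pm$c2 == c2]
  cols <- integer(0)
  for (i in seq_len(nrow(truth$effects))) {
    ef <- truth$effects[i, ]
    bands_hit <- which(pmin(bank$bands$f_high, ef$f_high) -
                         pmax(bank$bands$f_low, ef$f_low) > 1e-9)
    win_lo <- starts / fs
    win_hi <- (starts + L) / fs
    wins_hit <- which(pmin(win_hi, ef$t_end) - pmax(win_lo, ef$t_start) > 1e-9)
    if (length(bands_hit) == 0L || length(wins_hit) == 0L) {
      stop(sprintf(paste0("effect %d ([%g, %g] Hz, [%g, %g] s) overlaps no ",
                          "bank band or window"),
                   i, ef$f_low, ef$f_high, ef$t_start, ef$t_end),
           call. = FALSE)
    }
    p <- pair_of(ef$c1, ef$c2)
    for (b in bands_hit) {
      for (wi in wins_hit) {
        cols <- c(cols, (b - 1L) * W * P + (wi - 1L) * P + p)
      }
    }
  }
  sort(unique(cols))
}
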