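# Shared fixtures, built once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixtures)) assign(name, fun(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small synthetic subject for container / pipeline tests.
small_subject <- function() {
  fixture("small_subject", function() {
    generate_synthetic(synthetic_spec(C = 6L, trials_per_class = 15L,
                                      fs = 128, duration = 2,
                                      effects = tibble::tibble(
                                        f_low = 8, f_high = 12, t_start = 0,
                                        t_end = 2, c1 = 1L, c2 = 2L,
                                        gain = 0.9),
                                      seed = 11L))
  })
}

# Minimal tf_segments wrapper around a raw R x B x W x C x L array, for
# oracle tests that need direct control over the windowed values.
make_segments <- function(values, fs = 128, labels = NULL) {
  d <- dim(values)
  if (is.null(labels)) labels <- rep(c(0L, 1L), length.out = d[1L])
  structure(list(
    values = values, fs = fs,
    bands = tibble::tibble(band = seq_len(d[2L]), f_low = NA_real_,
                           f_high = NA_real_),
    windows = tibble::tibble(window = seq_len(d[3L]), start_sample = 0L,
                             t_start = 0, t_end = d[5L] / fs),
    tau = d[5L] / fs, overlap = 0, L = d[5L], step = d[5L],
    labels = labels, channel_names = paste0("ch", seq_len(d[4L])),
    montage = NULL, subject_id = "TEST"), class = "tf_segments")
}

# Minimal relevance model for selection / aggregation tests.
make_relmodel <- function(v, colmap = NULL) {
  av <- abs(v)
  nr <- if (max(av) > 0) (av - min(av)) / (max(av) - min(av)) else av
  structure(list(v = v, intercept = 0, alpha1 = 0, alpha2 = 0, lambda = 0,
                 mix_ratio = NA_real_, normalized_relevance = nr,
                 center = rep(0, length(v)), scale = rep(1, length(v)),
                 colmap = colmap, dropped = integer(0), cv = NULL, seed = 1L),
            class = "relevance_model")
}

# Column map for a bands x windows x pairs feature layout (vectorize order).
make_colmap <- function(B, W, C) {
  P <- C * (C - 1L) / 2L
  pm <- pair_index(C)
  cm <- tibble::tibble(
    column = seq_len(B * W * P),
    band = rep(seq_len(B), each = W * P),
    window = rep(rep(seq_len(W), each = P), times = B),
    pair = rep(seq_len(P), times = B * W))
  cm$c1 <- pm$c1[cm$pair]
  cm$c2 <- pm$c2[cm$pair]
  cm
}
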