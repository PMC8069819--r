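#' Labeled epoched EEG container
#'
#' Bundles a trials x channels x samples tensor with its sampling rate,
#' binary trial labels, channel names and (optionally) a 2D scalp montage.
#' This is the entry point of the pipeline: every downstream stage
#' (filter bank, windowing, connectivity, decoding) consumes an
#' `epochs_set`.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels per-trial class labels; coerced to integers in `{0, 1}`.
#' @param channel_names character vector, one name per channel. Defaults to
#'   `"ch1" ... "chC"`.
#' @param montage optional montage as returned by [make_montage()]: a tibble
#'   with columns `channel`, `x`, `y` inside the unit head circle.
#' @param subject_id subject identifier string.
#'
#' @return An object of class `epochs_set` with elements `data`, `fs`,
#'   `labels`, `channel_names`, `montage`, `subject_id`.
#' @seealso [validate_epochs()], [save_epochs()], [load_epochs()]
#' @export
epochs_set <- function(data, fs, labels, channel_names = NULL,
                       montage = NULL, subject_id = "S01") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array (trials x channels x samples)", call. = FALSE)
  }
  dims <- dim(data)
  if (length(labels) != dims[1L]) {
    stop("length(labels) (", length(labels), ") != number of trials (",
         dims[1L], ")", call. = FALSE)
  }
  labels <- coerce_labels(labels)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dims[2L]))
  if (length(channel_names) != dims[2L]) {
    stop("length(channel_names) (", length(channel_names),
         ") != number of channels (", dims[2L], ")", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive finite scalar (Hz)", call. = FALSE)
  }
  if (!is.null(montage)) {
    montage <- as_montage(montage)
    if (!all(channel_names %in% montage$channel)) {
      stop("montage is missing positions for some channels", call. = FALSE)
    }
    montage <- montage[match(channel_names, montage$channel), , drop = FALSE]
  }
  structure(
    list(data = data, fs = as.numeric(fs), labels = labels,
         channel_names = as.character(channel_names),
         montage = montage, subject_id = as.character(subject_id)),
    class = "epochs_set"
  )
}

coerce_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- as.integer(round(as.numeric(labels)))
  u <- sort(unique(labels))
  if (length(u) == 2L && !identical(u, c(0L, 1L))) {
    labels <- as.integer(labels == u[2L])
  }
  labels
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epochs_set> subject ", x$subject_id, "\n",
      "  ", d[1], " trials x ", d[2], " channels x ", d[3], " samples @ ",
      x$fs, " Hz\n", sep = "")
  tab <- table(factor(x$labels, levels = c(0, 1)))
  cat("  labels: ", tab[["0"]], " x class 0, ", tab[["1"]], " x class 1\n",
      sep = "")
  cat("  montage: ", if (is.null(x$montage)) "none" else
    paste0(nrow(x$montage), " positions"), "\n", sep = "")
  invisible(x)
}

#' Report invariant violations of an epochs set
#'
#' Checks the container invariants and reports (rather than raises) each
#' violation: at least two trials with both classes present, finite samples,
#' matching channel-name and montage lengths, positive sampling rate.
#'
#' @param e an [epochs_set()].
#' @return A tibble with columns `field` and `message`, one row per violated
#'   invariant; zero rows iff the set is well formed.
#' @export
validate_epochs <- function(e) {
  out <- list()
  add <- function(field, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  if (!inherits(e, "epochs_set")) {
    add("class", "not an epochs_set object")
    return(dplyr::bind_rows(out))
  }
  d <- dim(e$data)
  if (is.null(d) || length(d) != 3L) {
    add("data", "data is not a 3D trials x channels x samples array")
    return(dplyr::bind_rows(out))
  }
  if (!all(is.finite(e$data))) {
    add("data", sprintf("%d non-finite samples", sum(!is.finite(e$data))))
  }
  if (d[1L] < 2L) add("data", "fewer than 2 trials")
  if (length(e$labels) != d[1L]) add("labels", "labels length != trial count")
  if (!all(e$labels %in% c(0L, 1L))) add("labels", "labels outside {0, 1}")
  if (length(unique(e$labels)) < 2L) {
    add("labels", "single-class set: both classes required for supervised use")
  }
  if (length(e$channel_names) != d[2L]) {
    add("channel_names", "channel_names length != channel count")
  }
  if (anyDuplicated(e$channel_names)) add("channel_names", "duplicate channel names")
  if (!is.numeric(e$fs) || length(e$fs) != 1L || !is.finite(e$fs) || e$fs <= 0) {
    add("fs", "sampling rate must be a positive finite scalar")
  }
  if (!is.null(e$montage)) {
    if (!all(e$channel_names %in% e$montage$channel)) {
      add("montage", "montage missing positions for some channels")
    }
    r2 <- e$montage$x^2 + e$montage$y^2
    if (any(!is.finite(r2)) || any(r2 > 1 + 1e-9)) {
      add("montage", "positions outside the unit head circle")
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(field = character(), message = character()))
  }
  dplyr::bind_rows(out)
}

#' Save / load an epochs set as a single-file container
#'
#' One self-contained binary file per subject holding the named datasets
#' `data`, `fs`, `labels`, `channel_names`, `montage`, `subject_id`.
#' The round trip is bit-exact for the data tensor and all metadata.
#'
#' @param e an [epochs_set()].
#' @param path file path to write / read.
#' @return `save_epochs()` returns `path` invisibly; `load_epochs()` returns
#'   a validated [epochs_set()].
#' @export
save_epochs <- function(e, path) {
  stopifnot(inherits(e, "epochs_set"))
  payload <- list(
    container = "gfconn-epochs", version = 1L,
    data = e$data, fs = e$fs, labels = e$labels,
    channel_names = e$channel_names,
    montage = if (is.null(e$montage)) NULL else as.data.frame(e$montage),
    subject_id = e$subject_id
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @param strict if `TRUE` (default) raise an error when the loaded set
#'   violates structural invariants.
#' @rdname save_epochs
#' @export
load_epochs <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$container, "gfconn-epochs")) {
    stop("not a gfconn epochs container: ", path, call. = FALSE)
  }
  for (field in c("data", "fs", "labels", "channel_names")) {
    if (is.null(payload[[field]])) {
      stop(field, " absent from container ", path, call. = FALSE)
    }
  }
  montage <- payload$montage
  if (!is.null(montage)) montage <- tibble::as_tibble(montage)
  e <- epochs_set(payload$data, payload$fs, payload$labels,
                  payload$channel_names, montage,
                  subject_id = payload$subject_id %||% "S01")
  if (strict) {
    rep <- validate_epochs(e)
    rep <- rep[rep$field != "labels" | !grepl("single-class", rep$message), ,
               drop = FALSE]
    if (nrow(rep) > 0L) {
      stop("invalid epochs container: ",
           paste(rep$field, rep$message, sep = ": ", collapse = "; "),
           call. = FALSE)
    }
  }
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a
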