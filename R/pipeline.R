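#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run: filter bank, window length
#' and overlap, connectivity measure, optional CSP projection, elastic-net
#' grid, cross-validation folds and the seed. Validation happens here,
#' before any compute.
#'
#' @param measure connectivity measure: `"gfc"`, `"ccf"` or `"plv"`.
#' @param bank `"MI"`, `"ME"` or a `filter_bank_spec`.
#' @param tau sliding-window length in seconds.
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param csp if `TRUE`, use per-split CSP pattern vectors instead of the
#'   vectorized connectivity triangle.
#' @param csp_K CSP components per (band, window) split.
#' @param folds cross-validation folds (default 10).
#' @param mixing elastic-net `alpha2/alpha1` mixing-ratio grid.
#' @param nlambda penalty strengths per mixing ratio.
#' @param classifier `"lda"` or `"enet"`.
#' @param seed seed driving fold assignment, inner CV and any restart.
#' @return A validated `run_config` list.
#' @export
run_config <- function(measure = c("gfc", "ccf", "plv"), bank = "MI",
                       tau = 1, overlap = 0.75, csp = FALSE, csp_K = 3L,
                       folds = 10L, mixing = c(0.1, 0.3, 1, 3, 10),
                       nlambda = 10L, classifier = c("lda", "enet"),
                       seed = 1L) {
  measure <- match.arg(measure)
  classifier <- match.arg(classifier)
  if (is.character(bank)) bank <- preset_bank(bank)
  stopifnot(inherits(bank, "filter_bank_spec"))
  if (!is.numeric(tau) || any(tau <= 0)) {
    stop("tau must be positive (seconds)", call. = FALSE)
  }
  stopifnot(overlap >= 0, overlap < 1, folds >= 2)
  structure(list(measure = measure, bank = bank, tau = tau,
                 overlap = overlap, csp = isTRUE(csp),
                 csp_K = as.integer(csp_K), folds = as.integer(folds),
                 mixing = mixing, nlambda = as.integer(nlambda),
                 classifier = classifier, seed = as.integer(seed)),
            class = "run_config")
}

# Per-split median distances, from the squared-distance tensor.
split_medians <- function(d2) {
  apply(sqrt(d2), c(1L, 2L, 3L), stats::median)
}

# sigma by the averaged median heuristic restricted to `train` trials.
sigma_from_medians <- function(med, train) {
  s <- mean(med[train, , , drop = FALSE])
  if (!is.finite(s) || s <= 0) {
    stop("degenerate input: zero median pairwise distance", call. = FALSE)
  }
  s
}

#' Run the full single-subject decoding pipeline
#'
#' Stages: (i) filter-bank decomposition and sliding-window segmentation;
#' (ii) single-trial connectivity (Gaussian kernel, Pearson correlation
#' or phase locking) as either the vectorized matrix triangle or
#' per-split CSP pattern vectors; (iii) elastic-net relevance selection
#' and stratified k-fold cross-validated classification, with the kernel
#' bandwidth sigma and every model refitted inside the training folds;
#' (iv) a full-data relevance model with per-pair relevance and a
#' topography report for interpretation.
#'
#' @param epochs an [epochs_set()].
#' @param config a [run_config()].
#' @return A `pipeline_run`: list with `result` (a `subject_result`),
#'   `relevance` (full-data `relevance_model`), `pair_relevance`,
#'   `topography` (`NULL` for CSP features), `sigma` (full-data sigma for
#'   GFC), `config`, `subject_id`.
#' @export
run_pipeline <- function(epochs, config = run_config()) {
  stopifnot(inherits(epochs, "epochs_set"), inherits(config, "run_config"))
  rep <- validate_epochs(epochs)
  if (nrow(rep) > 0L) {
    stop("invalid epochs set: ",
         paste(rep$field, rep$message, sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  seg <- segment(apply_bank(epochs, config$bank),
                 window_spec(config$tau, config$overlap))
  y <- seg$labels
  sigma_full <- NULL
  if (config$measure == "gfc") {
    d2 <- distance_tensor(seg)
    med <- split_medians(d2)
    sigma_full <- sigma_from_medians(med, seq_len(dim(d2)[1L]))
    ct_full <- connectivity_tensor(seg, "gfc", sigma = sigma_full)
  } else {
    ct_full <- connectivity_tensor(seg, config$measure)
  }
  X_full <- vectorize(ct_full)
  if (config$csp) {
    feature_builder <- function(train) {
      ct <- if (config$measure == "gfc") {
        tmp <- ct_full
        s <- sigma_from_medians(med, train)
        tmp$values <- exp(-d2 / (2 * s^2))
        tmp
      } else ct_full
      csp_feature_matrix(ct, train = train, K = config$csp_K)$X
    }
    result <- cross_validate(NULL, y, k = config$folds, seed = config$seed,
                             classifier = config$classifier,
                             feature_builder = feature_builder,
                             config = run_config_meta(config),
                             mixing = config$mixing, nlambda = config$nlambda)
    rel_X <- csp_feature_matrix(ct_full, K = config$csp_K)$X
  } else if (config$measure == "gfc") {
    D2m <- matrix(aperm(d2, c(1L, 4L, 3L, 2L)), nrow = dim(d2)[1L])
    colmap <- attr(X_full, "colmap")
    feature_builder <- function(train) {
      s <- sigma_from_medians(med, train)
      Xf <- exp(-D2m / (2 * s^2))
      attr(Xf, "colmap") <- colmap
      Xf
    }
    result <- cross_validate(NULL, y, k = config$folds, seed = config$seed,
                             classifier = config$classifier,
                             feature_builder = feature_builder,
                             config = run_config_meta(config),
                             mixing = config$mixing, nlambda = config$nlambda)
    rel_X <- X_full
  } else {
    result <- cross_validate(X_full, y, k = config$folds, seed = config$seed,
                             classifier = config$classifier,
                             config = run_config_meta(config),
                             mixing = config$mixing, nlambda = config$nlambda)
    rel_X <- X_full
  }
  relevance <- suppressWarnings(
    fit_relevance(rel_X, y, mixing = config$mixing,
                  nlambda = config$nlambda, seed = config$seed))
  pr <- NULL; topo <- NULL
  if (!config$csp) {
    pr <- pair_relevance(relevance)
    topo <- topography_report(relevance, montage = epochs$montage)
  }
  structure(list(result = result, relevance = relevance,
                 pair_relevance = pr, topography = topo,
                 sigma = sigma_full, config = config,
                 subject_id = epochs$subject_id),
            class = "pipeline_run")
}

run_config_meta <- function(config) {
  list(measure = config$measure, tau = config$tau, overlap = config$overlap,
       csp = config$csp, bands = nrow(config$bank$bands))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> subject ", x$subject_id, ", ",
      toupper(x$config$measure), ", tau = ", x$config$tau, " s",
      if (x$config$csp) ", CSP", "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x a `pipeline_run`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.pipeline_run <- function(x, ...) {
  tibble::tibble(subject = x$subject_id, measure = x$config$measure,
                 tau = x$config$tau, csp = x$config$csp,
                 mean_accuracy = x$result$mean_accuracy,
                 sd_accuracy = x$result$sd_accuracy,
                 support = sum(x$relevance$v != 0),
                 sigma = x$sigma %||% NA_real_,
                 seed = x$config$seed)
}

#' Serialize a pipeline-run summary to JSON
#'
#' Embeds the full configuration and seed with the per-fold accuracies,
#' so identical config plus seed reproduces an identical document.
#'
#' @param run a `pipeline_run`.
#' @param path optional file to write.
#' @return The JSON string (invisibly when written to `path`).
#' @export
summary_json <- function(run, path = NULL) {
  stopifnot(inherits(run, "pipeline_run"))
  cfg <- run$config
  doc <- list(
    subject = run$subject_id,
    config = list(measure = cfg$measure,
                  bands = as.data.frame(cfg$bank$bands),
                  filter_order = cfg$bank$order, tau = cfg$tau,
                  overlap = cfg$overlap, csp = cfg$csp, folds = cfg$folds,
                  mixing = cfg$mixing, nlambda = cfg$nlambda,
                  classifier = cfg$classifier, seed = cfg$seed),
    sigma = run$sigma,
    folds = as.data.frame(run$result$folds),
    mean_accuracy = run$result$mean_accuracy,
    sd_accuracy = run$result$sd_accuracy,
    support = sum(run$relevance$v != 0)
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Sweep window lengths and measures
#'
#' Runs the pipeline for every combination of window length, measure and
#' CSP flag and returns the long-format comparison table.
#'
#' @param epochs an [epochs_set()].
#' @param taus window lengths in seconds (default the standard
#'   `c(0.5, 1, 1.5, 2)` grid).
#' @param measures connectivity measures to compare.
#' @param csp logical vector: feature representations to include.
#' @param ... further arguments to [run_config()].
#' @return A tibble with columns `subject`, `measure`, `tau`, `csp`,
#'   `mean_accuracy`, `sd_accuracy`, `support`, `sigma`, `seed`, plus a
#'   `runs` attribute holding the individual `pipeline_run` objects.
#' @export
sweep_pipeline <- function(epochs, taus = c(0.5, 1, 1.5, 2),
                           measures = c("gfc", "ccf", "plv"),
                           csp = FALSE, ...) {
  grid <- tidyr::expand_grid(tau = taus, measure = measures, use_csp = csp)
  runs <- purrr::pmap(grid, function(tau, measure, use_csp) {
    run_pipeline(epochs, run_config(measure = measure, tau = tau,
                                    csp = use_csp, ...))
  })
  out <- dplyr::bind_rows(lapply(runs, glance.pipeline_run))
  attr(out, "runs") <- runs
  out
}

#' Bar chart of a sweep table
#'
#' @param tab tibble from [sweep_pipeline()].
#' @return A ggplot.
#' @export
plot_sweep <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$tau),
                                    y = .data$mean_accuracy,
                                    fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_accuracy -
                                          .data$sd_accuracy,
                                        ymax = .data$mean_accuracy +
                                          .data$sd_accuracy),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::labs(x = "window length tau (s)", y = "CV accuracy") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
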