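## The four user-facing workflows: pre-processing, 380-method prediction,
## calibration against PXRD, multivariate modelling (PLS fit/predict) and
## PCA exploration.  Each takes a plain configuration list, returns tidy
## tables and optionally writes CSV results plus a JSON provenance block.

ramanci_version <- function() {
  as.character(utils::packageVersion("ramanci"))
}

write_provenance <- function(out_dir, workflow, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  prov <- list(workflow = workflow, package = "ramanci",
               version = ramanci_version(),
               timestamp = format(Sys.time(), tz = "UTC"),
               config = config[!vapply(config, is.function, logical(1))])
  jsonlite::write_json(prov, file.path(out_dir, paste0(workflow, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(NULL)
}

write_result <- function(tbl, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(tbl, file.path(out_dir, name), row.names = FALSE)
  invisible(NULL)
}

read_spectra_inputs <- function(paths, ...) {
  files <- unlist(lapply(paths, function(p) {
    if (file.exists(p)) p else Sys.glob(p)
  }))
  if (length(files) == 0) abort("no input spectra matched the given paths/globs.")
  dplyr::bind_rows(lapply(files, function(f) {
    if (grepl("\\.(jdx|dx|jcm)$", f, ignore.case = TRUE)) read_jcampdx(f, ...)
    else read_xy_table(f, kind = "spectrum", ...)
  }))
}

#' Pre-processing workflow
#'
#' Reads spectra (long table or file paths/globs), applies the anchor
#' baseline and optionally SNV, and writes the processed spectra.
#'
#' @param spectra A spectra table, or character paths/globs of XY or
#'   JCAMP-DX files.
#' @param anchors Anchor list.
#' @param snv Apply SNV?
#' @param out_dir Optional output directory for CSV results + provenance.
#' @return The processed spectra table.
#' @export
workflow_preprocess <- function(spectra, anchors = raman_anchors(), snv = TRUE,
                                out_dir = NULL) {
  data <- if (is.character(spectra)) read_spectra_inputs(spectra) else spectra
  validate_spectra(data)
  out <- preprocess_spectra(data, anchors = anchors, snv = snv)
  write_result(out, out_dir, "preprocessed_spectra.csv")
  write_provenance(out_dir, "preprocess",
                   list(anchors = anchors, snv = snv, n_spectra =
                          length(split_spectra(data))))
  out
}

#' 380-method crystallinity workflow
#'
#' Pre-processes each spectrum, computes the amorphous-subtracted 380/1096
#' ratio against the configured reference and maps it to %CI through the
#' configured calibration, reporting per-replicate values and per-batch
#' mean +- sd.  Spectra failing the ratio computation are flagged and the
#' run continues.
#'
#' @param spectra A spectra table or file paths/globs.
#' @param calibration A `ci_calibration`, or a built-in name
#'   (`"ORIGINAL"`, `"MR"`, `"PHAT"`), or a calibration JSON path.
#' @param reference An `amorphous_reference`, a probe name for
#'   [published_amorphous_reference()], or a reference JSON path.
#' @param anchors,snv Pre-processing settings.
#' @param scale_at_857,half_window Ratio settings
#'   (see [amorphous_subtracted_ratio()]).
#' @param preprocess Set `FALSE` when the spectra are already pre-processed.
#' @param out_dir Optional output directory.
#' @return A list with `replicates` and `batches` tibbles (see
#'   [batch_ci()]).
#' @export
workflow_ci380 <- function(spectra, calibration = "MR", reference = "MR",
                           anchors = raman_anchors(), snv = TRUE,
                           scale_at_857 = TRUE, half_window = 5,
                           preprocess = TRUE, out_dir = NULL) {
  data <- if (is.character(spectra)) read_spectra_inputs(spectra) else spectra
  validate_spectra(data)
  cal <- resolve_calibration(calibration)
  ref <- resolve_reference(reference)
  proc <- if (preprocess) preprocess_spectra(data, anchors = anchors, snv = snv) else data
  res <- batch_ci(proc, ref, cal, scale_at_857 = scale_at_857,
                  half_window = half_window)
  res$replicates$calibration <- cal$label
  write_result(res$replicates, out_dir, "ci380_replicates.csv")
  write_result(res$batches, out_dir, "ci380_batches.csv")
  write_provenance(out_dir, "ci380", list(
    calibration = glance(cal), anchors = anchors, snv = snv,
    scale_at_857 = scale_at_857, half_window = half_window,
    reference_probe = ref$probe, reference_n = ref$n_spectra))
  res
}

resolve_calibration <- function(calibration) {
  if (inherits(calibration, "ci_calibration")) return(calibration)
  if (is.character(calibration) && length(calibration) == 1) {
    if (calibration %in% c("ORIGINAL", "MR", "PHAT")) {
      return(builtin_calibration(calibration))
    }
    if (file.exists(calibration)) return(read_calibration(calibration))
  }
  abort("cannot resolve the calibration: give a ci_calibration, a built-in name or a file path.")
}

resolve_reference <- function(reference) {
  if (inherits(reference, "amorphous_reference")) return(reference)
  if (is.character(reference) && length(reference) == 1) {
    if (reference %in% c("MR", "PHAT")) return(published_amorphous_reference(reference))
    if (file.exists(reference)) return(read_amorphous_reference(reference))
  }
  abort("cannot resolve the amorphous reference: give an object, probe name or file path.")
}

#' Calibration workflow: blends with both Raman and PXRD
#'
#' For each blend the Segal %CI is computed from its diffractogram (with
#' optional blank subtraction) and the amorphous-subtracted band ratio from
#' its replicate Raman spectra (replicates averaged); a calibration line is
#' then fitted through the (mean ratio, Segal %CI) pairs.
#'
#' @param spectra Pre-processed (or raw, see `preprocess`) blend spectra
#'   table; blends identified by `sample_id`.
#' @param diffractograms Diffractogram table with matching `sample_id`s.
#' @param reference Amorphous reference used for the ratios.
#' @param blank Optional blank diffractogram for subtraction.
#' @param label Label of the fitted calibration.
#' @param windows Segal windows.
#' @param anchors,snv,preprocess Pre-processing settings for the spectra.
#' @param scale_at_857,half_window Ratio settings.
#' @param out_dir Optional output directory; the calibration is also
#'   serialized there.
#' @return A list with `calibration` (the fitted `ci_calibration`), `pairs`
#'   (per-blend tibble with `ratio`, `ci`), and `segal` (per-blend Segal
#'   results).
#' @export
workflow_calibrate <- function(spectra, diffractograms, reference,
                               blank = NULL, label = "CUSTOM",
                               windows = segal_windows(),
                               anchors = raman_anchors(), snv = TRUE,
                               preprocess = FALSE,
                               scale_at_857 = TRUE, half_window = 5,
                               out_dir = NULL) {
  validate_spectra(spectra)
  proc <- if (preprocess) preprocess_spectra(spectra, anchors = anchors, snv = snv)
    else spectra
  seg <- segal_ci(diffractograms, windows = windows, blank = blank)
  ratios <- amorphous_subtracted_ratio(proc, reference,
                                       scale_at_857 = scale_at_857,
                                       half_window = half_window)
  mean_ratio <- ratios |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ratio = mean(.data$ratio), n_replicates = dplyr::n(),
                     .groups = "drop")
  pairs <- dplyr::inner_join(mean_ratio, seg[, c("sample_id", "ci")],
                             by = "sample_id")
  if (nrow(pairs) < nrow(mean_ratio) || nrow(pairs) < nrow(seg)) {
    abort("Raman blends and diffractograms do not match one-to-one by sample_id.")
  }
  if (nrow(pairs) < 3) abort("at least 3 blends with both modalities are required.")
  cal <- fit_calibration(pairs, ratio = "ratio", ci = "ci", label = label)
  write_result(pairs, out_dir, "calibration_pairs.csv")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_calibration(cal, file.path(out_dir, "calibration.json"))
  }
  write_provenance(out_dir, "calibrate", list(
    label = label, windows = windows, scale_at_857 = scale_at_857,
    half_window = half_window, n_blends = nrow(pairs)))
  list(calibration = cal, pairs = pairs, segal = seg)
}

#' Multivariate model workflow (PLS fit / predict)
#'
#' Fit mode assembles the 250-1500 cm^-1 spectra matrix, fits PLS1 with
#' batch-grouped cross-validation and writes the model with per-factor
#' statistics.  Predict mode applies a fitted model and, when reference
#' values are supplied, reports RMSEP, bias, explained validation variance
#' and Pearson r.
#'
#' @param spectra A pre-processed spectra table on a common grid.
#' @param mode `"fit"` or `"predict"`.
#' @param y Reference %CI per spectrum (fit mode: required; predict mode:
#'   optional, enables metrics).  Matched to spectra by position.
#' @param model A `pls1_model` or model JSON path (predict mode).
#' @param max_factors Largest factor count (fit mode).
#' @param n_factors Factor count used for prediction (default: selected by
#'   [select_factors()] on the cross-validated RMSE in fit mode, or the
#'   model's largest in predict mode).
#' @param window Modelling window in cm^-1.
#' @param group Batch column for grouped cross-validation.
#' @param out_dir Optional output directory.
#' @return Fit mode: a list with `model`, `selected_factors`, `matrix`.
#'   Predict mode: a list with `predictions` tibble and `metrics` (or
#'   `NULL`).
#' @export
workflow_model <- function(spectra, mode = c("fit", "predict"), y = NULL,
                           model = NULL, max_factors = 3, n_factors = NULL,
                           window = c(250, 1500), group = "sample_id",
                           out_dir = NULL) {
  mode <- match.arg(mode)
  sm <- spectra_matrix(spectra, window = window, group = group)
  if (mode == "fit") {
    if (is.null(y)) abort("fit mode needs reference %CI values `y`.")
    segments <- tryCatch(grouped_segments(sm$meta[[group]]), error = function(e) NULL)
    fit <- pls1_fit(sm, y, max_factors = max_factors, segments = segments)
    sel <- if (!is.null(segments)) select_factors(fit$stats$rmsecv) else max_factors
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_pls_model(fit, file.path(out_dir, "pls_model.json"))
    }
    write_result(fit$stats, out_dir, "pls_factor_stats.csv")
    write_provenance(out_dir, "pls_fit", list(
      max_factors = max_factors, window = window, group = group,
      n_segments = length(segments), selected_factors = sel))
    list(model = fit, selected_factors = sel, matrix = sm)
  } else {
    if (is.null(model)) abort("predict mode needs a fitted model.")
    if (is.character(model)) model <- read_pls_model(model)
    pred <- predict(model, sm, n_factors = n_factors)
    out <- dplyr::bind_cols(sm$meta, tibble(ci_predicted = pred))
    metrics <- NULL
    if (!is.null(y)) {
      out$ci_reference <- y
      metrics <- regression_metrics(y, pred)
      names(metrics)[names(metrics) == "rmse"] <- "rmsep"
    }
    write_result(out, out_dir, "pls_predictions.csv")
    write_provenance(out_dir, "pls_predict", list(
      n_factors = n_factors %||% ncol(model$coefficients), window = window))
    list(predictions = out, metrics = metrics)
  }
}

#' PCA exploration workflow
#'
#' Fits a NIPALS PCA on the 250-1500 cm^-1 matrix, computes batch-grouped
#' cross-validated explained variance (skipped with a warning when only one
#' group is present) and correlation loadings.
#'
#' @param spectra A pre-processed spectra table on a common grid.
#' @param n_components Number of components.
#' @param window Modelling window.
#' @param group Batch column for grouping.
#' @param out_dir Optional output directory.
#' @return A list with `pca`, `scores`, `loadings`, `correlation_loadings`,
#'   `variance` (calibration + validation explained variance tibble).
#' @export
workflow_pca <- function(spectra, n_components = 2, window = c(250, 1500),
                         group = "sample_id", out_dir = NULL) {
  sm <- spectra_matrix(spectra, window = window, group = group)
  pca <- nipals_pca(sm, n_components = n_components)
  variance <- tidy(pca, "variance")
  cv <- tryCatch({
    segments <- grouped_segments(sm$meta[[group]])
    pca_cv_variance(sm, segments, n_components = n_components)
  }, error = function(e) {
    warn(paste("cross-validation skipped:", conditionMessage(e)))
    NULL
  })
  if (!is.null(cv)) {
    variance$validation_variance_pct <- cv$validation_variance_pct
  }
  scores <- tidy(pca, "scores")
  loadings <- tidy(pca, "loadings")
  corr <- correlation_loadings(pca, sm)
  write_result(scores, out_dir, "pca_scores.csv")
  write_result(loadings, out_dir, "pca_loadings.csv")
  write_result(corr, out_dir, "pca_correlation_loadings.csv")
  write_result(variance, out_dir, "pca_variance.csv")
  write_provenance(out_dir, "pca", list(
    n_components = n_components, window = window, group = group))
  list(pca = pca, scores = scores, loadings = loadings,
       correlation_loadings = corr, variance = variance)
}
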