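## The 380-method: amorphous-subtracted 380/1096 cm^-1 band ratio mapped to
## a crystallinity index by a linear calibration.

#' Band peak intensity
#'
#' Reads the intensity of a band as the maximum over grid points within
#' `center +- half_window`; with `half_window = 0` the (linearly
#' interpolated) value exactly at `center` is returned.  The window maximum
#' is robust to small (<= 2 cm^-1) wavenumber calibration shifts between
#' instruments.
#'
#' @param data A spectra table (one or more spectra).
#' @param center Band center (cm^-1).
#' @param half_window Half-width of the search window (cm^-1); default 5.
#' @return A tibble with one row per spectrum: the identity columns plus
#'   `intensity`.
#' @export
peak_intensity <- function(data, center, half_window = 5) {
  chunks <- split_spectra(data)
  rows <- purrr::map(chunks, function(ch) {
    meta <- ch[1, intersect(names(ch), SPECTRUM_ID_COLS), drop = FALSE]
    dplyr::bind_cols(meta, tibble(
      intensity = peak_value(ch$wavenumber, ch$intensity, center, half_window)))
  })
  dplyr::bind_rows(rows)
}

peak_value <- function(x, y, center, half_window) {
  if (half_window < 0) abort("half_window must be >= 0.")
  if (half_window == 0) return(value_at(x, y, center))
  lo <- center - half_window; hi <- center + half_window
  idx <- which(x >= lo & x <= hi)
  if (length(idx) == 0) {
    abort(sprintf("window [%g, %g] contains no grid points of the axis [%g, %g].",
                  lo, hi, min(x), max(x)))
  }
  max(y[idx])
}

#' Build an averaged amorphous reference
#'
#' Averages a set of pre-processed milled (amorphous) spectra pointwise and
#' records the mean and sample standard deviation (divisor `n - 1`; zero for
#' a single spectrum) of the per-spectrum 380 and 1096 cm^-1 band
#' intensities.
#'
#' @param data A spectra table of pre-processed amorphous spectra sharing a
#'   common grid.
#' @param probe Probe label stored with the reference; default taken from
#'   the data when unique.
#' @param half_window Band read-off half-window passed to [peak_intensity()].
#' @return An object of class `amorphous_reference`: a list with elements
#'   `spectrum` (averaged tibble), `i380` and `i1096` (named vectors with
#'   `mean` and `sd`), `n_spectra`, `probe`, `half_window`.
#' @export
build_amorphous_reference <- function(data, probe = NULL, half_window = 5) {
  chunks <- split_spectra(data)
  if (length(chunks) == 0) abort("empty spectrum set.")
  if (!spectra_share_grid(data)) {
    abort("amorphous spectra must share an identical wavenumber grid; resample first.")
  }
  if ("processing" %in% names(data) && any(data$processing == "")) {
    warn("building an amorphous reference from spectra with no processing tags.")
  }
  if (is.null(probe)) {
    probe <- if ("probe" %in% names(data) && length(unique(data$probe)) == 1) {
      data$probe[1]
    } else "OTHER"
  }
  wn <- chunks[[1]]$wavenumber
  mat <- vapply(chunks, function(ch) ch$intensity, numeric(length(wn)))
  avg <- rowMeans(mat)
  band_stats <- function(center) {
    v <- vapply(chunks, function(ch)
      peak_value(ch$wavenumber, ch$intensity, center, half_window), numeric(1))
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  }
  structure(list(
    spectrum = tibble(wavenumber = wn, intensity = avg),
    i380 = band_stats(380), i1096 = band_stats(1096),
    n_spectra = length(chunks), probe = probe, half_window = half_window
  ), class = "amorphous_reference")
}

#' @export
print.amorphous_reference <- function(x, ...) {
  cat(sprintf(
    "<amorphous_reference> probe %s, n = %d spectra\n  I380_am  = %.4g (sd %.4g)\n  I1096_am = %.4g (sd %.4g)\n",
    x$probe, x$n_spectra, x$i380[["mean"]], x$i380[["sd"]],
    x$i1096[["mean"]], x$i1096[["sd"]]))
  invisible(x)
}

#' Construct an amorphous reference from known band intensities
#'
#' Used when only the averaged band intensities (not the full averaged
#' spectrum) are available, e.g. the published instrument-specific values.
#'
#' @param i380,i1096 Band intensities at 380 and 1096 cm^-1 (means).
#' @param i380_sd,i1096_sd Their standard deviations.
#' @param n_spectra Number of spectra averaged.
#' @param probe Probe label.
#' @return An `amorphous_reference` with a `NULL` spectrum.
#' @export
amorphous_reference_values <- function(i380, i1096, i380_sd = 0, i1096_sd = 0,
                                       n_spectra = 1L, probe = "OTHER") {
  structure(list(
    spectrum = NULL,
    i380 = c(mean = i380, sd = i380_sd),
    i1096 = c(mean = i1096, sd = i1096_sd),
    n_spectra = as.integer(n_spectra), probe = probe, half_window = 5
  ), class = "amorphous_reference")
}

#' Published averaged amorphous reference values per probe
#'
#' The averaged amorphous band intensities for the MR probe
#' (I380 = 0.627 +- 0.246, I1096 = 2.745 +- 0.489, n = 70 spectra) and the
#' PhAT probe (I380 = 1.194 +- 0.277, I1096 = 2.607 +- 0.277, n = 55).
#'
#' @param probe `"MR"` or `"PHAT"`.
#' @return An `amorphous_reference` holding the published values.
#' @export
published_amorphous_reference <- function(probe = c("MR", "PHAT")) {
  probe <- match.arg(probe)
  if (probe == "MR") {
    amorphous_reference_values(0.627, 2.745, 0.246, 0.489, 70L, "MR")
  } else {
    amorphous_reference_values(1.194, 2.607, 0.277, 0.277, 55L, "PHAT")
  }
}

#' Amorphous-subtracted 380/1096 band ratio
#'
#' For each sample spectrum computes
#' `(I380 - I380_am) / (I1096 - I1096_am)`, the crystallinity-sensitive
#' band ratio after subtracting the amorphous contribution.  With
#' `scale_at_857 = TRUE` (the default, following the published procedure)
#' the reference spectrum is first rescaled to match each sample at
#' 857 cm^-1 and the amorphous band intensities are re-read from the scaled
#' reference; with `FALSE` the reference band intensities are used as-is.
#'
#' @param data A spectra table of pre-processed sample spectra.
#' @param reference An `amorphous_reference`.  Scaling requires its full
#'   averaged spectrum on the same grid as the samples.
#' @param scale_at_857 Rescale the reference per sample at 857 cm^-1?
#' @param half_window Band read-off half-window (cm^-1); 0 reads exact
#'   band-center values.
#' @return A tibble with one row per spectrum: identity columns plus
#'   `i380`, `i1096`, `i380_am`, `i1096_am`, `ratio`.
#' @export
amorphous_subtracted_ratio <- function(data, reference, scale_at_857 = TRUE,
                                       half_window = 5) {
  stopifnot(inherits(reference, "amorphous_reference"))
  chunks <- split_spectra(data)
  if (scale_at_857 && is.null(reference$spectrum)) {
    abort("857-scaling needs the full averaged reference spectrum; use scale_at_857 = FALSE for value-only references.")
  }
  rows <- purrr::map(chunks, function(ch) {
    i380 <- peak_value(ch$wavenumber, ch$intensity, 380, half_window)
    i1096 <- peak_value(ch$wavenumber, ch$intensity, 1096, half_window)
    if (!is.null(reference$spectrum)) {
      ref <- reference$spectrum
      if (!identical(ref$wavenumber, ch$wavenumber)) {
        abort("sample and amorphous reference must share a wavenumber grid; resample first.")
      }
      refint <- ref$intensity
      if (scale_at_857) {
        ir <- value_at(ref$wavenumber, refint, 857)
        if (!is.finite(ir) || ir == 0) {
          abort("reference intensity at 857 cm^-1 is zero; cannot scale.")
        }
        it <- value_at(ch$wavenumber, ch$intensity, 857)
        refint <- refint * (it / ir)
      }
      i380_am <- peak_value(ref$wavenumber, refint, 380, half_window)
      i1096_am <- peak_value(ref$wavenumber, refint, 1096, half_window)
    } else {
      i380_am <- reference$i380[["mean"]]
      i1096_am <- reference$i1096[["mean"]]
    }
    den <- i1096 - i1096_am
    if (abs(den) < 1e-12) {
      abort("degenerate denominator: sample is indistinguishable from the amorphous reference at 1096 cm^-1.")
    }
    meta <- ch[1, intersect(names(ch), SPECTRUM_ID_COLS), drop = FALSE]
    dplyr::bind_cols(meta, tibble(
      i380 = i380, i1096 = i1096, i380_am = i380_am, i1096_am = i1096_am,
      ratio = (i380 - i380_am) / den))
  })
  dplyr::bind_rows(rows)
}

## ---------------------------------------------------------------------------
## Calibration lines: ratio = slope * %CI + intercept  (classical direction),
## predicted as %CI = (ratio - intercept) / slope.

new_ci_calibration <- function(slope, intercept, label, pearson_r = NA_real_,
                               n_points = NA_integer_, fitted_on = NA_character_) {
  if (!is.finite(slope) || slope == 0) abort("calibration slope must be nonzero.")
  structure(list(slope = slope, intercept = intercept, label = label,
                 pearson_r = pearson_r, n_points = n_points,
                 fitted_on = fitted_on),
            class = "ci_calibration")
}

#' Built-in 380-method calibration lines
#'
#' The three published calibrations mapping the amorphous-subtracted
#' 380/1096 ratio to a crystallinity index, in the classical form
#' `ratio = slope * %CI + intercept`:
#' * `"ORIGINAL"` - the original FT-Raman calibration,
#'   `%CI = (ratio - 0.0286) / 0.0065`;
#' * `"MR"` - the MR probe correction, `%CI = (ratio + 0.134) / 0.005`;
#' * `"PHAT"` - the PhAT probe correction, `%CI = (ratio + 0.129) / 0.005`.
#'
#' @param label One of `"ORIGINAL"`, `"MR"`, `"PHAT"`.
#' @return A `ci_calibration` object.
#' @export
#' @examples
#' ci_from_ratio(0.366, builtin_calibration("MR"))  # 100
builtin_calibration <- function(label = c("ORIGINAL", "MR", "PHAT")) {
  label <- match.arg(label)
  switch(label,
    ORIGINAL = new_ci_calibration(0.0065, 0.0286, "ORIGINAL"),
    MR = new_ci_calibration(0.005, -0.134, "MR"),
    PHAT = new_ci_calibration(0.005, -0.129, "PHAT"))
}

#' @export
print.ci_calibration <- function(x, ...) {
  cat(sprintf("<ci_calibration> %s: ratio = %.6g * %%CI + %.6g", x$label,
              x$slope, x$intercept))
  if (is.finite(x$pearson_r)) cat(sprintf("  (r = %.4f, n = %d)", x$pearson_r, x$n_points))
  cat("\n")
  invisible(x)
}

#' @export
tidy.ci_calibration <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @export
glance.ci_calibration <- function(x, ...) {
  tibble(label = x$label, slope = x$slope, intercept = x$intercept,
         pearson_r = x$pearson_r, n_points = x$n_points)
}

#' Fit a calibration line from (ratio, %CI) pairs
#'
#' Ordinary least squares with the band ratio as response and the reference
#' crystallinity (typically the Segal PXRD index) as predictor - the
#' classical calibration direction, so that prediction inverts as
#' `%CI = (ratio - intercept) / slope`.  An inverse-regression variant
#' (regressing %CI on ratio) is available for sensitivity analysis.
#'
#' @param data A data frame with the calibration pairs.
#' @param ratio,ci Column names (strings) of the band ratio and reference
#'   %CI; defaults `"ratio"` and `"ci"`.
#' @param label Label stored with the calibration.
#' @param direction `"classical"` (ratio ~ %CI, default) or `"inverse"`
#'   (%CI ~ ratio, converted back to the classical parameterization).
#' @return A `ci_calibration` object.
#' @export
fit_calibration <- function(data, ratio = "ratio", ci = "ci", label = "CUSTOM",
                            direction = c("classical", "inverse")) {
  direction <- match.arg(direction)
  r <- data[[ratio]]; y <- data[[ci]]
  if (is.null(r) || is.null(y)) abort("calibration data must contain the ratio and ci columns.")
  keep <- is.finite(r) & is.finite(y)
  r <- r[keep]; y <- y[keep]
  if (length(r) < 3) abort("at least 3 calibration pairs are required.")
  if (var(y) == 0) abort("all reference %CI values are equal; calibration is rank-deficient.")
  if (direction == "classical") {
    fit <- lm(r ~ y)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  } else {
    if (var(r) == 0) abort("all ratios are equal; inverse calibration is rank-deficient.")
    fit <- lm(y ~ r)
    slope <- 1 / unname(coef(fit)[2])
    intercept <- -unname(coef(fit)[1]) * slope
  }
  if (!is.finite(slope) || slope == 0) abort("degenerate calibration fit (zero slope).")
  new_ci_calibration(slope, intercept, label,
                     pearson_r = cor(r, y), n_points = length(r),
                     fitted_on = format(Sys.Date()))
}

#' Crystallinity index from a band ratio
#'
#' Inverts a calibration line: `%CI = (ratio - intercept) / slope`.  Values
#' are not clipped to \[0, 100\] by default; a sample more amorphous than
#' the reference legitimately maps below zero, which is diagnostic.
#'
#' @param ratio Numeric vector of amorphous-subtracted band ratios.
#' @param calibration A `ci_calibration` object.
#' @param clip Clip results into \[0, 100\] (with a warning)?
#' @return Numeric vector of crystallinity indices (percent).
#' @export
ci_from_ratio <- function(ratio, calibration, clip = FALSE) {
  stopifnot(inherits(calibration, "ci_calibration"))
  ci <- (ratio - calibration$intercept) / calibration$slope
  if (clip) {
    out_of_range <- sum(ci < 0 | ci > 100, na.rm = TRUE)
    if (out_of_range > 0) {
      warn(sprintf("%d %%CI value(s) clipped into [0, 100].", out_of_range))
    }
    ci <- pmin(pmax(ci, 0), 100)
  }
  ci
}

#' Per-batch crystallinity with replicate aggregation
#'
#' Computes the 380-method %CI for every replicate spectrum and aggregates
#' per sample as mean and sample standard deviation (zero for a single
#' replicate).  Replicates whose ratio computation fails (degenerate
#' denominator) are flagged and excluded from the aggregate, with a warning
#' count in the output.
#'
#' @inheritParams amorphous_subtracted_ratio
#' @param calibration A `ci_calibration` object.
#' @return A list with `replicates` (per-spectrum tibble including `ci` and
#'   `failed`) and `batches` (per-sample tibble with `ci_mean`, `ci_sd`,
#'   `n`, `n_failed`).
#' @export
batch_ci <- function(data, reference, calibration, scale_at_857 = TRUE,
                     half_window = 5) {
  chunks <- split_spectra(data)
  if (length(chunks) == 0) abort("no spectra supplied.")
  rows <- purrr::map(chunks, function(ch) {
    meta <- ch[1, intersect(names(ch), SPECTRUM_ID_COLS), drop = FALSE]
    res <- tryCatch(
      amorphous_subtracted_ratio(ch, reference, scale_at_857 = scale_at_857,
                                 half_window = half_window),
      error = function(e) NULL)
    if (is.null(res)) {
      dplyr::bind_cols(meta, tibble(ratio = NA_real_, ci = NA_real_, failed = TRUE))
    } else {
      dplyr::bind_cols(meta, tibble(ratio = res$ratio,
                                    ci = ci_from_ratio(res$ratio, calibration),
                                    failed = FALSE))
    }
  })
  reps <- dplyr::bind_rows(rows)
  n_failed_total <- sum(reps$failed)
  if (n_failed_total > 0) {
    warn(sprintf("%d replicate(s) failed the ratio computation and were excluded.",
                 n_failed_total))
  }
  key <- if ("sample_id" %in% names(reps)) "sample_id" else character(0)
  batches <- reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      ci_mean = mean(.data$ci[!.data$failed]),
      ci_sd = if (sum(!.data$failed) > 1) sd(.data$ci[!.data$failed]) else 0,
      n = sum(!.data$failed),
      n_failed = sum(.data$failed),
      .groups = "drop")
  list(replicates = reps, batches = batches)
}

## ---------------------------------------------------------------------------
## Serialization (JSON with a schema version)

#' Write / read a calibration line
#'
#' Calibrations are stored as small JSON documents with a schema version and
#' fit provenance (label, n, Pearson r, fit date).
#'
#' @param calibration A `ci_calibration`.
#' @param path File path.
#' @return `path` (write) or a `ci_calibration` (read).
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "ci_calibration"))
  obj <- c(list(schema = "ramanci/calibration/1"),
           unclass(calibration))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ramanci/calibration/1")) {
    abort(sprintf("%s is not a ramanci calibration file.", path))
  }
  new_ci_calibration(obj$slope, obj$intercept, obj$label,
                     pearson_r = obj$pearson_r %||% NA_real_,
                     n_points = obj$n_points %||% NA_integer_,
                     fitted_on = obj$fitted_on %||% NA_character_)
}

#' Write / read an amorphous reference
#'
#' @param reference An `amorphous_reference`.
#' @param path File path.
#' @return `path` (write) or an `amorphous_reference` (read).
#' @export
write_amorphous_reference <- function(reference, path) {
  stopifnot(inherits(reference, "amorphous_reference"))
  obj <- list(
    schema = "ramanci/amorphous_reference/1",
    probe = reference$probe, n_spectra = reference$n_spectra,
    half_window = reference$half_window,
    i380 = as.list(reference$i380), i1096 = as.list(reference$i1096),
    wavenumber = reference$spectrum$wavenumber,
    intensity = reference$spectrum$intensity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_amorphous_reference
#' @export
read_amorphous_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ramanci/amorphous_reference/1")) {
    abort(sprintf("%s is not a ramanci amorphous reference file.", path))
  }
  spec <- if (length(obj$wavenumber)) {
    tibble(wavenumber = obj$wavenumber, intensity = obj$intensity)
  } else NULL
  structure(list(
    spectrum = spec,
    i380 = c(mean = obj$i380$mean, sd = obj$i380$sd),
    i1096 = c(mean = obj$i1096$mean, sd = obj$i1096$sd),
    n_spectra = obj$n_spectra, probe = obj$probe,
    half_window = obj$half_window %||% 5
  ), class = "amorphous_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probe sampling geometry
#'
#' Spot areas of the two non-contact probe heads, computed from their
#' sampling diameters: the MR probe has a nominal 100 um beam diameter
#' (area 7.85e-3 mm^2); the PhAT probe samples a 12.57 mm^2 area,
#' corresponding to an effective 4 mm diameter (its nominal beam diameter
#' is 6 mm).
#'
#' @return A tibble with `probe`, `nominal_beam_diameter_mm`,
#'   `sampling_diameter_mm`, `spot_area_mm2`.
#' @export
probe_geometry <- function() {
  tibble(
    probe = c("MR", "PHAT"),
    nominal_beam_diameter_mm = c(0.1, 6),
    sampling_diameter_mm = c(0.1, 4),
    spot_area_mm2 = spot_area(c(0.1, 4)))
}

#' Spot area from a beam diameter
#'
#' @param diameter_mm Beam diameter in millimetres.
#' @return Circular spot area in mm^2.
#' @export
#' @examples
#' spot_area(0.1)  # 100 um beam -> 7.85e-3 mm^2
spot_area <- function(diameter_mm) {
  pi * (diameter_mm / 2)^2
}
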