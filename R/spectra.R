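## Tidy data contracts
##
## A *spectra table* is a tibble with one row per (spectrum, wavenumber):
## numeric columns `wavenumber` (cm^-1, strictly increasing within a spectrum)
## and `intensity`, plus any of the identity columns `sample_id`, `probe`,
## `state`, `replicate` and the bookkeeping column `processing`.
## A *diffractogram table* uses `two_theta` (degrees) and `counts` instead.

SPECTRUM_ID_COLS <- c("sample_id", "probe", "state", "replicate")
PROBES <- c("MR", "PHAT", "OTHER")
STATES <- c("AS_RECEIVED", "MILLED", "SYNTHETIC")

#' Build a single-spectrum table
#'
#' Constructs a tidy one-spectrum tibble from an axis and intensities,
#' reversing descending input so that the stored wavenumber axis is always
#' ascending.
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1.
#' @param intensity Numeric vector of detector intensities, same length.
#' @param sample_id Sample identifier.
#' @param probe Probe head label: one of `"MR"`, `"PHAT"`, `"OTHER"`.
#' @param state Sample state: `"AS_RECEIVED"`, `"MILLED"` or `"SYNTHETIC"`.
#' @param replicate Positive integer replicate index.
#' @param processing Character scalar describing transforms already applied
#'   (`""` for raw data).
#'
#' @return A tibble with columns `sample_id`, `probe`, `state`, `replicate`,
#'   `processing`, `wavenumber`, `intensity`.
#' @export
#' @examples
#' raman_spectrum(c(200, 201, 202), c(1, 2, 1.5))
raman_spectrum <- function(wavenumber, intensity, sample_id = "sample",
                           probe = "OTHER", state = "SYNTHETIC",
                           replicate = 1L, processing = "") {
  probe <- match.arg(probe, PROBES)
  state <- match.arg(state, STATES)
  xy <- validate_trace(wavenumber, intensity, what = "spectrum")
  tibble(
    sample_id = as.character(sample_id), probe = probe, state = state,
    replicate = as.integer(replicate), processing = processing,
    wavenumber = xy$x, intensity = xy$y
  )
}

#' Build a single-diffractogram table
#'
#' @param two_theta Numeric vector of diffraction angles (degrees 2-theta).
#' @param counts Numeric vector of detector counts, same length.
#' @param sample_id Sample identifier.
#' @param blank_subtracted Logical; has an instrument blank already been
#'   subtracted?
#'
#' @return A tibble with columns `sample_id`, `blank_subtracted`,
#'   `two_theta`, `counts`.
#' @export
xrd_diffractogram <- function(two_theta, counts, sample_id = "sample",
                              blank_subtracted = FALSE) {
  xy <- validate_trace(two_theta, counts, what = "diffractogram")
  tibble(
    sample_id = as.character(sample_id),
    blank_subtracted = isTRUE(blank_subtracted),
    two_theta = xy$x, counts = xy$y
  )
}

## Shared axis/intensity validation; reverses descending axes.
validate_trace <- function(x, y, what = "spectrum") {
  if (length(x) != length(y)) {
    abort(sprintf("%s axis and intensities must have identical length (%d vs %d).",
                  what, length(x), length(y)))
  }
  if (length(x) < 2) {
    abort(sprintf("a %s needs at least 2 points, got %d.", what, length(x)))
  }
  if (anyNA(x) || any(!is.finite(x))) abort(sprintf("non-finite axis values in %s.", what))
  if (anyNA(y) || any(!is.finite(y))) abort(sprintf("non-finite intensity values in %s.", what))
  d <- diff(x)
  if (all(d < 0)) {
    x <- rev(x); y <- rev(y); d <- diff(x)
  }
  if (any(d == 0)) abort(sprintf("duplicate axis values in %s.", what))
  if (any(d < 0)) abort(sprintf("%s axis is neither ascending nor descending.", what))
  list(x = x, y = y)
}

#' Spectrum identity columns present in a table
#'
#' @param data A spectra or diffractogram table.
#' @return Character vector of identity column names (possibly empty).
#' @export
spectrum_id_cols <- function(data) {
  intersect(SPECTRUM_ID_COLS, names(data))
}

## Split a long table into a named list of per-spectrum tibbles, preserving
## first-appearance order.
split_spectra <- function(data) {
  ids <- spectrum_id_cols(data)
  if (length(ids) == 0) return(list(all = data))
  key <- do.call(paste, c(lapply(ids, function(c) data[[c]]), sep = "\r"))
  split(data, factor(key, levels = unique(key)))
}

## Apply a function(wavenumber, intensity, chunk) -> new intensity vector to
## every spectrum in a long table, optionally appending a processing tag.
map_spectra <- function(data, f, tag = NULL,
                        axis = "wavenumber", value = "intensity") {
  stopifnot(is.data.frame(data))
  if (!all(c(axis, value) %in% names(data))) {
    abort(sprintf("expected columns `%s` and `%s`.", axis, value))
  }
  chunks <- split_spectra(data)
  out <- purrr::map(chunks, function(ch) {
    ch[[value]] <- f(ch[[axis]], ch[[value]], ch)
    if (!is.null(tag)) {
      old <- if ("processing" %in% names(ch)) ch$processing[1] else ""
      ch$processing <- if (identical(old, "")) tag else paste(old, tag, sep = "+")
    }
    ch
  })
  dplyr::bind_rows(out)
}

#' Validate a spectra (or diffractogram) table
#'
#' Checks the per-spectrum invariants: strictly increasing finite axis, finite
#' intensities, at least two points, no duplicated axis values.
#'
#' @param data A spectra or diffractogram table.
#' @param kind `"spectrum"` or `"diffractogram"` (selects the expected axis
#'   and value columns).
#' @return `data`, invisibly; errors describe the offending spectrum.
#' @export
validate_spectra <- function(data, kind = c("spectrum", "diffractogram")) {
  kind <- match.arg(kind)
  axis <- if (kind == "spectrum") "wavenumber" else "two_theta"
  value <- if (kind == "spectrum") "intensity" else "counts"
  if (!all(c(axis, value) %in% names(data))) {
    abort(sprintf("expected columns `%s` and `%s`.", axis, value))
  }
  for (ch in split_spectra(data)) {
    x <- ch[[axis]]; y <- ch[[value]]
    if (length(x) < 2) abort(sprintf("a %s has fewer than 2 points.", kind))
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      abort(sprintf("non-finite values in a %s.", kind))
    }
    if (any(diff(x) <= 0)) {
      abort(sprintf("%s axis must be strictly increasing (duplicates or disorder found).", kind))
    }
  }
  invisible(data)
}

#' Do all spectra in a table share one wavenumber grid?
#'
#' @param data A spectra table.
#' @param axis Axis column name.
#' @return `TRUE` if every spectrum's axis is bitwise identical to the first.
#' @export
spectra_share_grid <- function(data, axis = "wavenumber") {
  chunks <- split_spectra(data)
  if (length(chunks) <= 1) return(TRUE)
  ref <- chunks[[1]][[axis]]
  all(vapply(chunks[-1], function(ch) identical(ch[[axis]], ref), logical(1)))
}

#' Resample spectra onto a target wavenumber grid
#'
#' Linear interpolation between bracketing points.  The target grid must lie
#' within each spectrum's axis span; no extrapolation is performed.
#' Resampling a spectrum onto its own axis returns identical intensities.
#'
#' @param data A spectra table.
#' @param grid Numeric vector of target wavenumbers (need not be sorted;
#'   stored ascending).
#' @return A spectra table on the new grid.
#' @export
#' @examples
#' s <- raman_spectrum(c(0, 2, 4), c(0, 4, 0))
#' resample_spectra(s, c(1, 3))$intensity  # 2 2
resample_spectra <- function(data, grid) {
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) < 1 || any(!is.finite(grid))) abort("invalid target grid.")
  chunks <- split_spectra(data)
  out <- purrr::map(chunks, function(ch) {
    x <- ch$wavenumber
    if (min(grid) < min(x) || max(grid) > max(x)) {
      abort(sprintf(
        "target grid [%g, %g] extends beyond the spectrum span [%g, %g]; no extrapolation.",
        min(grid), max(grid), min(x), max(x)))
    }
    newint <- approx(x, ch$intensity, xout = grid, method = "linear")$y
    meta <- ch[1, setdiff(names(ch), c("wavenumber", "intensity")), drop = FALSE]
    dplyr::bind_cols(meta[rep(1, length(grid)), , drop = FALSE],
                     tibble(wavenumber = grid, intensity = newint))
  })
  dplyr::bind_rows(out)
}

## Interpolated intensity read-off at a single axis position.
value_at <- function(x, y, at) {
  if (at < min(x) || at > max(x)) {
    abort(sprintf("position %g lies outside the axis span [%g, %g].", at, min(x), max(x)))
  }
  approx(x, y, xout = at, method = "linear")$y
}
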