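## Pre-processing: anchor-point baseline and SNV normalization.

#' Default anchor wavenumbers for the linear baseline
#'
#' The nine fixed anchor positions used for fluorescence background removal
#' from cellulose Raman spectra: 1500, 1200, 952, 857, 743, 632, 550, 260
#' and 200 cm^-1 (returned sorted ascending).
#'
#' @return Numeric vector of nine wavenumbers (cm^-1).
#' @export
raman_anchors <- function() {
  sort(c(1500, 1200, 952, 857, 743, 632, 550, 260, 200))
}

check_anchors <- function(anchors, x) {
  anchors <- sort(unique(as.numeric(anchors)))
  if (length(anchors) < 2) abort("at least 2 anchor points are required.")
  if (any(!is.finite(anchors))) abort("non-finite anchor wavenumbers.")
  if (min(anchors) < min(x) || max(anchors) > max(x)) {
    abort(sprintf("anchors [%g, %g] fall outside the spectrum span [%g, %g].",
                  min(anchors), max(anchors), min(x), max(x)))
  }
  anchors
}

#' Anchor-point baseline subtraction
#'
#' Subtracts, from every spectrum, the piecewise-linear curve through the
#' points `(a_i, I(a_i))` where `I(a_i)` is the spectrum intensity at anchor
#' `a_i` (linearly interpolated when an anchor is off-grid).  The corrected
#' intensity is exactly zero at every anchor.  Outside the outermost anchors
#' the baseline continues flat at the terminal anchor values.
#'
#' @param data A spectra table.
#' @param anchors Anchor wavenumbers, default [raman_anchors()].
#' @return The spectra table with baselined intensities and a `"baseline"`
#'   processing tag.
#' @export
#' @examples
#' s <- raman_spectrum(c(200, 400, 550), c(1, 4, 2))
#' anchor_baseline(s, anchors = c(200, 550))$intensity
anchor_baseline <- function(data, anchors = raman_anchors()) {
  map_spectra(data, function(x, y, chunk) {
    a <- check_anchors(anchors, x)
    ya <- approx(x, y, xout = a, method = "linear")$y
    base <- approx(a, ya, xout = x, method = "linear", rule = 2)$y
    y - base
  }, tag = "baseline")
}

#' Standard normal variate (SNV) normalization
#'
#' Centers each spectrum to mean zero and scales it to unit sample standard
#' deviation (divisor `n - 1`) over the full stored axis.
#'
#' @param data A spectra table.
#' @return The spectra table with SNV-normalized intensities and an `"snv"`
#'   processing tag.
#' @export
#' @examples
#' snv_normalize(raman_spectrum(1:3, c(1, 2, 3)))$intensity  # -1 0 1
snv_normalize <- function(data) {
  map_spectra(data, function(x, y, chunk) {
    s <- sd(y)
    if (!is.finite(s) || s == 0) {
      abort("cannot SNV-normalize a constant spectrum (zero standard deviation).")
    }
    (y - mean(y)) / s
  }, tag = "snv")
}

#' Standard pre-processing pipeline: baseline then SNV
#'
#' Applies [anchor_baseline()] followed (by default) by [snv_normalize()],
#' the order used throughout the crystallinity models: the baseline removes
#' the fluorescence background, SNV then removes multiplicative intensity
#' differences between spectra.
#'
#' @inheritParams anchor_baseline
#' @param snv Apply SNV after the baseline?
#' @return The pre-processed spectra table.
#' @export
preprocess_spectra <- function(data, anchors = raman_anchors(), snv = TRUE) {
  out <- anchor_baseline(data, anchors = anchors)
  if (snv) out <- snv_normalize(out)
  out
}

#' Scale a reference spectrum to match a target at one wavenumber
#'
#' Multiplies the reference spectrum by
#' `I_target(at) / I_reference(at)` so that the two traces are equal at the
#' matching wavenumber (857 cm^-1 by default, the band conventionally used
#' to put an amorphous reference on the scale of a sample spectrum).
#' Both spectra must share a common grid.
#'
#' @param target Single-spectrum table providing the matching intensity.
#' @param reference Single-spectrum table to be rescaled.
#' @param at Matching wavenumber (cm^-1).
#' @return The rescaled reference table.
#' @export
scale_to_match <- function(target, reference, at = 857) {
  tch <- split_spectra(target); rch <- split_spectra(reference)
  if (length(tch) != 1 || length(rch) != 1) {
    abort("scale_to_match() expects single-spectrum tables.")
  }
  t1 <- tch[[1]]; r1 <- rch[[1]]
  if (!identical(t1$wavenumber, r1$wavenumber)) {
    abort("target and reference must share an identical wavenumber grid.")
  }
  it <- value_at(t1$wavenumber, t1$intensity, at)
  ir <- value_at(r1$wavenumber, r1$intensity, at)
  if (!is.finite(ir) || ir == 0) {
    abort(sprintf("reference intensity at %g cm^-1 is zero; cannot scale.", at))
  }
  r1$intensity <- r1$intensity * (it / ir)
  r1
}
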