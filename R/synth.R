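## Synthetic semi-crystalline cellulose Raman spectra and PXRD
## diffractograms with known crystalline fraction.

#' Band tables for the synthetic cellulose components
#'
#' Crystalline component: 23 bands at the cellulose Raman shifts (the ten
#' crystallinity-informative bands at 380, 437, 458, 521, 1096, 1120, 1330,
#' 1340, 1380 and 1475 cm^-1 plus the surrounding fingerprint bands), with
#' 1096 cm^-1 the strongest and 380 cm^-1 nearly as strong.  Amorphous
#' component: the same centers broadened 1.8x at 0.55x amplitude, except
#' that the two marker bands are strongly attenuated - the 380 cm^-1
#' crystal-packing band almost vanishes and the amorphous 1096 cm^-1
#' backbone intensity is carried mostly by its broadened neighbours.
#'
#' @param component `"crystalline"` or `"amorphous"`.
#' @return A tibble with `center` (cm^-1), `amplitude`, `fwhm` (cm^-1),
#'   `shape`, `eta` (pseudo-Voigt mixing, 0 = Gaussian).
#' @export
cellulose_bands <- function(component = c("crystalline", "amorphous")) {
  component <- match.arg(component)
  center <- c(331, 345, 380, 437, 458, 494, 521, 900, 971, 997, 1037, 1057,
              1096, 1120, 1152, 1275, 1294, 1330, 1340, 1380, 1410, 1460, 1475)
  amp <- c(0.25, 0.22, 0.95, 0.30, 0.35, 0.18, 0.25, 0.28, 0.12, 0.15, 0.22,
           0.30, 1.00, 0.55, 0.30, 0.18, 0.25, 0.25, 0.30, 0.45, 0.22, 0.28, 0.30)
  fwhm <- c(16, 16, 14, 14, 14, 14, 14, 18, 14, 14, 14, 14,
            16, 16, 16, 18, 18, 20, 20, 18, 18, 16, 16)
  if (component == "amorphous") {
    amp <- amp * 0.55
    amp[center == 380] <- 0.06
    amp[center == 1096] <- 0.05
    fwhm <- fwhm * 1.8
  }
  tibble(center = center, amplitude = amp, fwhm = fwhm,
         shape = "gaussian", eta = 0)
}

#' Synthetic-data configuration
#'
#' Collects every tunable of the generator with the defaults used
#' throughout the package's validation studies.
#'
#' @param grid Wavenumber grid (cm^-1).
#' @param crystalline_bands,amorphous_bands Band tables
#'   (see [cellulose_bands()]).
#' @param background Coefficients `c(b0, b1, b2)` of the smooth fluorescence
#'   background `b0 + b1 u + b2 u^2`, `u = (nu - min) / span`.
#' @param gain_sdlog Log-normal standard deviation of the per-spectrum
#'   multiplicative gain.
#' @param noise_sd Additive Gaussian noise standard deviation as a fraction
#'   of the maximum clean intensity.
#' @param order_nonlinearity Interface (paracrystallinity) coefficient
#'   `kappa`: the crystalline 380 cm^-1 band contributes with weight
#'   `chi * (1 - kappa * (1 - chi))` instead of `chi`, reflecting that the
#'   low-frequency packing mode requires extended ordered domains.  `0`
#'   restores exact two-endmember linear mixing.
#' @param probe_effect Named list of per-probe `c(f380, f1096)` amplitude
#'   multipliers applied to the two marker bands.
#' @param diffraction List of diffractogram settings: `grid`, crystalline
#'   `peaks` (tibble center/amplitude/fwhm), halo `center`/`fwhm`, constant
#'   `baseline` counts, logical `poisson_noise`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(grid = 200:1500,
                         crystalline_bands = cellulose_bands("crystalline"),
                         amorphous_bands = cellulose_bands("amorphous"),
                         background = c(0.075, 0.12, 0.09),
                         gain_sdlog = 0.1,
                         noise_sd = 0.01,
                         order_nonlinearity = 1,
                         probe_effect = list(MR = c(1, 1), PHAT = c(0.8, 1.15),
                                             OTHER = c(1, 1)),
                         diffraction = list(
                           grid = seq(10, 30, by = 0.01),
                           peaks = tibble(center = c(14.9, 16.4, 22.7),
                                          amplitude = c(1500, 2500, 5000),
                                          fwhm = c(1.5, 1.5, 1.5)),
                           halo_center = 20.65, halo_fwhm = 8,
                           baseline = 20, poisson_noise = TRUE)) {
  if (any(diff(grid) <= 0)) abort("grid must be strictly ascending.")
  if (gain_sdlog < 0 || noise_sd < 0) abort("gain_sdlog and noise_sd must be >= 0.")
  if (order_nonlinearity < 0 || order_nonlinearity > 1.5) {
    abort("order_nonlinearity must lie in [0, 1.5].")
  }
  structure(list(grid = as.numeric(grid),
                 crystalline_bands = crystalline_bands,
                 amorphous_bands = amorphous_bands,
                 background = background, gain_sdlog = gain_sdlog,
                 noise_sd = noise_sd, order_nonlinearity = order_nonlinearity,
                 probe_effect = probe_effect, diffraction = diffraction),
            class = "synth_config")
}

#' Render a sum of analytic line shapes on a grid
#'
#' Gaussian, Lorentzian or pseudo-Voigt peaks parameterized by center,
#' amplitude (peak height) and full width at half maximum.
#'
#' @param peaks Tibble with `center`, `amplitude`, `fwhm` and optionally
#'   `shape` (`"gaussian"`, `"lorentzian"`, `"pseudo_voigt"`) and `eta`.
#' @param grid Numeric evaluation grid.
#' @return Numeric vector of summed intensities (zeros for an empty table).
#' @export
render_component <- function(peaks, grid) {
  out <- numeric(length(grid))
  if (is.null(peaks) || nrow(peaks) == 0) return(out)
  if (any(peaks$fwhm <= 0) || any(peaks$amplitude <= 0)) {
    abort("peak fwhm and amplitude must be positive.")
  }
  shape <- if ("shape" %in% names(peaks)) peaks$shape else rep("gaussian", nrow(peaks))
  eta <- if ("eta" %in% names(peaks)) peaks$eta else rep(0, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    out <- out + line_shape(grid, peaks$center[i], peaks$amplitude[i],
                            peaks$fwhm[i], shape[i], eta[i])
  }
  out
}

line_shape <- function(x, center, amplitude, fwhm, shape = "gaussian", eta = 0) {
  g <- amplitude * exp(-4 * log(2) * ((x - center) / fwhm)^2)
  if (shape == "gaussian") return(g)
  l <- amplitude / (1 + (2 * (x - center) / fwhm)^2)
  if (shape == "lorentzian") return(l)
  if (shape == "pseudo_voigt") {
    if (eta < 0 || eta > 1) abort("pseudo-Voigt eta must lie in [0, 1].")
    return(eta * l + (1 - eta) * g)
  }
  abort(sprintf("unknown line shape '%s'.", shape))
}

## Clean (noise-free, unit-gain) mixture spectrum for crystalline mass
## fraction chi under a config and probe.
synth_clean <- function(chi, config, probe = "MR") {
  pe <- config$probe_effect[[probe]] %||% c(1, 1)
  cb <- config$crystalline_bands
  ab <- config$amorphous_bands
  cb$amplitude[cb$center == 380] <- cb$amplitude[cb$center == 380] * pe[1]
  cb$amplitude[cb$center == 1096] <- cb$amplitude[cb$center == 1096] * pe[2]
  ab$amplitude[ab$center == 380] <- ab$amplitude[ab$center == 380] * pe[1]
  ab$amplitude[ab$center == 1096] <- ab$amplitude[ab$center == 1096] * pe[2]
  crystalline <- render_component(cb, config$grid)
  amorphous <- render_component(ab, config$grid)
  b380 <- cb[cb$center == 380, , drop = FALSE]
  g380 <- render_component(b380, config$grid)
  u <- (config$grid - min(config$grid)) / diff(range(config$grid))
  bg <- config$background[1] + config$background[2] * u + config$background[3] * u^2
  kappa <- config$order_nonlinearity
  chi * crystalline + (1 - chi) * amorphous -
    kappa * chi * (1 - chi) * g380 + bg
}

#' Generate one synthetic Raman spectrum with known crystalline fraction
#'
#' The clean spectrum is the convex mixture of the crystalline and
#' amorphous components plus the smooth fluorescence background, with the
#' interface (order-nonlinearity) deviation `-kappa chi (1 - chi) g380` on
#' the 380 cm^-1 band; a log-normal multiplicative gain and additive
#' Gaussian noise are then applied.  Output is a pure function of
#' `(fraction, config, probe, seed)`.
#'
#' @param fraction Crystalline mass fraction `chi` in \[0, 1\].
#' @param config A [synth_config()].
#' @param probe Probe label (selects the probe-effect multipliers).
#' @param seed Integer seed for the gain and noise draws.
#' @param sample_id,replicate Identity metadata for the output table.
#' @return A list with `spectrum` (spectra table) and `truth` (one-row
#'   tibble: `sample_id`, `probe`, `replicate`, `fraction`, `gain`, `seed`).
#' @export
synth_raman <- function(fraction, config = synth_config(), probe = "MR",
                        seed = 1, sample_id = "synth", replicate = 1L) {
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1].")
  clean <- synth_clean(fraction, config, probe)
  res <- withr::with_seed(as.integer(seed), {
    gain <- exp(rnorm(1, 0, config$gain_sdlog))
    noise <- rnorm(length(clean), 0, config$noise_sd * max(clean))
    list(y = gain * clean + noise, gain = gain)
  })
  spec <- raman_spectrum(config$grid, res$y, sample_id = sample_id,
                         probe = if (probe %in% PROBES) probe else "OTHER",
                         state = "SYNTHETIC", replicate = replicate)
  truth <- tibble(sample_id = sample_id, probe = probe,
                  replicate = as.integer(replicate), fraction = fraction,
                  gain = res$gain, seed = as.integer(seed))
  list(spectrum = spec, truth = truth)
}

## Derive a stream of per-spectrum seeds from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Generate the calibration blend series
#'
#' Replicated synthetic spectra at the seven calibration mass fractions of
#' crystalline (un-milled) material - 100, 83, 72, 58, 44, 33 and 22% w/w
#' by default - all sharing one grid, with per-spectrum seeds derived from
#' the master seed.
#'
#' @param fractions Crystalline mass fractions of the blends.
#' @param n_replicates Spectra per blend.
#' @param config A [synth_config()].
#' @param probe Probe label.
#' @param seed Master seed.
#' @return A list with `spectra` (long spectra table) and `truth`
#'   (per-spectrum tibble).
#' @export
synth_blend_series <- function(fractions = c(1, 0.83, 0.72, 0.58, 0.44, 0.33, 0.22),
                               n_replicates = 3, config = synth_config(),
                               probe = "MR", seed = 1) {
  if (length(fractions) == 0) {
    return(list(spectra = tibble(), truth = tibble()))
  }
  if (any(fractions < 0 | fractions > 1)) abort("fractions must lie in [0, 1].")
  n <- length(fractions) * n_replicates
  seeds <- derive_seeds(seed, n)
  out <- list(); k <- 0L
  for (i in seq_along(fractions)) {
    id <- sprintf("blend_%03d", round(100 * fractions[i]))
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      out[[k]] <- synth_raman(fractions[i], config, probe = probe,
                              seed = seeds[k], sample_id = id, replicate = r)
    }
  }
  list(spectra = dplyr::bind_rows(purrr::map(out, "spectrum")),
       truth = dplyr::bind_rows(purrr::map(out, "truth")))
}

#' Generate a synthetic powder diffractogram
#'
#' Counts are `chi * (crystalline reflections) + (1 - chi) * halo +
#' baseline + noise` on a 10-30 degree 2-theta grid.  The crystalline
#' pattern has Gaussian reflections at 14.9, 16.4 and 22.7 degrees; the
#' amorphous halo is a broad Gaussian centered between the two Segal
#' windows whose amplitude is normalized so that its mean over the
#' amorphous window equals the crystalline pattern's mean over the 200
#' window - which makes the Segal read-off of a blend linear in the mass
#' fraction, as the calibration design assumes.  Noise is Gaussian with
#' `sd = sqrt(max(counts, 1))` (Poisson approximation).
#'
#' @inheritParams synth_raman
#' @param sample_id Identity for the output table.
#' @return A list with `diffractogram` (table) and `truth` (one-row tibble).
#' @export
synth_diffractogram <- function(fraction, config = synth_config(), seed = 1,
                                sample_id = "synth") {
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1].")
  d <- config$diffraction
  tt <- d$grid
  cryst <- render_component(d$peaks, tt)
  halo1 <- line_shape(tt, d$halo_center, 1, d$halo_fwhm)
  w <- segal_windows()
  wc <- tt >= w$crystalline[1] & tt <= w$crystalline[2]
  wa <- tt >= w$amorphous[1] & tt <= w$amorphous[2]
  halo <- halo1 * mean(cryst[wc]) / mean(halo1[wa])
  clean <- fraction * cryst + (1 - fraction) * halo + d$baseline
  counts <- if (isTRUE(d$poisson_noise)) {
    withr::with_seed(as.integer(seed),
                     clean + rnorm(length(clean), 0, sqrt(pmax(clean, 1))))
  } else clean
  dg <- xrd_diffractogram(tt, counts, sample_id = sample_id,
                          blank_subtracted = FALSE)
  truth <- tibble(sample_id = sample_id, fraction = fraction,
                  seed = as.integer(seed))
  list(diffractogram = dg, truth = truth)
}

#' Instrument blank diffractogram
#'
#' The deterministic constant-baseline trace recorded with no sample,
#' for blank subtraction in [segal_ci()].
#'
#' @param config A [synth_config()].
#' @return A diffractogram table.
#' @export
synth_blank_diffractogram <- function(config = synth_config()) {
  d <- config$diffraction
  xrd_diffractogram(d$grid, rep(d$baseline, length(d$grid)),
                    sample_id = "blank", blank_subtracted = TRUE)
}

#' Generate a multi-batch two-probe panel
#'
#' Emulates a panel of commercial batches measured with both probes:
#' per-batch crystalline fraction drawn uniformly from `ci_range`, small
#' per-batch band-position jitter (up to 1 cm^-1) and log-normal amplitude
#' jitter, MR-probe triplicates and PhAT-probe duplicates by default.
#'
#' @param n_batches Number of batches (>= 2).
#' @param ci_range Range the per-batch crystalline fraction is drawn from;
#'   a degenerate range (equal endpoints) is allowed but flagged with a
#'   warning.
#' @param replicates Named integer vector of replicates per probe.
#' @param config A [synth_config()].
#' @param seed Master seed.
#' @param position_jitter_sd Per-batch band-center jitter sd (cm^-1,
#'   truncated at +-1).
#' @param amplitude_jitter_sdlog Per-batch log-normal band-amplitude jitter.
#' @return A list with `spectra` (long table) and `truth` (per-spectrum
#'   tibble including the batch `fraction`).
#' @export
synth_batch_panel <- function(n_batches = 30, ci_range = c(0.45, 0.90),
                              replicates = c(MR = 3, PHAT = 2),
                              config = synth_config(), seed = 1,
                              position_jitter_sd = 0.5,
                              amplitude_jitter_sdlog = 0.03) {
  if (n_batches < 2) abort("at least 2 batches are required.")
  if (ci_range[1] == ci_range[2]) {
    warn("degenerate ci_range: all batches share one crystalline fraction.")
  }
  master <- derive_seeds(seed, 3)
  fractions <- withr::with_seed(master[1],
                                runif(n_batches, min(ci_range), max(ci_range)))
  n_per_batch <- sum(replicates)
  jitters <- withr::with_seed(master[2], {
    lapply(seq_len(n_batches), function(i) {
      nb <- nrow(config$crystalline_bands)
      list(pos = pmax(-1, pmin(1, rnorm(nb, 0, position_jitter_sd))),
           amp = exp(rnorm(nb, 0, amplitude_jitter_sdlog)))
    })
  })
  seeds <- derive_seeds(master[3], n_batches * n_per_batch)
  out <- list(); k <- 0L
  for (b in seq_len(n_batches)) {
    id <- sprintf("batch_%02d", b)
    cfg_b <- config
    cfg_b$crystalline_bands$center <- config$crystalline_bands$center + jitters[[b]]$pos
    cfg_b$crystalline_bands$amplitude <- config$crystalline_bands$amplitude * jitters[[b]]$amp
    ## keep the marker-band centers identifiable for the probe effect
    cfg_b$crystalline_bands$center[config$crystalline_bands$center %in% c(380, 1096)] <-
      c(380, 1096)
    for (pr in names(replicates)) {
      for (r in seq_len(replicates[[pr]])) {
        k <- k + 1L
        out[[k]] <- synth_raman(fractions[b], cfg_b, probe = pr,
                                seed = seeds[k], sample_id = id, replicate = r)
      }
    }
  }
  list(spectra = dplyr::bind_rows(purrr::map(out, "spectrum")),
       truth = dplyr::bind_rows(purrr::map(out, "truth")))
}
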