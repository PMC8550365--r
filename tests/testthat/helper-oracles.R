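# Shared fixtures and independent oracles used across the test files.

# A small synthetic spectrum on the integer acquisition grid (so that the
# default anchors fall exactly on grid points).
toy_spectrum <- function(seed = 1, id = "toy") {
  withr::with_seed(seed, {
    x <- 200:1500
    y <- 1 + 0.5 * sin(x / 90) + exp(-((x - 700) / 40)^2) +
      runif(length(x), 0, 0.05)
    raman_spectrum(x, y, sample_id = id)
  })
}

# Independent PLS1 oracle: SIMPLS (de Jong 1993).  A genuinely different
# algorithm from the NIPALS sequence; for a univariate response the two give
# identical predictions, which is the property under test.
simpls1_coefficients <- function(x, y, max_factors) {
  x0 <- scale(x, center = TRUE, scale = FALSE)
  y0 <- y - mean(y)
  p <- ncol(x)
  s <- crossprod(x0, y0)
  R <- matrix(0, p, max_factors)
  V <- matrix(0, p, max_factors)
  q <- numeric(max_factors)
  for (k in seq_len(max_factors)) {
    r <- s
    t_vec <- x0 %*% r
    nt <- sqrt(sum(t_vec^2))
    t_vec <- t_vec / nt
    r <- r / nt
    pk <- crossprod(x0, t_vec)
    q[k] <- sum(y0 * t_vec)
    v <- pk
    if (k > 1) {
      Vk <- V[, seq_len(k - 1), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, pk)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, k] <- r
    V[, k] <- v
  }
  sapply(seq_len(max_factors), function(k)
    R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)])
}

simpls1_fitted <- function(x, y, k) {
  b <- simpls1_coefficients(x, y, k)[, k]
  mean(y) + scale(x, center = TRUE, scale = FALSE) %*% b
}

# Drives the full synthetic calibration pipeline (blend series + matched
# diffractograms -> Segal -> calibration -> 380-method prediction) and
# returns per-blend mean predicted %CI next to the generated fraction.
run_blend_recovery <- function(seed, config = synth_config(), n_replicates = 3,
                               n_reference = 10) {
  seeds <- ramanci:::derive_seeds(seed, 3)
  fractions <- c(1, 0.83, 0.72, 0.58, 0.44, 0.33, 0.22)
  blends <- synth_blend_series(fractions, n_replicates = n_replicates,
                               config = config, seed = seeds[1])
  milled <- synth_blend_series(0, n_replicates = n_reference, config = config,
                               seed = seeds[2])
  ref <- build_amorphous_reference(preprocess_spectra(milled$spectra),
                                   half_window = 0)
  proc <- preprocess_spectra(blends$spectra)
  dseeds <- ramanci:::derive_seeds(seeds[3], length(fractions))
  dx <- dplyr::bind_rows(lapply(seq_along(fractions), function(i)
    synth_diffractogram(fractions[i], config, seed = dseeds[i],
                        sample_id = sprintf("blend_%03d",
                                            round(100 * fractions[i])))$diffractogram))
  cal <- workflow_calibrate(proc, dx, ref,
                            blank = synth_blank_diffractogram(config),
                            label = "SYNTH", scale_at_857 = FALSE,
                            half_window = 0)
  pred <- workflow_ci380(proc, calibration = cal$calibration, reference = ref,
                         scale_at_857 = FALSE, half_window = 0,
                         preprocess = FALSE)
  truth <- dplyr::distinct(blends$truth, .data$sample_id, .data$fraction)
  out <- dplyr::left_join(pred$batches, truth, by = "sample_id")
  out <- out[order(-out$fraction), ]
  attr(out, "pearson_r") <- cal$calibration$pearson_r
  out
}
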