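test_that("peak_intensity reads window maxima and exact centers", {
  # triangular band with apex exactly at 380
  x <- 370:390
  tri <- raman_spectrum(x, pmax(0, 7.3 - 0.9 * abs(x - 380)))
  expect_equal(peak_intensity(tri, 380)$intensity, 7.3)

  # window arithmetic: spike at 384 seen at half_window 5 but not 3
  x2 <- 374:386
  y2 <- rep(1, 13); y2[x2 == 384] <- 2.5
  s2 <- raman_spectrum(x2, y2)
  expect_equal(peak_intensity(s2, 380, half_window = 5)$intensity, 2.5)
  expect_equal(peak_intensity(s2, 380, half_window = 3)$intensity, 1.0)

  # half_window 0 interpolates at the center
  s3 <- raman_spectrum(c(379, 381), c(1, 3))
  expect_equal(peak_intensity(s3, 380, half_window = 0)$intensity, 2)

  s4 <- toy_spectrum(1)
  expect_error(peak_intensity(s4, 5000), "window|span|outside")
})

test_that("build_amorphous_reference averages spectra and band statistics", {
  x <- seq(200, 1500, 5)
  mk <- function(a, id) {
    y <- a * exp(-((x - 380) / 10)^2) + 2 * exp(-((x - 1096) / 12)^2) + 0.1
    raman_spectrum(x, y, sample_id = id, state = "MILLED", processing = "baseline+snv")
  }
  one <- mk(0.4, "m1")
  ref1 <- build_amorphous_reference(one)
  expect_equal(ref1$spectrum$intensity, one$intensity)
  expect_equal(ref1$i380[["sd"]], 0)
  expect_equal(ref1$n_spectra, 1)

  # band read-offs include the 0.1 pedestal: 0.5 and 0.9 -> mean 0.7, sd as
  # for values 0.4 / 0.8 (the pedestal shifts only the mean)
  both <- dplyr::bind_rows(mk(0.4, "m1"), mk(0.8, "m2"))
  ref2 <- build_amorphous_reference(both)
  expect_equal(ref2$i380[["mean"]], 0.7, tolerance = 1e-6)
  expect_equal(ref2$i380[["sd"]], 0.2828427, tolerance = 1e-4)

  # pointwise mean of identical spectra is that spectrum
  same <- dplyr::bind_rows(mk(0.5, "a"), mk(0.5, "b"), mk(0.5, "c"))
  ref3 <- build_amorphous_reference(same)
  expect_equal(ref3$spectrum$intensity, mk(0.5, "a")$intensity)
  expect_equal(ref3$i380[["sd"]], 0)

  expect_error(build_amorphous_reference(
    dplyr::bind_rows(mk(0.4, "m1"),
                     raman_spectrum(seq(200, 1500, 10), rep(1, 131),
                                    sample_id = "odd"))), "grid")
})

test_that("amorphous reference invariant: stored band values match its spectrum", {
  milled <- synth_blend_series(0, n_replicates = 4, seed = 3)$spectra
  ref <- build_amorphous_reference(preprocess_spectra(milled))
  # the averaged spectrum's own band intensity should be consistent with the
  # recorded per-spectrum mean (identical up to max-vs-mean readoff ordering)
  own380 <- peak_intensity(
    raman_spectrum(ref$spectrum$wavenumber, ref$spectrum$intensity), 380)$intensity
  expect_lt(abs(own380 - ref$i380[["mean"]]), 0.05)
})

test_that("amorphous-subtracted ratio reproduces the published-value arithmetic", {
  x <- seq(200, 1500, 1)
  mk_flat_bands <- function(i380, i1096) {
    y <- rep(0, length(x))
    y[x >= 375 & x <= 385] <- i380
    y[x >= 1091 & x <= 1101] <- i1096
    raman_spectrum(x, y, processing = "baseline+snv")
  }
  mr <- published_amorphous_reference("MR")
  r <- amorphous_subtracted_ratio(mk_flat_bands(2.0, 3.5), mr,
                                  scale_at_857 = FALSE)
  expect_equal(r$ratio, (2.0 - 0.627) / (3.5 - 2.745), tolerance = 1e-12)
  expect_equal(r$ratio, 1.81854, tolerance = 1e-4)

  phat <- published_amorphous_reference("PHAT")
  r2 <- amorphous_subtracted_ratio(mk_flat_bands(1.694, 3.607), phat,
                                   scale_at_857 = FALSE)
  expect_equal(r2$ratio, 0.5, tolerance = 1e-12)

  # a sample identical to the reference has a degenerate denominator
  self <- mk_flat_bands(0.627, 2.745)
  expect_error(amorphous_subtracted_ratio(self, mr, scale_at_857 = FALSE),
               "degenerate|indistinguishable")

  # value-only references cannot be 857-scaled
  expect_error(amorphous_subtracted_ratio(mk_flat_bands(2, 3.5), mr,
                                          scale_at_857 = TRUE), "857")
})

test_that("ratio is monotone in the band intensities", {
  mr <- published_amorphous_reference("MR")
  x <- seq(200, 1500, 1)
  mk <- function(i380, i1096) {
    y <- rep(0, length(x))
    y[x >= 375 & x <= 385] <- i380
    y[x >= 1091 & x <= 1101] <- i1096
    raman_spectrum(x, y, processing = "baseline+snv")
  }
  r_base <- amorphous_subtracted_ratio(mk(2, 3.5), mr, scale_at_857 = FALSE)$ratio
  r_hi380 <- amorphous_subtracted_ratio(mk(2.4, 3.5), mr, scale_at_857 = FALSE)$ratio
  r_hi1096 <- amorphous_subtracted_ratio(mk(2, 4.0), mr, scale_at_857 = FALSE)$ratio
  expect_gt(r_hi380, r_base)
  expect_lt(r_hi1096, r_base)
})

test_that("built-in calibrations carry the published constants", {
  orig <- builtin_calibration("ORIGINAL")
  expect_equal(ci_from_ratio(0.0286, orig), 0)
  expect_equal(ci_from_ratio(0.678, orig), (0.678 - 0.0286) / 0.0065)
  expect_equal(ci_from_ratio(0.678, orig), 99.9077, tolerance = 1e-4)

  mr <- builtin_calibration("MR")
  expect_equal(ci_from_ratio(0.366, mr), 100, tolerance = 1e-10)
  expect_equal(ci_from_ratio(-0.134, mr), 0)

  phat <- builtin_calibration("PHAT")
  expect_equal(ci_from_ratio(-0.129, phat), 0)
  expect_equal(ci_from_ratio(0.371, phat), 100, tolerance = 1e-10)
})

test_that("ci_from_ratio is linear, optionally clipped, monotone", {
  cal <- builtin_calibration("ORIGINAL")
  r <- seq(-0.2, 1, 0.1)
  ci <- ci_from_ratio(r, cal)
  expect_equal(diff(ci), rep(0.1 / cal$slope, length(r) - 1), tolerance = 1e-9)
  expect_true(all(diff(ci) > 0))
  expect_warning(ci2 <- ci_from_ratio(c(-1, 0.0286, 2), cal, clip = TRUE), "clip")
  expect_equal(ci2, c(0, 0, 100))
})

test_that("fit_calibration recovers exact lines and stores provenance", {
  ci <- c(0, 25, 50, 75, 100)
  mr_like <- tibble::tibble(ratio = 0.005 * ci - 0.134, ci = ci)
  cal <- fit_calibration(mr_like, label = "MRfit")
  expect_equal(cal$slope, 0.005, tolerance = 1e-12)
  expect_equal(cal$intercept, -0.134, tolerance = 1e-12)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cal$n_points, 5)

  orig_like <- tibble::tibble(ratio = 0.0065 * ci + 0.0286, ci = ci)
  cal2 <- fit_calibration(orig_like)
  expect_equal(cal2$slope, 0.0065, tolerance = 1e-12)
  expect_equal(cal2$intercept, 0.0286, tolerance = 1e-12)

  # training %CI reproduced exactly on collinear pairs
  expect_lt(max(abs(ci_from_ratio(mr_like$ratio, cal) - ci)), 1e-9)

  expect_error(fit_calibration(tibble::tibble(ratio = c(1, 2, 3), ci = rep(50, 3))),
               "equal|rank")
  expect_error(fit_calibration(mr_like[1:2, ]), "3")

  # inverse direction agrees on exact lines
  cal3 <- fit_calibration(mr_like, direction = "inverse")
  expect_equal(cal3$slope, 0.005, tolerance = 1e-9)
  expect_equal(cal3$intercept, -0.134, tolerance = 1e-7)
})

test_that("calibration serialization round-trips", {
  cal <- fit_calibration(tibble::tibble(ratio = 0.005 * c(0, 50, 100) - 0.134,
                                        ci = c(0, 50, 100)), label = "RT")
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(back$label, "RT")
  expect_equal(back$pearson_r, cal$pearson_r)
})

test_that("amorphous reference serialization round-trips", {
  milled <- synth_blend_series(0, n_replicates = 2, seed = 5)$spectra
  ref <- build_amorphous_reference(preprocess_spectra(milled))
  f <- withr::local_tempfile(fileext = ".json")
  write_amorphous_reference(ref, f)
  back <- read_amorphous_reference(f)
  expect_equal(back$i380, ref$i380)
  expect_equal(back$i1096, ref$i1096)
  expect_equal(back$spectrum$intensity, ref$spectrum$intensity)
  expect_equal(back$n_spectra, ref$n_spectra)
})

test_that("batch_ci aggregates replicates and accommodates failures", {
  mr_cal <- builtin_calibration("MR")
  mr_ref <- published_amorphous_reference("MR")
  x <- seq(200, 1500, 1)
  mk <- function(ratio_target, id, rep) {
    # invert the ratio arithmetic: choose I380 so that the ratio is as asked
    i1096 <- 4
    i380 <- ratio_target * (i1096 - 2.745) + 0.627
    y <- rep(0, length(x))
    y[x >= 375 & x <= 385] <- i380
    y[x >= 1091 & x <= 1101] <- i1096
    raman_spectrum(x, y, sample_id = id, replicate = rep,
                   processing = "baseline+snv")
  }
  # ratios chosen to give %CI of 80, 82, 84 under the MR line
  want <- 0.005 * c(80, 82, 84) - 0.134
  batch <- dplyr::bind_rows(mk(want[1], "b1", 1), mk(want[2], "b1", 2),
                            mk(want[3], "b1", 3))
  res <- batch_ci(batch, mr_ref, mr_cal, scale_at_857 = FALSE)
  expect_equal(res$batches$ci_mean, 82, tolerance = 1e-9)
  expect_equal(res$batches$ci_sd, 2, tolerance = 1e-9)

  single <- batch_ci(mk(want[1], "b2", 1), mr_ref, mr_cal, scale_at_857 = FALSE)
  expect_equal(single$batches$ci_sd, 0)
  expect_equal(single$batches$n, 1)

  # a degenerate replicate is flagged, the rest aggregated, with a warning
  bad <- mk(want[1], "b3", 3)
  bad$intensity[bad$wavenumber >= 1091 & bad$wavenumber <= 1101] <- 2.745
  mixed <- dplyr::bind_rows(mk(want[1], "b3", 1), mk(want[2], "b3", 2), bad)
  expect_warning(res3 <- batch_ci(mixed, mr_ref, mr_cal, scale_at_857 = FALSE),
                 "excluded")
  expect_equal(res3$batches$n, 2)
  expect_equal(res3$batches$n_failed, 1)
  expect_equal(res3$batches$ci_mean, 81, tolerance = 1e-9)
})

test_that("probe geometry computes spot areas from diameters", {
  expect_equal(spot_area(0.1), pi * 0.05^2)
  geom <- probe_geometry()
  expect_equal(signif(geom$spot_area_mm2[geom$probe == "MR"], 3), 7.85e-3)
  expect_equal(signif(geom$spot_area_mm2[geom$probe == "PHAT"], 4), 12.57)
})
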