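test_that("line shapes honour the FWHM definition and sum additively", {
  peaks <- tibble::tibble(center = 380, amplitude = 1, fwhm = 10)
  y <- render_component(peaks, c(375, 380, 385))
  expect_equal(y[2], 1)
  expect_equal(y[1], 0.5, tolerance = 1e-12)  # half maximum at half the FWHM
  expect_equal(y[3], 0.5, tolerance = 1e-12)

  expect_equal(render_component(peaks[0, ], 1:5), rep(0, 5))

  two <- dplyr::bind_rows(peaks, peaks)
  expect_equal(render_component(two, 370:390), 2 * render_component(peaks, 370:390))

  lor <- tibble::tibble(center = 0, amplitude = 2, fwhm = 4, shape = "lorentzian")
  expect_equal(render_component(lor, c(-2, 0, 2)), c(1, 2, 1))
  pv <- tibble::tibble(center = 0, amplitude = 1, fwhm = 4,
                       shape = "pseudo_voigt", eta = 0.5)
  expect_equal(render_component(pv, 0), 1)
  expect_error(render_component(tibble::tibble(center = 1, amplitude = -1, fwhm = 2), 1:3),
               "positive")
})

test_that("pure endmembers and exact mixing at zero order-nonlinearity", {
  cfg <- synth_config(noise_sd = 0, gain_sdlog = 0, background = c(0, 0, 0),
                      order_nonlinearity = 0)
  c1 <- synth_raman(1, cfg, seed = 1)$spectrum$intensity
  a0 <- synth_raman(0, cfg, seed = 2)$spectrum$intensity
  expect_equal(c1, render_component(cellulose_bands("crystalline"), cfg$grid))
  expect_equal(a0, render_component(cellulose_bands("amorphous"), cfg$grid))

  for (chi in c(0.25, 0.5, 0.83)) {
    mix <- synth_raman(chi, cfg, seed = 3)$spectrum$intensity
    expect_equal(mix, chi * c1 + (1 - chi) * a0, tolerance = 1e-12)
  }
})

test_that("the interface deviation is exactly -kappa chi (1-chi) g380", {
  cfg <- synth_config(noise_sd = 0, gain_sdlog = 0, background = c(0, 0, 0))
  kappa <- cfg$order_nonlinearity
  c1 <- synth_raman(1, cfg, seed = 1)$spectrum$intensity
  a0 <- synth_raman(0, cfg, seed = 1)$spectrum$intensity
  g380 <- render_component(
    dplyr::filter(cellulose_bands("crystalline"), .data$center == 380), cfg$grid)
  for (chi in c(0.3, 0.58, 0.9)) {
    mix <- synth_raman(chi, cfg, seed = 2)$spectrum$intensity
    linear <- chi * c1 + (1 - chi) * a0
    expect_equal(mix - linear, -kappa * chi * (1 - chi) * g380, tolerance = 1e-12)
  }
})

test_that("generator outputs are pure functions of (config, args, seed)", {
  cfg <- synth_config()
  a <- synth_raman(0.6, cfg, seed = 123)
  b <- synth_raman(0.6, cfg, seed = 123)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_identical(a$truth$gain, b$truth$gain)
  c_ <- synth_raman(0.6, cfg, seed = 124)
  expect_false(identical(a$spectrum$intensity, c_$spectrum$intensity))

  s1 <- synth_blend_series(seed = 7)
  s2 <- synth_blend_series(seed = 7)
  expect_identical(s1$spectra, s2$spectra)

  p1 <- synth_batch_panel(n_batches = 4, seed = 5)
  p2 <- synth_batch_panel(n_batches = 4, seed = 5)
  expect_identical(p1$spectra, p2$spectra)

  d1 <- synth_diffractogram(0.4, cfg, seed = 9)
  d2 <- synth_diffractogram(0.4, cfg, seed = 9)
  expect_identical(d1$diffractogram$counts, d2$diffractogram$counts)

  expect_error(synth_raman(1.2, cfg), "\\[0, 1\\]")
})

test_that("blend series covers the seven calibration fractions", {
  s <- synth_blend_series(n_replicates = 3, seed = 1)
  expect_equal(length(split_spectra(s$spectra)), 21)
  expect_setequal(unique(s$truth$fraction),
                  c(1, 0.83, 0.72, 0.58, 0.44, 0.33, 0.22))
  expect_true(spectra_share_grid(s$spectra))

  empty <- synth_blend_series(fractions = numeric(0))
  expect_equal(nrow(empty$spectra), 0)
})

test_that("the subtracted ratio is monotone and affine in the fraction at zero noise", {
  cfg <- synth_config(noise_sd = 0, gain_sdlog = 0)
  fr <- c(1, 0.83, 0.72, 0.58, 0.44, 0.33, 0.22)
  blends <- synth_blend_series(fr, n_replicates = 1, config = cfg, seed = 1)
  milled <- synth_blend_series(0, n_replicates = 1, config = cfg, seed = 2)
  ref <- build_amorphous_reference(preprocess_spectra(milled$spectra),
                                   half_window = 0)
  proc <- preprocess_spectra(blends$spectra)
  rat <- amorphous_subtracted_ratio(proc, ref, scale_at_857 = FALSE,
                                    half_window = 0)
  truth <- blends$truth[match(rat$sample_id, blends$truth$sample_id), ]
  ord <- order(truth$fraction)
  expect_true(all(diff(rat$ratio[ord]) > 0))
  # affine in chi: r^2 of the straight-line fit above 0.999
  fit <- lm(rat$ratio ~ truth$fraction)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("synthetic diffractograms give a Segal read-off linear in the fraction", {
  cfg <- synth_config()
  cfg$diffraction$poisson_noise <- FALSE
  blank <- synth_blank_diffractogram(cfg)

  ci1 <- segal_ci(synth_diffractogram(1, cfg)$diffractogram, blank = blank)$ci
  expect_gte(ci1, 99)
  ci0 <- segal_ci(synth_diffractogram(0, cfg)$diffractogram, blank = blank)$ci
  expect_lte(abs(ci0), 5)

  cis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(chi)
    segal_ci(synth_diffractogram(chi, cfg)$diffractogram, blank = blank)$ci,
    numeric(1))
  expect_true(all(diff(cis) > 0))
  expect_lt(max(abs(cis - c(0, 25, 50, 75, 100))), 1)
})

test_that("batch panels have the declared size, truth and probe structure", {
  p <- synth_batch_panel(n_batches = 30, seed = 7)
  expect_equal(length(split_spectra(p$spectra)), 150)  # 30 x (3 MR + 2 PhAT)
  expect_equal(dplyr::n_distinct(p$truth$fraction), 30)
  expect_equal(sum(p$truth$probe == "MR"), 90)
  expect_equal(sum(p$truth$probe == "PHAT"), 60)
  expect_true(spectra_share_grid(p$spectra))

  expect_warning(synth_batch_panel(n_batches = 3, ci_range = c(0.6, 0.6), seed = 1),
                 "degenerate")
  expect_error(synth_batch_panel(n_batches = 1), "2 batches")
})
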