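test_that("noise-free blends are recovered almost exactly end to end", {
  cfg <- synth_config(noise_sd = 0, gain_sdlog = 0)
  cfg$diffraction$poisson_noise <- FALSE
  out <- run_blend_recovery(seed = 1, config = cfg, n_replicates = 1,
                            n_reference = 1)
  expect_lt(max(abs(out$ci_mean - 100 * out$fraction)), 0.5)
})

test_that("calibration workflow: exactness, minimum blends, noisy correlation", {
  cfg <- synth_config(noise_sd = 0, gain_sdlog = 0)
  cfg$diffraction$poisson_noise <- FALSE
  seeds <- ramanci:::derive_seeds(3, 2)
  fr <- c(1, 0.72, 0.44, 0.22)
  blends <- synth_blend_series(fr, n_replicates = 1, config = cfg, seed = seeds[1])
  milled <- synth_blend_series(0, n_replicates = 1, config = cfg, seed = seeds[2])
  ref <- build_amorphous_reference(preprocess_spectra(milled$spectra),
                                   half_window = 0)
  proc <- preprocess_spectra(blends$spectra)
  dx <- dplyr::bind_rows(lapply(fr, function(chi)
    synth_diffractogram(chi, cfg, sample_id = sprintf("blend_%03d",
                                                      round(100 * chi)))$diffractogram))
  res <- workflow_calibrate(proc, dx, ref, blank = synth_blank_diffractogram(cfg),
                            scale_at_857 = FALSE, half_window = 0)
  expect_gt(res$calibration$pearson_r, 1 - 1e-4)
  resid <- res$pairs$ratio -
    (res$calibration$slope * res$pairs$ci + res$calibration$intercept)
  # residuals below half a %CI unit once mapped through the slope
  expect_lt(max(abs(resid)) / res$calibration$slope, 0.5)

  # fewer than 3 blends is a configuration error
  two <- proc[proc$sample_id %in% c("blend_100", "blend_072"), ]
  dx2 <- dx[dx$sample_id %in% c("blend_100", "blend_072"), ]
  expect_error(workflow_calibrate(two, dx2, ref, scale_at_857 = FALSE,
                                  half_window = 0), "3 blends")

  # mismatched modalities
  dx3 <- dx[dx$sample_id != "blend_100", ]
  expect_error(workflow_calibrate(proc, dx3, ref, scale_at_857 = FALSE,
                                  half_window = 0), "one-to-one")

  # default-noise blends still calibrate with r > 0.99
  noisy <- run_blend_recovery(seed = 7)
  expect_gt(attr(noisy, "pearson_r"), 0.99)
})

test_that("ci380 workflow writes per-replicate and per-batch tables", {
  out_dir <- withr::local_tempdir()
  blends <- synth_blend_series(c(1, 0.5), n_replicates = 2, seed = 11)
  milled <- synth_blend_series(0, n_replicates = 3, seed = 12)
  ref <- build_amorphous_reference(preprocess_spectra(milled$spectra),
                                   half_window = 0)
  res <- workflow_ci380(blends$spectra, calibration = "MR", reference = ref,
                        scale_at_857 = FALSE, half_window = 0,
                        out_dir = out_dir)
  expect_equal(nrow(res$replicates), 4)
  expect_equal(nrow(res$batches), 2)
  expect_true(file.exists(file.path(out_dir, "ci380_replicates.csv")))
  expect_true(file.exists(file.path(out_dir, "ci380_provenance.json")))

  # re-running the same configuration reproduces the same numbers
  res2 <- workflow_ci380(blends$spectra, calibration = "MR", reference = ref,
                         scale_at_857 = FALSE, half_window = 0)
  expect_equal(res2$batches$ci_mean, res$batches$ci_mean, tolerance = 1e-12)

  expect_error(workflow_ci380(character(0)), "no input|resolve")
  expect_error(workflow_ci380("/nonexistent/glob*.csv"), "no input")
  expect_error(workflow_ci380(blends$spectra, calibration = "NOPE",
                              reference = ref), "resolve")
})

test_that("model workflow fits, selects factors, predicts and reports metrics", {
  panel <- synth_batch_panel(n_batches = 10, seed = 21)
  proc <- preprocess_spectra(panel$spectra)
  truth <- dplyr::distinct(panel$truth, .data$sample_id, .data$fraction)
  ids <- unique(proc$sample_id)
  cal_ids <- ids[1:8]; val_ids <- ids[9:10]
  cal <- proc[proc$sample_id %in% cal_ids, ]
  val <- proc[proc$sample_id %in% val_ids, ]
  y_of <- function(d) {
    m <- spectra_matrix(d)
    100 * truth$fraction[match(m$meta$sample_id, truth$sample_id)]
  }
  out_dir <- withr::local_tempdir()
  fit <- workflow_model(cal, "fit", y = y_of(cal), max_factors = 3,
                        out_dir = out_dir)
  expect_s3_class(fit$model, "pls1_model")
  expect_true(fit$selected_factors %in% 1:3)
  expect_true(file.exists(file.path(out_dir, "pls_model.json")))

  pred <- workflow_model(val, "predict", y = y_of(val),
                         model = file.path(out_dir, "pls_model.json"),
                         n_factors = 3)
  expect_true(is.finite(pred$metrics$rmsep))
  expect_lt(pred$metrics$rmsep, sd(y_of(val)))

  # grid mismatch is a configuration error
  shifted <- val
  shifted$wavenumber <- shifted$wavenumber + 0.5
  expect_error(workflow_model(shifted, "predict",
                              model = file.path(out_dir, "pls_model.json")),
               "grid")
})

test_that("single-latent-factor data is explained by one factor", {
  # spectra vary along a single spectral direction with y proportional to it
  x <- seq(250, 1500, 5)
  base <- exp(-((x - 900) / 120)^2)
  dirn <- exp(-((x - 400) / 60)^2)
  spectra <- dplyr::bind_rows(lapply(1:8, function(i) {
    a <- i / 8
    raman_spectrum(x, base + a * dirn, sample_id = sprintf("s%02d", i),
                   processing = "baseline+snv")
  }))
  y <- 100 * (1:8) / 8
  fit <- workflow_model(spectra, "fit", y = y, max_factors = 1)
  expect_gt(fit$model$stats$explained_calibration_pct[1], 99)
})

test_that("pca workflow separates probes and degrades gracefully", {
  panel <- synth_batch_panel(n_batches = 8, seed = 31)
  proc <- preprocess_spectra(panel$spectra)
  res <- workflow_pca(proc, n_components = 2)
  expect_true(all(c("PC1", "PC2") %in% names(res$scores)))
  expect_true("validation_variance_pct" %in% names(res$variance))

  # one of the first two components separates the probes by a threshold
  separable <- vapply(c("PC1", "PC2"), function(pc) {
    a <- res$scores[[pc]][res$scores$probe == "MR"]
    b <- res$scores[[pc]][res$scores$probe == "PHAT"]
    max(a) < min(b) || max(b) < min(a)
  }, logical(1))
  expect_true(any(separable))

  # single-group input: CV skipped with a warning, calibration variance kept
  single <- proc[proc$sample_id == proc$sample_id[1], ]
  expect_warning(res1 <- workflow_pca(single, n_components = 2), "skipped")
  expect_false("validation_variance_pct" %in% names(res1$variance))
  expect_true(all(is.finite(res1$variance$explained_variance_pct)))
})

test_that("the command-line front end drives the workflows", {
  out_dir <- withr::local_tempdir()
  sim_dir <- file.path(out_dir, "sim")
  expect_equal(ramanci_main(c("simulate", "blends", "--out", sim_dir,
                              "--seed", "3", "--replicates", "2")), 0L)
  files <- list.files(sim_dir, pattern = "^blend.*csv$", full.names = TRUE)
  expect_length(files, 14)
  expect_true(file.exists(file.path(sim_dir, "ground_truth.csv")))

  pre_dir <- file.path(out_dir, "pre")
  expect_equal(ramanci_main(c("preprocess", "--in",
                              file.path(sim_dir, "blend*.csv"),
                              "--out", pre_dir)), 0L)
  expect_true(file.exists(file.path(pre_dir, "preprocessed_spectra.csv")))

  ci_dir <- file.path(out_dir, "ci")
  expect_equal(ramanci_main(c("ci380", "--in", file.path(sim_dir, "blend*.csv"),
                              "--probe", "MR", "--no-scale857",
                              "--out", ci_dir)), 0L)
  expect_true(file.exists(file.path(ci_dir, "ci380_batches.csv")))

  # config errors exit non-zero without writing results
  bad_dir <- file.path(out_dir, "bad")
  expect_equal(ramanci_main(c("ci380", "--in", "/nonexistent/*.csv",
                              "--out", bad_dir)), 3L)
  expect_false(file.exists(file.path(bad_dir, "ci380_batches.csv")))
  expect_equal(ramanci_main("wat"), 2L)
})
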