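test_that("spectrum construction enforces its invariants", {
  expect_error(raman_spectrum(c(1, 2, 2), c(0, 0, 0)), "ascending")
  expect_error(raman_spectrum(1:3, c(0, NA, 0)), "finite")
  expect_error(raman_spectrum(1:3, 1:2), "equal length")
  s <- raman_spectrum(1:5, 5:1, meta = list(cell_id = 2L))
  expect_s3_class(s, "raman_spectrum")
  expect_equal(length(s), 5L)
})

test_that("two-column text and JCAMP-DX files round-trip", {
  s <- raman_spectrum(seq(400, 900, by = 5), sin(seq_len(101) / 7) + 2,
                      meta = list(cell_id = 4L))
  txt <- withr::local_tempfile(fileext = ".txt")
  write_spectrum_txt(s, txt)
  back <- read_spectrum_txt(txt)
  expect_equal(back$wavenumbers, s$wavenumbers)
  expect_equal(back$intensities, s$intensities, tolerance = 1e-9)

  jdx <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(s, jdx, title = "round trip")
  jback <- read_jcamp(jdx)
  expect_equal(jback$wavenumbers, s$wavenumbers, tolerance = 1e-5)
  expect_equal(jback$intensities, s$intensities, tolerance = 1e-5)
  expect_equal(jback$meta$title, "round trip")
})

test_that("polynomial baseline correction is exact for matched models", {
  wn <- seq(400, 1400, by = 2)
  u <- seq_along(wn) / length(wn)
  y <- 5 - 3 * u + 7 * u^2
  s <- raman_spectrum(wn, y)
  out <- baseline_correct(s, "polynomial", degree = 2L)
  expect_lt(max(abs(out$intensities)), 1e-8 * max(abs(y)))
  expect_equal(out$wavenumbers, wn)

  # constant offsets are absorbed for both estimators
  peaks <- 40 * exp(-(wn - 900)^2 / 200)
  noisy <- raman_spectrum(wn, peaks + 0.5 * u)
  shifted <- raman_spectrum(wn, peaks + 0.5 * u + 11)
  for (m in c("polynomial", "als")) {
    a <- baseline_correct(noisy, m)
    b <- baseline_correct(shifted, m)
    expect_equal(a$intensities, b$intensities, tolerance = 1e-6)
  }
  expect_error(baseline_correct(raman_spectrum(1:4, 1:4), "polynomial",
                                degree = 5L), "degree")
})

test_that("a known cubic baseline is removed to within 5% residual RMS", {
  cfg <- qc_grid_cfg()
  wn <- wavenumber_grid(cfg)
  coeffs <- c(100, 60, -90, 50)
  prof <- strain_profile("bl",
    data.frame(center = c(800, 1003, 1450),
               mean_amplitude = c(30, 60, 40),
               amplitude_cv = c(0, 0, 0),
               width_fwhm = c(15, 12, 20)),
    baseline_coeffs = coeffs, noise_sd = 1)
  u <- (wn - wn[1]) / (wn[length(wn)] - wn[1])
  true_baseline <- coeffs[1] + coeffs[2] * u + coeffs[3] * u^2 +
    coeffs[4] * u^3
  ratios <- vapply(1:100, function(seed) {
    s <- simulate_spectrum(prof, cfg, seed = seed)
    corrected <- baseline_correct(s, "polynomial", degree = 5L)
    residual <- corrected$intensities - (s$intensities - true_baseline)
    sqrt(mean(residual^2)) / sqrt(mean(true_baseline^2))
  }, numeric(1))
  expect_lt(mean(ratios), 0.05)
})

test_that("baseline correction handles spectral stacks column-wise", {
  wn <- seq(400, 1000, by = 3)
  u <- seq_along(wn) / length(wn)
  y1 <- 3 + u + 20 * exp(-(wn - 700)^2 / 100)
  y2 <- 1 - 2 * u + 35 * exp(-(wn - 800)^2 / 150)
  stack <- cbind(y1, y2)
  out <- baseline_correct(stack, "polynomial", degree = 3L,
                          wavenumbers = wn)
  single1 <- baseline_correct(raman_spectrum(wn, y1), "polynomial",
                              degree = 3L)
  expect_equal(out[, 1], single1$intensities, tolerance = 1e-10,
               ignore_attr = TRUE)
  st <- spectrum_set(t(stack), labels = c("a", "b"), wavenumbers = wn)
  st2 <- baseline_correct(st, "polynomial", degree = 3L)
  expect_equal(st2$intensities[1, ], single1$intensities,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Savitzky-Golay filtering is exact for polynomials", {
  wn <- seq(400, 1000, by = 2)
  ramp <- raman_spectrum(wn, 3 * wn + 1)
  d1 <- smooth_spectrum(ramp, window = 11, derivative_order = 1)
  interior <- 6:(length(wn) - 5)
  expect_equal(d1$intensities[interior], rep(3, length(interior)),
               tolerance = 1e-6)

  const <- raman_spectrum(wn, rep(4, length(wn)))
  d2 <- smooth_spectrum(const, window = 9, derivative_order = 2)
  expect_equal(d2$intensities, rep(0, length(wn)), tolerance = 1e-10)

  expect_error(smooth_spectrum(ramp, window = 10), "odd")
})

test_that("smoothing matches a pointwise local least-squares oracle", {
  set.seed(77)
  wn <- seq(500, 1000, by = 4)
  y <- sin(wn / 40) + rnorm(length(wn), 0, 0.3)
  s <- raman_spectrum(wn, y)
  sm <- smooth_spectrum(s, window = 11, derivative_order = 0)
  expect_lt(var(sm$intensities - sin(wn / 40)), var(y - sin(wn / 40)))
  pts <- sample(10:(length(wn) - 10), 5)
  for (i in pts) {
    expect_equal(sm$intensities[i],
                 local_ls_fit(wn, y, i, window = 11, poly_order = 2),
                 tolerance = 1e-8)
  }
  # derivative oracle as well
  sm1 <- smooth_spectrum(s, window = 11, derivative_order = 1)
  for (i in pts) {
    expect_equal(sm1$intensities[i],
                 local_ls_fit(wn, y, i, window = 11, poly_order = 2,
                              derivative_order = 1),
                 tolerance = 1e-8)
  }
})

test_that("the Fourier filter passes low frequencies and kills high ones", {
  n <- 64
  wn <- seq_len(n)
  set.seed(5)
  y <- rnorm(n)
  s <- raman_spectrum(wn, y)

  ident <- fourier_filter(s, 1, apodization = "none")
  expect_equal(ident$intensities, y, tolerance = 1e-10)

  low <- raman_spectrum(wn, cos(2 * pi * 3 * (wn - 1) / n))
  passed <- fourier_filter(low, 0.5, apodization = "none")
  expect_equal(passed$intensities, low$intensities, tolerance = 1e-8)

  high <- raman_spectrum(wn, cos(2 * pi * 28 * (wn - 1) / n))
  killed <- fourier_filter(high, 0.25, apodization = "none")
  expect_lt(max(abs(killed$intensities)), 1e-8)

  expect_error(fourier_filter(s, 0), "cutoff")
})

test_that("fourier_filter matches the naive DFT oracle and is linear", {
  n <- 64
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(n)
    s <- raman_spectrum(seq_len(n), y)
    for (apo in c("none", "cosine")) {
      got <- fourier_filter(s, 0.25, apodization = apo)
      expect_equal(got$intensities, naive_dft_filter(y, 0.25, apo),
                   tolerance = 1e-8)
    }
  }
  set.seed(99)
  a <- rnorm(n); b <- rnorm(n)
  fa <- fourier_filter(raman_spectrum(1:n, a), 0.3)$intensities
  fb <- fourier_filter(raman_spectrum(1:n, b), 0.3)$intensities
  fab <- fourier_filter(raman_spectrum(1:n, 2 * a - 5 * b), 0.3)$intensities
  expect_equal(fab, 2 * fa - 5 * fb, tolerance = 1e-8)
})

test_that("normalization modes behave and reject degenerate input", {
  s <- raman_spectrum(c(100, 200, 300), c(1, 2, 2))
  expect_equal(normalize_spectrum(s, "max")$intensities, c(0.5, 1, 1))
  expect_equal(sqrt(sum(normalize_spectrum(s, "vector")$intensities^2)), 1,
               tolerance = 1e-12)
  area <- normalize_spectrum(s, "area")
  trapz <- sum(diff(area$wavenumbers) *
                 (area$intensities[-1] + area$intensities[-3]) / 2)
  expect_equal(trapz, 1, tolerance = 1e-12)
  for (m in c("vector", "area", "max")) {
    s7 <- raman_spectrum(s$wavenumbers, 7 * s$intensities)
    expect_equal(normalize_spectrum(s7, m)$intensities,
                 normalize_spectrum(s, m)$intensities, tolerance = 1e-12)
  }
  expect_error(normalize_spectrum(raman_spectrum(1:4, rep(0, 4))),
               "degenerate")
})

test_that("the SNR estimator is calibrated against simulator truth", {
  cfg <- sim_config(wavenumber_range = c(400, 2000), n_windows = 0)
  prof <- one_peak_profile(amp = 30, noise = 10)
  vals <- vapply(1:200, function(i) {
    snr(simulate_spectrum(prof, cfg, seed = i), 1003, peak_halfwidth = 0)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 3) / 3, 0.15)

  clean <- simulate_spectrum(one_peak_profile(amp = 30, noise = 0), cfg)
  expect_identical(snr(clean, 1003, 5), Inf)

  # pure noise rarely crosses the promotion threshold
  wn <- 400:2000
  fired <- vapply(1:500, function(i) {
    set.seed(i)
    s <- raman_spectrum(wn, rnorm(length(wn), 0, 10))
    snr(s, 1003, 5) > 3
  }, logical(1))
  expect_lt(mean(fired), 0.10)

  expect_error(snr(clean, 1800, 5), "disjoint")
  expect_error(snr(clean, 3000, 5), "outside")
})

test_that("the QC chain composes, preserves the axis, and records steps", {
  cfg <- qc_grid_cfg()
  s <- simulate_spectrum(one_peak_profile(amp = 50, noise = 3), cfg,
                         seed = 21)
  ident_cfg <- qc_config(baseline = NULL,
                         smooth = list(window = 3, derivative_order = 0),
                         fourier = list(cutoff_fraction = 1,
                                        apodization = "none"),
                         normalize = "none")
  out <- qc_chain(s, ident_cfg)
  expect_equal(out$intensities, s$intensities, tolerance = 1e-6)

  full <- qc_chain(s, qc_config())
  expect_equal(full$wavenumbers, s$wavenumbers)
  expect_equal(sqrt(sum(full$intensities^2)), 1, tolerance = 1e-10)
  expect_equal(full$meta$qc_steps,
               c("baseline:polynomial", "sgolay:w11,d0",
                 "fourier:c0.4,cosine", "normalize:vector"))
})

test_that("quality control improves downstream classification", {
  pair <- strain_pair(noise = 8)
  cfg <- qc_grid_cfg()
  qc <- qc_config()
  acc <- function(seed, use_qc) {
    set.seed(seed)
    seeds <- sample.int(1e6, 60)
    tr <- gen_labeled_set(pair, 10, seeds[1:20], cfg,
                          qc = if (use_qc) qc else NULL)
    te <- gen_labeled_set(pair, 20, seeds[21:60], cfg,
                          qc = if (use_qc) qc else NULL)
    ed <- ed_model(tr)
    preds <- vapply(seq_len(length(te)), function(i) {
      classify_spectrum(set_member(te, i), ed)
    }, character(1))
    mean(preds == te$labels)
  }
  with_qc <- mean(vapply(1:20, acc, numeric(1), use_qc = TRUE))
  without <- mean(vapply(1:20, acc, numeric(1), use_qc = FALSE))
  expect_gte(with_qc, without)
})
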