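test_that("place_cells respects counts, bounds and the empty case", {
  prof <- yeast_profile()
  cfg0 <- sim_config(n_windows = 2, cells_per_window = 0)
  expect_equal(nrow(place_cells(cfg0, prof)), 0L)

  cfg <- sim_config(window_size = c(100, 100), n_windows = 3,
                    cells_per_window = 25, rng_seed = 11L)
  tr <- place_cells(cfg, prof)
  expect_equal(nrow(tr), 75L)
  expect_equal(as.vector(table(tr$window_id)), rep(25L, 3))
  expect_true(all(tr$x >= 0 & tr$x <= 100 & tr$y >= 0 & tr$y <= 100))
  expect_true(all(tr$radius > 0))
  # reproducible from the master seed
  expect_identical(tr, place_cells(cfg, prof))
  # overlap flags agree with a direct pairwise check
  w1 <- tr[tr$window_id == 1, ]
  d <- as.matrix(dist(w1[, c("x", "y")]))
  diag(d) <- Inf
  expect_identical(w1$overlaps,
                   unname(apply(d < outer(w1$radius, w1$radius, "+"), 1,
                                any)))
})

test_that("non-overlapping placement fails when the window is too crowded", {
  prof <- yeast_profile()
  cfg <- sim_config(window_size = c(25, 25), n_windows = 1,
                    cells_per_window = 12, rng_seed = 2L)
  expect_error(place_cells(cfg, prof, non_overlapping = TRUE,
                           max_retries = 5L),
               "non-overlapping")
  ok <- place_cells(sim_config(window_size = c(200, 200), n_windows = 1,
                               cells_per_window = 10, rng_seed = 2L),
                    prof, non_overlapping = TRUE)
  expect_false(any(ok$overlaps))
})

test_that("overlap fraction increases with cell density", {
  prof <- yeast_profile()
  frac <- function(n, seed) {
    cfg <- sim_config(window_size = c(100, 100), n_windows = 1,
                      cells_per_window = n, rng_seed = seed)
    mean(place_cells(cfg, prof)$overlaps)
  }
  f100 <- mean(vapply(1:50, function(s) frac(100, s), numeric(1)))
  f200 <- mean(vapply(1:50, function(s) frac(200, s), numeric(1)))
  expect_gt(f200, f100)
})

test_that("Brownian trajectories have the closed-form MSD", {
  frozen <- brownian_positions(c(3, 4), 0, dt = 1, n_steps = 50, seed = 1)
  expect_true(all(frozen[, 1] == 3 & frozen[, 2] == 4))
  expect_error(brownian_positions(c(0, 0), -1, 1, 10), "diffusion")
  expect_error(brownian_positions(c(0, 0), 1, 0, 10), "dt")

  msd_per_step <- function(D, dt, seed) {
    p <- brownian_positions(c(0, 0), D, dt, n_steps = 1e4, seed = seed)
    steps <- diff(p)
    mean(rowSums(steps^2))
  }
  m <- msd_per_step(0.1, 1, seed = 42)
  expect_lt(abs(m - 4 * 0.1 * 1) / (4 * 0.1 * 1), 0.05)
  m2 <- msd_per_step(0.1, 2, seed = 43)
  expect_lt(abs(m2 - 2 * m) / (2 * m), 0.1)
})

test_that("render_field reproduces background statistics and geometry", {
  cfg <- sim_config(window_size = c(50, 50), n_windows = 1, pixel_size = 0.5)
  empty <- manual_truths(numeric(0), numeric(0), numeric(0))
  img <- render_field(empty, cfg, background_level = 0.3,
                      background_noise_sd = 0.05, seed = 7)
  expect_equal(dim(img$pixels), c(100L, 100L))
  expect_lt(abs(mean(img$pixels) - 0.3), 0.005)
  expect_lt(abs(sd(img$pixels) - 0.05), 0.005)

  # one disk, zero noise: every pixel whose center lies inside the disk is
  # brighter than the background
  tr <- manual_truths(25, 25, 4)
  clean <- render_field(tr, cfg, background_level = 0.2,
                        background_noise_sd = 0)
  xc <- (col(clean$pixels) - 0.5) * 0.5
  yc <- (row(clean$pixels) - 0.5) * 0.5
  inside <- sqrt((xc - 25)^2 + (yc - 25)^2) < 4
  expect_true(all(clean$pixels[inside] > 0.2))

  # determinism contract
  a <- render_field(tr, cfg, seed = 5)
  b <- render_field(tr, cfg, seed = 5)
  c <- render_field(tr, cfg, seed = 6)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("simulate_spectrum places peaks, baseline and noise correctly", {
  cfg <- qc_grid_cfg()
  wn <- seq(600, 1800, by = 2)

  s <- simulate_spectrum(one_peak_profile(amp = 50, noise = 0), cfg)
  expect_equal(s$wavenumbers, wn)
  expect_equal(wn[which.max(s$intensities)], 1002)  # grid point nearest 1003

  # zero amplitudes, zero noise: exactly the baseline polynomial
  flat <- strain_profile("flat",
    data.frame(center = 1003, mean_amplitude = 0, amplitude_cv = 0,
               width_fwhm = 12),
    baseline_coeffs = c(2, 3, 4), noise_sd = 0)
  sb <- simulate_spectrum(flat, cfg)
  u <- (wn - 600) / (1800 - 600)
  expect_equal(sb$intensities, 2 + 3 * u + 4 * u^2, tolerance = 1e-12)

  # peak outside the grid is rejected
  expect_error(simulate_spectrum(one_peak_profile(center = 2500), cfg),
               "outside")

  # expected intensity at the peak center = baseline + mean amplitude
  prof <- one_peak_profile(amp = 40, noise = 5, cv = 0.1, baseline = 10)
  at_peak <- vapply(1:500, function(i) {
    sp <- simulate_spectrum(prof, cfg, seed = i)
    sp$intensities[which.min(abs(wn - 1003))]
  }, numeric(1))
  expected <- 10 +
    40 * exp(-(1002 - 1003)^2 / (2 * (12 / 2.3548200450309493)^2))
  expect_lt(abs(mean(at_peak) - expected) / expected, 0.05)

  # determinism
  expect_identical(simulate_spectrum(prof, cfg, seed = 9)$intensities,
                   simulate_spectrum(prof, cfg, seed = 9)$intensities)
})

test_that("lorentzian peaks have the configured half maximum width", {
  cfg <- qc_grid_cfg()
  prof <- strain_profile("lz",
    data.frame(center = 1200, mean_amplitude = 100, amplitude_cv = 0,
               width_fwhm = 40),
    noise_sd = 0, peak_shape = "lorentzian")
  s <- simulate_spectrum(prof, cfg)
  at <- function(w) s$intensities[which.min(abs(s$wavenumbers - w))]
  expect_equal(at(1200), 100, tolerance = 1e-8)
  expect_equal(at(1220), 50, tolerance = 1e-8)  # half max at center + FWHM/2
})

test_that("knn resampling covers degenerate and hand-computed cases", {
  wn <- c(1000, 1001, 1002, 1003, 1004)
  mk <- function(v) raman_spectrum(wn, v)
  tr3 <- spectrum_set(list(mk(c(1, 2, 3, 4, 5)), mk(c(2, 2, 2, 2, 2)),
                           mk(c(0, 1, 0, 1, 0)), mk(c(9, 9, 9, 9, 9))),
                      labels = c("A", "A", "A", "B"))
  # k = 3 over all three A spectra: pointwise mean by hand
  out <- knn_resample_spectrum(tr3, "A", k = 3, perturbation_sd = 0, seed = 1)
  expect_equal(out$intensities, c(1, 5 / 3, 5 / 3, 7 / 3, 7 / 3))

  # k = 1, no perturbation: an exact copy of one training spectrum
  one <- knn_resample_spectrum(tr3, "B", k = 1, perturbation_sd = 0, seed = 2)
  expect_equal(one$intensities, c(9, 9, 9, 9, 9))

  # identical training spectra are a fixed point for any k
  same <- spectrum_set(list(mk(1:5), mk(1:5), mk(1:5)), rep("A", 3))
  expect_equal(knn_resample_spectrum(same, "A", k = 3,
                                     perturbation_sd = 0)$intensities,
               as.numeric(1:5))

  expect_error(knn_resample_spectrum(tr3, "B", k = 2), "fewer than k")
  expect_error(spectrum_set(list(mk(1:5),
                                 raman_spectrum(wn + 1, 1:5)), c("A", "A")),
               "grid")
})

test_that("acquisition hits on target, misses on overlap and drift", {
  cfg <- qc_grid_cfg(detect_to_acquire_lag = 0, diffusion_coefficient = 0)
  prof <- one_peak_profile(noise = 1)
  tr <- manual_truths(50, 50, 2.5)
  hit <- acquire_spectrum(tr[1, ], c(50, 50), prof, cfg, seed = 1)
  expect_s3_class(hit, "raman_spectrum")

  ov <- tr; ov$overlaps <- TRUE
  miss <- acquire_spectrum(ov[1, ], c(50, 50), prof, cfg, seed = 1)
  expect_true(is_miss(miss))
  expect_equal(miss$reason, "overlap")

  # expected displacement far above the radius: mostly misses
  drift_cfg <- qc_grid_cfg(detect_to_acquire_lag = 1,
                           diffusion_coefficient = 200)
  missed <- vapply(1:500, function(i) {
    is_miss(acquire_spectrum(tr[1, ], c(50, 50), prof, drift_cfg, seed = i))
  }, logical(1))
  expect_gt(mean(missed), 0.5)
})

test_that("field images and manifests round-trip through files", {
  cfg <- sim_config(window_size = c(30, 30), n_windows = 1, pixel_size = 0.5,
                    rng_seed = 3L)
  tr <- manual_truths(c(10, 20), c(15, 22), 3)
  img <- render_field(tr, cfg, seed = 3)
  png_path <- withr::local_tempfile(fileext = ".png")
  tif_path <- withr::local_tempfile(fileext = ".tif")
  write_field_image(img, png_path)
  write_field_image(img, tif_path)
  expect_lt(max(abs(read_field_image(png_path, 0.5)$pixels - img$pixels)),
            1 / 255)
  expect_lt(max(abs(read_field_image(tif_path, 0.5)$pixels - img$pixels)),
            1 / 65535)

  man <- withr::local_tempfile(fileext = ".tsv")
  tr_all <- place_cells(cfg, yeast_profile())
  write_truth_manifest(tr_all, man)
  back <- read_truth_manifest(man)
  expect_equal(back$x, tr_all$x, tolerance = 1e-9)
  expect_equal(back$overlaps, tr_all$overlaps)
})
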