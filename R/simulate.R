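#' Generative description of a strain's Raman phenotype
#'
#' A `strain_profile` drives the parametric simulator: a peak library
#' (center, mean amplitude, amplitude CV, FWHM), a polynomial baseline over
#' the wavenumber axis, additive Gaussian noise, and a cell-size
#' distribution. Peaks are Gaussian by default; Lorentzian is available.
#'
#' @param strain_name Text label.
#' @param peaks Data frame with columns `center` (cm^-1), `mean_amplitude`
#'   (intensity units), `amplitude_cv` (dimensionless, >= 0), `width_fwhm`
#'   (cm^-1, > 0).
#' @param baseline_coeffs Polynomial coefficients (ascending powers) over a
#'   wavenumber axis rescaled to \[0, 1\]; default no baseline.
#' @param noise_sd Additive Gaussian noise sd, intensity units.
#' @param cell_radius_mean,cell_radius_sd Cell radius distribution, um.
#' @param peak_shape `"gaussian"` or `"lorentzian"`.
#' @return A `strain_profile`.
#' @export
strain_profile <- function(strain_name, peaks,
                           baseline_coeffs = 0,
                           noise_sd = 0,
                           cell_radius_mean = 2.5,
                           cell_radius_sd = 0.25,
                           peak_shape = c("gaussian", "lorentzian")) {
  peak_shape <- match.arg(peak_shape)
  peaks <- as.data.frame(peaks)
  need <- c("center", "mean_amplitude", "amplitude_cv", "width_fwhm")
  if (!all(need %in% names(peaks))) {
    stop("peaks needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(peaks) && any(peaks$width_fwhm <= 0)) {
    stop("peak widths must be > 0", call. = FALSE)
  }
  if (nrow(peaks) && any(peaks$amplitude_cv < 0)) {
    stop("amplitude_cv must be >= 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cell_radius_mean <= 0) stop("cell_radius_mean must be > 0", call. = FALSE)
  structure(list(strain_name = as.character(strain_name), peaks = peaks,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd, cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd, peak_shape = peak_shape),
            class = "strain_profile")
}

#' Built-in yeast-like strain profile
#'
#' A budding-yeast-like phenotype: the 1003 cm^-1 phenylalanine
#' ring-breathing marker band plus CH2 deformation (1450), amide I (1655)
#' and CH stretch (2935) bands, with mild amplitude variability and shot
#' noise. Amplitudes are in the arbitrary intensity units of the simulator.
#'
#' @param noise_sd Additive noise sd (default 2).
#' @param phe_amplitude Mean amplitude of the 1003 cm^-1 band (default 60,
#'   i.e. SNR approximately `phe_amplitude / noise_sd` at the band).
#' @return A `strain_profile`.
#' @export
yeast_profile <- function(noise_sd = 2, phe_amplitude = 60) {
  strain_profile(
    "yeast-like",
    peaks = data.frame(
      center         = c(1003, 1450, 1655, 2935),
      mean_amplitude = c(phe_amplitude, 35, 30, 50),
      amplitude_cv   = c(0.10, 0.10, 0.12, 0.10),
      width_fwhm     = c(12, 20, 25, 40)),
    baseline_coeffs = c(20, 10, -6),
    noise_sd = noise_sd,
    cell_radius_mean = 2.5, cell_radius_sd = 0.25)
}

#' Simulation configuration
#'
#' Window geometry, wavenumber grid, acquisition timing and the master seed
#' for the whole simulation. The master seed streams child seeds per window
#' and per cell so that every experiment is replayable.
#'
#' Defaults define the shipped calibration: 5 windows of 100 cells in a
#' 800 x 800 um window imaged at 0.5 um/pixel (a sparse plating of roughly
#' 150 cells/mm^2), slide-like Brownian motion (D = 0.05 um^2/s) and a
#' 0.5 s detection-to-acquisition lag.
#'
#' @param window_size `(width, height)` in um.
#' @param n_windows Number of fields.
#' @param cells_per_window Cells per field.
#' @param wavenumber_range `(min, max)` cm^-1.
#' @param wavenumber_step Grid step, cm^-1.
#' @param pixel_size um per pixel.
#' @param diffusion_coefficient Brownian D, um^2/s. See [brownian_presets].
#' @param detect_to_acquire_lag Seconds between imaging and laser pointing.
#' @param rng_seed Master seed (integer).
#' @return A `sim_config`.
#' @export
sim_config <- function(window_size = c(800, 800), n_windows = 5,
                       cells_per_window = 100,
                       wavenumber_range = c(400, 3200), wavenumber_step = 1,
                       pixel_size = 0.5,
                       diffusion_coefficient = 0.05,
                       detect_to_acquire_lag = 0.5,
                       rng_seed = 1L) {
  stopifnot(length(window_size) == 2L, all(window_size > 0),
            n_windows >= 0, cells_per_window >= 0,
            wavenumber_range[1] < wavenumber_range[2], wavenumber_step > 0,
            pixel_size > 0, diffusion_coefficient >= 0,
            detect_to_acquire_lag >= 0)
  structure(list(window_size = as.numeric(window_size),
                 n_windows = as.integer(n_windows),
                 cells_per_window = as.integer(cells_per_window),
                 wavenumber_range = as.numeric(wavenumber_range),
                 wavenumber_step = wavenumber_step,
                 pixel_size = pixel_size,
                 diffusion_coefficient = diffusion_coefficient,
                 detect_to_acquire_lag = detect_to_acquire_lag,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Brownian diffusion presets for suspension vs immobilized conditions
#'
#' Cells suspended in a tube move much more between imaging and laser
#' pointing than cells settled on a slide. These presets emulate the two
#' acquisition conditions as diffusion coefficients.
#'
#' @return Named numeric vector of D values in um^2/s.
#' @export
brownian_presets <- function() c(slide = 0.05, tube = 20)

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d window(s) %g x %g um, %d cells/window, ",
                     "grid %g-%g cm^-1 step %g, pixel %g um, D=%g um^2/s, ",
                     "lag %g s, seed %d\n"),
              x$n_windows, x$window_size[1], x$window_size[2],
              x$cells_per_window, x$wavenumber_range[1], x$wavenumber_range[2],
              x$wavenumber_step, x$pixel_size, x$diffusion_coefficient,
              x$detect_to_acquire_lag, x$rng_seed))
  invisible(x)
}

wavenumber_grid <- function(config) {
  seq(config$wavenumber_range[1], config$wavenumber_range[2],
      by = config$wavenumber_step)
}

# Run code under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic child-seed stream: master seed -> n seeds below 2^31.
child_seeds <- function(master, n, salt = 0L) {
  if (n == 0L) return(integer(0))
  with_seed(master + salt, sample.int(.Machine$integer.max - 1L, n))
}

#' Randomly place cells in simulation windows
#'
#' Cells are placed uniformly inside each window with a margin of one
#' radius plus `border_margin` from the border, so every cell body (and its
#' rendered boundary) lies inside the imaged field. Each
#' cell's `overlaps` flag is TRUE iff its center is closer to another cell's
#' than the sum of their radii.
#'
#' @param config A [sim_config].
#' @param profile A [strain_profile] (radius distribution, strain label).
#' @param non_overlapping If TRUE, resample until no two cells overlap.
#' @param separation Extra edge-to-edge clearance (um) enforced between
#'   cells when `non_overlapping = TRUE` (overlap *flags* always use the
#'   plain sum-of-radii criterion).
#' @param max_retries Placement attempts per window before failing when
#'   `non_overlapping = TRUE`.
#' @param border_margin Extra clearance from the window border beyond the
#'   cell radius, um (default 2).
#' @param seed Optional seed overriding `config$rng_seed`.
#' @return Data frame (one row per cell): `cell_id`, `window_id`, `x`, `y`,
#'   `radius` (um), `strain`, `overlaps`.
#' @export
place_cells <- function(config, profile, non_overlapping = FALSE,
                        separation = 0, max_retries = 200L,
                        border_margin = 2, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(profile, "strain_profile"))
  master <- if (is.null(seed)) config$rng_seed else seed
  seeds <- child_seeds(master, config$n_windows, salt = 101L)
  out <- vector("list", config$n_windows)
  for (w in seq_len(config$n_windows)) {
    out[[w]] <- with_seed(seeds[w],
      place_window(config, profile, w, non_overlapping, separation,
                   max_retries, border_margin))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = integer(0), window_id = integer(0), x = numeric(0),
               y = numeric(0), radius = numeric(0), strain = character(0),
               overlaps = logical(0))
  rownames(res) <- NULL
  res
}

place_window <- function(config, profile, window_id, non_overlapping,
                         separation, max_retries, border_margin = 2) {
  n <- config$cells_per_window
  W <- config$window_size[1]; H <- config$window_size[2]
  empty <- data.frame(cell_id = integer(0), window_id = integer(0),
                      x = numeric(0), y = numeric(0), radius = numeric(0),
                      strain = character(0), overlaps = logical(0))
  if (n == 0L) return(empty)
  for (attempt in seq_len(if (non_overlapping) max_retries else 1L)) {
    r <- abs(stats::rnorm(n, profile$cell_radius_mean, profile$cell_radius_sd))
    r <- pmax(r, 0.2)
    if (any(2 * (r + border_margin) >= W) || any(2 * (r + border_margin) >= H)) {
      stop("window too small for the requested cell radii", call. = FALSE)
    }
    m <- r + border_margin
    x <- stats::runif(n, m, W - m)
    y <- stats::runif(n, m, H - m)
    ov <- overlap_flags(x, y, r)
    crowded <- if (separation > 0) {
      overlap_flags(x, y, r + separation / 2)
    } else ov
    if (!non_overlapping || !any(crowded)) {
      return(data.frame(cell_id = seq_len(n), window_id = window_id,
                        x = x, y = y, radius = r,
                        strain = profile$strain_name, overlaps = ov))
    }
  }
  stop("could not place ", n, " non-overlapping cells in ", max_retries,
       " attempts; window too small", call. = FALSE)
}

overlap_flags <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) return(rep(FALSE, n))
  d <- as.matrix(stats::dist(cbind(x, y)))
  lim <- outer(r, r, "+")
  diag(d) <- Inf
  unname(apply(d < lim, 1L, any))
}

#' Brownian trajectory of a cell
#'
#' Isotropic 2-D Gaussian random walk: per-axis step variance `2 * D * dt`,
#' so the mean squared displacement per step is `4 * D * dt`.
#'
#' @param center Starting `(x, y)` in um.
#' @param diffusion_coefficient D in um^2/s, >= 0.
#' @param dt Time step, s (> 0).
#' @param n_steps Number of steps.
#' @param seed Optional seed.
#' @return `(n_steps + 1) x 2` matrix of positions, row 1 = `center`.
#' @export
brownian_positions <- function(center, diffusion_coefficient, dt, n_steps,
                               seed = NULL) {
  if (diffusion_coefficient < 0) stop("diffusion coefficient must be >= 0",
                                      call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  stopifnot(length(center) == 2L, n_steps >= 0)
  run <- function() {
    sd_step <- sqrt(2 * diffusion_coefficient * dt)
    steps <- matrix(stats::rnorm(2L * n_steps, 0, sd_step), ncol = 2L)
    pos <- rbind(c(0, 0), apply(steps, 2L, cumsum))
    if (n_steps == 0L) pos <- matrix(0, 1L, 2L)
    sweep(pos, 2L, as.numeric(center), "+")
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  colnames(p) <- c("x", "y")
  p
}

#' Field image container
#'
#' @param pixels Numeric matrix (rows = y, cols = x), intensities in
#'   \[0, 1\] nominal range, finite and >= 0.
#' @param pixel_size um per pixel.
#' @param window_id Integer id.
#' @return A `field_image`.
#' @export
field_image <- function(pixels, pixel_size, window_id = 1L) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and >= 0", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 window_id = as.integer(window_id)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px (%.1f x %.1f um), window %d\n",
              nrow(x$pixels), ncol(x$pixels),
              ncol(x$pixels) * x$pixel_size, nrow(x$pixels) * x$pixel_size,
              x$window_id))
  invisible(x)
}

#' Render a field of cells as a grayscale image
#'
#' Each cell is a radially shaded disk: intensity rises above background by
#' `cell_contrast` inside the cell, rolled off at the boundary by a logistic
#' edge of width `boundary_sharpness`. Additive Gaussian background noise is
#' applied last. Pixel (row, col) is 0-based internally with its center at
#' `((col + 0.5) * pixel_size, (row + 0.5) * pixel_size)` in stage
#' coordinates (x rightward, y downward, origin at the window's top-left).
#'
#' @param truths Data frame from [place_cells] (one window's rows).
#' @param config A [sim_config].
#' @param background_level Background intensity (default 0.15).
#' @param background_noise_sd Gaussian noise sd (default 0.02).
#' @param cell_contrast Intensity added at a cell's center (default 0.5).
#' @param boundary_sharpness Logistic edge width, um (default 0.3).
#' @param seed Optional seed for the noise field.
#' @return A [field_image].
#' @export
render_field <- function(truths, config, background_level = 0.15,
                         background_noise_sd = 0.02, cell_contrast = 0.5,
                         boundary_sharpness = 0.3, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  psz <- config$pixel_size
  nc <- max(1L, as.integer(round(config$window_size[1] / psz)))
  nr <- max(1L, as.integer(round(config$window_size[2] / psz)))
  img <- matrix(background_level, nr, nc)
  xc <- (seq_len(nc) - 0.5) * psz
  yc <- (seq_len(nr) - 0.5) * psz
  for (i in seq_len(NROW(truths))) {
    r <- truths$radius[i]
    ext <- r + 6 * boundary_sharpness
    cols <- which(xc >= truths$x[i] - ext & xc <= truths$x[i] + ext)
    rows <- which(yc >= truths$y[i] - ext & yc <= truths$y[i] + ext)
    if (!length(cols) || !length(rows)) next
    d <- sqrt(outer((yc[rows] - truths$y[i])^2, (xc[cols] - truths$x[i])^2, "+"))
    img[rows, cols] <- img[rows, cols] +
      cell_contrast * stats::plogis((r - d) / boundary_sharpness)
  }
  if (background_noise_sd > 0) {
    wid <- if (NROW(truths)) truths$window_id[1] else 1L
    nseed <- if (is.null(seed)) config$rng_seed + 7919L * wid else seed
    img <- img + with_seed(nseed,
      matrix(stats::rnorm(nr * nc, 0, background_noise_sd), nr, nc))
  }
  img <- pmin(pmax(img, 0), 1)
  field_image(img, psz,
              window_id = if (NROW(truths)) truths$window_id[1] else 1L)
}

#' Simulate one single-cell Raman spectrum
#'
#' Sum of peak-library bands (amplitudes drawn with the configured CV),
#' a polynomial baseline and additive Gaussian noise, on the configured
#' wavenumber grid.
#'
#' @param profile A [strain_profile].
#' @param config A [sim_config] (wavenumber grid).
#' @param seed Optional seed.
#' @param meta Extra metadata stored on the spectrum.
#' @return A [raman_spectrum].
#' @export
simulate_spectrum <- function(profile, config, seed = NULL, meta = list()) {
  stopifnot(inherits(profile, "strain_profile"), inherits(config, "sim_config"))
  wn <- wavenumber_grid(config)
  pk <- profile$peaks
  if (nrow(pk) && (any(pk$center < min(wn)) || any(pk$center > max(wn)))) {
    stop("peak center outside the configured wavenumber range", call. = FALSE)
  }
  run <- function() {
    y <- eval_baseline(profile$baseline_coeffs, wn)
    for (i in seq_len(nrow(pk))) {
      amp <- stats::rnorm(1, pk$mean_amplitude[i],
                          pk$amplitude_cv[i] * abs(pk$mean_amplitude[i]))
      y <- y + peak_shape_fun(profile$peak_shape, wn, pk$center[i],
                              pk$width_fwhm[i]) * amp
    }
    if (profile$noise_sd > 0) {
      y <- y + stats::rnorm(length(wn), 0, profile$noise_sd)
    }
    y
  }
  y <- if (is.null(seed)) run() else with_seed(seed, run())
  raman_spectrum(wn, y, meta = c(list(strain = profile$strain_name), meta))
}

# polynomial baseline over the wavenumber axis rescaled to [0, 1]
eval_baseline <- function(coeffs, wn) {
  u <- (wn - wn[1]) / (wn[length(wn)] - wn[1])
  y <- numeric(length(wn))
  for (j in seq_along(coeffs)) y <- y + coeffs[j] * u^(j - 1)
  y
}

peak_shape_fun <- function(shape, wn, center, fwhm) {
  if (shape == "gaussian") {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-(wn - center)^2 / (2 * sigma^2))
  } else {
    hw <- fwhm / 2
    hw^2 / ((wn - center)^2 + hw^2)
  }
}

#' Resample a spectrum from labeled templates (k-nearest-neighbour model)
#'
#' Supervised alternative to the parametric generator for when template
#' spectra (for instance, real acquisitions) are available: pick a random
#' anchor of the query label, average its `k` nearest same-label neighbours
#' (Euclidean distance, anchor included), and add Gaussian perturbation.
#'
#' @param training A [spectrum_set] of templates.
#' @param query_label Label to simulate.
#' @param k Number of neighbours averaged (>= 1).
#' @param perturbation_sd Gaussian perturbation sd.
#' @param seed Optional seed.
#' @return A [raman_spectrum].
#' @export
knn_resample_spectrum <- function(training, query_label, k = 3L,
                                  perturbation_sd = 0, seed = NULL) {
  stopifnot(inherits(training, "spectrum_set"), k >= 1L)
  idx <- which(training$labels == query_label)
  if (length(idx) < k) {
    stop("fewer than k spectra labelled '", query_label, "'", call. = FALSE)
  }
  run <- function() {
    anchor <- sample(idx, 1L)
    ref <- training$intensities[idx, , drop = FALSE]
    d <- sqrt(rowSums(sweep(ref, 2L, training$intensities[anchor, ])^2))
    near <- idx[order(d)][seq_len(k)]
    y <- colMeans(training$intensities[near, , drop = FALSE])
    if (perturbation_sd > 0) {
      y <- y + stats::rnorm(length(y), 0, perturbation_sd)
    }
    y
  }
  y <- if (is.null(seed)) run() else with_seed(seed, run())
  raman_spectrum(training$wavenumbers, y,
                 meta = list(strain = query_label, simulated = "knn"))
}

#' Acquisition miss marker
#' @param reason Character reason (`"drift"` or `"overlap"`).
#' @return An `acquisition_miss` object.
#' @export
acquisition_miss <- function(reason) {
  structure(list(reason = reason), class = "acquisition_miss")
}

#' @export
print.acquisition_miss <- function(x, ...) {
  cat("<acquisition_miss>", x$reason, "\n"); invisible(x)
}

#' Test for an acquisition miss
#' @param x Any object.
#' @return TRUE iff `x` is an `acquisition_miss`.
#' @export
is_miss <- function(x) inherits(x, "acquisition_miss")

#' Simulate pointing the laser at a detected cell
#'
#' Between detection and acquisition the cell drifts by Brownian motion for
#' `detect_to_acquire_lag` seconds. The acquisition succeeds iff the cell's
#' drifted position is still within one cell radius of the pointed
#' coordinate AND the cell is not flagged as overlapping another cell;
#' otherwise a miss marker is returned. This is the mechanism that makes
#' Raman-profiling sensitivity lag image-analysis sensitivity.
#'
#' @param truth One row of the [place_cells] ground truth.
#' @param pointed_at `(x, y)` laser target in um (typically the detected
#'   centroid).
#' @param profile A [strain_profile].
#' @param config A [sim_config] (D, lag, wavenumber grid).
#' @param seed Optional seed.
#' @return A [raman_spectrum], or an [acquisition_miss].
#' @export
acquire_spectrum <- function(truth, pointed_at, profile, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(pointed_at) == 2L)
  run <- function() {
    lag <- config$detect_to_acquire_lag
    pos <- c(truth$x, truth$y)
    if (lag > 0 && config$diffusion_coefficient > 0) {
      pos <- pos + stats::rnorm(2L, 0,
        sqrt(2 * config$diffusion_coefficient * lag))
    }
    if (isTRUE(truth$overlaps)) return(acquisition_miss("overlap"))
    if (sqrt(sum((pos - as.numeric(pointed_at))^2)) > truth$radius) {
      return(acquisition_miss("drift"))
    }
    simulate_spectrum(profile, config,
                      meta = list(cell_id = truth$cell_id,
                                  window_id = truth$window_id))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write a ground-truth manifest
#' @param truths Data frame from [place_cells].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truths, path) {
  utils::write.table(truths, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth manifest written by [write_truth_manifest]
#' @param path Manifest path.
#' @return Data frame of ground-truth cells.
#' @export
read_truth_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read field images as PNG (8-bit) or TIFF (16-bit) grayscale
#'
#' Intensities are clipped to \[0, 1\] on write. The physical pixel size is
#' not stored by these raster formats; supply it again on read.
#'
#' @param image A [field_image].
#' @param path Output path; format chosen by extension (.png / .tif(f)).
#' @param pixel_size um/pixel to attach on read.
#' @param window_id Window id to attach on read.
#' @return `write_field_image` returns `path` invisibly; `read_field_image`
#'   a [field_image].
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_field_image
#' @export
read_field_image <- function(path, pixel_size, window_id = 1L) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  field_image(px, pixel_size, window_id)
}
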