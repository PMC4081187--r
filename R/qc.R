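#' Baseline correction
#'
#' Subtracts a slowly varying background so the corrected spectrum has a
#' zero baseline. Two estimators are offered:
#' \describe{
#'   \item{`polynomial`}{iterative polynomial fitting: fit a degree-`degree`
#'     polynomial, clip the data to the fit from above, refit until
#'     convergence. Peaks are progressively excluded from the fit, leaving
#'     the lower envelope.}
#'   \item{`als`}{asymmetric least squares (Whittaker smoother with
#'     asymmetric weights): minimizes a second-difference roughness penalty
#'     `lambda` while weighting points above the baseline by `p` and points
#'     below by `1 - p`.}
#' }
#'
#' @param s A [raman_spectrum], or a numeric matrix whose *columns* are
#'   spectra sharing one grid, or a [spectrum_set].
#' @param method `"polynomial"` (default) or `"als"`.
#' @param degree Polynomial degree (polynomial method).
#' @param max_iter,tol Iteration control for the polynomial method.
#' @param lambda,p ALS roughness penalty and asymmetry (defaults 1e5, 0.01).
#' @param wavenumbers Grid, needed only for matrix input.
#' @return Same container as the input, baseline-subtracted.
#' @export
baseline_correct <- function(s, method = c("polynomial", "als"),
                             degree = 5L, max_iter = 100L, tol = 1e-8,
                             lambda = 1e5, p = 0.01, wavenumbers = NULL) {
  method <- match.arg(method)
  UseMethod("baseline_correct")
}

#' @export
baseline_correct.raman_spectrum <- function(s, method = c("polynomial", "als"),
                                            degree = 5L, max_iter = 100L,
                                            tol = 1e-8, lambda = 1e5, p = 0.01,
                                            wavenumbers = NULL) {
  method <- match.arg(method)
  b <- estimate_baseline(s$intensities, s$wavenumbers, method, degree,
                         max_iter, tol, lambda, p)
  set_intensities(s, s$intensities - b,
                  step = paste0("baseline:", method))
}

#' @export
baseline_correct.matrix <- function(s, method = c("polynomial", "als"),
                                    degree = 5L, max_iter = 100L, tol = 1e-8,
                                    lambda = 1e5, p = 0.01,
                                    wavenumbers = NULL) {
  method <- match.arg(method)
  if (is.null(wavenumbers)) wavenumbers <- seq_len(nrow(s))
  apply(s, 2L, function(y) {
    y - estimate_baseline(y, wavenumbers, method, degree, max_iter, tol,
                          lambda, p)
  })
}

#' @export
baseline_correct.spectrum_set <- function(s, method = c("polynomial", "als"),
                                          degree = 5L, max_iter = 100L,
                                          tol = 1e-8, lambda = 1e5, p = 0.01,
                                          wavenumbers = NULL) {
  method <- match.arg(method)
  corrected <- baseline_correct(t(s$intensities), method = method,
                                degree = degree, max_iter = max_iter,
                                tol = tol, lambda = lambda, p = p,
                                wavenumbers = s$wavenumbers)
  s$intensities <- t(corrected)
  s
}

estimate_baseline <- function(y, wn, method, degree, max_iter, tol,
                              lambda, p) {
  if (method == "polynomial") {
    if (degree >= length(y)) {
      stop("polynomial degree must be below the number of points",
           call. = FALSE)
    }
    u <- (wn - wn[1]) / (wn[length(wn)] - wn[1])  # conditioning
    X <- stats::poly(u, degree = degree, raw = FALSE)
    z <- y
    fit <- rep(mean(y), length(y))
    for (it in seq_len(max_iter)) {
      fit_new <- stats::lm.fit(cbind(1, X), z)$fitted.values
      z_new <- pmin(z, fit_new)
      delta <- max(abs(z_new - z))
      z <- z_new
      fit <- fit_new
      if (delta <= tol * max(1, max(abs(y)))) break
    }
    fit
  } else {
    n <- length(y)
    if (n < 10L) stop("ALS baseline needs at least 10 points", call. = FALSE)
    D <- Matrix::bandSparse(n - 2L, n,
                            k = 0:2, diagonals = list(rep(1, n - 2L),
                                                      rep(-2, n - 2L),
                                                      rep(1, n - 2L)))
    DtD <- lambda * Matrix::crossprod(D)
    w <- rep(1, n)
    z <- y
    for (it in seq_len(50L)) {
      W <- Matrix::Diagonal(n, w)
      z <- as.numeric(Matrix::solve(W + DtD, w * y))
      w_new <- ifelse(y > z, p, 1 - p)
      if (all(w_new == w)) break
      w <- w_new
    }
    z
  }
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local polynomial (Savitzky-Golay) filtering: smoothing
#' (`derivative_order = 0`) or the smoothed first/second derivative with
#' respect to wavenumber. Spectrum edges are handled by reflection.
#'
#' @param s A [raman_spectrum].
#' @param window Odd window length in points, >= 3.
#' @param derivative_order 0, 1 or 2.
#' @param poly_order Fitting polynomial degree (default 2, raised to 3 for
#'   second derivatives).
#' @return A [raman_spectrum] (derivatives are per cm^-1).
#' @export
smooth_spectrum <- function(s, window = 11L, derivative_order = 0L,
                            poly_order = NULL) {
  stopifnot(is_spectrum(s), derivative_order %in% 0:2)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window < 3L || window > length(s$wavenumbers)) {
    stop("window must be odd, >= 3 and <= spectrum length", call. = FALSE)
  }
  if (is.null(poly_order)) poly_order <- max(2L, derivative_order + 1L)
  poly_order <- min(poly_order, window - 1L)
  step <- s$wavenumbers[2L] - s$wavenumbers[1L]
  h <- (window - 1L) %/% 2L
  y <- s$intensities
  n <- length(y)
  # reflect both ends (no edge repetition), filter, crop
  pad <- c(y[(h + 1L):2L], y, y[(n - 1L):(n - h)])
  sm <- signal::sgolayfilt(pad, p = poly_order, n = window,
                           m = derivative_order, ts = step)
  set_intensities(s, sm[(h + 1L):(h + n)],
                  step = sprintf("sgolay:w%d,d%d", window, derivative_order))
}

#' Fourier low-pass filtering with apodization
#'
#' Transforms the intensities to the frequency domain, suppresses the
#' high-frequency content (noise) above `cutoff_fraction` of the Nyquist
#' frequency, and transforms back, keeping the medium and low frequencies
#' that carry the Raman bands. Truncation ringing can be softened by a
#' taper (apodization) applied across the top `taper_width` fraction of the
#' passband.
#'
#' @param s A [raman_spectrum].
#' @param cutoff_fraction Passband edge as a fraction of Nyquist, in (0, 1].
#' @param apodization `"none"`, `"triangular"` or `"cosine"` (default
#'   cosine).
#' @param taper_width Fraction of the passband over which the taper falls
#'   from 1 to 0 (default 0.1).
#' @return A [raman_spectrum].
#' @export
fourier_filter <- function(s, cutoff_fraction,
                           apodization = c("cosine", "triangular", "none"),
                           taper_width = 0.1) {
  stopifnot(is_spectrum(s))
  apodization <- match.arg(apodization)
  if (cutoff_fraction <= 0 || cutoff_fraction > 1) {
    stop("cutoff_fraction must be in (0, 1]", call. = FALSE)
  }
  y <- s$intensities
  n <- length(y)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / n            # folded frequency, Nyquist = 0.5
  fc <- cutoff_fraction * 0.5
  gain <- as.numeric(f <= fc)
  if (apodization != "none" && taper_width > 0) {
    f0 <- fc * (1 - taper_width)
    tr <- f > f0 & f <= fc
    u <- (f[tr] - f0) / (fc - f0)    # 0 at passband, 1 at cutoff
    gain[tr] <- if (apodization == "cosine") 0.5 * (1 + cos(pi * u)) else 1 - u
  }
  yf <- stats::fft(y) * gain
  out <- Re(stats::fft(yf, inverse = TRUE)) / n
  set_intensities(s, out, step = sprintf("fourier:c%.3g,%s", cutoff_fraction,
                                         apodization))
}

#' Spectrum normalization
#'
#' @param s A [raman_spectrum].
#' @param mode `"vector"` (unit Euclidean norm, default), `"area"` (unit
#'   trapezoidal integral) or `"max"` (peak intensity 1).
#' @return A [raman_spectrum].
#' @export
normalize_spectrum <- function(s, mode = c("vector", "area", "max")) {
  stopifnot(is_spectrum(s))
  mode <- match.arg(mode)
  y <- s$intensities
  denom <- switch(mode,
    vector = sqrt(sum(y^2)),
    area = sum(diff(s$wavenumbers) * (y[-1L] + y[-length(y)]) / 2),
    max = max(y))
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate spectrum: ", mode, " normalizer is not positive",
         call. = FALSE)
  }
  set_intensities(s, y / denom, step = paste0("normalize:", mode))
}

#' Peak signal-to-noise ratio
#'
#' `(max intensity within the peak window - median of the noise window) /
#' robust sd of the noise window`, with the robust sd taken as the
#' MAD-based estimator. Used by the database promotion rule ("a specific
#' peak has appeared" at sufficient SNR).
#'
#' @param s A [raman_spectrum].
#' @param peak_center Peak position, cm^-1.
#' @param peak_halfwidth Half-width of the peak window, cm^-1.
#' @param noise_window `(lo, hi)` cm^-1 of a peak-free region (default
#'   1750-1850 cm^-1, the biological silent region).
#' @return Dimensionless ratio; `Inf` when the noise sd is zero.
#' @export
snr <- function(s, peak_center, peak_halfwidth = 5,
                noise_window = c(1750, 1850)) {
  stopifnot(is_spectrum(s), peak_halfwidth >= 0, length(noise_window) == 2L)
  wn <- s$wavenumbers
  if (peak_center < min(wn) || peak_center > max(wn)) {
    stop("peak window outside the wavenumber grid", call. = FALSE)
  }
  if (noise_window[1] < min(wn) || noise_window[2] > max(wn)) {
    stop("noise window outside the wavenumber grid", call. = FALSE)
  }
  in_peak <- wn >= peak_center - peak_halfwidth &
             wn <= peak_center + peak_halfwidth
  in_noise <- wn >= noise_window[1] & wn <= noise_window[2]
  if (any(in_peak & in_noise)) {
    stop("peak and noise windows must be disjoint", call. = FALSE)
  }
  if (!any(in_peak) || sum(in_noise) < 3L) {
    stop("peak/noise windows contain too few grid points", call. = FALSE)
  }
  noise <- s$intensities[in_noise]
  sdn <- stats::mad(noise)
  signal <- max(s$intensities[in_peak]) - stats::median(noise)
  if (sdn == 0) return(Inf)
  signal / sdn
}

#' Quality-control configuration and chain
#'
#' `qc_config()` bundles the parameters of the four QC steps; `qc_chain()`
#' applies them in the fixed order baseline correction, Savitzky-Golay
#' smoothing, Fourier filtering, normalization. Any step can be disabled by
#' passing `NULL` (or `normalize = "none"`). Each applied step is recorded
#' in the spectrum's `meta$qc_steps`, which classification models use as a
#' preprocessing fingerprint.
#'
#' @param baseline List of arguments for [baseline_correct], or `NULL`.
#' @param smooth List of arguments for [smooth_spectrum], or `NULL`.
#' @param fourier List of arguments for [fourier_filter], or `NULL`.
#' @param normalize Mode for [normalize_spectrum], or `"none"`.
#' @return `qc_config()` returns a `qc_config`; `qc_chain()` the processed
#'   [raman_spectrum].
#' @export
qc_config <- function(baseline = list(method = "polynomial", degree = 5L),
                      smooth = list(window = 11L, derivative_order = 0L),
                      fourier = list(cutoff_fraction = 0.4,
                                     apodization = "cosine"),
                      normalize = "vector") {
  structure(list(baseline = baseline, smooth = smooth, fourier = fourier,
                 normalize = normalize),
            class = "qc_config")
}

#' @rdname qc_config
#' @param s A [raman_spectrum].
#' @param config A `qc_config`.
#' @export
qc_chain <- function(s, config = qc_config()) {
  stopifnot(is_spectrum(s), inherits(config, "qc_config"))
  if (!is.null(config$baseline)) {
    s <- do.call(baseline_correct, c(list(s), config$baseline))
  }
  if (!is.null(config$smooth)) {
    s <- do.call(smooth_spectrum, c(list(s), config$smooth))
  }
  if (!is.null(config$fourier)) {
    s <- do.call(fourier_filter, c(list(s), config$fourier))
  }
  if (!identical(config$normalize, "none") && !is.null(config$normalize)) {
    s <- normalize_spectrum(s, mode = config$normalize)
  }
  s
}
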