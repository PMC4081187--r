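# Shared fixtures and independent oracles used across the suite.

# small wavenumber grids keep simulation-heavy tests fast
qc_grid_cfg <- function(...) {
  sim_config(wavenumber_range = c(600, 1800), wavenumber_step = 2,
             n_windows = 0, ...)
}

one_peak_profile <- function(amp = 30, noise = 10, center = 1003,
                             fwhm = 12, cv = 0, baseline = 0,
                             name = "probe") {
  strain_profile(name,
                 data.frame(center = center, mean_amplitude = amp,
                            amplitude_cv = cv, width_fwhm = fwhm),
                 baseline_coeffs = baseline, noise_sd = noise)
}

manual_truths <- function(x, y, radius, window_id = 1L) {
  n <- length(x)
  data.frame(cell_id = seq_len(n), window_id = rep(window_id, n), x = x,
             y = y, radius = rep_len(radius, n),
             strain = rep("manual", n), overlaps = rep(FALSE, n))
}

# O(N^2) discrete Fourier transform low-pass filter, the brute-force
# counterpart of fourier_filter (gain derived independently).
naive_dft_filter <- function(y, cutoff_fraction, apodization = "none",
                             taper_width = 0.1) {
  n <- length(y)
  ks <- 0:(n - 1)
  coef <- vapply(ks, function(k) {
    sum(y * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
  f <- pmin(ks, n - ks) / n
  fc <- cutoff_fraction * 0.5
  gain <- as.numeric(f <= fc)
  if (apodization != "none") {
    f0 <- fc * (1 - taper_width)
    tr <- f > f0 & f <= fc
    u <- (f[tr] - f0) / (fc - f0)
    gain[tr] <- if (apodization == "cosine") (1 + cos(pi * u)) / 2 else 1 - u
  }
  coef <- coef * gain
  out <- vapply(0:(n - 1), function(j) {
    sum(coef * exp(2i * pi * ks * j / n)) / n
  }, complex(1))
  Re(out)
}

# pointwise local least-squares polynomial fit: the definitional oracle for
# Savitzky-Golay smoothing at interior points
local_ls_fit <- function(x, y, i, window, poly_order = 2L,
                         derivative_order = 0L) {
  h <- (window - 1) %/% 2
  idx <- (i - h):(i + h)
  dx <- x[idx] - x[i]
  X <- outer(dx, 0:poly_order, "^")
  beta <- qr.solve(X, y[idx])
  factorial(derivative_order) * beta[derivative_order + 1L]
}

# direct 3x3 convolution with reflected borders; oracle for edge_map
conv3_oracle <- function(img, operator) {
  a <- if (operator == "sobel") 2 else 1
  kx <- rbind(c(-1, 0, 1), c(-a, 0, a), c(-1, 0, 1))
  ky <- t(kx)
  nr <- nrow(img); nc <- ncol(img)
  ref <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    sx <- 0; sy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- img[ref(r + dr, nr), ref(c + dc, nc)]
      sx <- sx + kx[dr + 2, dc + 2] * v
      sy <- sy + ky[dr + 2, dc + 2] * v
    }
    gx[r, c] <- sx; gy[r, c] <- sy
  }
  sqrt(gx^2 + gy^2)
}

# exhaustive optimal one-to-one assignment (max matches, then min total
# distance) for <= 5 x 5 problems; oracle for greedy matching
brute_force_matching <- function(truths, detections, tolerance) {
  nt <- nrow(truths); nd <- nrow(detections)
  d <- sqrt(outer(truths$x, detections$x, "-")^2 +
              outer(truths$y, detections$y, "-")^2)
  best_n <- -1L; best_cost <- Inf
  assign_rec <- function(ti, used, matched, cost) {
    if (ti > nt) {
      if (matched > best_n || (matched == best_n && cost < best_cost)) {
        best_n <<- matched; best_cost <<- cost
      }
      return(invisible())
    }
    assign_rec(ti + 1L, used, matched, cost)  # leave truth ti unmatched
    for (di in seq_len(nd)) {
      if (!used[di] && d[ti, di] <= tolerance) {
        used[di] <- TRUE
        assign_rec(ti + 1L, used, matched + 1L, cost + d[ti, di])
        used[di] <- FALSE
      }
    }
  }
  assign_rec(1L, logical(nd), 0L, 0)
  list(n_matched = best_n, cost = best_cost)
}

# two-strain profiles sharing a backbone, differing in one band amplitude;
# the matched-noise classification scenario
strain_pair <- function(noise, a1655_a = 35, a1655_b = 22) {
  mk <- function(name, a1655) strain_profile(name,
    data.frame(center = c(1003, 1450, 1655),
               mean_amplitude = c(60, 35, a1655),
               amplitude_cv = c(0.10, 0.10, 0.10),
               width_fwhm = c(12, 20, 25)),
    baseline_coeffs = c(20, 10, -6), noise_sd = noise)
  list(a = mk("strainA", a1655_a), b = mk("strainB", a1655_b))
}

gen_labeled_set <- function(profiles, n_each, seeds, cfg = qc_grid_cfg(),
                            qc = NULL) {
  sp <- list(); labs <- character(0); k <- 0L
  for (p in profiles) {
    for (i in seq_len(n_each)) {
      k <- k + 1L
      s <- simulate_spectrum(p, cfg, seed = seeds[k])
      if (!is.null(qc)) s <- qc_chain(s, qc)
      sp[[k]] <- s
      labs[k] <- p$strain_name
    }
  }
  spectrum_set(sp, labs)
}
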