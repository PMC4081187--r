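#' Construct a Raman spectrum
#'
#' The basic data unit of the package: a strictly ascending wavenumber axis
#' (cm^-1) with one intensity per grid point, plus free-form acquisition
#' metadata (cell id, window id, exposure, laser label, QC history, ...).
#'
#' @param wavenumbers Numeric vector, strictly ascending, in cm^-1.
#' @param intensities Numeric vector of the same length, finite.
#' @param meta Named list of acquisition metadata.
#' @return An object of class `raman_spectrum` with elements `wavenumbers`,
#'   `intensities` and `meta`.
#' @examples
#' s <- raman_spectrum(400:1800, rexp(1401), meta = list(cell_id = 1L))
#' s
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 grid points", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be finite and strictly ascending", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         meta = as.list(meta)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), rng[1], rng[2]))
  if (length(x$meta)) {
    flat <- vapply(x$meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(names(flat), flat, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, intensity = x$intensities)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

is_spectrum <- function(x) inherits(x, "raman_spectrum")

#' Replace the intensities of a spectrum, keeping axis and metadata
#' @param s A `raman_spectrum`.
#' @param intensities New intensity vector, same length as the grid.
#' @param step Optional character tag appended to `meta$qc_steps`.
#' @return A `raman_spectrum`.
#' @keywords internal
set_intensities <- function(s, intensities, step = NULL) {
  stopifnot(is_spectrum(s), length(intensities) == length(s$wavenumbers))
  s$intensities <- as.numeric(intensities)
  if (!is.null(step)) s$meta$qc_steps <- c(s$meta$qc_steps, step)
  s
}

same_grid <- function(a, b, tol = 1e-8) {
  length(a$wavenumbers) == length(b$wavenumbers) &&
    max(abs(a$wavenumbers - b$wavenumbers)) <= tol
}

#' Bundle spectra sharing one wavenumber grid, with strain labels
#'
#' @param spectra List of `raman_spectrum` objects on an identical grid, or a
#'   numeric matrix with one spectrum per row.
#' @param labels Character/factor vector, one strain label per spectrum.
#' @param wavenumbers Grid, required only when `spectra` is a matrix.
#' @return A `spectrum_set`: list with `intensities` (n_spectra x n_points
#'   matrix), `wavenumbers`, `labels`.
#' @export
spectrum_set <- function(spectra, labels, wavenumbers = NULL) {
  if (is.matrix(spectra)) {
    if (is.null(wavenumbers)) {
      stop("wavenumbers required for matrix input", call. = FALSE)
    }
    mat <- spectra
  } else {
    stopifnot(length(spectra) >= 1L, all(vapply(spectra, is_spectrum, TRUE)))
    wavenumbers <- spectra[[1L]]$wavenumbers
    ok <- vapply(spectra, function(s) same_grid(s, spectra[[1L]]), TRUE)
    if (!all(ok)) stop("all spectra must share one wavenumber grid", call. = FALSE)
    mat <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(mat)) {
    stop("one label per spectrum required", call. = FALSE)
  }
  structure(list(intensities = mat, wavenumbers = as.numeric(wavenumbers),
                 labels = labels),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points; labels: %s\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) nrow(x$intensities)

#' Extract one member of a spectrum set as a `raman_spectrum`
#' @param set A `spectrum_set`.
#' @param i Row index.
#' @return A `raman_spectrum` carrying the member's label in `meta$label`.
#' @export
set_member <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"), i >= 1L, i <= nrow(set$intensities))
  raman_spectrum(set$wavenumbers, set$intensities[i, ],
                 meta = list(label = set$labels[i]))
}

# ---- file formats ---------------------------------------------------------

#' Read / write two-column delimited spectra
#'
#' Plain-text exchange format: one `wavenumber<sep>intensity` pair per line;
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param meta Metadata attached to the returned spectrum (read) .
#' @param s A `raman_spectrum` (write).
#' @param sep Field separator, default tab.
#' @return `read_spectrum_txt` returns a `raman_spectrum`;
#'   `write_spectrum_txt` returns `path` invisibly.
#' @export
read_spectrum_txt <- function(path, meta = list(), sep = "") {
  d <- utils::read.table(path, header = FALSE, sep = sep,
                         comment.char = "#", col.names = c("wn", "it"))
  raman_spectrum(d$wn, d$it, meta = c(meta, list(source = basename(path))))
}

#' @rdname read_spectrum_txt
#' @export
write_spectrum_txt <- function(s, path, sep = "\t") {
  stopifnot(is_spectrum(s))
  utils::write.table(
    data.frame(s$wavenumbers, s$intensities), path,
    sep = sep, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write JCAMP-DX spectra
#'
#' Minimal JCAMP-DX 4.24 support for the `##XYDATA=(X++(Y..Y))` dialect with
#' fixed-point (AFFN) values on an evenly spaced abscissa; sufficient for
#' round-tripping spectra with common spectroscopy software.
#'
#' @param path File path.
#' @param s A `raman_spectrum` (write).
#' @param title Value of the `##TITLE=` record on write.
#' @return `read_jcamp` returns a `raman_spectrum`; `write_jcamp` returns
#'   `path` invisibly.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^##", name, "="), "", hit[1L]))
  }
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block found", call. = FALSE)
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1L]]) else length(lines) + 1L
  body <- lines[(start[1L] + 1L):(end - 1L)]
  xfac <- as.numeric(ldr("XFACTOR")); if (is.na(xfac)) xfac <- 1
  yfac <- as.numeric(ldr("YFACTOR")); if (is.na(yfac)) yfac <- 1
  wn <- numeric(0); it <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]])
    if (length(vals) < 2L || any(is.na(vals))) next
    x0 <- vals[1L] * xfac
    ys <- vals[-1L] * yfac
    # per-line X is the abscissa of the first Y; remaining implied by spacing
    wn <- c(wn, x0 + seq_along(ys) - 1)  # placeholder; fixed below via DELTAX
    it <- c(it, ys)
  }
  deltax <- as.numeric(ldr("DELTAX"))
  firstx <- as.numeric(ldr("FIRSTX"))
  if (is.na(deltax)) {
    npt <- as.numeric(ldr("NPOINTS"))
    lastx <- as.numeric(ldr("LASTX"))
    deltax <- (lastx - firstx) / (npt - 1)
  }
  wn <- firstx + deltax * (seq_along(it) - 1)
  meta <- list(title = ldr("TITLE"), source = basename(path))
  if (deltax < 0) { wn <- rev(wn); it <- rev(it) }
  raman_spectrum(wn, it, meta = meta)
}

#' @rdname read_jcamp
#' @export
write_jcamp <- function(s, path, title = "scraman spectrum") {
  stopifnot(is_spectrum(s))
  dx <- diff(s$wavenumbers)
  if (max(abs(dx - dx[1L])) > 1e-6 * abs(dx[1L])) {
    stop("JCAMP (X++(Y..Y)) requires an evenly spaced grid", call. = FALSE)
  }
  n <- length(s$wavenumbers)
  header <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM", "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%.6f", s$wavenumbers[1L]),
    sprintf("##LASTX=%.6f", s$wavenumbers[n]),
    sprintf("##DELTAX=%.6f", dx[1L]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))")
  idx <- split(seq_len(n), ceiling(seq_len(n) / 8))
  body <- vapply(idx, function(i) {
    paste(c(sprintf("%.4f", s$wavenumbers[i[1L]]),
            sprintf("%.6f", s$intensities[i])), collapse = " ")
  }, character(1))
  writeLines(c(header, body, "##END="), path)
  invisible(path)
}
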