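#' Gradient-magnitude edge map of a field image
#'
#' Standard 3x3 Sobel or Prewitt operators; the two directional responses
#' are combined as the Euclidean magnitude. Image borders are handled by
#' reflection, so the output has the same shape as the input.
#'
#' @param image A [field_image] or a plain numeric matrix.
#' @param operator `"sobel"` or `"prewitt"`.
#' @return Numeric matrix of gradient magnitudes, same dimensions as the
#'   input pixels.
#' @export
edge_map <- function(image, operator = c("sobel", "prewitt")) {
  operator <- match.arg(operator)
  px <- if (inherits(image, "field_image")) image$pixels else image
  stopifnot(is.matrix(px))
  if (nrow(px) < 3L || ncol(px) < 3L) {
    stop("image must be at least 3 x 3 pixels", call. = FALSE)
  }
  a <- if (operator == "sobel") 2 else 1
  # kernel rows: smoothing (1, a, 1) across, difference (-1, 0, 1) along
  p <- pad_reflect(px)
  nr <- nrow(px); nc <- ncol(px)
  sh <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  gx <- (sh(-1L,  1L) + a * sh(0L,  1L) + sh(1L,  1L)) -
        (sh(-1L, -1L) + a * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh( 1L, -1L) + a * sh( 1L, 0L) + sh( 1L, 1L)) -
        (sh(-1L, -1L) + a * sh(-1L, 0L) + sh(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

# reflect-pad a matrix by one pixel on each side (no edge repetition)
pad_reflect <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(2L, seq_len(nr), nr - 1L)
  ci <- c(2L, seq_len(nc), nc - 1L)
  m[ri, ci]
}

#' Detection thresholds and acceptance rules
#'
#' @param k_sigma Gradient threshold: `median + k_sigma * MAD` of the
#'   gradient magnitude (default 5).
#' @param area_bounds_um2 `(min, max)` accepted region area in um^2.
#'   Regions above the maximum are treated as merged/overlapping cells.
#' @param circularity_min Floor on `4 * pi * area / perimeter^2`; regions
#'   below it are rejected as abnormally shaped (default 0.6).
#' @param closing_size Side of the square morphological closing element in
#'   pixels (default 3).
#' @return A `detect_params` list.
#' @export
detect_params <- function(k_sigma = 5, area_bounds_um2 = c(5, 60),
                          circularity_min = 0.6, closing_size = 3L) {
  stopifnot(k_sigma > 0, length(area_bounds_um2) == 2L,
            area_bounds_um2[1] < area_bounds_um2[2], circularity_min >= 0,
            closing_size >= 1L)
  structure(list(k_sigma = k_sigma, area_bounds_um2 = area_bounds_um2,
                 circularity_min = circularity_min,
                 closing_size = as.integer(closing_size)),
            class = "detect_params")
}

#' Detect single cells in a field image
#'
#' Conservative single-cell extraction: threshold the Sobel/Prewitt edge
#' map, close small gaps in the boundary, fill closed boundaries and label
#' the resulting regions. A region is accepted only if
#' \itemize{
#'   \item it does not touch the image border (otherwise
#'     `rejected_open_boundary` -- its boundary cannot be verified closed),
#'   \item it is not adjacent to another region and its area does not exceed
#'     the single-cell maximum (otherwise `rejected_overlap`),
#'   \item its area is above the minimum and its circularity above the floor
#'     (otherwise `rejected_shape`).
#' }
#' Rejected regions are returned with their rejection reason, so the
#' detector trades sensitivity for specificity by design.
#'
#' @param image A [field_image].
#' @param params A [detect_params].
#' @param operator Edge operator, `"sobel"` (default) or `"prewitt"`.
#' @return Data frame, one row per candidate region: `det_id`, `window_id`,
#'   `x`, `y` (centroid, um), `area_um2`, `circularity`, `quality`
#'   (`accepted` / `rejected_open_boundary` / `rejected_overlap` /
#'   `rejected_shape`). The filled region label matrix is attached as
#'   attribute `"labels"`.
#' @export
detect_cells <- function(image, params = detect_params(),
                         operator = c("sobel", "prewitt")) {
  stopifnot(inherits(image, "field_image"), inherits(params, "detect_params"))
  operator <- match.arg(operator)
  psz <- image$pixel_size
  g <- edge_map(image, operator)
  # The gradient magnitude of a noisy background is Rayleigh-like
  # (nonnegative, median > 0), so the threshold is median + k * MAD,
  # floored at 10% of the strongest edge so a noiseless image does not
  # threshold at zero.
  thr <- max(stats::median(g) + params$k_sigma * stats::mad(g),
             0.10 * max(g))
  mask <- g > thr
  empty <- data.frame(det_id = integer(0), window_id = integer(0),
                      x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                      circularity = numeric(0), quality = character(0))
  if (!any(mask)) return(empty)

  img <- EBImage::Image(mask * 1)
  if (params$closing_size > 1L) {
    img <- EBImage::closing(img,
      EBImage::makeBrush(params$closing_size, shape = "box"))
  }
  filled <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(filled)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)

  shape <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  labm <- EBImage::imageData(lab)
  # EBImage reports m.cx along dim 1 (our rows / y) and m.cy along dim 2
  row_c <- mom[, "m.cx"]; col_c <- mom[, "m.cy"]
  area_px <- shape[, "s.area"]
  perim <- pmax(shape[, "s.perimeter"], 1)
  circ <- 4 * pi * area_px / perim^2
  area_um2 <- area_px * psz^2

  border <- border_labels(labm)
  adj <- adjacent_labels(labm, nlab)

  quality <- rep("accepted", nlab)
  quality[area_um2 < params$area_bounds_um2[1] |
            circ < params$circularity_min] <- "rejected_shape"
  quality[adj | area_um2 > params$area_bounds_um2[2]] <- "rejected_overlap"
  quality[border] <- "rejected_open_boundary"

  out <- data.frame(det_id = seq_len(nlab), window_id = image$window_id,
                    x = (col_c - 0.5) * psz, y = (row_c - 0.5) * psz,
                    area_um2 = area_um2, circularity = as.numeric(circ),
                    quality = quality)
  rownames(out) <- NULL
  attr(out, "labels") <- labm
  out
}

# labels touching the image border
border_labels <- function(labm) {
  nlab <- max(labm)
  edge <- unique(c(labm[1L, ], labm[nrow(labm), ], labm[, 1L], labm[, ncol(labm)]))
  seq_len(nlab) %in% edge[edge > 0]
}

# labels 8-adjacent to a different label
adjacent_labels <- function(labm, nlab) {
  adj <- rep(FALSE, nlab)
  nr <- nrow(labm); nc <- ncol(labm)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    r1 <- seq_len(nr - abs(s[1L])); c1 <- seq_len(nc - abs(s[2L]))
    r2 <- r1 + abs(s[1L])
    c2 <- if (s[2L] >= 0L) c1 + s[2L] else c1
    c1s <- if (s[2L] < 0L) c1 - s[2L] else c1
    a <- labm[r1, c1s]; b <- labm[r2, c2]
    hit <- a > 0 & b > 0 & a != b
    if (any(hit)) adj[unique(c(a[hit], b[hit]))] <- TRUE
  }
  adj
}

#' Match detections to ground truth
#'
#' Greedy one-to-one nearest-centroid matching within a distance tolerance:
#' candidate pairs are sorted by distance (ties by lower `cell_id`) and
#' consumed greedily, so each truth and each detection is matched at most
#' once.
#'
#' @param detections Data frame from [detect_cells] (accepted rows are
#'   matched; pass a subset to change that).
#' @param truths Data frame from [place_cells] (same window).
#' @param tolerance Maximum centroid distance in um (> 0).
#' @return List with `matches` (data frame `cell_id`, `det_id`, `distance`),
#'   `unmatched_truths` (cell ids) and `unmatched_detections` (det ids).
#' @export
match_detections <- function(detections, truths, tolerance) {
  stopifnot(tolerance > 0)
  det <- detections[detections$quality == "accepted", , drop = FALSE]
  matches <- data.frame(cell_id = integer(0), det_id = integer(0),
                        distance = numeric(0))
  if (nrow(det) && nrow(truths)) {
    d <- outer(truths$x, det$x, "-")^2 + outer(truths$y, det$y, "-")^2
    d <- sqrt(d)
    cand <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], truths$cell_id[cand[, 1L]])
      cand <- cand[ord, , drop = FALSE]
      used_t <- logical(nrow(truths)); used_d <- logical(nrow(det))
      for (i in seq_len(nrow(cand))) {
        ti <- cand[i, 1L]; di <- cand[i, 2L]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        matches <- rbind(matches, data.frame(
          cell_id = truths$cell_id[ti], det_id = det$det_id[di],
          distance = d[ti, di]))
      }
    }
  }
  list(matches = matches,
       unmatched_truths = setdiff(truths$cell_id, matches$cell_id),
       unmatched_detections = setdiff(det$det_id, matches$det_id))
}

#' Write a detection table
#' @param detections Data frame from [detect_cells].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.table(detections, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
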