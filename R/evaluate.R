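#' Recognition sensitivity
#'
#' The pipeline's headline metric: the number of correctly recognized cells
#' divided by the number of correct cells, as a fraction in \[0, 1\].
#'
#' @param n_correctly_recognized Non-negative count, at most `n_correct`.
#' @param n_correct Positive count of true cells.
#' @return Fraction `n_correctly_recognized / n_correct`.
#' @examples
#' sensitivity(475, 500)  # 0.95
#' @export
sensitivity <- function(n_correctly_recognized, n_correct) {
  if (length(n_correct) != 1L || is.na(n_correct) || n_correct <= 0) {
    stop("sensitivity undefined: n_correct must be > 0", call. = FALSE)
  }
  if (n_correctly_recognized < 0 || n_correctly_recognized > n_correct) {
    stop("n_correctly_recognized must be in [0, n_correct]", call. = FALSE)
  }
  n_correctly_recognized / n_correct
}

#' Search accuracy
#'
#' Fraction of query cells whose predicted strain label matches the truth.
#'
#' @param predictions,truths Equal-length label vectors.
#' @return Fraction of exact matches.
#' @export
search_accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0L) {
    stop("predictions and truths must have equal positive length",
         call. = FALSE)
  }
  mean(as.character(predictions) == as.character(truths))
}

#' Peak-based sorting decision
#'
#' The cell-sorting trigger: fire (return TRUE) iff the intensity of peak A
#' over (ratio mode) or minus (difference mode) the intensity of peak B is
#' strictly greater than the threshold. Peak intensities are window maxima
#' around each center.
#'
#' @param s A [raman_spectrum].
#' @param peak_a,peak_b Peak centers, cm^-1.
#' @param mode `"ratio"` or `"difference"`.
#' @param threshold Decision threshold (strict inequality).
#' @param halfwidth Peak window half-width, cm^-1 (default 5).
#' @return Logical: sort this cell?
#' @export
sorting_decision <- function(s, peak_a, peak_b,
                             mode = c("ratio", "difference"), threshold,
                             halfwidth = 5) {
  stopifnot(is_spectrum(s))
  mode <- match.arg(mode)
  wn <- s$wavenumbers
  peak_max <- function(center) {
    w <- wn >= center - halfwidth & wn <= center + halfwidth
    if (!any(w)) stop("peak at ", center, " cm^-1 is off the grid",
                      call. = FALSE)
    max(s$intensities[w])
  }
  ia <- peak_max(peak_a); ib <- peak_max(peak_b)
  if (mode == "ratio") {
    if (ib == 0) stop("zero denominator peak intensity in ratio mode",
                      call. = FALSE)
    ia / ib > threshold
  } else {
    ia - ib > threshold
  }
}

#' Replay the end-to-end simulated sensitivity experiment
#'
#' For every window: place cells, render the field, detect cells, match
#' accepted detections to ground truth, then point the (simulated) laser at
#' each matched detection's centroid after the configured lag, during which
#' the cell drifts by Brownian motion. A cell is image-correct if it was
#' matched within tolerance, and Raman-correct if it was image-correct and
#' its spectrum acquisition did not miss. Sensitivities are pooled counts
#' over all windows. The run is fully replayable from `config$rng_seed`.
#'
#' @param config A [sim_config].
#' @param profile A [strain_profile].
#' @param params A [detect_params].
#' @param tolerance Matching tolerance in um (default: the profile's mean
#'   cell radius).
#' @param render_args Extra arguments to [render_field].
#' @param place_args Extra arguments to [place_cells] (e.g.
#'   `non_overlapping = TRUE`).
#' @param classifier Optional `raman_classifier`; when given, every acquired
#'   spectrum is classified and `accuracy_search` reports the fraction of
#'   correct strain labels.
#' @param operator Edge operator for detection.
#' @return An `eval_report`: counts, pooled sensitivities, per-window
#'   breakdown, config echo and the per-window seed list.
#' @export
run_benchmark <- function(config, profile, params = detect_params(),
                          tolerance = NULL, render_args = list(),
                          place_args = list(), classifier = NULL,
                          operator = "sobel") {
  stopifnot(inherits(config, "sim_config"), inherits(profile, "strain_profile"))
  if (is.null(tolerance)) tolerance <- profile$cell_radius_mean
  truths <- do.call(place_cells, c(list(config, profile), place_args))
  acq_seeds <- child_seeds(config$rng_seed, max(1L, config$n_windows),
                          salt = 409L)
  per_window <- data.frame(window_id = integer(0), n_cells = integer(0),
                           n_detected = integer(0), n_image = integer(0),
                           n_raman = integer(0))
  errors <- character(0)
  all_preds <- character(0); all_truth <- character(0)
  for (w in seq_len(config$n_windows)) {
    tw <- truths[truths$window_id == w, , drop = FALSE]
    res <- tryCatch({
      img <- do.call(render_field, c(list(tw, config), render_args))
      det <- detect_cells(img, params, operator = operator)
      mt <- match_detections(det, tw, tolerance)
      n_image <- nrow(mt$matches)
      n_raman <- 0L
      preds <- character(0); truth_labels <- character(0)
      if (n_image) {
        cseeds <- child_seeds(acq_seeds[w], n_image)
        acc <- det[det$quality == "accepted", , drop = FALSE]
        for (i in seq_len(n_image)) {
          ti <- tw[tw$cell_id == mt$matches$cell_id[i], , drop = FALSE]
          di <- acc[acc$det_id == mt$matches$det_id[i], , drop = FALSE]
          sp <- acquire_spectrum(ti[1L, ], c(di$x[1L], di$y[1L]), profile,
                                 config, seed = cseeds[i])
          if (!is_miss(sp)) {
            n_raman <- n_raman + 1L
            if (!is.null(classifier)) {
              preds <- c(preds, classify_spectrum(sp, classifier))
              truth_labels <- c(truth_labels, ti$strain[1L])
            }
          }
        }
      }
      list(counts = data.frame(window_id = w, n_cells = nrow(tw),
                               n_detected = sum(det$quality == "accepted"),
                               n_image = n_image, n_raman = n_raman),
           preds = preds, truth_labels = truth_labels)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("window %d: %s", w, conditionMessage(res)))
      next
    }
    per_window <- rbind(per_window, res$counts)
    all_preds <- c(all_preds, res$preds)
    all_truth <- c(all_truth, res$truth_labels)
  }
  n_cells <- sum(per_window$n_cells)
  n_image <- sum(per_window$n_image)
  n_raman <- sum(per_window$n_raman)
  report <- structure(list(
    n_cells = n_cells,
    n_detected_correct = n_image,
    n_raman_correct = n_raman,
    sensitivity_image = if (n_cells > 0) sensitivity(n_image, n_cells) else NA,
    sensitivity_raman = if (n_cells > 0) sensitivity(n_raman, n_cells) else NA,
    accuracy_search = if (length(all_preds)) {
      search_accuracy(all_preds, all_truth)
    } else NA_real_,
    per_window = per_window,
    config = config, profile_name = profile$strain_name,
    tolerance = tolerance,
    seeds = list(master = config$rng_seed, acquisition = acq_seeds),
    errors = errors), class = "eval_report")
  stopifnot(report$n_raman_correct <= report$n_detected_correct)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Simulated single-cell extraction sensitivity\n")
  cat(sprintf("  %-28s %d\n", "# cells (pooled)", x$n_cells))
  cat(sprintf("  %-28s %d\n", "# image-correct cells", x$n_detected_correct))
  cat(sprintf("  %-28s %d\n", "# Raman-correct cells", x$n_raman_correct))
  cat(sprintf("  %-28s %.1f%%\n", "Sensitivity, image analysis",
              100 * x$sensitivity_image))
  cat(sprintf("  %-28s %.1f%%\n", "Sensitivity, Raman profiling",
              100 * x$sensitivity_raman))
  if (length(x$errors)) {
    cat("  window errors:\n")
    for (e in x$errors) cat("   -", e, "\n")
  }
  invisible(x)
}

#' Serialize an evaluation report to structured text (JSON)
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    n_cells = report$n_cells,
    n_detected_correct = report$n_detected_correct,
    n_raman_correct = report$n_raman_correct,
    sensitivity_image = report$sensitivity_image,
    sensitivity_raman = report$sensitivity_raman,
    per_window = report$per_window,
    master_seed = report$seeds$master,
    tolerance_um = report$tolerance,
    profile = report$profile_name,
    errors = report$errors)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
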