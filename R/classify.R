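#' Radial basis function kernel
#'
#' `K(x_i, x_j) = exp(-gamma * ||x_i - x_j||^2)` for `gamma > 0`; the
#' similarity function used by the SVM classifier. Always in (0, 1], equal
#' to 1 iff the two vectors are identical.
#'
#' @param x_i,x_j Numeric vectors of equal length.
#' @param gamma Radial width, > 0.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(x_i, x_j, gamma) {
  if (length(x_i) != length(x_j)) {
    stop("x_i and x_j must have equal length", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive scalar", call. = FALSE)
  }
  exp(-gamma * sum((x_i - x_j)^2))
}

qc_fingerprint <- function(s) {
  if (is_spectrum(s) && length(s$meta$qc_steps)) {
    paste(s$meta$qc_steps, collapse = "|")
  } else {
    NA_character_
  }
}

#' Train an RBF nu-SVM spectrum classifier with grid search
#'
#' Stratified cross-validated grid search over the RBF width `gamma` and
#' the nu-SVC regularization `nu`; the model is refit on all spectra at the
#' best setting (ties broken by the smaller gamma, then smaller nu).
#' Deterministic given `seed`.
#'
#' @param train A [spectrum_set] with at least 2 label classes and at least
#'   `folds` members per class.
#' @param gamma_grid Gamma candidates (default `2^(-15:3)`).
#' @param nu_grid nu candidates (default 0.1-0.5).
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for the fold assignment (default 1).
#' @param fingerprint Optional preprocessing fingerprint string recorded on
#'   the model and checked at prediction time.
#' @return A `raman_classifier` of kind `"svm"` with elements `gamma`, `nu`,
#'   `cv_accuracy`, `cv_table` (the full grid), `model`, `wavenumbers`,
#'   `labels`.
#' @export
train_svm <- function(train, gamma_grid = 2^(-15:3),
                      nu_grid = seq(0.1, 0.5, by = 0.1), folds = 5L,
                      seed = 1L, fingerprint = NA_character_) {
  stopifnot(inherits(train, "spectrum_set"))
  y <- factor(train$labels)
  if (nlevels(y) < 2L) stop("need at least two label classes", call. = FALSE)
  if (min(table(y)) < folds) {
    stop("each class needs at least `folds` members", call. = FALSE)
  }
  X <- train$intensities
  fold_id <- integer(length(y))
  fold_id[] <- with_seed(seed, {
    out <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      out[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    out
  })
  grid <- expand.grid(gamma = gamma_grid, nu = nu_grid)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L; total <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      fit <- tryCatch(
        e1071::svm(X[tr, , drop = FALSE], y[tr], type = "nu-classification",
                   kernel = "radial", gamma = grid$gamma[g], nu = grid$nu[g],
                   scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- stats::predict(fit, X[te, , drop = FALSE])
      correct <- correct + sum(pred == y[te])
      total <- total + sum(te)
    }
    correct / total
  }, numeric(1))
  grid$accuracy <- acc
  if (all(is.na(acc))) stop("no feasible (gamma, nu) setting", call. = FALSE)
  best <- order(-acc, grid$gamma, grid$nu, na.last = TRUE)[1L]
  fit <- e1071::svm(X, y, type = "nu-classification", kernel = "radial",
                    gamma = grid$gamma[best], nu = grid$nu[best],
                    scale = FALSE)
  structure(list(kind = "svm", gamma = grid$gamma[best], nu = grid$nu[best],
                 cv_accuracy = acc[best], cv_table = grid, model = fit,
                 wavenumbers = train$wavenumbers, labels = levels(y),
                 fingerprint = fingerprint),
            class = "raman_classifier")
}

#' Build a Euclidean-distance search model
#'
#' @param reference A [spectrum_set] used as the search library.
#' @param k Neighbours used for the majority vote at prediction time.
#' @param fingerprint Optional preprocessing fingerprint.
#' @return A `raman_classifier` of kind `"euclidean"`.
#' @export
ed_model <- function(reference, k = 1L, fingerprint = NA_character_) {
  stopifnot(inherits(reference, "spectrum_set"), k >= 1L)
  structure(list(kind = "euclidean", reference = reference, k = as.integer(k),
                 wavenumbers = reference$wavenumbers,
                 labels = sort(unique(reference$labels)),
                 fingerprint = fingerprint),
            class = "raman_classifier")
}

#' @export
print.raman_classifier <- function(x, ...) {
  if (x$kind == "svm") {
    cat(sprintf("<raman_classifier:svm> gamma=%g nu=%g cv_accuracy=%.3f (%s)\n",
                x$gamma, x$nu, x$cv_accuracy,
                paste(x$labels, collapse = ", ")))
  } else {
    cat(sprintf("<raman_classifier:euclidean> %d reference spectra, k=%d (%s)\n",
                nrow(x$reference$intensities), x$k,
                paste(x$labels, collapse = ", ")))
  }
  invisible(x)
}

check_query_grid <- function(query, model) {
  if (length(query$wavenumbers) != length(model$wavenumbers) ||
      max(abs(query$wavenumbers - model$wavenumbers)) > 1e-8) {
    stop("query grid differs from the model grid", call. = FALSE)
  }
  qf <- qc_fingerprint(query)
  if (!is.na(model$fingerprint) && !is.na(qf) &&
      !identical(qf, model$fingerprint)) {
    stop("query preprocessing does not match the model fingerprint: '",
         qf, "' vs '", model$fingerprint, "'", call. = FALSE)
  }
}

#' Euclidean-distance search of a reference library
#'
#' Ranks all reference spectra by Euclidean distance to the query
#' (ascending). The predicted label is the majority vote over the top `k`
#' (default 1); ties are broken by the smaller mean distance, then by
#' lexical label order.
#'
#' @param query A [raman_spectrum] on the reference grid.
#' @param reference A [spectrum_set] (or a `raman_classifier` from
#'   [ed_model]).
#' @param k Neighbours for the vote.
#' @return Data frame `(label, distance)` ranked ascending, with the
#'   predicted label as attribute `"label"`.
#' @export
ed_search <- function(query, reference, k = 1L) {
  if (inherits(reference, "raman_classifier")) {
    k <- reference$k
    reference <- reference$reference
  }
  stopifnot(is_spectrum(query), inherits(reference, "spectrum_set"), k >= 1L)
  if (length(query$wavenumbers) != length(reference$wavenumbers) ||
      max(abs(query$wavenumbers - reference$wavenumbers)) > 1e-8) {
    stop("query grid differs from the reference grid", call. = FALSE)
  }
  d <- sqrt(rowSums(sweep(reference$intensities, 2L, query$intensities)^2))
  ord <- order(d, reference$labels)
  out <- data.frame(label = reference$labels[ord], distance = d[ord])
  top <- out[seq_len(min(k, nrow(out))), , drop = FALSE]
  tab <- stats::aggregate(distance ~ label, data = top,
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  votes <- data.frame(label = tab$label, n = tab$distance[, "n"],
                      mean = tab$distance[, "mean"])
  votes <- votes[order(-votes$n, votes$mean, votes$label), , drop = FALSE]
  attr(out, "label") <- as.character(votes$label[1L])
  out
}

#' Classify a query spectrum with a trained model
#'
#' @param query A [raman_spectrum], QC'd identically to the training
#'   spectra (checked via the preprocessing fingerprint when both carry
#'   one).
#' @param model A `raman_classifier`.
#' @return Predicted strain label (character scalar).
#' @export
classify_spectrum <- function(query, model) {
  stopifnot(is_spectrum(query), inherits(model, "raman_classifier"))
  check_query_grid(query, model)
  if (model$kind == "svm") {
    as.character(stats::predict(model$model,
                                matrix(query$intensities, nrow = 1L)))
  } else {
    attr(ed_search(query, model$reference, k = model$k), "label")
  }
}

#' Save / load a classifier model as a plain-text archive
#'
#' The archive is a directory holding `model.json` (kind, parameters,
#' labels, fingerprint, grid) plus, for Euclidean models, the reference
#' intensities as a delimited table. SVM models are stored as their support
#' spectra, coefficients and intercept, and are rebuilt exactly on load.
#'
#' @param model A `raman_classifier`.
#' @param dir Archive directory.
#' @return `save_classifier` returns `dir` invisibly; `load_classifier` the
#'   model.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "raman_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- list(kind = model$kind, wavenumbers = model$wavenumbers,
               labels = model$labels, fingerprint = model$fingerprint)
  if (model$kind == "svm") {
    info$gamma <- model$gamma
    info$nu <- model$nu
    info$cv_accuracy <- model$cv_accuracy
    utils::write.table(model$model$SV, file.path(dir, "support.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(model$model$coefs, file.path(dir, "coefs.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    info$rho <- model$model$rho
    info$svm_labels <- as.character(model$model$levels)
    info$nSV <- model$model$nSV
  } else {
    info$k <- model$k
    utils::write.table(
      cbind(label = model$reference$labels,
            as.data.frame(model$reference$intensities)),
      file.path(dir, "reference.tsv"), sep = "\t", row.names = FALSE)
  }
  jsonlite::write_json(info, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (info$kind == "euclidean") {
    ref <- utils::read.table(file.path(dir, "reference.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    set <- spectrum_set(as.matrix(ref[, -1L, drop = FALSE]),
                        labels = ref$label, wavenumbers = info$wavenumbers)
    ed_model(set, k = info$k, fingerprint = info$fingerprint)
  } else {
    sv <- as.matrix(utils::read.table(file.path(dir, "support.tsv"),
                                      sep = "\t", header = FALSE))
    coefs <- as.matrix(utils::read.table(file.path(dir, "coefs.tsv"),
                                         sep = "\t", header = FALSE))
    fit <- list(SV = sv, coefs = coefs, rho = info$rho,
                gamma = info$gamma, levels = info$svm_labels,
                nSV = info$nSV)
    model <- structure(list(kind = "svm", gamma = info$gamma, nu = info$nu,
                            cv_accuracy = info$cv_accuracy, cv_table = NULL,
                            model = manual_svm(fit),
                            wavenumbers = info$wavenumbers,
                            labels = info$labels,
                            fingerprint = info$fingerprint),
                       class = "raman_classifier")
    model
  }
}

# Minimal self-contained RBF nu-SVC decision object rebuilt from saved
# support vectors; prediction implemented directly from the one-vs-one
# decision functions.
manual_svm <- function(fit) {
  structure(fit, class = "scraman_svm")
}

#' @export
predict.scraman_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  levels <- object$levels
  ncls <- length(levels)
  nSV <- as.integer(object$nSV)
  start <- cumsum(c(1L, nSV))
  K <- exp(-object$gamma *
             outer(rowSums(X^2), rowSums(object$SV^2), "+") -
             -2 * object$gamma * (X %*% t(object$SV)))
  preds <- character(nrow(X))
  for (q in seq_len(nrow(X))) {
    votes <- integer(ncls)
    p <- 0L
    for (i in seq_len(ncls - 1L)) {
      for (j in (i + 1L):ncls) {
        p <- p + 1L
        si <- start[i]:(start[i] + nSV[i] - 1L)
        sj <- start[j]:(start[j] + nSV[j] - 1L)
        dec <- sum(object$coefs[si, j - 1L] * K[q, si]) +
          sum(object$coefs[sj, i] * K[q, sj]) - object$rho[p]
        if (dec > 0) votes[i] <- votes[i] + 1L else votes[j] <- votes[j] + 1L
      }
    }
    preds[q] <- levels[which.max(votes)]
  }
  factor(preds, levels = levels)
}

#' Two-strain separation by principal component analysis
#'
#' Projects a two-label spectrum set onto its top two principal components
#' and assigns each cell to the nearer of the two label centroids in PC
#' space. The separation error rate is the number of wrongly assigned cells
#' divided by the total number of cells.
#'
#' @param set A [spectrum_set] with exactly two labels, each with >= 2
#'   spectra.
#' @param n_components Number of components (fixed at 2).
#' @return List with `scores` (n x 2 matrix), `assigned` (labels),
#'   `error_rate`, `centroids` and the `prcomp` object as `pca`.
#' @export
pca_separation <- function(set, n_components = 2L) {
  stopifnot(inherits(set, "spectrum_set"), n_components == 2L)
  labs <- unique(set$labels)
  if (length(labs) != 2L) {
    stop("pca_separation requires exactly two labels", call. = FALSE)
  }
  if (min(table(set$labels)) < 2L) {
    stop("each label needs at least 2 spectra", call. = FALSE)
  }
  pca <- stats::prcomp(set$intensities, center = TRUE, scale. = FALSE,
                       rank. = 2L)
  sc <- pca$x[, 1:2, drop = FALSE]
  cen <- rbind(colMeans(sc[set$labels == labs[1L], , drop = FALSE]),
               colMeans(sc[set$labels == labs[2L], , drop = FALSE]))
  rownames(cen) <- labs
  d1 <- sqrt(rowSums(sweep(sc, 2L, cen[1L, ])^2))
  d2 <- sqrt(rowSums(sweep(sc, 2L, cen[2L, ])^2))
  assigned <- ifelse(d1 <= d2, labs[1L], labs[2L])
  list(scores = sc, assigned = assigned,
       error_rate = mean(assigned != set$labels), centroids = cen, pca = pca)
}
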