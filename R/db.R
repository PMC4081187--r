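#' Create a single-cell phenotype record
#'
#' Records follow a four-block schema: (A) project information (cell id,
#' project id, date), (B) sample preparation (name, temperature, shaking,
#' optical density, plus free key-value extras), (C) instrument parameters
#' (laser, filter, objective, grating), (D) cell phenotype (image and
#' spectrum references, stage coordinates).
#'
#' @param cell_id Integer cell id, unique within a project.
#' @param project_id Project label.
#' @param date ISO-8601 date string (`YYYY-MM-DD`).
#' @param sample_name,temperature_c,shaking,od Sample-preparation block.
#' @param laser,filter,objective,grating Instrument block.
#' @param image_ref,spectrum_ref Relative file references (may be `NA` until
#'   assets are attached).
#' @param stage_x,stage_y Stage coordinates, um.
#' @param extra Named list of free-form extra sample-prep fields.
#' @return A `db_record` (named list).
#' @export
db_record <- function(cell_id, project_id, date = format(Sys.Date()),
                      sample_name = NA, temperature_c = NA, shaking = NA,
                      od = NA, laser = NA, filter = NA, objective = NA,
                      grating = NA, image_ref = NA, spectrum_ref = NA,
                      stage_x = NA, stage_y = NA, extra = list()) {
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", date)) {
    stop("date must be ISO-8601 (YYYY-MM-DD)", call. = FALSE)
  }
  structure(list(cell_id = as.integer(cell_id),
                 project_id = as.character(project_id), date = date,
                 sample_name = sample_name, temperature_c = temperature_c,
                 shaking = shaking, od = od,
                 laser = laser, filter = filter, objective = objective,
                 grating = grating,
                 image_ref = image_ref, spectrum_ref = spectrum_ref,
                 stage_x = stage_x, stage_y = stage_y,
                 extra = extra),
            class = "db_record")
}

db_manifest_cols <- c("cell_id", "project_id", "date", "sample_name",
                      "temperature_c", "shaking", "od", "laser", "filter",
                      "objective", "grating", "image_ref", "spectrum_ref",
                      "stage_x", "stage_y", "extra", "tier",
                      "promotion_reason")

empty_manifest <- function() {
  m <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(db_manifest_cols)), db_manifest_cols),
    stringsAsFactors = FALSE)
  m$cell_id <- integer(0)
  m$stage_x <- numeric(0); m$stage_y <- numeric(0)
  m
}

#' Create or open a directory-backed phenotype database
#'
#' The store is a plain directory: a UTF-8 tab-delimited `manifest.tsv`
#' holding the metadata (one row per record per tier), with spectra and
#' images as files referenced by relative path under `spectra/` and
#' `images/`. The raw tier keeps everything acquired; the refined tier only
#' records promoted by [evaluate_promotion] / [db_promote], so refined is a
#' subset of raw at all times.
#'
#' @param dir Store directory.
#' @return A `raman_db` handle.
#' @export
db_create <- function(dir) {
  if (file.exists(file.path(dir, "manifest.tsv"))) {
    stop("store already exists at ", dir, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  write_manifest(empty_manifest(), dir)
  db_open(dir)
}

#' @rdname db_create
#' @export
db_open <- function(dir) {
  if (!file.exists(file.path(dir, "manifest.tsv"))) {
    stop("no manifest.tsv under ", dir, call. = FALSE)
  }
  structure(list(dir = dir), class = "raman_db")
}

#' @export
print.raman_db <- function(x, ...) {
  m <- read_manifest(x$dir)
  cat(sprintf("<raman_db> %s: %d raw, %d refined record(s)\n", x$dir,
              sum(m$tier == "raw"), sum(m$tier == "refined")))
  invisible(x)
}

read_manifest <- function(dir) {
  m <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (nrow(m)) {
    m$cell_id <- as.integer(m$cell_id)
    m$stage_x <- as.numeric(m$stage_x)
    m$stage_y <- as.numeric(m$stage_y)
  } else {
    m <- empty_manifest()
  }
  m
}

write_manifest <- function(m, dir) {
  utils::write.table(m, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

record_row <- function(record, tier = "raw", promotion_reason = "none") {
  extra <- if (length(record$extra)) {
    paste(names(record$extra), vapply(record$extra, format, character(1)),
          sep = "=", collapse = ";")
  } else ""
  data.frame(cell_id = record$cell_id, project_id = record$project_id,
             date = record$date, sample_name = as.character(record$sample_name),
             temperature_c = as.character(record$temperature_c),
             shaking = as.character(record$shaking),
             od = as.character(record$od), laser = as.character(record$laser),
             filter = as.character(record$filter),
             objective = as.character(record$objective),
             grating = as.character(record$grating),
             image_ref = as.character(record$image_ref),
             spectrum_ref = as.character(record$spectrum_ref),
             stage_x = as.numeric(record$stage_x),
             stage_y = as.numeric(record$stage_y),
             extra = extra, tier = tier, promotion_reason = promotion_reason,
             stringsAsFactors = FALSE)
}

#' Insert a record into the raw tier
#'
#' Optionally writes an attached spectrum (two-column text) and/or image
#' (PNG) into the store and fills the record's file references. The
#' `(project_id, cell_id)` pair must be unique within the raw tier.
#'
#' @param db A `raman_db`.
#' @param record A [db_record].
#' @param spectrum Optional [raman_spectrum] to attach.
#' @param image Optional [field_image] to attach.
#' @return The record id string `"project_id/cell_id"`, invisibly.
#' @export
db_insert_raw <- function(db, record, spectrum = NULL, image = NULL) {
  stopifnot(inherits(db, "raman_db"), inherits(record, "db_record"))
  m <- read_manifest(db$dir)
  dup <- m$tier == "raw" & m$project_id == record$project_id &
    m$cell_id == record$cell_id
  if (any(dup)) {
    stop("duplicate (project_id, cell_id): ", record$project_id, "/",
         record$cell_id, call. = FALSE)
  }
  stem <- sprintf("%s_%06d", gsub("[^A-Za-z0-9_.-]", "-", record$project_id),
                  record$cell_id)
  if (!is.null(spectrum)) {
    rel <- file.path("spectra", paste0(stem, ".txt"))
    write_spectrum_txt(spectrum, file.path(db$dir, rel))
    record$spectrum_ref <- rel
  }
  if (!is.null(image)) {
    rel <- file.path("images", paste0(stem, ".png"))
    write_field_image(image, file.path(db$dir, rel))
    record$image_ref <- rel
  }
  utils::write.table(record_row(record, tier = "raw"),
                     file.path(db$dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE,
                     append = TRUE)
  invisible(paste0(record$project_id, "/", record$cell_id))
}

#' Load the spectrum attached to a record
#' @param db A `raman_db`.
#' @param row One manifest row (from [db_query]).
#' @return A [raman_spectrum].
#' @export
db_load_spectrum <- function(db, row) {
  if (is.na(row$spectrum_ref) || row$spectrum_ref == "" ||
      row$spectrum_ref == "NA") {
    stop("record has no spectrum reference", call. = FALSE)
  }
  read_spectrum_txt(file.path(db$dir, row$spectrum_ref),
                    meta = list(cell_id = row$cell_id,
                                project_id = row$project_id))
}

#' Promotion rule for the refined tier
#'
#' @param mode `"peak_presence"` (promote when the SNR of a marker peak is
#'   strictly over `snr_threshold`), `"intensity_threshold"` (promote when
#'   the maximum intensity in the peak window is strictly over
#'   `intensity_threshold`) or `"manual"` (promote on a curator flag).
#' @param peak_center,peak_halfwidth Marker peak window, cm^-1 (defaults:
#'   the 1003 cm^-1 phenylalanine band, half-width 5).
#' @param snr_threshold SNR threshold (default 3; strict inequality).
#' @param intensity_threshold Intensity threshold for intensity mode.
#' @param noise_window Noise window passed to [snr].
#' @return A `promotion_rule`.
#' @export
promotion_rule <- function(mode = c("peak_presence", "intensity_threshold",
                                    "manual"),
                           peak_center = 1003, peak_halfwidth = 5,
                           snr_threshold = 3, intensity_threshold = NULL,
                           noise_window = c(1750, 1850)) {
  mode <- match.arg(mode)
  if (mode == "peak_presence" && snr_threshold <= 0) {
    stop("snr_threshold must be > 0", call. = FALSE)
  }
  if (mode == "intensity_threshold" &&
      (is.null(intensity_threshold) || intensity_threshold <= 0)) {
    stop("intensity_threshold must be > 0", call. = FALSE)
  }
  structure(list(mode = mode, peak_center = peak_center,
                 peak_halfwidth = peak_halfwidth,
                 snr_threshold = snr_threshold,
                 intensity_threshold = intensity_threshold,
                 noise_window = noise_window),
            class = "promotion_rule")
}

#' Evaluate (and apply) the refined-tier promotion rule for one record
#'
#' In `peak_presence` mode a record is promoted iff the marker peak's SNR is
#' strictly over the threshold ("over 3" is read as a strict inequality);
#' in `intensity_threshold` mode iff the peak-window maximum exceeds the
#' intensity threshold; in `manual` mode iff the curator flag is set.
#' Promotion copies the record into the refined tier with the reason
#' recorded, and is idempotent: an already-refined record is not duplicated.
#'
#' @param db A `raman_db`.
#' @param project_id,cell_id Record key.
#' @param rule A [promotion_rule].
#' @param manual_flag Curator flag for manual mode.
#' @param apply If TRUE (default), promote in the store when the rule fires.
#' @return List `promote` (logical) and `reason` (`"auto_peak"`, `"manual"`
#'   or `"none"`).
#' @export
evaluate_promotion <- function(db, project_id, cell_id, rule,
                               manual_flag = FALSE, apply = TRUE) {
  stopifnot(inherits(db, "raman_db"), inherits(rule, "promotion_rule"))
  m <- read_manifest(db$dir)
  i <- which(m$tier == "raw" & m$project_id == project_id &
               m$cell_id == cell_id)
  if (!length(i)) stop("no raw record ", project_id, "/", cell_id,
                       call. = FALSE)
  row <- m[i[1L], ]
  promote <- FALSE; reason <- "none"
  if (rule$mode == "manual") {
    promote <- isTRUE(manual_flag)
    if (promote) reason <- "manual"
  } else {
    s <- db_load_spectrum(db, row)
    if (rule$mode == "peak_presence") {
      value <- snr(s, rule$peak_center, rule$peak_halfwidth,
                   rule$noise_window)
      promote <- value > rule$snr_threshold
    } else {
      wn <- s$wavenumbers
      in_peak <- wn >= rule$peak_center - rule$peak_halfwidth &
                 wn <= rule$peak_center + rule$peak_halfwidth
      if (!any(in_peak)) stop("peak window off the grid", call. = FALSE)
      promote <- max(s$intensities[in_peak]) > rule$intensity_threshold
    }
    if (promote) reason <- "auto_peak"
  }
  if (promote && apply) {
    already <- any(m$tier == "refined" & m$project_id == project_id &
                     m$cell_id == cell_id)
    if (!already) {
      ref <- row
      ref$tier <- "refined"
      ref$promotion_reason <- reason
      write_manifest(rbind(m, ref), db$dir)
    }
  }
  list(promote = promote, reason = reason)
}

#' Promote every raw record that satisfies a rule
#'
#' @param db A `raman_db`.
#' @param rule A [promotion_rule].
#' @param manual_flags Optional data frame `(project_id, cell_id, flag)` for
#'   manual mode, e.g. read from a curator-edited table.
#' @return Number of newly promoted records, invisibly.
#' @export
db_promote <- function(db, rule, manual_flags = NULL) {
  m <- read_manifest(db$dir)
  raw <- m[m$tier == "raw", , drop = FALSE]
  n_before <- sum(m$tier == "refined")
  for (i in seq_len(nrow(raw))) {
    flag <- FALSE
    if (!is.null(manual_flags)) {
      hit <- manual_flags$project_id == raw$project_id[i] &
        manual_flags$cell_id == raw$cell_id[i]
      flag <- any(hit) && isTRUE(manual_flags$flag[which(hit)[1L]])
    }
    evaluate_promotion(db, raw$project_id[i], raw$cell_id[i], rule,
                       manual_flag = flag, apply = TRUE)
  }
  m2 <- read_manifest(db$dir)
  invisible(sum(m2$tier == "refined") - n_before)
}

#' Query the database
#'
#' Conjunctive filtering over the manifest fields. Each filter is either a
#' value (matched by equality) or a predicate function over the column.
#' Results are ordered by `(project_id, cell_id)`.
#'
#' @param db A `raman_db`.
#' @param filters Named list of filters over manifest columns.
#' @param tier `"refined"` (default) or `"raw"`.
#' @return Data frame of matching manifest rows.
#' @export
db_query <- function(db, filters = list(), tier = c("refined", "raw")) {
  stopifnot(inherits(db, "raman_db"))
  tier <- match.arg(tier)
  m <- read_manifest(db$dir)
  keep <- m$tier == tier
  for (f in names(filters)) {
    if (!f %in% names(m)) stop("unknown field: ", f, call. = FALSE)
    flt <- filters[[f]]
    keep <- keep & if (is.function(flt)) {
      isTRUE_vec(flt(m[[f]]))
    } else {
      !is.na(m[[f]]) & m[[f]] == flt
    }
  }
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$project_id, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Check the refined-subset-of-raw invariant
#' @param db A `raman_db`.
#' @return TRUE iff every refined record also exists in the raw tier and
#'   every refined record has a promotion reason other than `"none"`.
#' @export
db_check_invariants <- function(db) {
  m <- read_manifest(db$dir)
  key <- function(d) paste(d$project_id, d$cell_id)
  ref <- m[m$tier == "refined", , drop = FALSE]
  raw <- m[m$tier == "raw", , drop = FALSE]
  all(key(ref) %in% key(raw)) && !any(ref$promotion_reason == "none") &&
    !anyDuplicated(key(raw)) && !anyDuplicated(key(ref))
}
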