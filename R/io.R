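#' Write spike trains as TSV
#'
#' Tab-separated, UTF-8, '.' decimal, header line
#' `unit_id\trow\tcol\ttime_s`; one row per spike, sorted by unit then
#' time. Every unit appears in the file's unit registry even if it fired
#' no spikes (a zero-spike unit contributes no rows but its channel is
#' recoverable from the sidecar written by [write_ground_truth()] runs;
#' for plain TSV round-trips, spikeless units are dropped).
#'
#' @param rec An [mea_recording()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(rec, path) {
  tab <- spike_table(rec)
  tab <- tab[order(tab$unit_id, tab$time_s), , drop = FALSE]
  tab$time_s <- sprintf("%.9f", tab$time_s)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read spike trains from TSV
#'
#' @param path TSV file in the dialect of [write_spikes()].
#' @param grid_rows,grid_cols Grid dimensions of the array.
#' @param pitch Interelectrode spacing, um.
#' @param duration Recording length, s; when `NULL`, the latest spike
#'   time rounded up to the next second is used.
#' @param ground_channel Optional `(row, col)` of the ground electrode.
#' @return An [mea_recording()]. Malformed rows — negative or non-numeric
#'   times, off-grid channels, per-unit time order violations — raise a
#'   parse error naming the offending line number.
#' @export
read_spikes <- function(path, grid_rows = 8L, grid_cols = 8L, pitch = 200,
                        duration = NULL, ground_channel = NULL) {
  tab <- read.delim(path, colClasses = c("character", "integer", "integer",
                                         "numeric"))
  needed <- c("unit_id", "row", "col", "time_s")
  if (!identical(names(tab), needed))
    stop("expected columns ", paste(needed, collapse = ", "))
  line <- seq_len(nrow(tab)) + 1L  # header is line 1
  bad <- which(!is.finite(tab$time_s) | tab$time_s < 0)
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L, ": invalid time_s")
  bad <- which(tab$row < 1L | tab$row > grid_rows |
                 tab$col < 1L | tab$col > grid_cols)
  if (length(bad))
    stop("parse error at line ", line[bad[1]], ": channel off the grid")
  for (id in unique(tab$unit_id)) {
    w <- which(tab$unit_id == id)
    if (is.unsorted(tab$time_s[w])) {
      k <- w[which(diff(tab$time_s[w]) < 0)[1] + 1L]
      stop("parse error at line ", line[k], ": unsorted times for unit ", id)
    }
  }
  if (is.null(duration))
    duration <- if (nrow(tab)) ceiling(max(tab$time_s)) else 1
  units <- unique(tab[, c("unit_id", "row", "col")])
  spikes <- split(tab$time_s, tab$unit_id)[units$unit_id]
  if (nrow(units) == 0L)
    spikes <- setNames(list(), character(0))
  mea_recording(units, spikes, grid_rows, grid_cols, pitch, duration,
                ground_channel)
}

#' Write simulator ground truth as JSON
#' @param truth Ground-truth list from [simulate_mea()] or the image
#'   simulators.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a dLGN section stack as TIFF files
#'
#' Per section `i`: 16-bit intensity images `<prefix>_<i>_contra.tif` and
#' `<prefix>_<i>_ipsi.tif` plus 8-bit masks `<prefix>_<i>_dlgn_mask.tif`
#' and `<prefix>_<i>_bg_mask.tif` (and reference-ROI masks when present),
#' with a JSON sidecar `<prefix>_meta.json` carrying the scale.
#'
#' @param sections List of [section_image_pair()]s.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"section"`).
#' @return `dir`, invisibly.
#' @export
write_sections <- function(sections, dir, prefix = "section") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(i, kind) file.path(dir, sprintf("%s_%03d_%s.tif", prefix, i, kind))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    tiff::writeTIFF(pmin(s$contra, 65535) / 65535, f(i, "contra"),
                    bits.per.sample = 16L)
    tiff::writeTIFF(pmin(s$ipsi, 65535) / 65535, f(i, "ipsi"),
                    bits.per.sample = 16L)
    tiff::writeTIFF(s$dlgn_mask * 1, f(i, "dlgn_mask"), bits.per.sample = 8L)
    tiff::writeTIFF(s$background_mask * 1, f(i, "bg_mask"), bits.per.sample = 8L)
    if (!is.null(s$contra_ref_mask))
      tiff::writeTIFF(s$contra_ref_mask * 1, f(i, "contra_ref_mask"),
                      bits.per.sample = 8L)
    if (!is.null(s$ipsi_ref_mask))
      tiff::writeTIFF(s$ipsi_ref_mask * 1, f(i, "ipsi_ref_mask"),
                      bits.per.sample = 8L)
  }
  jsonlite::write_json(list(n_sections = length(sections),
                            um_per_pixel = sections[[1]]$um_per_pixel),
                       file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dLGN section stack written by [write_sections()]
#' @param dir Directory holding the TIFFs.
#' @param prefix File-name prefix.
#' @return List of [section_image_pair()]s.
#' @export
read_sections <- function(dir, prefix = "section") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")))
  f <- function(i, kind) file.path(dir, sprintf("%s_%03d_%s.tif", prefix, i, kind))
  rd16 <- function(p) round(tiff::readTIFF(p) * 65535)
  rdmask <- function(p) if (file.exists(p)) tiff::readTIFF(p) > 0.5 else NULL
  lapply(seq_len(meta$n_sections), function(i) {
    section_image_pair(rd16(f(i, "contra")), rd16(f(i, "ipsi")),
                       rdmask(f(i, "dlgn_mask")), rdmask(f(i, "bg_mask")),
                       meta$um_per_pixel,
                       rdmask(f(i, "contra_ref_mask")),
                       rdmask(f(i, "ipsi_ref_mask")))
  })
}

#' Serialise a burst table to CSV
#'
#' Columns `unit_id, start_s, end_s, n_spikes, surprise, kept,
#' exclusion_reason` and, when present, `is_wab, n_supporting,
#' supporting_channels` (semicolon-separated `row,col` pairs).
#'
#' @param kept Labelled kept bursts (e.g. from [classify_wabs()]).
#' @param excluded Excluded bursts from [filter_bursts()] (optional).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_bursts_csv <- function(kept, excluded = NULL, path) {
  fmt <- function(b, kept_flag) {
    nb <- nrow(b)
    df <- data.frame(unit_id = b$unit_id, start_s = b$start, end_s = b$end,
                     n_spikes = b$n_spikes, surprise = b$surprise,
                     kept = rep(kept_flag, nb),
                     exclusion_reason = if (!is.null(b$exclusion_reason))
                       b$exclusion_reason else rep(NA_character_, nb))
    if (!is.null(b$is_wab)) {
      df$is_wab <- b$is_wab
      df$n_supporting <- b$n_supporting
      df$supporting_channels <- vapply(b$supporting_channels, function(m)
        paste(paste(m[, "row"], m[, "col"], sep = ","), collapse = ";"),
        character(1))
    }
    df
  }
  out <- fmt(kept, TRUE)
  if (!is.null(excluded) && nrow(excluded)) {
    ex <- fmt(excluded, FALSE)
    for (nm in setdiff(names(out), names(ex))) ex[[nm]] <- NA
    out <- rbind(out, ex[names(out)])
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
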