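#' Construct an MEA recording
#'
#' The central spike-train container: one sorted timestamp vector per unit,
#' each unit assigned to an electrode on a rectangular grid.
#'
#' @param units Data frame with columns `unit_id` (character, unique),
#'   `row`, `col` (1-based integer grid coordinates).
#' @param spikes Named list of numeric vectors (seconds, sorted ascending,
#'   within `[0, duration]`), names matching `units$unit_id`.
#' @param grid_rows,grid_cols Grid dimensions.
#' @param pitch Interelectrode spacing, um.
#' @param duration Recording length, s.
#' @param ground_channel Optional length-2 integer `(row, col)` of the
#'   ground electrode; its units are flagged by [flag_invalid_units()].
#' @return An `mea_recording` object.
#' @export
mea_recording <- function(units, spikes, grid_rows, grid_cols, pitch,
                          duration, ground_channel = NULL) {
  stopifnot(is.data.frame(units),
            all(c("unit_id", "row", "col") %in% names(units)))
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) stop("duplicate unit_id")
  if (duration <= 0) stop("duration must be > 0")
  if (!setequal(names(spikes), units$unit_id))
    stop("spikes names must match units$unit_id")
  spikes <- spikes[units$unit_id]
  if (nrow(units) > 0L) {
    if (any(units$row < 1L | units$row > grid_rows |
            units$col < 1L | units$col > grid_cols))
      stop("unit channel off the grid")
    for (id in units$unit_id) {
      ts <- spikes[[id]]
      if (is.unsorted(ts)) stop("timestamps not sorted for unit ", id)
      if (length(ts) && (ts[1] < 0 || ts[length(ts)] > duration))
        stop("timestamps outside [0, duration] for unit ", id)
    }
  }
  structure(list(units = units, spikes = spikes,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 pitch = pitch, duration = duration,
                 ground_channel = ground_channel),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d units on a %dx%d grid (pitch %g um), %g s, %d spikes\n",
              nrow(x$units), x$grid_rows, x$grid_cols, x$pitch, x$duration,
              total_spikes(x)))
  invisible(x)
}

#' Total spike count of a recording
#' @param rec An [mea_recording()].
#' @return Integer count over all units.
#' @export
total_spikes <- function(rec) {
  sum(vapply(rec$spikes, length, integer(1)))
}

#' Restrict a recording to a subset of units
#' @param rec An [mea_recording()].
#' @param unit_ids Character vector of units to keep.
#' @return The restricted `mea_recording`.
#' @export
subset_units <- function(rec, unit_ids) {
  keep <- rec$units$unit_id %in% unit_ids
  mea_recording(rec$units[keep, , drop = FALSE], rec$spikes[rec$units$unit_id[keep]],
                rec$grid_rows, rec$grid_cols, rec$pitch, rec$duration,
                rec$ground_channel)
}

# long-format view: one row per spike, sorted by time
spike_table <- function(rec) {
  n <- vapply(rec$spikes, length, integer(1))
  df <- data.frame(
    unit_id = rep(rec$units$unit_id, n),
    row = rep(rec$units$row, n),
    col = rep(rec$units$col, n),
    time_s = unlist(rec$spikes, use.names = FALSE)
  )
  df[order(df$time_s), , drop = FALSE]
}
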