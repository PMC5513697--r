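#' Remove multi-channel artifact spikes
#'
#' Spikes appearing within a short time window on a large fraction of
#' channels are assumed to be artifacts (bubbles or other mechanical
#' disturbances affecting the whole array) and are discarded. The scan is a
#' greedy sweep over the channel-merged, time-sorted spike list: a window
#' `[t, t + window]` opens at every spike not already consumed by an
#' artifact group; if the spikes inside it cover at least
#' `channel_fraction` of the channels bearing at least one unit, the whole
#' group is removed.
#'
#' The fraction is taken over channels that carry units, not over the full
#' grid: electrodes with no sorted unit cannot report an artifact.
#'
#' @param rec An [mea_recording()].
#' @param window Coincidence window, s (default 1 ms).
#' @param channel_fraction Minimum fraction of unit-bearing channels that
#'   must spike inside the window (default 0.70).
#' @return A list: `recording` (the cleaned [mea_recording()]) and
#'   `removed_count` (spikes discarded).
#' @export
reject_artifacts <- function(rec, window = 0.001, channel_fraction = 0.70) {
  stopifnot(inherits(rec, "mea_recording"))
  if (window <= 0) stop("window must be > 0")
  if (channel_fraction <= 0 || channel_fraction > 1)
    stop("channel_fraction must be in (0, 1]")
  tab <- spike_table(rec)
  if (nrow(tab) == 0L)
    return(list(recording = rec, removed_count = 0L))

  n_active <- nrow(unique(rec$units[, c("row", "col")]))
  need <- channel_fraction * n_active
  chan <- tab$row * (rec$grid_cols + 1L) + tab$col
  tt <- tab$time_s
  n <- length(tt)
  removed <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    hi <- tt[i] + window
    while (j < n && tt[j + 1L] <= hi) j <- j + 1L
    if (j > i && length(unique(chan[i:j])) >= need) {
      removed[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  keep <- tab[!removed, , drop = FALSE]
  spikes <- setNames(vector("list", nrow(rec$units)), rec$units$unit_id)
  kept_by_unit <- split(keep$time_s, keep$unit_id)
  for (id in names(spikes)) {
    v <- kept_by_unit[[id]]
    spikes[[id]] <- if (is.null(v)) numeric(0) else sort(v)
  }
  out <- mea_recording(rec$units, spikes, rec$grid_rows, rec$grid_cols,
                       rec$pitch, rec$duration, rec$ground_channel)
  list(recording = out, removed_count = sum(removed))
}

#' Flag units unusable for analysis
#'
#' Units whose mean firing rate over the whole recording falls strictly
#' below `min_rate` are taken to come from electrodes with poor retinal
#' contact; units on the ground channel are flagged regardless of rate.
#' Flagged units are excluded from all downstream analyses.
#'
#' @param rec An [mea_recording()].
#' @param min_rate Validity threshold, Hz (default 0.25).
#' @return Character vector of flagged `unit_id`s.
#' @export
flag_invalid_units <- function(rec, min_rate = 0.25) {
  stopifnot(inherits(rec, "mea_recording"), rec$duration > 0)
  rate <- vapply(rec$spikes, length, integer(1)) / rec$duration
  flagged <- rec$units$unit_id[rate < min_rate]
  if (!is.null(rec$ground_channel)) {
    g <- rec$ground_channel
    on_ground <- rec$units$row == g[1] & rec$units$col == g[2]
    flagged <- union(flagged, rec$units$unit_id[on_ground])
  }
  flagged
}

#' Valid units of a recording
#'
#' Convenience complement of [flag_invalid_units()].
#'
#' @inheritParams flag_invalid_units
#' @return Character vector of unit ids passing the validity criteria.
#' @export
valid_units <- function(rec, min_rate = 0.25) {
  setdiff(rec$units$unit_id, flag_invalid_units(rec, min_rate))
}
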