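#' Bin-start times of a burst
#'
#' Each burst is divided into `n_bins` bins of equal duration; the
#' association rule compares the left edges (starts) of these bins.
#'
#' @param start,end Burst interval, s, `end > start`.
#' @param n_bins Number of bins (default 10).
#' @return Numeric vector of `n_bins` bin-start times:
#'   `start, start + d, ..., start + (n_bins - 1) d` with
#'   `d = (end - start) / n_bins`.
#' @export
burst_bin_starts <- function(start, end, n_bins = 10L) {
  if (end <= start) stop("burst must have positive duration")
  d <- (end - start) / n_bins
  start + (seq_len(n_bins) - 1L) * d
}

#' Are two bursts associated?
#'
#' Two bursts on different units and different channels are associated when
#' the start of at least one bin of one lies within `delta_t` of the start
#' of any bin of the other, with `delta_t` equal to half the sum of the two
#' bursts' bin durations. The comparison is inclusive and the relation is
#' symmetric.
#'
#' @param a,b Lists or one-row data frames with fields `start`, `end`,
#'   `unit_id`, `row`, `col`.
#' @param n_bins Bins per burst (default 10).
#' @return `TRUE`/`FALSE`; always `FALSE` for bursts on the same unit or
#'   the same channel, which can never be associated.
#' @export
bursts_associated <- function(a, b, n_bins = 10L) {
  if (identical(a$unit_id, b$unit_id)) return(FALSE)
  if (a$row == b$row && a$col == b$col) return(FALSE)
  da <- (a$end - a$start) / n_bins
  db <- (b$end - b$start) / n_bins
  delta_t <- (da + db) / 2
  sa <- burst_bin_starts(a$start, a$end, n_bins)
  sb <- burst_bin_starts(b$start, b$end, n_bins)
  any(abs(outer(sa, sb, "-")) <= delta_t)
}

# neighbouring channel coordinates (8-neighbourhood clipped to the grid)
channel_neighbors <- function(row, col, grid_rows, grid_cols) {
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  r <- row + nb$dr
  c <- col + nb$dc
  ok <- r >= 1L & r <= grid_rows & c >= 1L & c <= grid_cols
  cbind(row = r[ok], col = c[ok])
}

#' Classify kept bursts as wave-associated bursts (WABs)
#'
#' A burst is a WAB when it is associated (see [bursts_associated()]) with
#' bursts on at least `cfg$min_neighbor_channels` distinct neighbouring
#' channels, where a channel's neighbours are the up-to-eight electrodes
#' physically surrounding it on the grid (five on an edge, three in a
#' corner). A neighbouring channel counts at most once no matter how many
#' of its units carry an associated burst, and bursts on the same unit or
#' channel never associate.
#'
#' @param kept_bursts Burst table (after [filter_bursts()]) with columns
#'   `unit_id`, `row`, `col`, `start`, `end`.
#' @param grid_rows,grid_cols Electrode grid dimensions.
#' @param cfg An [association_config()].
#' @return `kept_bursts` with columns added: `is_wab` (logical),
#'   `n_supporting` (distinct supporting neighbour channels), and
#'   `supporting_channels` (list column of `row,col` matrices).
#' @export
classify_wabs <- function(kept_bursts, grid_rows, grid_cols,
                          cfg = association_config()) {
  b <- kept_bursts
  n <- nrow(b)
  b$is_wab <- logical(n)
  b$n_supporting <- integer(n)
  b$supporting_channels <- vector("list", n)
  if (n == 0L) return(b)
  if (any(b$row < 1L | b$row > grid_rows | b$col < 1L | b$col > grid_cols))
    stop("burst channel off the grid")

  nb_bins <- cfg$n_bins
  chan_id <- (b$row - 1L) * grid_cols + b$col
  by_chan <- vector("list", grid_rows * grid_cols)
  for (g in split(seq_len(n), chan_id)) by_chan[[chan_id[g[1]]]] <- g
  d <- (b$end - b$start) / nb_bins
  last_bin <- b$end - d  # start of the final bin
  bin_off <- seq_len(nb_bins) - 1L
  bstart <- b$start

  # inline bin-start comparison on plain vectors (bursts_associated on data
  # frame rows is too slow for whole recordings)
  assoc_fast <- function(k, j) {
    dt <- (d[k] + d[j]) / 2
    sa <- bstart[k] + bin_off * d[k]
    sb <- bstart[j] + bin_off * d[j]
    any(abs(rep(sa, times = nb_bins) - rep(sb, each = nb_bins)) <= dt)
  }

  # neighbour coordinates per channel, computed once for the whole grid
  nbr_of <- vector("list", grid_rows * grid_cols)
  for (cc in sort(unique(chan_id)))
    nbr_of[[cc]] <- channel_neighbors((cc - 1L) %/% grid_cols + 1L,
                                      (cc - 1L) %% grid_cols + 1L,
                                      grid_rows, grid_cols)

  for (k in seq_len(n)) {
    nbrs <- nbr_of[[chan_id[k]]]
    supp <- list()
    for (m in seq_len(nrow(nbrs))) {
      idx <- by_chan[[(nbrs[m, "row"] - 1L) * grid_cols + nbrs[m, "col"]]]
      if (is.null(idx)) next
      # a pair can only associate if its bin-start ranges come within delta_t
      delta_t <- (d[k] + d[idx]) / 2
      cand <- idx[bstart[idx] - last_bin[k] <= delta_t &
                    bstart[k] - last_bin[idx] <= delta_t]
      hit <- FALSE
      for (j in cand) {
        if (assoc_fast(k, j)) { hit <- TRUE; break }
      }
      if (hit) supp[[length(supp) + 1L]] <- nbrs[m, , drop = FALSE]
    }
    sc <- if (length(supp)) do.call(rbind, supp) else
      matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
    b$supporting_channels[[k]] <- sc
    b$n_supporting[k] <- nrow(sc)
    b$is_wab[k] <- nrow(sc) >= cfg$min_neighbor_channels
  }
  b
}

# names of the spiking-property registry; conditional properties are only
# defined for units possessing WABs (>= 2 for the inter-WAB interval)
property_registry <- function() {
  c("mean_wab_duration_s", "in_wab_rate_hz", "spikes_per_wab",
    "inter_wab_interval_s", "n_wabs", "wab_rate_per_min", "total_spikes",
    "spikes_outside_wabs", "out_wab_rate_hz", "mean_rate_hz",
    "frac_spikes_in_wabs")
}

wab_conditional_properties <- function() {
  c("mean_wab_duration_s", "in_wab_rate_hz", "spikes_per_wab",
    "inter_wab_interval_s")
}

#' Per-unit and per-retina spiking properties
#'
#' Computes the spiking-property registry for each analysed unit and
#' averages over units to obtain retina-level values (the experimental
#' unit for group statistics). All of a unit's spikes — including those of
#' bursts excluded by the duration or edge rules — enter the count and
#' rate properties; WAB-conditional properties (mean WAB duration, in-WAB
#' rate, spikes per WAB, inter-WAB interval) are averaged only over units
#' that possess at least one WAB (two for the interval), avoiding 0/0.
#'
#' Properties: mean WAB duration (s); in-WAB firing rate (Hz, WAB spikes
#' per second of WAB time); spikes per WAB; mean inter-WAB interval (s,
#' end of one WAB to start of the next on the same unit); WAB count; WAB
#' rate (WABs/min); total spikes; spikes outside WABs; out-of-WAB firing
#' rate (Hz, non-WAB spikes per second of non-WAB time); overall mean rate
#' (Hz); fraction of spikes inside WABs.
#'
#' @param rec The artifact-cleaned [mea_recording()].
#' @param labeled_bursts Output of [classify_wabs()] (kept bursts with
#'   `is_wab`).
#' @param units Unit ids to summarise (normally [valid_units()]).
#' @return A list: `per_unit` (data frame, one row per unit) and
#'   `per_retina` (named numeric vector of unweighted means over units,
#'   with the conditional-property restriction above).
#' @export
compute_properties <- function(rec, labeled_bursts,
                               units = rec$units$unit_id) {
  dur <- rec$duration
  rows <- lapply(units, function(id) {
    total <- length(rec$spikes[[id]])
    w <- labeled_bursts[labeled_bursts$unit_id == id & labeled_bursts$is_wab,
                        , drop = FALSE]
    nw <- nrow(w)
    wd <- w$end - w$start
    in_spk <- sum(w$n_spikes)
    iwi <- if (nw >= 2L) mean(w$start[-1L] - w$end[-nw]) else NA_real_
    data.frame(
      unit_id = id,
      mean_wab_duration_s = if (nw) mean(wd) else NA_real_,
      in_wab_rate_hz = if (nw) in_spk / sum(wd) else NA_real_,
      spikes_per_wab = if (nw) in_spk / nw else NA_real_,
      inter_wab_interval_s = iwi,
      n_wabs = nw,
      wab_rate_per_min = nw / (dur / 60),
      total_spikes = total,
      spikes_outside_wabs = total - in_spk,
      out_wab_rate_hz = (total - in_spk) / (dur - sum(wd)),
      mean_rate_hz = total / dur,
      frac_spikes_in_wabs = if (total) in_spk / total else NA_real_
    )
  })
  reg <- property_registry()
  if (!length(rows)) {
    per_unit <- data.frame(unit_id = character(0))
    for (p in reg) per_unit[[p]] <- numeric(0)
    return(list(per_unit = per_unit,
                per_retina = setNames(rep(NA_real_, length(reg)), reg)))
  }
  per_unit <- do.call(rbind, rows)
  rownames(per_unit) <- NULL
  per_retina <- vapply(reg, function(p)
    suppressWarnings(mean(per_unit[[p]], na.rm = TRUE)), numeric(1))
  per_retina[is.nan(per_retina)] <- NA_real_
  list(per_unit = per_unit, per_retina = per_retina)
}

#' Run the full wave-analysis pipeline on one recording
#'
#' Convenience wrapper chaining [reject_artifacts()],
#' [flag_invalid_units()], [detect_bursts_recording()], [filter_bursts()],
#' [classify_wabs()] and [compute_properties()].
#'
#' @param rec An [mea_recording()].
#' @param burst_cfg A [burst_filter_config()].
#' @param assoc_cfg An [association_config()].
#' @param min_rate Unit validity threshold, Hz.
#' @param artifact_window,artifact_fraction Artifact-rejection parameters.
#' @return A list with `recording` (cleaned), `flagged_units`, `bursts`
#'   (all detected), `kept` (labelled kept bursts), `excluded`, `pool`,
#'   and `properties` (per-unit and per-retina).
#' @export
analyze_waves <- function(rec, burst_cfg = burst_filter_config(),
                          assoc_cfg = association_config(),
                          min_rate = 0.25, artifact_window = 0.001,
                          artifact_fraction = 0.70) {
  art <- reject_artifacts(rec, artifact_window, artifact_fraction)
  clean <- art$recording
  flagged <- flag_invalid_units(clean, min_rate)
  ok <- setdiff(clean$units$unit_id, flagged)
  bursts <- detect_bursts_recording(clean, burst_cfg, units = ok)
  filt <- filter_bursts(bursts, burst_cfg, clean$duration)
  labeled <- classify_wabs(filt$kept, clean$grid_rows, clean$grid_cols,
                           assoc_cfg)
  props <- compute_properties(clean, labeled, units = ok)
  list(recording = clean, removed_count = art$removed_count,
       flagged_units = flagged, bursts = bursts, kept = labeled,
       excluded = filt$excluded, pool = filt$pool, properties = props)
}
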