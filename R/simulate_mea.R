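#' Simulate an MEA recording containing propagating retinal waves
#'
#' Generates spike trains on a rectangular electrode grid from a simple
#' generative model: wave events arrive as a Poisson process in time, each
#' wave being a planar front with uniformly random direction that starts at
#' a random electrode and crosses the grid at `wave_speed`. When the front
#' reaches an electrode, every unit there emits a burst of homogeneous
#' Poisson spikes at `burst_rate` lasting `burst_duration` times log-normal
#' jitter (sdlog 0.1), delayed by the front's arrival time, so that bursts
#' on neighbouring electrodes overlap in time. Background firing is an
#' independent homogeneous Poisson process per unit at `background_rate`.
#'
#' Each injected burst is drawn with at least two spikes, so every
#' ground-truth interval is a detectable spiking episode whenever
#' `burst_rate * burst_duration` is appreciable. Bursts from waves arriving
#' near the end of the recording are truncated at the recording edge.
#'
#' @param params A [wave_sim_params()] object.
#' @return A list with components:
#'   \describe{
#'     \item{recording}{An [mea_recording()] with all spikes merged and
#'       sorted per unit.}
#'     \item{truth}{Ground truth: `waves` (one row per wave event: id,
#'       start time, origin electrode, direction) and `bursts` (one row per
#'       injected burst: `unit_id`, `start`, `end`, `wave_id`,
#'       `n_spikes`).}
#'   }
#' @examples
#' sim <- simulate_mea(wave_sim_params(duration = 120, seed = 42))
#' sim$recording
#' head(sim$truth$bursts)
#' @export
simulate_mea <- function(params) {
  stopifnot(inherits(params, "wave_sim_params"))
  set.seed(params$seed)
  p <- params

  ch <- expand.grid(row = seq_len(p$grid_rows), col = seq_len(p$grid_cols))
  ch <- ch[order(ch$row, ch$col), ]
  units <- ch[rep(seq_len(nrow(ch)), each = p$units_per_channel), , drop = FALSE]
  units$unit_id <- sprintf("r%02dc%02du%d", units$row, units$col,
                           rep(seq_len(p$units_per_channel), times = nrow(ch)))
  rownames(units) <- NULL
  units <- units[, c("unit_id", "row", "col")]

  # electrode positions in um
  ex <- (units$col - 1) * p$pitch
  ey <- (units$row - 1) * p$pitch

  n_waves <- rpois(1, p$wave_rate * p$duration)
  waves <- data.frame(
    wave_id = integer(0), t_start = numeric(0), origin_row = integer(0),
    origin_col = integer(0), direction_rad = numeric(0)
  )
  spikes <- setNames(vector("list", nrow(units)), units$unit_id)
  for (i in seq_along(spikes)) spikes[[i]] <- numeric(0)
  tb <- list()

  if (n_waves > 0L) {
    t0 <- sort(runif(n_waves, 0, p$duration))
    theta <- runif(n_waves, 0, 2 * pi)
    origin <- sample.int(nrow(ch), n_waves, replace = TRUE)
    waves <- data.frame(
      wave_id = seq_len(n_waves), t_start = t0,
      origin_row = ch$row[origin], origin_col = ch$col[origin],
      direction_rad = theta
    )
    nu <- nrow(units)
    for (w in seq_len(n_waves)) {
      ox <- (ch$col[origin[w]] - 1) * p$pitch
      oy <- (ch$row[origin[w]] - 1) * p$pitch
      proj <- (ex - ox) * cos(theta[w]) + (ey - oy) * sin(theta[w])
      arrival <- t0[w] + (proj - min(proj)) / p$wave_speed
      dur <- p$burst_duration * exp(rnorm(nu, 0, 0.1))
      b0 <- arrival
      b1 <- pmin(b0 + dur, p$duration)
      live <- which(b0 < p$duration & b1 > b0)
      if (!length(live)) next
      n <- pmax(rpois(length(live), p$burst_rate * (b1 - b0)[live]), 2L)
      st <- runif(sum(n), rep(b0[live], n), rep(b1[live], n))
      by_unit <- split(st, rep(seq_along(live), n))
      for (k in seq_along(live)) {
        i <- live[k]
        spikes[[i]] <- c(spikes[[i]], by_unit[[k]])
      }
      tb[[length(tb) + 1L]] <- data.frame(
        unit_id = units$unit_id[live], start = b0[live], end = b1[live],
        wave_id = w, n_spikes = n
      )
    }
  }

  if (p$background_rate > 0) {
    for (i in seq_len(nrow(units))) {
      n <- rpois(1, p$background_rate * p$duration)
      if (n > 0L) spikes[[i]] <- c(spikes[[i]], runif(n, 0, p$duration))
    }
  }
  spikes <- lapply(spikes, sort)

  bursts <- if (length(tb)) do.call(rbind, tb) else
    data.frame(unit_id = character(0), start = numeric(0), end = numeric(0),
               wave_id = integer(0), n_spikes = integer(0))
  bursts <- bursts[order(bursts$unit_id, bursts$start), , drop = FALSE]
  rownames(bursts) <- NULL

  rec <- mea_recording(units, spikes, p$grid_rows, p$grid_cols, p$pitch,
                       p$duration)
  list(recording = rec, truth = list(waves = waves, bursts = bursts))
}
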