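#' Parameters for the synthetic MEA wave simulator
#'
#' Bundles the physical and statistical parameters of the spike-train
#' generator. Defaults describe a 10-minute dark recording on an 8x8 array
#' with 200 um electrode pitch: planar wave fronts sweep the grid roughly
#' every 45 s at 200 um/s, each front triggering a ~2 s burst at 10 Hz on
#' every unit it passes, on top of 0.1 Hz homogeneous Poisson background
#' firing.
#'
#' @param grid_rows,grid_cols Electrode grid dimensions (each >= 2).
#' @param pitch Interelectrode spacing, um.
#' @param duration Recording length, s.
#' @param wave_rate Wave initiation rate, waves/s.
#' @param wave_speed Planar front propagation speed, um/s.
#' @param burst_rate In-burst firing rate, Hz.
#' @param burst_duration Nominal burst duration, s; each burst's realised
#'   duration is multiplied by log-normal jitter (sdlog 0.1).
#' @param background_rate Out-of-wave firing rate per unit, Hz.
#' @param units_per_channel Sorted units per electrode.
#' @param condition_scalers Optional named list of multipliers applied by
#'   [apply_condition()] to derive a second experimental condition, e.g.
#'   `list(burst_duration = 1.5, background_rate = 2)`.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   recording bit for bit.
#' @return A `wave_sim_params` list.
#' @seealso [simulate_mea()]
#' @export
wave_sim_params <- function(grid_rows = 8L, grid_cols = 8L, pitch = 200,
                            duration = 600, wave_rate = 1 / 45,
                            wave_speed = 200, burst_rate = 10,
                            burst_duration = 2, background_rate = 0.1,
                            units_per_channel = 1L,
                            condition_scalers = NULL, seed = 1L) {
  p <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pitch = pitch, duration = duration, wave_rate = wave_rate,
    wave_speed = wave_speed, burst_rate = burst_rate,
    burst_duration = burst_duration, background_rate = background_rate,
    units_per_channel = as.integer(units_per_channel),
    condition_scalers = condition_scalers, seed = as.integer(seed)
  )
  if (p$grid_rows < 2L || p$grid_cols < 2L)
    stop("grid dimensions must be >= 2")
  if (p$duration <= 0) stop("duration must be > 0")
  if (p$wave_speed <= 0) stop("wave_speed must be > 0")
  if (p$pitch <= 0) stop("pitch must be > 0")
  if (p$burst_rate <= 0 || p$burst_duration <= 0)
    stop("burst rate and duration must be > 0")
  if (p$wave_rate < 0 || p$background_rate < 0)
    stop("rates must be >= 0")
  if (p$units_per_channel < 1L) stop("units_per_channel must be >= 1")
  class(p) <- "wave_sim_params"
  p
}

#' Derive a second condition by scaling simulator parameters
#'
#' Applies the multipliers in `params$condition_scalers` (or `scalers`) to a
#' parameter set, e.g. to produce a condition with longer bursts and more
#' background spiking than its control.
#'
#' @param params A [wave_sim_params()] object.
#' @param scalers Named list of multipliers; defaults to
#'   `params$condition_scalers`.
#' @return A new `wave_sim_params` with the scaled values.
#' @export
apply_condition <- function(params, scalers = params$condition_scalers) {
  stopifnot(inherits(params, "wave_sim_params"))
  if (is.null(scalers) || length(scalers) == 0L) return(params)
  bad <- setdiff(names(scalers), names(params))
  if (length(bad)) stop("unknown condition_scalers: ", paste(bad, collapse = ", "))
  for (nm in names(scalers)) params[[nm]] <- params[[nm]] * scalers[[nm]]
  params$condition_scalers <- NULL
  do.call(wave_sim_params, params[setdiff(names(params), "condition_scalers")])
}

#' Parameters for the synthetic dLGN section-image simulator
#'
#' @param height,width Image size in pixels.
#' @param um_per_pixel Physical scale.
#' @param n_sections Sections per hemisphere stack (the quantification
#'   protocol analyses 15 mid-dLGN sections).
#' @param ipsi_area_fraction Fraction of dLGN-mask pixels occupied by the
#'   ipsilateral patch.
#' @param programmed_overlap Fraction of dLGN-mask pixels that carry
#'   supra-threshold signal in \emph{both} channels in the noise-free limit;
#'   must not exceed `ipsi_area_fraction`.
#' @param mixing Fraction of dLGN pixels (in `[0, 1]`) whose two channels
#'   are replaced by their mean, emulating unsegregated binocular input
#'   (R near 0) at those pixels. For a fixed seed the mixed pixel sets are
#'   nested across mixing levels, so programmed series are monotone by
#'   construction.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param background_margin Width in pixels of the guaranteed no-innervation
#'   margin from which the background region is drawn.
#' @param seed Integer seed.
#' @return An `image_sim_params` list.
#' @seealso [simulate_dlgn_sections()]
#' @export
image_sim_params <- function(height = 160L, width = 200L, um_per_pixel = 5,
                             n_sections = 15L, ipsi_area_fraction = 0.15,
                             programmed_overlap = 0.05, mixing = 0,
                             noise_sd = 2, background_margin = 12L,
                             seed = 1L) {
  p <- list(
    height = as.integer(height), width = as.integer(width),
    um_per_pixel = um_per_pixel, n_sections = as.integer(n_sections),
    ipsi_area_fraction = ipsi_area_fraction,
    programmed_overlap = programmed_overlap, mixing = mixing,
    noise_sd = noise_sd, background_margin = as.integer(background_margin),
    seed = as.integer(seed)
  )
  if (p$ipsi_area_fraction < 0 || p$ipsi_area_fraction > 1)
    stop("ipsi_area_fraction must be in [0, 1]")
  if (p$programmed_overlap < 0 || p$programmed_overlap > p$ipsi_area_fraction)
    stop("programmed_overlap must be in [0, ipsi_area_fraction]")
  if (p$mixing < 0 || p$mixing > 1) stop("mixing must be in [0, 1]")
  if (p$n_sections < 1L) stop("n_sections must be >= 1")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$height < 4L * p$background_margin || p$width < 4L * p$background_margin)
    stop("image too small for the requested background_margin")
  class(p) <- "image_sim_params"
  p
}

#' Burst filtering configuration
#'
#' Thresholds applied after surprise-based burst detection: a minimum
#' surprise of 4 (Poisson tail probability below 1e-4), exclusion of bursts
#' shorter than 0.75 s or longer than 15 s, and exclusion of bursts starting
#' or ending within half the maximum burst duration (7.5 s) of a recording
#' edge, so that bursts interrupted by starting or stopping the recording
#' are never analysed.
#'
#' @param min_duration,max_duration Burst duration bounds, s.
#' @param edge_margin Exclusion margin at each recording edge, s; defaults
#'   to half of `max_duration`.
#' @param min_surprise Minimum Poisson surprise (-log10 tail probability).
#' @return A `burst_filter_config` list.
#' @export
burst_filter_config <- function(min_duration = 0.75, max_duration = 15,
                                edge_margin = max_duration / 2,
                                min_surprise = 4) {
  if (min_duration <= 0 || min_duration >= max_duration)
    stop("need 0 < min_duration < max_duration")
  if (edge_margin < 0) stop("edge_margin must be >= 0")
  if (min_surprise < 0) stop("min_surprise must be >= 0")
  structure(list(min_duration = min_duration, max_duration = max_duration,
                 edge_margin = edge_margin, min_surprise = min_surprise),
            class = "burst_filter_config")
}

#' Wave-association configuration
#'
#' @param n_bins Number of equal-duration bins each burst is divided into.
#' @param min_neighbor_channels Minimum count of distinct neighbouring
#'   channels with an associated burst for WAB status.
#' @return An `association_config` list.
#' @export
association_config <- function(n_bins = 10L, min_neighbor_channels = 2L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (min_neighbor_channels < 1L) stop("min_neighbor_channels must be >= 1")
  structure(list(n_bins = as.integer(n_bins),
                 min_neighbor_channels = as.integer(min_neighbor_channels)),
            class = "association_config")
}

#' STTC configuration
#'
#' @param tau Correlation time window, s (the +/- tiling half-width).
#' @param max_distance_for_stats Largest interelectrode distance, um,
#'   entering group statistics.
#' @param include_same_channel Include distance-0 (same-electrode) pairs in
#'   the distance curve.
#' @return An `sttc_config` list.
#' @export
sttc_config <- function(tau = 0.05, max_distance_for_stats = 800,
                        include_same_channel = TRUE) {
  if (tau <= 0) stop("tau must be > 0")
  structure(list(tau = tau, max_distance_for_stats = max_distance_for_stats,
                 include_same_channel = isTRUE(include_same_channel)),
            class = "sttc_config")
}
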