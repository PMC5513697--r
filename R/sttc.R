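#' Spike time tiling coefficient of two trains
#'
#' The STTC quantifies pairwise spike-train correlation in a way that is
#' insensitive to firing rate. With `T_X` the fraction of the recording
#' tiled by +/- `tau` windows around train X's spikes (windows clipped to
#' the recording and merged where they overlap) and `P_X` the proportion
#' of X's spikes falling within `tau` of any spike of the other train,
#' \deqn{STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
#'   \frac{P_B - T_A}{1 - P_B T_A}\right).}
#'
#' @param a,b Sorted spike timestamp vectors, s, within `[0, duration]`.
#' @param tau Correlation window half-width, s (default 50 ms).
#' @param duration Recording length, s.
#' @return STTC in `[-1, 1]`, symmetric in the two trains; `NA` when
#'   either train is empty or a denominator vanishes (such pairs are
#'   excluded from distance curves rather than set to 0).
#' @references Cutts & Eglen style tiling coefficient.
#' @export
sttc <- function(a, b, tau = 0.05, duration) {
  if (tau <= 0 || tau >= duration) stop("need 0 < tau < duration")
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  ta <- tiled_fraction(a, tau, duration)
  tb <- tiled_fraction(b, tau, duration)
  pa <- prop_within(a, b, tau)
  pb <- prop_within(b, a, tau)
  d1 <- 1 - pa * tb
  d2 <- 1 - pb * ta
  if (d1 == 0 || d2 == 0) return(NA_real_)
  ((pa - tb) / d1 + (pb - ta) / d2) / 2
}

# fraction of [0, duration] covered by the union of clipped +/- tau windows
tiled_fraction <- function(times, tau, duration) {
  s <- pmax(times - tau, 0)
  e <- pmin(times + tau, duration)
  prev_end <- c(-Inf, e[-length(e)])  # e is nondecreasing for sorted times
  sum(pmax(0, e - pmax(s, prev_end))) / duration
}

# proportion of a's spikes lying within tau of some spike of b (b sorted)
prop_within <- function(a, b, tau) {
  idx <- findInterval(a, b)
  nb <- length(b)
  lo <- ifelse(idx >= 1L, b[pmax(idx, 1L)], -Inf)
  hi <- ifelse(idx < nb, b[pmin(idx + 1L, nb)], Inf)
  mean((a - lo) <= tau | (hi - a) <= tau)
}

#' STTC versus interelectrode distance
#'
#' Computes the STTC for every unordered pair of the given units, assigns
#' each pair the Euclidean distance between its electrodes (`pitch` times
#' the grid offset), groups pairs by exact distance (the grid guarantees a
#' discrete set) and reports the median STTC per distance.
#'
#' Pairs with an undefined STTC (empty train or degenerate denominator)
#' are dropped from the medians and counted in `n_dropped`. Same-channel
#' (distance 0) pairs are included by default; set
#' `cfg$include_same_channel = FALSE` to exclude them.
#'
#' @param rec An [mea_recording()].
#' @param units Unit ids to correlate (normally [valid_units()]); at least
#'   two.
#' @param cfg An [sttc_config()].
#' @return A list: `pairs` (data frame `unit_a`, `unit_b`, `distance_um`,
#'   `sttc`), `curve` (data frame `distance_um`, `median_sttc`,
#'   `n_pairs`, ascending in distance), and `n_dropped`.
#' @export
sttc_curve <- function(rec, units = rec$units$unit_id, cfg = sttc_config()) {
  units <- intersect(units, rec$units$unit_id)
  if (length(units) < 2L)
    return(list(pairs = data.frame(unit_a = character(0), unit_b = character(0),
                                   distance_um = numeric(0), sttc = numeric(0)),
                curve = data.frame(distance_um = numeric(0),
                                   median_sttc = numeric(0),
                                   n_pairs = integer(0)),
                n_dropped = 0L))
  k <- match(units, rec$units$unit_id)
  rows <- rec$units$row[k]; cols <- rec$units$col[k]
  cmb <- utils::combn(length(units), 2L)
  i <- cmb[1, ]; j <- cmb[2, ]
  dist_um <- rec$pitch * sqrt((rows[i] - rows[j])^2 + (cols[i] - cols[j])^2)
  keep <- if (cfg$include_same_channel) rep(TRUE, length(dist_um)) else dist_um > 0
  i <- i[keep]; j <- j[keep]; dist_um <- dist_um[keep]
  vals <- vapply(seq_along(i), function(m)
    sttc(rec$spikes[[units[i[m]]]], rec$spikes[[units[j[m]]]],
         cfg$tau, rec$duration), numeric(1))
  pairs <- data.frame(unit_a = units[i], unit_b = units[j],
                      distance_um = dist_um, sttc = vals)
  ok <- !is.na(vals)
  grp <- split(vals[ok], signif(dist_um[ok], 10))
  curve <- data.frame(
    distance_um = as.numeric(names(grp)),
    median_sttc = vapply(grp, median, numeric(1)),
    n_pairs = vapply(grp, length, integer(1))
  )
  curve <- curve[order(curve$distance_um), , drop = FALSE]
  rownames(curve) <- NULL
  list(pairs = pairs, curve = curve, n_dropped = sum(!ok))
}

#' Distinct interelectrode distances of a rectangular grid
#'
#' Enumerates the achievable pair distances on a `grid_rows` x `grid_cols`
#' electrode grid with the given pitch, optionally capped. Distance 0
#' (same-channel pairs) is included when `include_zero` is `TRUE`.
#'
#' @param grid_rows,grid_cols Grid dimensions.
#' @param pitch Interelectrode spacing, um.
#' @param max_distance Cap, um (default `Inf`).
#' @param include_zero Include the same-channel distance 0.
#' @return Sorted numeric vector of distinct distances in um.
#' @export
interelectrode_distances <- function(grid_rows = 8L, grid_cols = 8L,
                                     pitch = 200, max_distance = Inf,
                                     include_zero = TRUE) {
  off <- expand.grid(dr = 0:(grid_rows - 1L), dc = 0:(grid_cols - 1L))
  d <- pitch * sqrt(off$dr^2 + off$dc^2)
  if (!include_zero) d <- d[d > 0]
  d <- sort(unique(signif(d, 10)))
  d[d <= max_distance]
}
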