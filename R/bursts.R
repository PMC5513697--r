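#' Poisson surprise of a spike run
#'
#' The surprise of observing `n_spikes` or more events in `interval`
#' seconds from a homogeneous Poisson process with rate `mean_rate`:
#' \deqn{S = -\log_{10} P(X \ge n), \quad X \sim Poisson(rate \cdot interval).}
#' A surprise of 4 corresponds to a tail probability of 1e-4, the detection
#' threshold used throughout this package. Base 10 is fixed by that
#' correspondence.
#'
#' @param n_spikes Spike count(s), >= 0 (vectorised).
#' @param interval Run duration(s), s, > 0.
#' @param mean_rate Unit mean firing rate, Hz, > 0.
#' @return Surprise value(s), >= 0; 0 when `n_spikes == 0`.
#' @examples
#' poisson_surprise(10, 1, 1)   # Poisson(1) upper tail at 10
#' surprise_from_p(1e-4)        # the threshold identity: 4
#' @export
poisson_surprise <- function(n_spikes, interval, mean_rate) {
  if (any(mean_rate <= 0)) stop("mean_rate must be > 0")
  if (any(interval <= 0)) stop("interval must be > 0")
  if (any(n_spikes < 0)) stop("n_spikes must be >= 0")
  lambda <- mean_rate * interval
  # P(X >= n) on the log scale; n = 0 gives log P = 0 exactly
  logp <- ppois(n_spikes - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  s <- -logp / log(10)
  pmax(s, 0)
}

#' Convert a tail probability to a surprise value
#'
#' @param p Poisson tail probability in (0, 1].
#' @return `-log10(p)`.
#' @rdname poisson_surprise
#' @export
surprise_from_p <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  -log10(p)
}

empty_bursts <- function() {
  df <- data.frame(start = numeric(0), end = numeric(0),
                   n_spikes = integer(0), surprise = numeric(0))
  df$spike_times <- list()
  df
}

#' Detect bursts in one spike train by the Poisson-surprise method
#'
#' A Legendy-Salcman style search: candidate runs are seeded wherever
#' consecutive inter-spike intervals fall below half the unit's mean ISI,
#' extended forward and then backward one spike at a time while the
#' surprise increases, and emitted if the final surprise reaches
#' `cfg$min_surprise`. Overlapping candidates are merged, keeping the
#' higher-surprise extent. Burst start and end are the first and last spike
#' times of the run (closed interval, no padding).
#'
#' @param times Sorted spike timestamps, s.
#' @param cfg A [burst_filter_config()]; only `min_surprise` is used here.
#' @param mean_rate The unit's mean firing rate over the whole recording,
#'   Hz (spike count / recording duration, computed on the artifact-cleaned
#'   train).
#' @return Data frame with one row per burst: `start`, `end`, `n_spikes`,
#'   `surprise`, and a list column `spike_times` holding each burst's
#'   constituent timestamps. Empty (zero rows) for trains with fewer than
#'   two spikes.
#' @export
detect_bursts <- function(times, cfg = burst_filter_config(), mean_rate) {
  n <- length(times)
  if (n < 2L) return(empty_bursts())
  if (mean_rate <= 0) stop("mean_rate must be > 0")

  surp <- function(i, j) {
    poisson_surprise(j - i + 1L, max(times[j] - times[i], 1e-9), mean_rate)
  }

  mean_isi <- 1 / mean_rate
  short <- diff(times) < mean_isi / 2
  if (!any(short)) return(empty_bursts())

  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seed_i <- starts[r$values]        # run of k short ISIs = spikes i..i+k
  seed_j <- ends[r$values] + 1L

  cand <- vector("list", length(seed_i))
  for (k in seq_along(seed_i)) {
    i <- seed_i[k]; j <- seed_j[k]
    s <- surp(i, j)
    while (j < n && surp(i, j + 1L) > s) { j <- j + 1L; s <- surp(i, j) }
    while (i > 1L && surp(i - 1L, j) > s) { i <- i - 1L; s <- surp(i, j) }
    cand[[k]] <- c(i = i, j = j, s = s)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand[, "s"] >= cfg$min_surprise, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_bursts())
  cand <- cand[order(cand[, "i"], cand[, "j"]), , drop = FALSE]

  # merge overlapping extents, keeping the higher surprise
  merged <- list(cand[1, ])
  if (nrow(cand) > 1L) {
    for (k in 2:nrow(cand)) {
      cur <- merged[[length(merged)]]
      nxt <- cand[k, ]
      if (nxt["i"] <= cur["j"]) {
        if (nxt["s"] > cur["s"]) merged[[length(merged)]] <- nxt
      } else {
        merged[[length(merged) + 1L]] <- nxt
      }
    }
  }
  m <- do.call(rbind, merged)
  out <- data.frame(
    start = times[m[, "i"]], end = times[m[, "j"]],
    n_spikes = as.integer(m[, "j"] - m[, "i"] + 1L),
    surprise = m[, "s"]
  )
  out$spike_times <- lapply(seq_len(nrow(m)),
                            function(k) times[m[k, "i"]:m[k, "j"]])
  out
}

#' Detect bursts for every valid unit of a recording
#'
#' @param rec An [mea_recording()], normally after [reject_artifacts()].
#' @param cfg A [burst_filter_config()].
#' @param units Unit ids to analyse; defaults to all units. Pass
#'   [valid_units()] output to honour the validity criteria.
#' @return Data frame of bursts across units with columns `unit_id`, `row`,
#'   `col` prepended to the per-train columns of [detect_bursts()].
#' @export
detect_bursts_recording <- function(rec, cfg = burst_filter_config(),
                                    units = rec$units$unit_id) {
  out <- list()
  for (id in units) {
    ts <- rec$spikes[[id]]
    if (length(ts) < 2L) next
    b <- detect_bursts(ts, cfg, mean_rate = length(ts) / rec$duration)
    if (nrow(b) == 0L) next
    k <- match(id, rec$units$unit_id)
    b <- cbind(data.frame(unit_id = id, row = rec$units$row[k],
                          col = rec$units$col[k]), b)
    out[[length(out) + 1L]] <- b
  }
  if (!length(out)) {
    df <- cbind(data.frame(unit_id = character(0), row = integer(0),
                           col = integer(0)), empty_bursts())
    return(df)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply burst duration and recording-edge exclusions
#'
#' Bursts shorter than `cfg$min_duration` or longer than
#' `cfg$max_duration`, and bursts starting within `cfg$edge_margin` of the
#' recording start or ending within `cfg$edge_margin` of its end, are
#' excluded from burst-level analysis. Their constituent spikes are
#' returned in a pool so they still count toward firing-rate numerators and
#' denominators.
#'
#' @param bursts Burst table from [detect_bursts_recording()] (or
#'   [detect_bursts()] output for a single unit).
#' @param cfg A [burst_filter_config()].
#' @param rec_duration Recording length, s; must exceed twice the edge
#'   margin or there is no analysable interior.
#' @return A list: `kept` (burst rows passing all rules, with an
#'   `exclusion_reason` of `NA`), `excluded` (the excluded rows with their
#'   reason: `"too_short"`, `"too_long"`, or `"edge"`), and `pool` (data
#'   frame `unit_id`, `time_s` of the excluded bursts' spikes).
#' @export
filter_bursts <- function(bursts, cfg = burst_filter_config(), rec_duration) {
  if (rec_duration <= 2 * cfg$edge_margin)
    stop("rec_duration must exceed twice the edge margin")
  if (is.null(bursts$unit_id)) bursts$unit_id <- rep("unit", nrow(bursts))
  dur <- bursts$end - bursts$start
  reason <- rep(NA_character_, nrow(bursts))
  reason[dur > cfg$max_duration] <- "too_long"
  reason[dur < cfg$min_duration] <- "too_short"
  edge <- is.na(reason) & (bursts$start < cfg$edge_margin |
                             bursts$end > rec_duration - cfg$edge_margin)
  reason[edge] <- "edge"
  keep <- is.na(reason)
  kept <- bursts[keep, , drop = FALSE]
  kept$exclusion_reason <- rep(NA_character_, nrow(kept))
  excluded <- bursts[!keep, , drop = FALSE]
  excluded$exclusion_reason <- reason[!keep]
  pool <- data.frame(
    unit_id = rep(excluded$unit_id,
                  vapply(excluded$spike_times, length, integer(1))),
    time_s = unlist(excluded$spike_times, use.names = FALSE)
  )
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded, pool = pool)
}
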