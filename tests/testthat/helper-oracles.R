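# Brute-force reference implementations used as independent oracles.
# Each is written as a literal transcription of the rule it checks and is
# deliberately quadratic/naive.

# greedy sliding-window artifact count over a merged, time-sorted list
oracle_artifact_count <- function(times, chans, window, frac, n_active) {
  o <- order(times)
  times <- times[o]; chans <- chans[o]
  removed <- logical(length(times))
  i <- 1L
  while (i <= length(times)) {
    grp <- which(times >= times[i] & times <= times[i] + window)
    grp <- grp[grp >= i]
    if (length(grp) > 1L && length(unique(chans[grp])) >= frac * n_active) {
      removed[grp] <- TRUE
      i <- max(grp) + 1L
    } else {
      i <- i + 1L
    }
  }
  sum(removed)
}

# Poisson upper tail by direct pmf summation
oracle_tail_surprise <- function(n, lambda, kmax = 5000L) {
  -log10(sum(dpois(n:(n + kmax), lambda)))
}

# is there any contiguous spike run (up to max_len spikes) with surprise >= s?
oracle_any_burst <- function(times, rate, max_len = 30L, min_s = 4) {
  n <- length(times)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):min(n, i + max_len - 1L)) {
      lam <- rate * max(times[j] - times[i], 1e-9)
      s <- -log10(sum(dpois((j - i + 1L):(j - i + 2001L), lam)))
      if (s >= min_s) return(TRUE)
    }
  }
  FALSE
}

# STTC via explicit union of tiled intervals and spike membership
oracle_sttc <- function(a, b, tau, dur) {
  union_len <- function(ts) {
    iv <- cbind(pmax(ts - tau, 0), pmin(ts + tau, dur))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    tot <- 0; cs <- iv[1, 1]; ce <- iv[1, 2]
    for (k in seq_len(nrow(iv))[-1]) {
      if (iv[k, 1] > ce) {
        tot <- tot + (ce - cs); cs <- iv[k, 1]; ce <- iv[k, 2]
      } else ce <- max(ce, iv[k, 2])
    }
    tot + (ce - cs)
  }
  TA <- union_len(a) / dur
  TB <- union_len(b) / dur
  PA <- mean(vapply(a, function(x) any(abs(x - b) <= tau), logical(1)))
  PB <- mean(vapply(b, function(x) any(abs(x - a) <= tau), logical(1)))
  0.5 * ((PA - TB) / (1 - PA * TB) + (PB - TA) / (1 - PB * TA))
}

# association decision over all n_bins x n_bins bin-start pairs
oracle_associated <- function(a_start, a_end, b_start, b_end, n_bins = 10L) {
  da <- (a_end - a_start) / n_bins
  db <- (b_end - b_start) / n_bins
  dt <- (da + db) / 2
  for (i in 0:(n_bins - 1L)) for (j in 0:(n_bins - 1L)) {
    if (abs((a_start + i * da) - (b_start + j * db)) <= dt) return(TRUE)
  }
  FALSE
}

# WAB status by complete double loop over bursts
oracle_classify <- function(b, min_nb = 2L, n_bins = 10L) {
  vapply(seq_len(nrow(b)), function(k) {
    supp <- character(0)
    for (j in seq_len(nrow(b))) {
      if (j == k) next
      if (b$unit_id[j] == b$unit_id[k]) next
      if (b$row[j] == b$row[k] && b$col[j] == b$col[k]) next
      if (max(abs(b$row[j] - b$row[k]), abs(b$col[j] - b$col[k])) != 1L) next
      if (oracle_associated(b$start[k], b$end[k], b$start[j], b$end[j], n_bins))
        supp <- union(supp, paste(b$row[j], b$col[j]))
    }
    length(supp) >= min_nb
  }, logical(1))
}

# Welch statistic, df and two-tailed p by direct formula evaluation
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# literal Holm step-down decisions
oracle_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) rej[o[i]] <- TRUE else break
  }
  rej
}
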