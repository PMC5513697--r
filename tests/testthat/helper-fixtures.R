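# Small fixtures built in code.

# recording with one unit per listed channel and given spike vectors
make_rec <- function(spikes, rows, cols, grid = 8L, pitch = 200,
                     duration = 600, ground = NULL) {
  ids <- sprintf("u%02d", seq_along(spikes))
  mea_recording(data.frame(unit_id = ids, row = rows, col = cols),
                setNames(spikes, ids), grid, grid, pitch, duration,
                ground_channel = ground)
}

# a full 8x8 recording of independent Poisson trains
poisson_rec <- function(rate = 0.1, duration = 600, seed = 1) {
  set.seed(seed)
  ch <- expand.grid(row = 1:8, col = 1:8)
  spikes <- lapply(seq_len(64), function(i)
    sort(runif(rpois(1, rate * duration), 0, duration)))
  make_rec(spikes, ch$row, ch$col, duration = duration)
}

# burst table row in the layout classify_wabs() expects
burst_row <- function(unit_id, row, col, start, end) {
  data.frame(unit_id = unit_id, row = row, col = col, start = start,
             end = end, n_spikes = 10L, surprise = 10)
}

# label kept bursts of a simulation as wave or background via ground truth:
# a kept burst is wave-born if a true burst of the same unit covers more
# than half of it
label_by_truth <- function(kept, truth_bursts) {
  vapply(seq_len(nrow(kept)), function(i) {
    w <- truth_bursts[truth_bursts$unit_id == kept$unit_id[i], , drop = FALSE]
    if (!nrow(w)) return(FALSE)
    any(pmin(w$end, kept$end[i]) - pmax(w$start, kept$start[i]) >
          0.5 * (kept$end[i] - kept$start[i]))
  }, logical(1))
}

# per-retina spiking properties for a fresh simulation
retina_properties <- function(params) {
  analyze_waves(simulate_mea(params)$recording)$properties$per_retina
}
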