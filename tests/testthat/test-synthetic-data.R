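test_that("simulator with no spike sources produces an empty recording", {
  sim <- simulate_mea(wave_sim_params(wave_rate = 0, background_rate = 0,
                                      seed = 3))
  expect_equal(total_spikes(sim$recording), 0L)
  expect_equal(nrow(sim$truth$bursts), 0L)
  expect_equal(nrow(sim$truth$waves), 0L)
})

test_that("background-only spike counts are Poisson-calibrated", {
  sim <- simulate_mea(wave_sim_params(wave_rate = 0, background_rate = 0.1,
                                      duration = 600, seed = 11))
  # total over 64 units: Poisson(3840), check within 4 SD
  n <- total_spikes(sim$recording)
  expect_lt(abs(n - 3840), 4 * sqrt(3840))

  # chi-square goodness of fit of per-unit counts against Poisson(60)
  counts <- vapply(sim$recording$spikes, length, integer(1))
  breaks <- c(-Inf, 50, 56, 60, 64, 70, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-Inf, 50, 56, 60, 64, 70, Inf), 60))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("identical seed reproduces the recording bit for bit", {
  p <- wave_sim_params(duration = 120, seed = 99)
  s1 <- simulate_mea(p)
  s2 <- simulate_mea(p)
  expect_identical(s1, s2)
  s3 <- simulate_mea(wave_sim_params(duration = 120, seed = 100))
  expect_false(identical(s1$recording$spikes, s3$recording$spikes))
})

test_that("ground-truth burst intervals contain their spikes and >= 2 of them", {
  sim <- simulate_mea(wave_sim_params(seed = 21))
  tb <- sim$truth$bursts
  expect_gt(nrow(tb), 0)
  expect_true(all(tb$start >= 0 & tb$end <= 600))
  expect_true(all(tb$n_spikes >= 2L))
  for (i in seq_len(nrow(tb))) {
    ts <- sim$recording$spikes[[tb$unit_id[i]]]
    inside <- sum(ts >= tb$start[i] & ts <= tb$end[i])
    expect_gte(inside, tb$n_spikes[i])
  }
  # wave ids are consistent: every referenced wave exists
  expect_true(all(tb$wave_id %in% sim$truth$waves$wave_id))
})

test_that("condition scalers produce a scaled parameter set", {
  p <- wave_sim_params(condition_scalers = list(burst_duration = 1.5,
                                                background_rate = 2))
  pb <- apply_condition(p)
  expect_equal(pb$burst_duration, 3)
  expect_equal(pb$background_rate, 0.2)
  expect_equal(pb$burst_rate, p$burst_rate)
  expect_error(apply_condition(p, list(nonsense = 2)), "unknown")
})

test_that("simulator rejects invalid parameters", {
  expect_error(wave_sim_params(duration = 0), "duration")
  expect_error(wave_sim_params(wave_speed = -1), "wave_speed")
  expect_error(wave_sim_params(grid_rows = 1), "grid")
  expect_error(image_sim_params(programmed_overlap = 0.3,
                                ipsi_area_fraction = 0.2), "programmed_overlap")
})

test_that("dLGN simulator rasterises the programmed fractions exactly", {
  p <- image_sim_params(n_sections = 2, noise_sd = 0,
                        ipsi_area_fraction = 0.2, programmed_overlap = 0.1,
                        seed = 5)
  sim <- simulate_dlgn_sections(p)
  expect_length(sim$sections, 2)
  for (s in seq_along(sim$sections)) {
    sec <- sim$sections[[s]]
    expect_false(any(sec$dlgn_mask & sec$background_mask))
    # realised fractions recorded in truth match pixel counts in the images
    th_c <- max(sec$contra[sec$background_mask])
    th_i <- max(sec$ipsi[sec$background_mask])
    both <- sum((sec$contra > th_c & sec$ipsi > th_i)[sec$dlgn_mask])
    expect_equal(both / sum(sec$dlgn_mask), sim$truth$overlap_fraction[s])
  }
  expect_true(all(abs(sim$truth$ipsi_fraction - 0.2) < 0.001))
})

test_that("edge cases of programmed overlap behave as constructed", {
  # no overlap: no pixel is on in both channels
  s0 <- simulate_dlgn_sections(image_sim_params(
    n_sections = 1, noise_sd = 0, programmed_overlap = 0, seed = 2))
  sec <- s0$sections[[1]]
  th_c <- max(sec$contra[sec$background_mask])
  th_i <- max(sec$ipsi[sec$background_mask])
  expect_equal(sum((sec$contra > th_c & sec$ipsi > th_i)[sec$dlgn_mask]), 0)

  # full containment: overlap count equals ipsi count
  s1 <- simulate_dlgn_sections(image_sim_params(
    n_sections = 1, noise_sd = 0, ipsi_area_fraction = 0.15,
    programmed_overlap = 0.15, seed = 2))
  sec <- s1$sections[[1]]
  th_c <- max(sec$contra[sec$background_mask])
  th_i <- max(sec$ipsi[sec$background_mask])
  on_i <- sec$ipsi[sec$dlgn_mask] > th_i
  on_c <- sec$contra[sec$dlgn_mask] > th_c
  expect_equal(sum(on_i & on_c), sum(on_i))
})

test_that("SC simulator realises trivial and ramp profiles", {
  full <- simulate_sc_sections(sc_sim_params(profile = function(u) 100))
  expect_true(all(full$truth$density_pct == 100))
  half <- simulate_sc_sections(sc_sim_params(
    profile = function(u) ifelse(u < 0.5, 100, 0)))
  lat <- half$truth[half$truth$position_um >
                      max(half$truth$position_um) / 2, ]
  expect_true(all(lat$density_pct == 0))
  ramp <- simulate_sc_sections(sc_sim_params())
  u <- ramp$truth$position_um / max(ramp$truth$position_um + 2)
  expect_lt(max(abs(ramp$truth$density_pct - 100 * u)), 2)
})
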