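test_that("bin starts divide a burst into ten equal bins", {
  expect_equal(burst_bin_starts(0, 10), 0:9)
  expect_equal(burst_bin_starts(2, 3), seq(2.0, 2.9, by = 0.1))
  b <- burst_bin_starts(13.7, 29.2)
  d <- (29.2 - 13.7) / 10
  expect_equal(max(b) + d, 29.2, tolerance = 1e-9)
  expect_error(burst_bin_starts(5, 5), "duration")
})

test_that("association follows the bin-start rule and its exclusions", {
  a <- list(unit_id = "a", row = 1, col = 1, start = 10, end = 11)
  # identical co-timed burst on a neighbouring channel: distance 0 <= dt
  b <- list(unit_id = "b", row = 1, col = 2, start = 10, end = 11)
  expect_true(bursts_associated(a, b))
  # nearest bin starts 0.15 apart with dt = 0.1: not associated
  b2 <- list(unit_id = "b", row = 1, col = 2, start = 11.05, end = 12.05)
  expect_false(bursts_associated(a, b2))
  # same unit or same channel can never associate
  expect_false(bursts_associated(a, list(unit_id = "a", row = 1, col = 2,
                                         start = 10, end = 11)))
  expect_false(bursts_associated(a, list(unit_id = "c", row = 1, col = 1,
                                         start = 10, end = 11)))
})

test_that("association equals the exhaustive bin-pair oracle and is symmetric", {
  set.seed(7)
  for (k in 1:1000) {
    s1 <- runif(1, 0, 100); d1 <- runif(1, 0.75, 15)
    s2 <- s1 + runif(1, -20, 20); d2 <- runif(1, 0.75, 15)
    a <- list(unit_id = "a", row = 2, col = 2, start = s1, end = s1 + d1)
    b <- list(unit_id = "b", row = 2, col = 3, start = s2, end = s2 + d2)
    got <- bursts_associated(a, b)
    expect_identical(got, oracle_associated(s1, s1 + d1, s2, s2 + d2))
    expect_identical(got, bursts_associated(b, a))
  }
})

test_that("a synchronous 3x3 block makes the centre burst a WAB", {
  grid <- expand.grid(row = 3:5, col = 3:5)
  b <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    burst_row(sprintf("u%d", i), grid$row[i], grid$col[i], 50, 52)))
  out <- classify_wabs(b, 8, 8)
  centre <- which(b$row == 4 & b$col == 4)
  expect_true(out$is_wab[centre])
  expect_equal(out$n_supporting[centre], 8L)
  expect_true(all(out$is_wab))  # corners of the block still have >= 2 neighbours
})

test_that("bursts supported only by their own channel are not WABs", {
  b <- rbind(burst_row("u1", 4, 4, 50, 52),
             burst_row("u2", 4, 4, 50, 52),
             burst_row("u3", 4, 4, 50, 52))
  out <- classify_wabs(b, 8, 8)
  expect_false(any(out$is_wab))
})

test_that("one neighbouring channel counts once regardless of its unit count", {
  b <- rbind(burst_row("u1", 4, 4, 50, 52),
             burst_row("u2", 4, 5, 50, 52),
             burst_row("u3", 4, 5, 50, 52))  # two units, one neighbour channel
  out <- classify_wabs(b, 8, 8)
  expect_equal(out$n_supporting[1], 1L)
  expect_false(out$is_wab[1])
})

test_that("classification equals the brute-force oracle on random tables", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 50L
    b <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- runif(1, 10, 500)
      burst_row(sprintf("u%02d", i), sample(8, 1), sample(8, 1),
                s, s + runif(1, 0.75, 10))
    }))
    out <- classify_wabs(b, 8, 8)
    expect_identical(out$is_wab, oracle_classify(b))
  }
})

test_that("WAB status survives relabeling, translation, and far-channel removal", {
  set.seed(13)
  b <- do.call(rbind, lapply(1:30, function(i) {
    s <- runif(1, 10, 200)
    burst_row(sprintf("u%02d", i), sample(8, 1), sample(8, 1),
              s, s + runif(1, 1, 6))
  }))
  ref <- classify_wabs(b, 8, 8)

  shuffled <- b[sample(nrow(b)), ]
  out_s <- classify_wabs(shuffled, 8, 8)
  expect_equal(out_s$is_wab[order(shuffled$unit_id)],
               ref$is_wab[order(b$unit_id)])

  shifted <- b; shifted$start <- b$start + 37; shifted$end <- b$end + 37
  expect_equal(classify_wabs(shifted, 8, 8)$is_wab, ref$is_wab)

  # removing every burst not adjacent to channel (4,4) cannot change the
  # status of bursts on (4,4)
  keep <- pmax(abs(b$row - 4), abs(b$col - 4)) <= 1
  if (any(b$row == 4 & b$col == 4)) {
    sub <- classify_wabs(b[keep, ], 8, 8)
    at44 <- function(df, flags) flags[df$row == 4 & df$col == 4]
    expect_equal(at44(b[keep, ], sub$is_wab), at44(b, ref$is_wab))
  }
})

test_that("spiking properties compute the documented arithmetic", {
  rec <- make_rec(list(sort(c(seq(100, 102, length.out = 20),
                              seq(200, 202, length.out = 20), 300, 400))),
                  rows = 4, cols = 4)
  lb <- rbind(burst_row("u01", 4, 4, 100, 102),
              burst_row("u01", 4, 4, 200, 202))
  lb$n_spikes <- c(20L, 20L)
  lb$is_wab <- TRUE
  pr <- compute_properties(rec, lb)
  u <- pr$per_unit
  expect_equal(u$spikes_per_wab, 20)
  expect_equal(u$in_wab_rate_hz, 10)
  expect_equal(u$inter_wab_interval_s, 98)  # end of first to start of second
  expect_equal(u$n_wabs, 2L)
  expect_equal(u$total_spikes, 42L)
  expect_equal(u$spikes_outside_wabs, 2L)
  expect_equal(u$frac_spikes_in_wabs, 40 / 42)
  expect_equal(pr$per_retina[["mean_wab_duration_s"]], 2)
})

test_that("units without WABs enter count properties but not WAB-conditional ones", {
  rec <- make_rec(list(sort(runif(60, 0, 600)),
                       sort(c(seq(100, 102, length.out = 20)))),
                  rows = c(4, 5), cols = c(4, 4))
  lb <- burst_row("u02", 5, 4, 100, 102)
  lb$n_spikes <- 20L
  lb$is_wab <- TRUE
  pr <- compute_properties(rec, lb)
  expect_equal(pr$per_retina[["n_wabs"]], 0.5)          # mean over both units
  expect_equal(pr$per_retina[["spikes_per_wab"]], 20)   # only the WAB-bearing unit
  expect_true(is.na(pr$per_unit$mean_wab_duration_s[1]))
})

test_that("a waveless recording flows through the whole pipeline", {
  # no waves: only sparse background spiking, every unit below the validity
  # threshold and any chance burst excluded by the duration rules
  sim <- simulate_mea(wave_sim_params(wave_rate = 0, seed = 4))
  res <- analyze_waves(sim$recording)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(sum(res$kept$is_wab), 0L)
  expect_true(all(is.na(res$properties$per_retina)))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_bursts_csv(res$kept, res$excluded, f)
  expect_true(file.exists(f))
})

test_that("wave-born bursts are classified WAB with high recall and precision", {
  sim <- simulate_mea(wave_sim_params(seed = 31))
  expect_gte(nrow(sim$truth$waves), 10)
  res <- analyze_waves(sim$recording)
  truthy <- label_by_truth(res$kept, sim$truth$bursts)
  expect_gte(mean(res$kept$is_wab[truthy]), 0.9)   # recall
  expect_gte(mean(truthy[res$kept$is_wab]), 0.9)   # precision
})
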