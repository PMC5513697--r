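test_that("the background threshold is the maximum background intensity", {
  img <- matrix(12, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:3, 1:3] <- TRUE
  expect_equal(background_threshold(img, mask), 12)
  img[2, 2] <- 200
  expect_equal(background_threshold(img, mask), 200)  # max, not a percentile
  expect_error(background_threshold(img, matrix(FALSE, 10, 10)), "empty")
})

make_pair <- function(contra, ipsi, roi, bg) {
  section_image_pair(contra, ipsi, roi, bg, um_per_pixel = 5)
}

test_that("overlap percentages follow the binarise-and-count definition", {
  H <- 20; W <- 20
  bg <- matrix(FALSE, H, W); bg[1:2, ] <- TRUE
  roi <- matrix(FALSE, H, W); roi[6:15, 6:15] <- TRUE  # 100 px
  contra <- matrix(10, H, W); ipsi <- matrix(10, H, W)
  contra[6:15, 6:10] <- 1000   # left half of ROI
  ipsi[6:15, 11:15] <- 1000    # right half, disjoint
  o <- overlap_fractions(make_pair(contra, ipsi, roi, bg))
  expect_equal(o$percent_overlap, 0)
  expect_equal(o$percent_ipsi, 50)
  expect_equal(o$percent_contra, 50)

  # containment: ipsi entirely inside contra
  contra2 <- matrix(10, H, W); contra2[roi] <- 1000
  ipsi2 <- matrix(10, H, W); ipsi2[8:11, 8:11] <- 1000  # 16 px inside ROI
  o2 <- overlap_fractions(make_pair(contra2, ipsi2, roi, bg))
  expect_equal(o2$percent_overlap, o2$percent_ipsi)
  expect_equal(o2$percent_overlap, 16)
  expect_lte(o2$percent_overlap, min(o2$percent_ipsi, o2$percent_contra))
})

test_that("percentages are invariant under rescaling a channel with its background", {
  sim <- simulate_dlgn_sections(image_sim_params(n_sections = 1, seed = 9))
  sec <- sim$sections[[1]]
  o1 <- overlap_fractions(sec)
  sec2 <- sec; sec2$contra <- sec$contra * 3.7
  o2 <- overlap_fractions(sec2)
  expect_equal(o1$percent_overlap, o2$percent_overlap)
  expect_equal(o1$percent_contra, o2$percent_contra)
})

test_that("programmed overlap is recovered within one percentage point", {
  sim <- simulate_dlgn_sections(image_sim_params(
    n_sections = 3, noise_sd = 0, programmed_overlap = 0.10, seed = 14))
  for (s in 1:3) {
    o <- overlap_fractions(sim$sections[[s]])
    expect_lt(abs(o$percent_overlap - 10), 1)
  }
})

test_that("R-values are an antisymmetric log intensity ratio", {
  H <- 12; W <- 12
  bg <- matrix(FALSE, H, W); bg[1, ] <- TRUE
  roi <- matrix(FALSE, H, W); roi[5:8, 5:8] <- TRUE
  contra <- matrix(50, H, W); ipsi <- matrix(50, H, W)
  pair <- make_pair(contra, ipsi, roi, bg)
  expect_true(all(r_map(pair) == 0))       # equal channels -> R = 0
  ipsi2 <- ipsi; ipsi2[roi] <- 500
  p1 <- make_pair(contra, ipsi2, roi, bg)
  p2 <- make_pair(ipsi2, contra, roi, bg)  # channels swapped
  expect_equal(r_map(p1), -r_map(p2))
  expect_true(all(r_map(p1) > 0))          # ipsi-dominant -> positive
})

test_that("R variance equals a two-pass oracle", {
  sim <- simulate_dlgn_sections(image_sim_params(n_sections = 2, seed = 6))
  r <- lapply(sim$sections, r_map)
  rc <- lapply(sim$sections, function(p) r_map(p, p$contra_ref_mask))
  ri <- lapply(sim$sections, function(p) r_map(p, p$ipsi_ref_mask))
  st <- unsegregated_stats(r, rc, ri)
  x <- unlist(r)
  mu <- sum(x) / length(x)
  v2 <- sum((x - mu)^2) / (length(x) - 1)
  expect_equal(st$r_variance, v2, tolerance = 1e-10)
})

test_that("unsegregated fraction separates segregated from mixed stacks", {
  set.seed(77)
  ref_c <- rnorm(20000, -1, 0.1)
  ref_i <- rnorm(20000, 1, 0.1)
  # perfectly segregated: every pixel drawn from one reference population
  seg <- c(rnorm(25000, -1, 0.1), rnorm(25000, 1, 0.1))
  st_seg <- unsegregated_stats(seg, ref_c, ref_i)
  expect_lt(st_seg$unsegregated_fraction, 0.01)
  # fully mixed: all pixels near 0, references at +/- 1
  st_mix <- unsegregated_stats(rnorm(50000, 0, 0.05), ref_c, ref_i)
  expect_gt(st_mix$unsegregated_fraction, 0.99)
  expect_gt(st_seg$r_variance, st_mix$r_variance)
  # crossed cutoffs are flagged degenerate
  expect_warning(st_bad <- unsegregated_stats(seg, ref_i, ref_c), "crossed")
  expect_true(st_bad$degenerate)
  expect_equal(st_bad$unsegregated_fraction, 1)
})

test_that("mixing series: unsegregated fraction rises, R-variance falls", {
  # a balanced field (comparable ipsi and contra territories) keeps the
  # R-distribution near-symmetric, where the variance metric is monotone in
  # binocular mixing; in a strongly contra-dominant field moving contra
  # pixels toward R = 0 can widen the spread around the (negative) mean
  mix <- c(0, 0.25, 0.5, 0.75, 1)
  stack_params <- function(m) image_sim_params(
    n_sections = 3, seed = 55, ipsi_area_fraction = 0.5,
    programmed_overlap = 0.05, mixing = m)
  pure <- simulate_dlgn_sections(stack_params(0))
  ref_c <- lapply(pure$sections, function(p) r_map(p, p$contra_ref_mask))
  ref_i <- lapply(pure$sections, function(p) r_map(p, p$ipsi_ref_mask))
  frac <- var_r <- numeric(length(mix))
  for (k in seq_along(mix)) {
    sim <- simulate_dlgn_sections(stack_params(mix[k]))
    r <- lapply(sim$sections, r_map)
    st <- unsegregated_stats(r, ref_c, ref_i)
    frac[k] <- st$unsegregated_fraction
    var_r[k] <- st$r_variance
  }
  expect_true(all(diff(frac) > 0))
  expect_true(all(diff(var_r) < 0))
})

test_that("segregation_stack combines both methods over a stack", {
  sim <- simulate_dlgn_sections(image_sim_params(n_sections = 4, seed = 3,
                                                 programmed_overlap = 0.06))
  res <- segregation_stack(sim$sections)
  expect_equal(nrow(res$per_section), 4)
  expect_true(all(abs(res$per_section$percent_overlap - 6) < 1))
  expect_lt(res$r_stats$unsegregated_fraction, 0.2)
})
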