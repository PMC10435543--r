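test_that("dF/F0 is the framewise fractional change over baseline", {
  pr <- make_stim_protocol(n_positions = 2, n_repeats = 1, order = c(1, 2),
                           pre_s = 1, frame_rate = 2)
  nT <- pr$n_frames
  movie <- array(100, c(2, 2, nT))
  expect_equal(compute_dff(movie, pr), array(0, c(2, 2, nT)))

  movie[, , pr$schedule$onset[1]] <- 300
  dff <- compute_dff(movie, pr)
  expect_equal(dff[1, 1, pr$schedule$onset[1]], 2.0)

  # arbitrary small movie against per-pixel hand computation
  withr::local_seed(2)
  m <- array(runif(2 * 2 * 6, 50, 150), c(2, 2, 6))
  d <- compute_dff(m, pr)
  for (i in 1:2) for (j in 1:2) {
    f0 <- mean(m[i, j, pr$baseline_frames])
    expect_equal(d[i, j, ], (m[i, j, ] - f0) / f0)
  }

  expect_error(compute_dff(array(0, c(2, 2, nT)), pr), "all-zero baseline")
})

test_that("ROI responses average presentations of the same position", {
  pr <- make_stim_protocol(n_positions = 2, n_repeats = 2,
                           order = c(1, 2, 1, 2), pre_s = 1, frame_rate = 1,
                           stim_s = 1, isi_s = 2)
  dff <- array(0, c(2, 2, pr$n_frames))
  roi <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  # presentations of position 1 respond 1.0 then 3.0 (windows of one frame)
  dff[1, 1, pr$schedule$onset[1]] <- 1
  dff[1, 1, pr$schedule$onset[3]] <- 3
  tab <- position_response_table(dff, pr, roi, decay_allowance_s = 0)
  expect_equal(unname(tab$responses[1, 1]), 2.0)
  expect_equal(unname(tab$responses[1, 2]), 0)

  expect_error(position_response_table(dff, pr, matrix(0L, 2, 2)), "no ROIs")
})

test_that("optimal stimulus position is the rectified response-weighted mean", {
  expect_equal(optimal_stimulus_position(c(0, 0, 5, 0, 0)), 3.0)
  expect_equal(optimal_stimulus_position(rep(2, 5)), 3.0)
  expect_equal(optimal_stimulus_position(c(1, 2, 6, 2, 1)), 3.0)
  expect_equal(optimal_stimulus_position(c(0, 0, 0, 4, 4)), 4.5)
  # negatives are rectified, not propagated
  expect_equal(optimal_stimulus_position(c(-3, 0, 5, 0, -3)), 3.0)
  expect_true(is.na(optimal_stimulus_position(c(-1, 0, 0, 0, 0))))
})

test_that("sharpness follows the two-closest versus periphery ratio", {
  expect_equal(receptive_field_sharpness(c(1, 2, 6, 2, 1), 3.0), 3.0)
  expect_equal(receptive_field_sharpness(c(0, 1, 4, 1, 0), 3.0), 7.5)
  expect_equal(receptive_field_sharpness(rep(4, 5), 3.0), 1.0)
  # ties toward the lower index: optimal 3 ranks {3, 2} closest
  expect_equal(receptive_field_sharpness(c(0, 9, 3, 1, 0), 3.0),
               mean(c(3, 9)) / mean(c(0, 1, 0)))
  expect_true(is.na(receptive_field_sharpness(c(0, 0, 1, 0, 0), 3.0)))
})

test_that("optimal position and sharpness are scale invariant", {
  r <- c(0.5, 2, 5, 1.5, 0.2)
  for (k in c(0.1, 3, 40)) {
    expect_equal(optimal_stimulus_position(k * r),
                 optimal_stimulus_position(r))
    expect_equal(receptive_field_sharpness(k * r),
                 receptive_field_sharpness(r))
  }
})

test_that("inclusion criteria reproduce the stated thresholds", {
  est <- data.frame(
    animal_id = "a1",
    roi_id = 1:5,
    roi_px = c(40, 40, 40, 29, 40),
    max_response = c(1.9, 3, 3, 3, 3),
    optimal_position = c(3, 4.3, 3, 3, 3),
    sharpness = c(2, 2, NA, 2, 2))
  out <- apply_inclusion_criteria(est, min_cells_per_animal = 1)
  expect_equal(out$exclusion_reason[1], "weak_response")
  expect_equal(out$exclusion_reason[2], "peripheral_optimum")
  expect_equal(out$exclusion_reason[3], "undefined_sharpness")
  expect_equal(out$exclusion_reason[4], "small_roi")
  expect_true(out$included[5])

  # a 29-cell animal is dropped wholesale
  est29 <- data.frame(animal_id = "a2", roi_id = 1:29, roi_px = 40,
                      max_response = 3, optimal_position = 3, sharpness = 2)
  out29 <- apply_inclusion_criteria(est29, min_cells_per_animal = 30)
  expect_false(any(out29$included))
  expect_true(all(out29$exclusion_reason == "animal_below_min_cells"))
})

test_that("grid maps recover on-grid centres and ignore silent pixels", {
  pr <- make_stim_protocol(seed = 31, n_repeats = 2)
  # the central position is exact by symmetry; edge positions carry a tiny
  # one-sided Gaussian-tail bias, negligible at sigma = 10 degrees
  cells <- data.frame(center_deg = c(-22, 0, 22), sigma_deg = 10,
                      amplitude_dff = 6)  # positions 2, 3, 4
  g <- generate_calcium_movie(32, pr, cells, dims = c(16, 32))
  dff <- compute_dff(g$movie, pr)
  gm <- grid_map(dff, pr)
  expect_equal(mean(gm[g$roi_labels == 2]), 3.0)
  expect_equal(mean(gm[g$roi_labels == 1]), 2.0, tolerance = 1e-3)
  expect_equal(mean(gm[g$roi_labels == 3]), 4.0, tolerance = 1e-3)
  expect_true(all(is.na(gm[g$roi_labels == 0])))
  # invariant under positive scaling of dF/F
  expect_equal(grid_map(2.5 * dff, pr), gm)
})

test_that("two-sample KS distance matches the pooled-ECDF oracle", {
  expect_equal(ks_two_sample(1:20, 1:20)$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  withr::local_seed(44)
  for (r in 1:10) {
    a <- rnorm(50)
    b <- rnorm(50, 0.3)
    expect_equal(ks_two_sample(a, b)$statistic, ks_oracle_D(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})
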