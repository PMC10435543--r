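test_that("generators are deterministic in their seed", {
  a1 <- generate_arbor(7, 5)
  a2 <- generate_arbor(7, 5)
  expect_identical(as.data.frame(a1$arbor), as.data.frame(a2$arbor))

  f1 <- generate_puncta_field(9)
  f2 <- generate_puncta_field(9)
  expect_identical(f1$channel_a, f2$channel_a)
  expect_identical(f1$channel_b, f2$channel_b)

  pr <- make_stim_protocol(seed = 5, n_repeats = 1)
  cells <- sample_rf_cells(6, 2, 15)
  m1 <- generate_calcium_movie(8, pr, cells, dims = c(16, 24), noise_sd = 3)
  m2 <- generate_calcium_movie(8, pr, cells, dims = c(16, 24), noise_sd = 3)
  expect_identical(m1$movie, m2$movie)
})

test_that("arbor generation attaches exact ground truth", {
  for (seed in 1:6) {
    g <- generate_arbor(seed, n_branch_events = seed)
    expect_equal(total_dendritic_length(g$arbor), g$truth$total_length)
    expect_equal(count_branch_tips(g$arbor), g$truth$n_tips)
  }
  # no branching forces a single unbranched path
  g0 <- generate_arbor(3, n_branch_events = 0)
  expect_equal(g0$truth$n_tips, 1)
  expect_equal(count_branch_tips(g0$arbor), 1)
  expect_error(generate_arbor(1, mean_segment_length = 0), "positive")
})

test_that("certain loss empties the process population after one interval", {
  g <- generate_arbor(2)
  s <- generate_arbor_series(4, g$arbor, n_intervals = 2, p_add = 0,
                             p_loss = 1, step_sd = 0)
  expect_gt(s$truth$n_processes[1], 0)
  expect_equal(s$truth$n_processes[2], 0)
  expect_equal(nrow(extract_terminal_processes(s$series$timepoints[[2]])), 0)
  expect_error(generate_arbor_series(1, g$arbor, p_loss = 1.5), "\\[0, 1\\]")
})

test_that("zero-rate series are constant with an empty event log", {
  g <- generate_arbor(10)
  s <- generate_arbor_series(11, g$arbor, n_intervals = 4, p_add = 0,
                             p_loss = 0, step_sd = 0)
  for (k in 2:5) {
    expect_identical(as.data.frame(s$series$timepoints[[k]]),
                     as.data.frame(s$series$timepoints[[1]]))
  }
  expect_equal(nrow(s$truth$event_log), 0)
})

test_that("puncta placement respects feasibility and the coloc bound", {
  expect_error(generate_puncta_field(1, n_a = 2, n_b = 2, n_coloc = 3),
               "n_coloc")
  expect_error(generate_puncta_field(1, field_size_um = c(6, 6),
                                     n_a = 60, n_b = 60, n_coloc = 10),
               "too many spots")
  f <- generate_puncta_field(2, n_a = 0, n_b = 0, n_coloc = 0, noise_sd = 0)
  expect_true(all(f$channel_a == 50))
  expect_true(all(f$channel_b == 50))
})

test_that("spot centres stay inside the field", {
  f <- generate_puncta_field(13, n_a = 10, n_b = 10, n_coloc = 5)
  expect_true(all(f$truth$centers$x_um > 0 & f$truth$centers$x_um < 20))
  expect_true(all(f$truth$centers$y_um > 0 & f$truth$centers$y_um < 20))
  expect_equal(sum(f$truth$centers$colocalized), 5)
})

test_that("a null cell leaves the movie at baseline", {
  pr <- make_stim_protocol(seed = 21, n_repeats = 1)
  cells <- data.frame(center_deg = 0, sigma_deg = 15, amplitude_dff = 0)
  g <- generate_calcium_movie(22, pr, cells, dims = c(16, 16), noise_sd = 0)
  expect_true(all(g$movie == 100))
  expect_error(generate_calcium_movie(1, pr, cells, dims = c(16, 16),
                                      decay_tau_s = 0), "positive")
})

test_that("an on-grid receptive field centre is recovered exactly", {
  pr <- make_stim_protocol(seed = 23, n_repeats = 2)
  cells <- data.frame(center_deg = 0, sigma_deg = 15, amplitude_dff = 6)
  g <- generate_calcium_movie(24, pr, cells, dims = c(16, 16), noise_sd = 0)
  tab <- position_response_table(compute_dff(g$movie, pr), pr, g$roi_labels)
  expect_equal(optimal_stimulus_position(tab$responses[1, ]), 3.0)
})

test_that("narrower receptive fields are sharper, monotonically in sigma", {
  for (seed in 1:4) {
    pr <- make_stim_protocol(seed = seed, n_repeats = 2)
    sharp <- sapply(c(5, 15, 40), function(sg) {
      cells <- data.frame(center_deg = 0, sigma_deg = sg, amplitude_dff = 6)
      g <- generate_calcium_movie(seed + 50, pr, cells, dims = c(16, 16))
      tab <- position_response_table(compute_dff(g$movie, pr), pr,
                                     g$roi_labels)
      receptive_field_sharpness(tab$responses[1, ])
    })
    expect_true(all(diff(sharp) < 0), info = paste("seed", seed))
  }
})

test_that("stimulus protocols are well formed", {
  pr <- make_stim_protocol(seed = 2, n_positions = 5, n_repeats = 3)
  expect_equal(sort(unique(pr$schedule$position)), 1:5)
  expect_equal(nrow(pr$schedule), 15)
  expect_true(all(pr$schedule$onset < pr$schedule$offset))
  expect_true(max(pr$baseline_frames) < min(pr$schedule$onset))
  expect_error(make_stim_protocol(order = c(1, 1, 1, 1, 1)), "every position")
})
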