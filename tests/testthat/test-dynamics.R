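test_that("terminal processes run from each leaf to the nearest branch point", {
  # unbranched 8 um path
  a <- path_arbor(rbind(c(0, 0, 0), c(3, 0, 0), c(8, 0, 0)))
  p <- extract_terminal_processes(a)
  expect_equal(nrow(p), 1)
  expect_equal(p$length_um, 8)
  expect_equal(p$class, "filopodium")

  # limbs of 4 and 15 um beyond the branch point
  b <- neuron_arbor(data.frame(
    node_id = 1:4, parent_id = c(NA, 1, 2, 2),
    x = c(0, 5, 9, 20), y = 0, z = 0,
    label = c("soma", rep("dendrite", 3))))
  p <- extract_terminal_processes(b)
  expect_setequal(p$length_um, c(4, 15))
  expect_setequal(p$class, c("filopodium", "branch"))

  expect_equal(nrow(extract_terminal_processes(path_arbor(matrix(0, 1, 3)))), 0)
})

test_that("the 10 um boundary belongs to branches", {
  expect_equal(classify_process(9.99), "filopodium")
  expect_equal(classify_process(10), "branch")
  expect_equal(classify_process(0), "filopodium")
  expect_error(classify_process(-1), "non-negative")
})

test_that("diffing arbors reports additions, losses, and length deltas", {
  pe <- data.frame(process_id = c(1L, 2L), length_um = c(6, 12),
                   class = c("filopodium", "branch"))
  pl <- data.frame(process_id = c(2L, 3L), length_um = c(12, 4),
                   class = c("branch", "filopodium"))
  d <- diff_arbors(pe, pl)
  expect_equal(d$added$process_id, 3L)
  expect_equal(d$lost$process_id, 1L)
  expect_equal(d$shared$delta_length, 0)

  d2 <- diff_arbors(pe, data.frame(process_id = c(1L, 2L),
                                   length_um = c(9, 12),
                                   class = c("filopodium", "branch")))
  expect_equal(d2$shared$delta_length[d2$shared$process_id == 1L], 3)

  expect_error(diff_arbors(rbind(pe, pe), pl), "duplicate")
})

test_that("a +2 then -3 um excursion gives elongation 2, retraction 3, motility (2,3)", {
  mk <- function(len) {
    neuron_arbor(data.frame(
      node_id = 1:2, parent_id = c(NA, 1), x = c(0, len), y = 0, z = 0,
      label = c("soma", "dendrite"), process_id = c(NA, 7L)))
  }
  s <- list(mk(6), mk(8), mk(5))
  out <- summarize_dynamics(s)
  fil <- out$per_class[out$per_class$class == "filopodium", ]
  expect_equal(fil$total_elongation, 2)
  expect_equal(fil$total_retraction, 3)
  expect_equal(unname(out$motility["filopodium", ]), c(2, 3))
  expect_equal(fil$n_added, 0)
  expect_equal(fil$n_lost, 0)
})

test_that("a static series has no events and zero motility", {
  g <- generate_arbor(2)
  s <- generate_arbor_series(1, g$arbor, n_intervals = 5, p_add = 0,
                             p_loss = 0, step_sd = 0)
  out <- summarize_dynamics(s$series)
  expect_equal(sum(out$per_class$n_added), 0)
  expect_equal(sum(out$per_class$n_lost), 0)
  expect_equal(sum(out$per_class$total_elongation), 0)
  expect_true(all(out$motility == 0))
  expect_equal(nrow(s$truth$event_log), 0)
})

test_that("summaries reproduce the generator event log exactly", {
  for (seed in 1:10) {
    g <- generate_arbor(seed)
    s <- generate_arbor_series(seed + 100, g$arbor, n_intervals = 6)
    out <- summarize_dynamics(s$series)
    want <- aggregate_event_log(s$truth$event_log, 6)
    for (cl in c("filopodium", "branch")) {
      row <- out$per_class[out$per_class$class == cl, ]
      expect_equal(row$n_added, want[[cl]]$n_added)
      expect_equal(row$n_lost, want[[cl]]$n_lost)
      expect_equal(row$total_elongation, want[[cl]]$total_elongation)
      expect_equal(row$total_retraction, want[[cl]]$total_retraction)
      expect_equal(unname(out$motility[cl, ]), want[[cl]]$motility)
    }
  }
})

test_that("process counts obey the addition-loss conservation law", {
  for (seed in 1:8) {
    g <- generate_arbor(seed + 30)
    s <- generate_arbor_series(seed, g$arbor, n_intervals = 6,
                               p_add = 0.6, p_loss = 0.2)
    n <- s$truth$n_processes
    el <- s$truth$event_log
    for (k in seq_len(6)) {
      expect_equal(n[k + 1],
                   n[k] + sum(el$event == "added" & el$interval == k) -
                     sum(el$event == "lost" & el$interval == k))
    }
  }
})

test_that("motility bounds the absolute net length change per interval", {
  g <- generate_arbor(4)
  s <- generate_arbor_series(8, g$arbor, n_intervals = 6, p_add = 0,
                             p_loss = 0, step_sd = 2)
  out <- summarize_dynamics(s$series)
  procs <- lapply(s$series$timepoints, extract_terminal_processes)
  for (k in 1:6) {
    d <- diff_arbors(procs[[k]], procs[[k + 1]])
    for (cl in c("filopodium", "branch")) {
      del <- d$shared$delta_length[d$shared$class == cl]
      expect_gte(out$motility[cl, k] + 1e-12, abs(sum(del)))
      if (length(del) > 0 && (all(del >= 0) || all(del <= 0))) {
        expect_equal(unname(out$motility[cl, k]), abs(sum(del)))
      }
    }
  }
})

test_that("time reversal swaps additions with losses and growth with retraction", {
  g <- generate_arbor(13)
  s <- generate_arbor_series(21, g$arbor, n_intervals = 6)$series
  rev_s <- structure(list(timepoints = rev(s$timepoints),
                          interval_minutes = s$interval_minutes),
                     class = "arbor_series")
  fwd <- summarize_dynamics(s)$per_class
  bwd <- summarize_dynamics(rev_s)$per_class
  expect_equal(sum(fwd$n_added), sum(bwd$n_lost))
  expect_equal(sum(fwd$n_lost), sum(bwd$n_added))
  expect_equal(sum(fwd$total_elongation), sum(bwd$total_retraction))
  expect_equal(sum(fwd$total_retraction), sum(bwd$total_elongation))
})

test_that("process density scales inversely with coordinate dilation", {
  g <- generate_arbor(6)
  a <- g$arbor
  d1 <- process_density(a)
  b <- a
  b$x <- 2 * b$x; b$y <- 2 * b$y; b$z <- 2 * b$z
  b <- neuron_arbor(b)
  d2 <- process_density(b)
  # counts may reclassify (lengths double) but total count/length halves
  expect_equal(sum(d2), sum(d1) / 2)
  expect_error(process_density(path_arbor(matrix(0, 1, 3))), "zero-length")

  simple <- neuron_arbor(data.frame(
    node_id = 1:3, parent_id = c(NA, 1, 1),
    x = c(0, 50, -50), y = 0, z = 0,
    label = c("soma", "dendrite", "dendrite")))
  expect_equal(unname(process_density(simple)["branches_per_um"]), 0.02)
})
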