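#' Describe a bar-stimulus protocol for retinotopic grid mapping
#'
#' The mapping stimulus is a dark bar (18 degrees wide by default) flashed at
#' `n_positions` equidistant positions along the azimuth or elevation axis in
#' randomised order. The protocol ties each presentation to onset/offset
#' frames of the calcium movie and designates a pre-stimulus block as
#' baseline frames for computing F0.
#'
#' @param n_positions Number of bar positions (default 5).
#' @param n_repeats Presentations per position (default 3).
#' @param frame_rate Acquisition rate in Hz (default 6).
#' @param stim_s Bar presentation duration in seconds (default 1).
#' @param isi_s Inter-stimulus interval in seconds (default 4).
#' @param pre_s Pre-stimulus baseline duration in seconds (default 5).
#' @param axis `"azimuth"` or `"elevation"`.
#' @param bar_width_deg Bar width in degrees of visual angle (default 18).
#' @param position_spacing_deg Angular spacing between adjacent bar
#'   positions (default 22, five positions spanning ~110 degrees of azimuth).
#' @param order Optional explicit presentation order (vector of position
#'   indices, length `n_positions * n_repeats`); by default each repeat block
#'   is a random permutation.
#' @param seed Optional seed for the randomised order.
#' @return A `stim_protocol` list: `axis`, `n_positions`, `bar_width_deg`,
#'   `position_deg` (centred angular position of each index), `schedule`
#'   (data frame `position`, `onset`, `offset` in frames), `baseline_frames`,
#'   `frame_rate`, `n_frames`.
#' @export
make_stim_protocol <- function(n_positions = 5, n_repeats = 3,
                               frame_rate = 6, stim_s = 1, isi_s = 4,
                               pre_s = 5, axis = c("azimuth", "elevation"),
                               bar_width_deg = 18,
                               position_spacing_deg = 22,
                               order = NULL, seed = NULL) {
  axis <- match.arg(axis)
  stopifnot(n_positions >= 2, n_repeats >= 1, frame_rate > 0)
  if (is.null(order)) {
    perm_block <- function() sample.int(n_positions)
    order <- if (is.null(seed)) {
      unlist(replicate(n_repeats, perm_block(), simplify = FALSE))
    } else {
      withr::with_seed(seed, unlist(replicate(n_repeats, perm_block(),
                                              simplify = FALSE)))
    }
  }
  order <- as.integer(order)
  if (length(order) != n_positions * n_repeats ||
      !all(sort(unique(order)) == seq_len(n_positions))) {
    stop("order must present every position, length n_positions * n_repeats")
  }
  stim_f <- max(1L, round(stim_s * frame_rate))
  isi_f <- max(1L, round(isi_s * frame_rate))
  pre_f <- max(1L, round(pre_s * frame_rate))
  onset <- pre_f + 1L + (seq_along(order) - 1L) * (stim_f + isi_f)
  offset <- onset + stim_f - 1L
  n_frames <- max(offset) + isi_f
  structure(list(
    axis = axis, n_positions = as.integer(n_positions),
    bar_width_deg = bar_width_deg,
    position_deg = (seq_len(n_positions) - (n_positions + 1) / 2) *
      position_spacing_deg,
    schedule = data.frame(position = order, onset = onset, offset = offset),
    baseline_frames = seq_len(pre_f),
    frame_rate = frame_rate, n_frames = as.integer(n_frames)
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %s axis, %d positions x %d presentations, %d frames @ %g Hz\n",
    x$axis, x$n_positions, nrow(x$schedule) / x$n_positions, x$n_frames,
    x$frame_rate))
  invisible(x)
}

response_window_frames <- function(protocol, i, n_frames,
                                   decay_allowance_s = 1) {
  allow <- round(decay_allowance_s * protocol$frame_rate)
  seq(protocol$schedule$onset[i],
      min(protocol$schedule$offset[i] + allow, n_frames))
}

#' Fractional fluorescence change of a calcium movie
#'
#' Per pixel, the baseline F0 is the mean intensity over the protocol's
#' baseline frames and the output is `(F - F0) / F0` framewise. Pixels with
#' non-positive F0 are set to `NA` (invalid).
#'
#' @param movie 3-D array, rows x cols x frames, non-negative intensities.
#' @param protocol A [make_stim_protocol()] object (supplies the baseline
#'   frames).
#' @return Array of the same shape holding dF/F0.
#' @export
compute_dff <- function(movie, protocol) {
  stopifnot(length(dim(movie)) == 3L)
  bf <- protocol$baseline_frames
  if (length(bf) == 0L) stop("protocol designates no baseline frames")
  if (max(bf) > dim(movie)[3]) stop("baseline frames beyond movie length")
  f0 <- apply(movie[, , bf, drop = FALSE], c(1, 2), mean)
  if (all(f0 <= 0)) stop("all-zero baseline: F0 undefined everywhere")
  f0[f0 <= 0] <- NA_real_
  sweep(sweep(movie, c(1, 2), f0, "-"), c(1, 2), f0, "/")
}

#' Mean dF/F0 response per ROI and stimulus position
#'
#' For each ROI and bar position: dF/F0 averaged over the ROI's pixels and
#' over the frames of each presentation's response window (onset to offset
#' plus a decay allowance for the slow indicator transient), then averaged
#' across that position's presentations.
#'
#' @param dff dF/F0 array from [compute_dff()].
#' @param protocol A [make_stim_protocol()] object.
#' @param roi_masks Integer label matrix (rows x cols; 0 = background) or a
#'   list of logical masks.
#' @param decay_allowance_s Seconds appended to each response window
#'   (default 1).
#' @return A list with `responses` (ROI x position matrix of mean dF/F0) and
#'   `roi_px` (pixels per ROI).
#' @export
position_response_table <- function(dff, protocol, roi_masks,
                                    decay_allowance_s = 1) {
  if (is.list(roi_masks)) {
    lab <- matrix(0L, dim(dff)[1], dim(dff)[2])
    for (i in seq_along(roi_masks)) lab[roi_masks[[i]]] <- i
    roi_masks <- lab
  }
  stopifnot(identical(dim(roi_masks), dim(dff)[1:2]))
  ids <- sort(unique(roi_masks[roi_masks > 0L]))
  if (length(ids) == 0L) stop("no ROIs in the label image")
  n_frames <- dim(dff)[3]
  flat <- matrix(dff, ncol = n_frames)   # pixels x frames
  roi_rows <- lapply(ids, function(id) which(roi_masks == id))
  if (any(vapply(roi_rows, length, integer(1)) == 0L)) stop("empty ROI")
  # per-presentation mean within ROI and window, then average per position
  pres_mean <- matrix(NA_real_, length(ids), nrow(protocol$schedule))
  for (i in seq_len(nrow(protocol$schedule))) {
    win <- response_window_frames(protocol, i, n_frames, decay_allowance_s)
    for (r in seq_along(ids)) {
      pres_mean[r, i] <- mean(flat[roi_rows[[r]], win, drop = FALSE])
    }
  }
  responses <- t(vapply(seq_along(ids), function(r) {
    vapply(seq_len(protocol$n_positions), function(p) {
      mean(pres_mean[r, protocol$schedule$position == p])
    }, numeric(1))
  }, numeric(protocol$n_positions)))
  rownames(responses) <- ids
  list(responses = responses,
       roi_px = vapply(roi_rows, length, integer(1)))
}

#' Optimal stimulus position (receptive-field centre estimate)
#'
#' Response-weighted average of the position indices: negative responses are
#' rectified to zero and the centre is `sum(i * r_i) / sum(r_i)` over
#' positions `i = 1..n`. Undefined (returns `NA`) when no response is
#' positive.
#'
#' @param responses Numeric vector of mean dF/F0 responses, one per position.
#' @return Continuous position index in `[1, n]`, or `NA` if undefined.
#' @export
optimal_stimulus_position <- function(responses) {
  r <- pmax(responses, 0)
  if (sum(r) <= 0) return(NA_real_)
  sum(seq_along(r) * r) / sum(r)
}

#' Receptive-field sharpness
#'
#' Ratio of the mean response at the two stimulus positions closest to the
#' optimal position to the mean response at the remaining positions.
#' Positions are ranked by distance `|i - optimal|` with ties broken toward
#' the lower index. Undefined (returns `NA`) when the peripheral mean is not
#' positive; higher values indicate a more compact receptive field.
#'
#' @param responses Numeric response vector, one entry per position.
#' @param optimal Optimal stimulus position; computed from `responses` via
#'   [optimal_stimulus_position()] when omitted.
#' @return Dimensionless sharpness ratio, or `NA` if undefined.
#' @export
receptive_field_sharpness <- function(responses, optimal = NULL) {
  if (is.null(optimal)) optimal <- optimal_stimulus_position(responses)
  if (is.na(optimal)) return(NA_real_)
  idx <- seq_along(responses)
  ranked <- idx[order(abs(idx - optimal), idx)]
  closest <- ranked[1:2]
  periph <- ranked[-(1:2)]
  denom <- mean(responses[periph])
  if (denom <= 0) return(NA_real_)
  mean(responses[closest]) / denom
}

#' Per-ROI receptive-field estimates from a response table
#'
#' Convenience wrapper applying [optimal_stimulus_position()] and
#' [receptive_field_sharpness()] to each ROI of a
#' [position_response_table()] result.
#'
#' @param table Result of [position_response_table()].
#' @param animal_id Identifier attached to every ROI (used by the per-animal
#'   inclusion rule).
#' @return Data frame: `animal_id`, `roi_id`, `roi_px`, `max_response`,
#'   `optimal_position`, `sharpness`.
#' @export
estimate_receptive_fields <- function(table, animal_id = "animal1") {
  resp <- table$responses
  opt <- apply(resp, 1, optimal_stimulus_position)
  sharp <- vapply(seq_len(nrow(resp)), function(i) {
    receptive_field_sharpness(resp[i, ], opt[i])
  }, numeric(1))
  data.frame(animal_id = animal_id,
             roi_id = as.integer(rownames(resp)),
             roi_px = as.integer(table$roi_px),
             max_response = apply(resp, 1, max),
             optimal_position = opt,
             sharpness = sharp,
             stringsAsFactors = FALSE)
}

#' Apply the cell and animal inclusion criteria
#'
#' A cell body is evaluated only if its maximal stimulus response exceeds
#' `min_dff` (dF/F0 units), its optimal stimulus position falls within the
#' three central positions (`[2, 4]` of 5 by default), and its ROI is at
#' least `min_roi_px` pixels. Cells with undefined sharpness are excluded,
#' and animals retaining fewer than `min_cells_per_animal` cells are dropped
#' entirely. Every exclusion is logged with its reason.
#'
#' @param estimates Data frame from [estimate_receptive_fields()] (columns
#'   `animal_id`, `roi_id`, `roi_px`, `max_response`, `optimal_position`,
#'   `sharpness`).
#' @param min_dff Minimum maximal response in dF/F0 units (default 2).
#' @param central_range Closed interval of acceptable optimal positions
#'   (default `c(2, 4)`).
#' @param min_roi_px Minimum ROI size in pixels (default 30).
#' @param min_cells_per_animal Minimum surviving cells per animal
#'   (default 30).
#' @return `estimates` with logical `included` and character
#'   `exclusion_reason` (`NA` for included cells) columns appended. Reasons:
#'   `weak_response`, `peripheral_optimum`, `small_roi`,
#'   `undefined_sharpness`, `animal_below_min_cells`.
#' @export
apply_inclusion_criteria <- function(estimates, min_dff = 2,
                                     central_range = c(2, 4),
                                     min_roi_px = 30,
                                     min_cells_per_animal = 30) {
  reason <- rep(NA_character_, nrow(estimates))
  weak <- estimates$max_response <= min_dff
  reason[weak] <- "weak_response"
  periph <- is.na(reason) &
    (is.na(estimates$optimal_position) |
       estimates$optimal_position < central_range[1] |
       estimates$optimal_position > central_range[2])
  reason[periph] <- "peripheral_optimum"
  small <- is.na(reason) & estimates$roi_px < min_roi_px
  reason[small] <- "small_roi"
  undef <- is.na(reason) & is.na(estimates$sharpness)
  reason[undef] <- "undefined_sharpness"
  surviving <- table(estimates$animal_id[is.na(reason)])
  for (an in unique(estimates$animal_id)) {
    n <- if (an %in% names(surviving)) surviving[[an]] else 0L
    if (n < min_cells_per_animal) {
      drop <- is.na(reason) & estimates$animal_id == an
      reason[drop] <- "animal_below_min_cells"
    }
  }
  estimates$included <- is.na(reason)
  estimates$exclusion_reason <- reason
  estimates
}

#' Per-pixel optimal-position map ("grid map")
#'
#' Applies the response-weighted optimal stimulus position pixelwise to
#' produce a retinotopic map image; pixels with no positive response (or an
#' invalid F0) are `NA`.
#'
#' @param dff dF/F0 array from [compute_dff()].
#' @param protocol A [make_stim_protocol()] object.
#' @param decay_allowance_s Response-window decay allowance in seconds.
#' @return Matrix of continuous position indices in `[1, n_positions]`.
#' @export
grid_map <- function(dff, protocol, decay_allowance_s = 1) {
  n_frames <- dim(dff)[3]
  np <- protocol$n_positions
  resp <- array(NA_real_, c(dim(dff)[1], dim(dff)[2], np))
  for (p in seq_len(np)) {
    pres <- which(protocol$schedule$position == p)
    acc <- matrix(0, dim(dff)[1], dim(dff)[2])
    for (i in pres) {
      win <- response_window_frames(protocol, i, n_frames, decay_allowance_s)
      acc <- acc + apply(dff[, , win, drop = FALSE], c(1, 2), mean)
    }
    resp[, , p] <- acc / length(pres)
  }
  rect <- pmax(resp, 0)
  wsum <- apply(rect, c(1, 2), sum)
  num <- matrix(0, dim(dff)[1], dim(dff)[2])
  for (p in seq_len(np)) num <- num + p * rect[, , p]
  out <- num / wsum
  out[!is.finite(out) | wsum <= 0] <- NA_real_
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Supremum distance between the two empirical CDFs with the asymptotic
#' two-sided p-value (Kolmogorov distribution with effective
#' `n = n_a * n_b / (n_a + n_b)`), as used to compare pooled cumulative
#' distributions of receptive-field sharpness between rearing conditions.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty")
  }
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
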