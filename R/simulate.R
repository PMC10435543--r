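#' @keywords internal
random_unit_vectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Generate a synthetic dendritic arbor with known ground truth
#'
#' Grows a rooted tree from a soma at the origin: a short unbranched stem
#' followed by `n_branch_events` branch additions at randomly chosen existing
#' nodes, with gamma-distributed segment lengths. The attached ground truth
#' records the exact total length (sum of generated segment lengths) and the
#' leaf count, so downstream morphometry can be checked without tolerance.
#'
#' @param seed Integer seed; identical seeds give identical arbors.
#' @param n_branch_events Number of branch additions (>= 0).
#' @param mean_segment_length Mean segment length in micrometres (> 0).
#' @return List with `arbor` (a [neuron_arbor()]) and `truth` (list:
#'   `total_length`, `n_tips`).
#' @export
generate_arbor <- function(seed, n_branch_events = 10,
                           mean_segment_length = 15) {
  if (mean_segment_length <= 0) stop("mean_segment_length must be positive")
  if (n_branch_events < 0) stop("n_branch_events must be >= 0")
  withr::with_seed(seed, {
    seg_len <- function(n) stats::rgamma(n, shape = 2,
                                         scale = mean_segment_length / 2)
    nodes <- data.frame(node_id = 1L, parent_id = NA_integer_,
                        x = 0, y = 0, z = 0, label = "soma",
                        stringsAsFactors = FALSE)
    total <- 0
    add_child <- function(parent_row) {
      len <- seg_len(1)
      dir <- random_unit_vectors(1)
      id <- max(nodes$node_id) + 1L
      nodes <<- rbind(nodes, data.frame(
        node_id = id, parent_id = nodes$node_id[parent_row],
        x = nodes$x[parent_row] + dir[1] * len,
        y = nodes$y[parent_row] + dir[2] * len,
        z = nodes$z[parent_row] + dir[3] * len,
        label = "dendrite", stringsAsFactors = FALSE))
      total <<- total + len
      id
    }
    # unbranched stem of three segments
    for (i in 1:3) add_child(nrow(nodes))
    for (e in seq_len(n_branch_events)) {
      candidates <- which(nodes$label != "soma")
      add_child(sample(candidates, 1))
    }
    arbor <- neuron_arbor(nodes)
    n_tips <- sum(!(nodes$node_id %in% nodes$parent_id) &
                    nodes$label != "soma")
    list(arbor = arbor,
         truth = list(total_length = total, n_tips = as.integer(n_tips)))
  })
}

#' Generate a time series of terminal-process dynamics with an event log
#'
#' Seeds the process population from the terminal processes of `base`, then
#' evolves it over `n_intervals` imaging intervals: each existing process is
#' lost with probability `p_loss` per interval, each survivor changes length
#' by a Gaussian step of SD `step_sd` (clamped to stay positive), and with
#' probability `p_add` a new process appears with a fresh identity and an
#' initial length drawn uniformly from `new_length_range` (1-5 um by
#' default, so new processes are filopodia under the 10-um rule). Every
#' event is recorded in the ground-truth event log.
#'
#' Timepoint arbors are laid out as a soma-centred star (one straight edge
#' per terminal process), which keeps leaf-to-branch-point extraction exact
#' for any surviving process count; dynamics metrics depend only on process
#' identities and lengths.
#'
#' @param seed Integer seed.
#' @param base A [neuron_arbor()] whose terminal processes seed the series
#'   (e.g. from [generate_arbor()]).
#' @param n_intervals Number of imaging intervals (>= 1); the series has
#'   `n_intervals + 1` timepoints.
#' @param p_add Probability of one new process per interval, in `[0, 1]`.
#' @param p_loss Loss probability per process per interval, in `[0, 1]`.
#'   The defaults balance expected additions (`p_add`) against expected
#'   losses (`p_loss` times the typical process count) so the process
#'   density stays roughly stationary over the hour, as in short-interval
#'   imaging of tectal arbors.
#' @param step_sd SD of the per-interval Gaussian length change (um, >= 0).
#' @param interval_minutes Minutes between timepoints (default 10).
#' @param new_length_range Range of initial lengths for added processes (um).
#' @return List with `series` (an `arbor_series`: `timepoints` list of
#'   [neuron_arbor()]s plus `interval_minutes`) and `truth` (list:
#'   `event_log` data frame with columns `interval`, `process_id`, `event`
#'   in added/lost/delta_length, `magnitude`, `length_before`,
#'   `length_after`; and `n_processes` per timepoint).
#' @export
generate_arbor_series <- function(seed, base, n_intervals = 6,
                                  p_add = 0.4, p_loss = 0.05, step_sd = 1.5,
                                  interval_minutes = 10,
                                  new_length_range = c(1, 5)) {
  if (p_add < 0 || p_add > 1 || p_loss < 0 || p_loss > 1) {
    stop("p_add and p_loss must lie in [0, 1]")
  }
  if (step_sd < 0) stop("step_sd must be >= 0")
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  procs0 <- extract_terminal_processes(base)
  if (nrow(procs0) == 0L) stop("base arbor has no terminal processes")
  root <- arbor_root_index(base)
  soma <- c(base$x[root], base$y[root], base$z[root])
  withr::with_seed(seed, {
    state <- data.frame(process_id = procs0$process_id,
                        length = procs0$length_um)
    dirs <- random_unit_vectors(nrow(state))
    next_id <- max(state$process_id) + 1L
    log_rows <- list()
    star_arbor <- function(st, dr) {
      nodes <- data.frame(node_id = 1L, parent_id = NA_integer_,
                          x = soma[1], y = soma[2], z = soma[3],
                          label = "soma", process_id = NA_integer_,
                          stringsAsFactors = FALSE)
      if (nrow(st) > 0L) {
        nodes <- rbind(nodes, data.frame(
          node_id = st$process_id + 1L, parent_id = 1L,
          x = soma[1] + dr[, 1] * st$length,
          y = soma[2] + dr[, 2] * st$length,
          z = soma[3] + dr[, 3] * st$length,
          label = "dendrite", process_id = st$process_id,
          stringsAsFactors = FALSE))
      }
      neuron_arbor(nodes)
    }
    timepoints <- list(star_arbor(state, dirs))
    n_proc <- nrow(state)
    for (k in seq_len(n_intervals)) {
      n <- nrow(state)
      lost <- if (n > 0L) stats::runif(n) < p_loss else logical(0)
      for (i in which(lost)) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          interval = k, process_id = state$process_id[i], event = "lost",
          magnitude = state$length[i], length_before = state$length[i],
          length_after = NA_real_, stringsAsFactors = FALSE)
      }
      state <- state[!lost, , drop = FALSE]
      dirs <- dirs[!lost, , drop = FALSE]
      if (nrow(state) > 0L && step_sd > 0) {
        new_len <- pmax(state$length +
                          stats::rnorm(nrow(state), 0, step_sd), 0.3)
        for (i in which(new_len != state$length)) {
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            interval = k, process_id = state$process_id[i],
            event = "delta_length",
            magnitude = new_len[i] - state$length[i],
            length_before = state$length[i], length_after = new_len[i],
            stringsAsFactors = FALSE)
        }
        state$length <- new_len
      }
      if (p_add > 0 && stats::runif(1) < p_add) {
        len0 <- stats::runif(1, new_length_range[1], new_length_range[2])
        state <- rbind(state,
                       data.frame(process_id = next_id, length = len0))
        dirs <- rbind(dirs, random_unit_vectors(1))
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          interval = k, process_id = next_id, event = "added",
          magnitude = len0, length_before = NA_real_, length_after = len0,
          stringsAsFactors = FALSE)
        next_id <- next_id + 1L
      }
      timepoints[[k + 1L]] <- star_arbor(state, dirs)
      n_proc <- c(n_proc, nrow(state))
    }
    event_log <- if (length(log_rows) > 0L) {
      do.call(rbind, log_rows)
    } else {
      data.frame(interval = integer(0), process_id = integer(0),
                 event = character(0), magnitude = numeric(0),
                 length_before = numeric(0), length_after = numeric(0),
                 stringsAsFactors = FALSE)
    }
    series <- structure(list(timepoints = timepoints,
                             interval_minutes = interval_minutes),
                        class = "arbor_series")
    list(series = series,
         truth = list(event_log = event_log,
                      n_processes = as.integer(n_proc)))
  })
}

#' @export
print.arbor_series <- function(x, ...) {
  cat(sprintf("<arbor_series> %d timepoints, %g min interval\n",
              length(x$timepoints), x$interval_minutes))
  invisible(x)
}

place_spots <- function(n, lo, hi, min_sep, existing = NULL,
                        max_tries = 20000L) {
  pts <- existing
  placed <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("cannot place ", n, " spots with separation ", min_sep,
           " um in the available field; too many spots for the field")
    }
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    all_pts <- rbind(pts, placed)
    if (is.null(all_pts) || nrow(all_pts) == 0L ||
        all(sqrt(rowSums(sweep(all_pts, 2, cand)^2)) >= min_sep)) {
      placed <- rbind(placed, cand)
    }
  }
  placed
}

render_gaussian_spots <- function(dims, pixel_size, centers, amplitude,
                                  sigma) {
  xs <- (seq_len(dims[2]) - 0.5) * pixel_size
  ys <- (seq_len(dims[1]) - 0.5) * pixel_size
  img <- matrix(0, dims[1], dims[2])
  if (is.null(centers) || nrow(centers) == 0L) return(img)
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - centers[i, 2])^2 / (2 * sigma^2))
    img <- img + amplitude * outer(gy, gx)
  }
  img
}

#' Generate a two-channel punctate field with a known colocalised fraction
#'
#' Emulates a 20 x 20 um neuropil field with pre- and postsynaptic marker
#' puncta: `n_coloc` Gaussian spots share centres across both channels and
#' the remaining spots are placed at non-overlapping channel-specific
#' positions, all over a constant background plus optional additive Gaussian
#' noise.
#'
#' @param seed Integer seed.
#' @param field_size_um Field extent `c(width, height)` in micrometres.
#' @param pixel_size Micrometres per pixel (default 0.496).
#' @param n_a,n_b Spot counts in channels A and B.
#' @param n_coloc Number of spots with shared centres
#'   (`<= min(n_a, n_b)`).
#' @param spot_sigma_um Gaussian spot SD in micrometres.
#' @param amplitude Peak spot intensity above background.
#' @param background Constant background intensity.
#' @param noise_sd SD of additive Gaussian noise (0 = noiseless).
#' @param min_sep_um Minimum centre-to-centre separation (default 3.5 um:
#'   spots are kept individually resolvable, i.e. farther apart than one
#'   above-threshold footprint diameter).
#' @return List with `channel_a`, `channel_b` (matrices), `pixel_size`, and
#'   `truth` (list: `n_spots_channel_a`, `n_spots_channel_b`,
#'   `n_colocalized`, `centers` data frame with um coordinates and a
#'   `colocalized` flag, `spot_area_um2` nominal full-width-half-maximum
#'   area).
#' @export
generate_puncta_field <- function(seed, field_size_um = c(20, 20),
                                  pixel_size = 0.496,
                                  n_a = 10, n_b = 10, n_coloc = 5,
                                  spot_sigma_um = 0.5, amplitude = 150,
                                  background = 50, noise_sd = 8,
                                  min_sep_um = 3.5) {
  if (n_coloc > min(n_a, n_b)) stop("n_coloc must be <= min(n_a, n_b)")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  dims <- c(round(field_size_um[2] / pixel_size),
            round(field_size_um[1] / pixel_size))
  margin <- max(3 * spot_sigma_um, 1)
  lo <- c(margin, margin)
  hi <- c(field_size_um[1] - margin, field_size_um[2] - margin)
  if (any(hi <= lo)) stop("field too small for the requested spot size")
  withr::with_seed(seed, {
    shared <- place_spots(n_coloc, lo, hi, min_sep_um)
    a_only <- place_spots(n_a - n_coloc, lo, hi, min_sep_um, shared)
    b_only <- place_spots(n_b - n_coloc, lo, hi, min_sep_um,
                          rbind(shared, a_only))
    ca <- rbind(shared, a_only)
    cb <- rbind(shared, b_only)
    img_a <- background +
      render_gaussian_spots(dims, pixel_size, ca, amplitude, spot_sigma_um)
    img_b <- background +
      render_gaussian_spots(dims, pixel_size, cb, amplitude, spot_sigma_um)
    if (noise_sd > 0) {
      img_a <- pmax(img_a + matrix(stats::rnorm(length(img_a), 0, noise_sd),
                                   dims[1], dims[2]), 0)
      img_b <- pmax(img_b + matrix(stats::rnorm(length(img_b), 0, noise_sd),
                                   dims[1], dims[2]), 0)
    }
    centers <- data.frame(
      x_um = c(ca[, 1], if (nrow(b_only) > 0) b_only[, 1]),
      y_um = c(ca[, 2], if (nrow(b_only) > 0) b_only[, 2]),
      channel = c(rep("a", nrow(ca)), rep("b", nrow(b_only))),
      colocalized = c(rep(TRUE, n_coloc), rep(FALSE, nrow(a_only)),
                      rep(FALSE, nrow(b_only))),
      stringsAsFactors = FALSE)
    list(channel_a = img_a, channel_b = img_b, pixel_size = pixel_size,
         truth = list(n_spots_channel_a = n_a, n_spots_channel_b = n_b,
                      n_colocalized = n_coloc, centers = centers,
                      spot_area_um2 = pi * (1.1774 * spot_sigma_um)^2))
  })
}

#' Generate a two-channel dendrite z-stack with inside/outside puncta
#'
#' Channel A holds a tube-like dendrite (plus a bright soma blob at one end)
#' over constant background; channel B holds Gaussian puncta with known
#' inside/outside status relative to the dendrite. An exclusion mask marks
#' the synthetic soma region. Voxels are anisotropic: `pixel_size` um in
#' x/y, `z_step` um between slices.
#'
#' @param seed Integer seed.
#' @param dims Stack shape `c(rows, cols, slices)` in voxels.
#' @param pixel_size,z_step Voxel size in micrometres.
#' @param n_puncta_inside Puncta centred on the dendrite axis.
#' @param n_puncta_outside Puncta placed clear of the dendrite.
#' @param n_puncta_soma Puncta placed inside the excluded soma region.
#' @param tube_radius_um Dendrite radius (> 0).
#' @param soma_radius_um Soma radius.
#' @param spot_sigma_um Lateral (x/y) Gaussian punctum SD.
#' @param spot_sigma_z_um Axial (z) punctum SD; defaults to the lateral SD,
#'   but can be larger to emulate the axial elongation imposed by the
#'   microscope's point spread.
#' @param dendrite_intensity,puncta_amplitude,background,noise_sd
#'   Intensity parameters (noise is additive Gaussian).
#' @return List with `dendrite_channel`, `puncta_channel` (3-D arrays),
#'   `exclusion_mask` (logical array), `pixel_size`, `z_step`, and `truth`
#'   (counts and punctum centres in um).
#' @export
generate_dendrite_stack <- function(seed, dims = c(40, 64, 9),
                                    pixel_size = 0.496, z_step = 1,
                                    n_puncta_inside = 3,
                                    n_puncta_outside = 5,
                                    n_puncta_soma = 0,
                                    tube_radius_um = 1,
                                    soma_radius_um = 2.5,
                                    spot_sigma_um = 0.5,
                                    spot_sigma_z_um = spot_sigma_um,
                                    dendrite_intensity = 120,
                                    puncta_amplitude = 150,
                                    background = 20, noise_sd = 0) {
  if (tube_radius_um <= 0) stop("zero-volume dendrite: tube_radius_um must be > 0")
  if (min(n_puncta_inside, n_puncta_outside, n_puncta_soma) < 0) {
    stop("punctum counts must be >= 0")
  }
  xs <- (seq_len(dims[2]) - 0.5) * pixel_size
  ys <- (seq_len(dims[1]) - 0.5) * pixel_size
  zs <- (seq_len(dims[3]) - 0.5) * z_step
  y0 <- ys[ceiling(dims[1] / 2)]
  z0 <- zs[ceiling(dims[3] / 2)]
  soma_c <- c(soma_radius_um + 0.5, y0, z0)
  withr::with_seed(seed, {
    # distance fields
    grid <- expand.grid(y = ys, x = xs)
    tube_d2 <- outer((ys - y0)^2, rep(1, dims[2])) # per-slice radial part
    dend <- array(background, dims)
    excl <- array(FALSE, dims)
    for (k in seq_len(dims[3])) {
      rad2 <- tube_d2 + (zs[k] - z0)^2
      in_tube <- sqrt(rad2) <= tube_radius_um
      soma_d2 <- outer((ys - soma_c[2])^2, (xs - soma_c[1])^2, "+") +
        (zs[k] - soma_c[3])^2
      in_soma <- sqrt(soma_d2) <= soma_radius_um
      dend[, , k] <- background +
        dendrite_intensity * ((in_tube | in_soma) * 1)
      excl[, , k] <- sqrt(soma_d2) <= soma_radius_um + 0.75
    }
    # punctum centres
    x_min <- soma_c[1] + soma_radius_um + 2
    x_max <- max(xs) - 1.5
    if (n_puncta_inside > 0 &&
        (x_max - x_min) < (n_puncta_inside - 1) * 2.5) {
      stop("stack too small for the requested inside puncta")
    }
    inside <- if (n_puncta_inside > 0) {
      cbind(seq(x_min, x_max, length.out = max(n_puncta_inside, 2))[
        seq_len(n_puncta_inside)], y0, z0)
    } else matrix(numeric(0), ncol = 3)
    clear <- tube_radius_um + 3 * spot_sigma_um + 1
    outside <- matrix(numeric(0), ncol = 3)
    while (nrow(outside) < n_puncta_outside) {
      cand <- c(stats::runif(1, 1.5, max(xs) - 1.5),
                stats::runif(1, 1.5, max(ys) - 1.5), z0)
      if (abs(cand[2] - y0) >= clear &&
          sqrt(sum((cand - soma_c)^2)) > soma_radius_um + clear) {
        outside <- rbind(outside, cand)
      }
    }
    soma_pts <- if (n_puncta_soma > 0) {
      matrix(rep(soma_c, n_puncta_soma), ncol = 3, byrow = TRUE)
    } else matrix(numeric(0), ncol = 3)
    centers <- rbind(inside, outside, soma_pts)
    punc <- array(background, dims)
    for (k in seq_len(dims[3])) {
      sl <- matrix(0, dims[1], dims[2])
      for (i in seq_len(nrow(centers))) {
        zfac <- exp(-(zs[k] - centers[i, 3])^2 / (2 * spot_sigma_z_um^2))
        if (zfac < 1e-4) next
        gx <- exp(-(xs - centers[i, 1])^2 / (2 * spot_sigma_um^2))
        gy <- exp(-(ys - centers[i, 2])^2 / (2 * spot_sigma_um^2))
        sl <- sl + puncta_amplitude * zfac * outer(gy, gx)
      }
      punc[, , k] <- punc[, , k] + sl
    }
    if (noise_sd > 0) {
      dend <- pmax(dend + array(stats::rnorm(length(dend), 0, noise_sd),
                                dims), 0)
      punc <- pmax(punc + array(stats::rnorm(length(punc), 0, noise_sd),
                                dims), 0)
    }
    list(dendrite_channel = dend, puncta_channel = punc,
         exclusion_mask = excl, pixel_size = pixel_size, z_step = z_step,
         truth = list(n_puncta_inside = n_puncta_inside,
                      n_puncta_outside = n_puncta_outside,
                      n_puncta_soma = n_puncta_soma,
                      centers = centers))
  })
}

#' Sample a cohort of synthetic receptive-field cells
#'
#' Draws cells with Gaussian receptive fields along the stimulus axis:
#' centres uniform within the span of the three central bar positions,
#' a common tuning width, and log-normal response amplitudes.
#'
#' @param seed Integer seed.
#' @param n_cells Number of cells.
#' @param sigma_deg Receptive-field width (Gaussian SD, degrees).
#' @param amplitude_mean Mean peak response in dF/F0 units (default 6).
#' @param center_range_deg Range for receptive-field centres in degrees
#'   (default the central three positions at 22-degree spacing).
#' @return Data frame `center_deg`, `sigma_deg`, `amplitude_dff`.
#' @export
sample_rf_cells <- function(seed, n_cells, sigma_deg,
                            amplitude_mean = 6,
                            center_range_deg = c(-22, 22)) {
  withr::with_seed(seed, {
    data.frame(
      center_deg = stats::runif(n_cells, center_range_deg[1],
                                center_range_deg[2]),
      sigma_deg = sigma_deg,
      amplitude_dff = amplitude_mean *
        exp(stats::rnorm(n_cells, 0, 0.2)))
  })
}

#' Generate a synthetic calcium movie over a bar-mapping protocol
#'
#' Each cell occupies a square ROI; every presentation of bar position `p`
#' evokes, in each cell, a transient of peak dF/F0 amplitude
#' `A * exp(-(d_p - center)^2 / (2 * sigma^2))` (where `d_p` is the
#' position's angular location) rising instantaneously at stimulus onset and
#' decaying exponentially with time constant `decay_tau_s`, truncated at the
#' next presentation's onset. The fluorescence movie is
#' `f0 * (1 + dff)` plus optional additive Gaussian noise.
#'
#' @param seed Integer seed.
#' @param protocol A [make_stim_protocol()] object.
#' @param cells Data frame with columns `center_deg`, `sigma_deg`,
#'   `amplitude_dff` (see [sample_rf_cells()]).
#' @param dims Frame shape `c(rows, cols)`; ROIs are tiled on a grid and an
#'   error is raised if the frame cannot hold all cells.
#' @param f0 Baseline fluorescence intensity.
#' @param decay_tau_s Indicator decay time constant in seconds
#'   (default 1.5; > 0).
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param roi_size_px Side of each square ROI in pixels (default 6).
#' @param roi_gap_px Gap between ROIs in pixels.
#' @return List with `movie` (rows x cols x frames), `roi_labels` (integer
#'   label matrix), `protocol`, and `truth` (the `cells` table with `roi_id`
#'   and the per-position programmed response amplitudes `response_matrix`).
#' @export
generate_calcium_movie <- function(seed, protocol, cells, dims = c(48, 64),
                                   f0 = 100, decay_tau_s = 1.5,
                                   noise_sd = 0, roi_size_px = 6,
                                   roi_gap_px = 2) {
  if (!inherits(protocol, "stim_protocol")) stop("protocol must be a stim_protocol")
  if (nrow(protocol$schedule) == 0L) stop("empty protocol")
  if (decay_tau_s <= 0) stop("decay_tau_s must be positive")
  n_cells <- nrow(cells)
  pitch <- roi_size_px + roi_gap_px
  per_row <- (dims[2] - roi_gap_px) %/% pitch
  per_col <- (dims[1] - roi_gap_px) %/% pitch
  if (per_row * per_col < n_cells) {
    stop("frame of ", dims[1], "x", dims[2], " px cannot hold ", n_cells,
         " ROIs of ", roi_size_px, " px")
  }
  nT <- protocol$n_frames
  roi_labels <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(n_cells)) {
    gr <- (i - 1L) %/% per_row
    gc <- (i - 1L) %% per_row
    r0 <- roi_gap_px + gr * pitch + 1L
    c0 <- roi_gap_px + gc * pitch + 1L
    roi_labels[r0:(r0 + roi_size_px - 1L), c0:(c0 + roi_size_px - 1L)] <- i
  }
  # programmed response amplitude per cell and position
  resp <- outer(seq_len(n_cells), seq_len(protocol$n_positions),
                function(i, p) {
                  cells$amplitude_dff[i] *
                    exp(-(protocol$position_deg[p] - cells$center_deg[i])^2 /
                          (2 * cells$sigma_deg[i]^2))
                })
  # per-cell dF/F0 trace
  onsets <- protocol$schedule$onset
  ends <- c(onsets[-1] - 1L, nT)
  tau_f <- decay_tau_s * protocol$frame_rate
  traces <- matrix(0, n_cells, nT)
  for (j in seq_along(onsets)) {
    frames <- onsets[j]:ends[j]
    kern <- exp(-(frames - onsets[j]) / tau_f)
    p <- protocol$schedule$position[j]
    traces[, frames] <- resp[, p, drop = FALSE] %*% t(kern)
  }
  movie <- withr::with_seed(seed, {
    m <- array(f0, c(dims[1], dims[2], nT))
    for (i in seq_len(n_cells)) {
      px <- which(roi_labels == i)
      for (t in which(traces[i, ] != 0)) {
        frame <- m[, , t]
        frame[px] <- f0 * (1 + traces[i, t])
        m[, , t] <- frame
      }
    }
    if (noise_sd > 0) {
      m <- pmax(m + array(stats::rnorm(length(m), 0, noise_sd), dim(m)), 0)
    }
    m
  })
  cells$roi_id <- seq_len(n_cells)
  list(movie = movie, roi_labels = roi_labels, protocol = protocol,
       truth = list(cells = cells, response_matrix = resp))
}
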