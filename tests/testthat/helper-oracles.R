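# Independent brute-force oracles used across the suite. These deliberately
# use naive scalar loops so they share no code path with the implementation.

# Kapur maximum-entropy threshold by exhaustive candidate enumeration
kapur_oracle <- function(counts, levels) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf
  idx <- integer(0)
  for (k in 1:(n - 1)) {
    P0 <- sum(p[1:k])
    P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    h0 <- 0
    for (i in 1:k) if (p[i] > 0) h0 <- h0 - (p[i] / P0) * log(p[i] / P0)
    h1 <- 0
    for (i in (k + 1):n) if (p[i] > 0) h1 <- h1 - (p[i] / P1) * log(p[i] / P1)
    obj <- h0 + h1
    if (obj > best) {
      best <- obj
      idx <- k
    } else if (obj == best) {
      idx <- c(idx, k)
    }
  }
  levels[idx[ceiling(length(idx) / 2)]]
}

# moment-preserving threshold: enumerate candidates, pick the one whose
# two-level image (fractions fixed by the candidate, levels matching moments
# 1 and 2 exactly) best preserves moment 3
moments_oracle <- function(counts, levels) {
  p <- counts / sum(counts)
  n <- length(p)
  m1 <- 0; m2 <- 0; m3 <- 0
  for (i in 1:n) {
    m1 <- m1 + p[i] * levels[i]
    m2 <- m2 + p[i] * levels[i]^2
    m3 <- m3 + p[i] * levels[i]^3
  }
  v <- m2 - m1^2
  best <- Inf
  idx <- integer(0)
  for (k in 1:(n - 1)) {
    q0 <- sum(p[1:k])
    q1 <- 1 - q0
    if (q0 <= 0 || q1 <= 0) next
    a <- m1 - sqrt(v * q1 / q0)
    b <- m1 + sqrt(v * q0 / q1)
    e <- (q0 * a^3 + q1 * b^3 - m3)^2
    if (e < best) {
      best <- e
      idx <- k
    } else if (e == best) {
      idx <- c(idx, k)
    }
  }
  levels[idx[ceiling(length(idx) / 2)]]
}

# random bimodal-ish 8-bit histogram for oracle-equivalence tests
random_histogram <- function() {
  z <- 0:255
  w <- stats::runif(2, 0.2, 0.8)
  mu <- sample(0:255, 2)
  sd <- stats::runif(2, 5, 60)
  dens <- w[1] * stats::dnorm(z, mu[1], sd[1]) +
    w[2] * stats::dnorm(z, mu[2], sd[2]) + 1e-4
  as.vector(stats::rmultinom(1, 5000, dens))
}

# Sholl crossings by dense sampling of each segment at ~0.01 um steps
sholl_dense_oracle <- function(arbor, radii, step = 0.01) {
  root <- which(is.na(arbor$parent_id))
  cx <- arbor$x[root]; cy <- arbor$y[root]; cz <- arbor$z[root]
  pidx <- match(arbor$parent_id, arbor$node_id)
  out <- integer(length(radii))
  for (i in which(!is.na(pidx))) {
    p1 <- c(arbor$x[pidx[i]] - cx, arbor$y[pidx[i]] - cy,
            arbor$z[pidx[i]] - cz)
    p2 <- c(arbor$x[i] - cx, arbor$y[i] - cy, arbor$z[i] - cz)
    len <- sqrt(sum((p2 - p1)^2))
    if (len == 0) next
    ns <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = ns)
    s <- sqrt((p1[1] + t * (p2[1] - p1[1]))^2 +
                (p1[2] + t * (p2[2] - p1[2]))^2 +
                (p1[3] + t * (p2[3] - p1[3]))^2)
    for (j in seq_along(radii)) {
      sgn <- s > radii[j]
      out[j] <- out[j] + sum(sgn[-1] != sgn[-ns])
    }
  }
  out
}

# grayscale opening by explicit per-pixel erode-then-dilate with the ball
opening_oracle <- function(image, radius) {
  r <- ceiling(radius)
  nr <- nrow(image); nc <- ncol(image)
  off <- list()
  for (di in -r:r) for (dj in -r:r) {
    if (di^2 + dj^2 <= radius^2) {
      off[[length(off) + 1]] <- c(di, dj, sqrt(radius^2 - di^2 - dj^2))
    }
  }
  er <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    m <- Inf
    for (o in off) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        m <- min(m, image[ii, jj] - o[3])
      }
    }
    er[i, j] <- m
  }
  di_ <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    m <- -Inf
    for (o in off) {
      ii <- i - o[1]; jj <- j - o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        m <- max(m, er[ii, jj] + o[3])
      }
    }
    di_[i, j] <- m
  }
  di_
}

# per-pixel disk median with mirror edges, by explicit sort
median_oracle <- function(image, radius) {
  r <- ceiling(radius)
  nr <- nrow(image); nc <- ncol(image)
  refl <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 <= radius^2) {
        vals <- c(vals, image[refl(i + di, nr), refl(j + dj, nc)])
      }
    }
    out[i, j] <- stats::median(vals)
  }
  out
}

# aggregate a generator event log into the dynamics summary quantities,
# using only simple arithmetic on the log
aggregate_event_log <- function(event_log, n_intervals, threshold = 10) {
  classes <- c("filopodium", "branch")
  cl_of <- function(len) ifelse(len < threshold, "filopodium", "branch")
  out <- list()
  for (cl in classes) {
    added <- event_log$event == "added" &
      cl_of(event_log$length_after) == cl
    lost <- event_log$event == "lost" &
      cl_of(event_log$length_before) == cl
    delta <- event_log$event == "delta_length" &
      cl_of(event_log$length_before) == cl
    mot <- numeric(n_intervals)
    for (k in seq_len(n_intervals)) {
      mot[k] <- sum(abs(event_log$magnitude[delta & event_log$interval == k]))
    }
    mg <- event_log$magnitude[delta]
    out[[cl]] <- list(
      n_added = sum(added), n_lost = sum(lost),
      total_elongation = sum(mg[mg > 0]),
      total_retraction = sum(-mg[mg < 0]),
      motility = mot)
  }
  out
}

# ECDF-evaluation oracle for the two-sample KS distance
ks_oracle_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# included sharpness values for a simulated animal (one cohort member)
cohort_sharpness <- function(seed, sigma_deg, n_cells = 60, noise_sd = 5) {
  pr <- make_stim_protocol(seed = seed, n_repeats = 2)
  cells <- sample_rf_cells(seed + 1, n_cells, sigma_deg)
  g <- generate_calcium_movie(seed + 2, pr, cells, dims = c(64, 80),
                              noise_sd = noise_sd)
  tab <- position_response_table(compute_dff(g$movie, pr), pr, g$roi_labels)
  est <- apply_inclusion_criteria(estimate_receptive_fields(tab))
  est$sharpness[est$included]
}

# minimal hand-built arbors reused across tests
path_arbor <- function(coords, labels = NULL) {
  n <- nrow(coords)
  if (is.null(labels)) labels <- c("soma", rep("dendrite", n - 1))
  neuron_arbor(data.frame(
    node_id = seq_len(n), parent_id = c(NA, seq_len(n - 1)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3], label = labels))
}

y_arbor <- function() {
  # soma -> (0,0,10), then two limbs to (0,6,18) and (0,-6,18)
  neuron_arbor(data.frame(
    node_id = 1:4, parent_id = c(NA, 1, 2, 2),
    x = c(0, 0, 0, 0), y = c(0, 0, 6, -6), z = c(0, 10, 18, 18),
    label = c("soma", rep("dendrite", 3))))
}
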