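#' Rolling-ball background subtraction
#'
#' Estimates the image background as the grayscale morphological opening by a
#' ball-shaped structuring element of the given radius (a true sphere by
#' default; the paraboloid dialect common in other tools is available via
#' `shape`) and subtracts it, clipping at zero. Small bright features
#' narrower than the ball survive; smooth background is removed. Pixels
#' outside the image are ignored by the min/max (equivalent to padding with
#' +/- infinity).
#'
#' @param image Numeric intensity matrix.
#' @param radius_px Ball radius in pixels (default 10).
#' @param shape `"ball"` (spherical cap heights) or `"paraboloid"`.
#' @return Background-subtracted image, same shape, non-negative.
#' @export
rolling_ball_subtract <- function(image, radius_px = 10,
                                  shape = c("ball", "paraboloid")) {
  shape <- match.arg(shape)
  stopifnot(is.matrix(image), is.numeric(image))
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (2 * radius_px + 1 > min(dim(image))) {
    stop("rolling-ball radius exceeds image size")
  }
  r <- as.integer(ceiling(radius_px))
  off <- expand.grid(di = -r:r, dj = -r:r)
  d2 <- off$di^2 + off$dj^2
  keep <- d2 <= radius_px^2
  off <- off[keep, , drop = FALSE]
  h <- switch(shape,
              ball = sqrt(radius_px^2 - d2[keep]),
              paraboloid = radius_px - d2[keep] / (2 * radius_px))
  eroded <- gray_shift_reduce(image, off, -h, r, pad = Inf, fun = pmin)
  bg <- gray_shift_reduce(eroded, off, h, r, pad = -Inf, fun = pmax)
  pmax(image - bg, 0)
}

# min/max over the structuring element via shifted padded slices;
# offsets are symmetric so erosion and dilation reuse the same set
gray_shift_reduce <- function(image, off, h, r, pad, fun) {
  nr <- nrow(image); nc <- ncol(image)
  p <- matrix(pad, nr + 2L * r, nc + 2L * r)
  p[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- image
  out <- matrix(pad, nr, nc)
  for (k in seq_len(nrow(off))) {
    slice <- p[(r + 1L + off$di[k]):(r + nr + off$di[k]),
               (r + 1L + off$dj[k]):(r + nc + off$dj[k]), drop = FALSE]
    out <- fun(out, slice + h[k])
  }
  out
}

#' Disk median filter
#'
#' Replaces each pixel by the median over the disk of the given radius,
#' with mirror (reflect) handling at the edges.
#'
#' @param image Numeric intensity matrix.
#' @param radius_px Disk radius in pixels (default 2, a 13-pixel disk).
#' @return Filtered image, same shape.
#' @export
median_filter <- function(image, radius_px = 2) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (radius_px < 1) stop("radius_px must be >= 1")
  r <- as.integer(ceiling(radius_px))
  nr <- nrow(image); nc <- ncol(image)
  ref <- function(n) c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
  p <- image[ref(nr), ref(nc), drop = FALSE]
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= radius_px^2, , drop = FALSE]
  vals <- matrix(NA_real_, nrow(off), nr * nc)
  for (k in seq_len(nrow(off))) {
    vals[k, ] <- p[(r + 1L + off$di[k]):(r + nr + off$di[k]),
                   (r + 1L + off$dj[k]):(r + nc + off$dj[k])]
  }
  matrix(apply(vals, 2, stats::median), nr, nc)
}

#' Pixelwise AND of two binary masks
#'
#' @param mask_a,mask_b Logical matrices (or arrays) of identical shape.
#' @return Logical mask of the same shape.
#' @export
colocalization_mask <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  }
  mask_a & mask_b
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation; 8-connectivity by default
#' (4-connectivity available).
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = background), numbered
#'   consecutively from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shifts <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  p <- matrix(Inf, nr + 2L, nc + 2L)
  repeat {
    p[2:(nr + 1L), 2:(nc + 1L)] <- lab
    new <- lab
    for (s in shifts) {
      new <- pmin(new, p[(2L + s[1]):(nr + 1L + s[1]),
                         (2L + s[2]):(nc + 1L + s[2]), drop = FALSE])
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  ids <- sort(unique(lab[is.finite(lab)]))
  out[mask] <- match(lab[mask], ids)
  out
}

#' Detect particles in a binary mask with a size criterion
#'
#' Connected components of the mask (8-connectivity by default) whose
#' physical area, pixel count times `pixel_size^2`, lies inside the closed
#' interval `[min_area, max_area]` (the 0.1-5.0 um^2 synapse size criterion
#' by default).
#'
#' @param mask Logical matrix.
#' @param pixel_size Pixel edge in micrometres per pixel.
#' @param min_area,max_area Area criterion bounds in um^2 (closed interval).
#' @param connectivity 8 (default) or 4.
#' @return A `puncta_set`: list with `particles` (data frame: `id`, `n_px`,
#'   `area_um2`, centroid `x_um`, `y_um`), `n` (retained count), `labels`
#'   (full label matrix before size filtering), and `kept_ids`.
#' @export
find_particles <- function(mask, pixel_size, min_area = 0.1, max_area = 5.0,
                           connectivity = 8) {
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive")
  }
  if (min_area >= max_area) stop("min_area must be below max_area")
  labels <- label_components(mask, connectivity)
  nlab <- max(labels)
  if (nlab == 0L) {
    particles <- data.frame(id = integer(0), n_px = integer(0),
                            area_um2 = numeric(0), x_um = numeric(0),
                            y_um = numeric(0))
  } else {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lb <- labels[labels > 0L]
    n_px <- as.integer(tabulate(lb, nbins = nlab))
    # centroids at pixel centres, in micrometres (x along columns)
    cx <- tapply((idx[, 2] - 0.5) * pixel_size, lb, mean)
    cy <- tapply((idx[, 1] - 0.5) * pixel_size, lb, mean)
    particles <- data.frame(id = seq_len(nlab), n_px = n_px,
                            area_um2 = n_px * pixel_size^2,
                            x_um = as.numeric(cx), y_um = as.numeric(cy))
  }
  keep <- particles$area_um2 >= min_area & particles$area_um2 <= max_area
  structure(list(particles = particles[keep, , drop = FALSE],
                 n = sum(keep), labels = labels,
                 kept_ids = particles$id[keep],
                 pixel_size = pixel_size),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d particle(s) within size criterion (of %d components)\n",
              x$n, max(x$labels)))
  invisible(x)
}
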