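#' Automatic histogram thresholding (moment-preserving or maximum-entropy)
#'
#' Computes a single global intensity threshold `t`; pixels strictly above `t`
#' are foreground. Two classic histogram criteria are implemented from
#' scratch:
#'
#' * `"moments"` (Tsai's moment-preserving criterion): every candidate
#'   threshold splits the histogram into two classes; the two class levels
#'   that exactly preserve the first two gray-level moments have a closed
#'   form, and the selected threshold is the candidate whose two-level image
#'   best preserves the third moment as well.
#' * `"maxentropy"` (Kapur's criterion): the selected threshold maximises the
#'   sum of the Shannon entropies of the normalised foreground and background
#'   histograms.
#'
#' Ties in either objective are broken at the median tied candidate, so a
#' perfectly bimodal image yields a threshold strictly between the two modes.
#' Integer-valued images are binned at unit width (so adding an integer
#' constant to every pixel shifts the threshold by exactly that constant);
#' other images are binned into `n_bins` equal bins over their range.
#'
#' @param image Numeric matrix or array of non-negative intensities.
#' @param method `"moments"` or `"maxentropy"`.
#' @param n_bins Number of histogram bins for non-integer images.
#' @return The threshold intensity `t` (foreground is `image > t`).
#' @export
auto_threshold <- function(image, method = c("moments", "maxentropy"),
                           n_bins = 256L) {
  method <- match.arg(method)
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("image has no finite pixels")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("cannot threshold a constant image (needs >= 2 distinct intensities)")
  }
  integerish <- all(v == round(v)) && (rng[2] - rng[1]) <= 65535
  if (integerish) {
    levels <- seq(rng[1], rng[2])
    counts <- tabulate(v - rng[1] + 1, nbins = length(levels))
  } else {
    w <- (rng[2] - rng[1]) / n_bins
    bin <- pmin(floor((v - rng[1]) / w) + 1L, n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    # threshold reported at the upper edge of the selected bin
    levels <- rng[1] + seq_len(n_bins) * w
  }
  threshold_from_hist(counts, levels, method)
}

#' Threshold directly from a histogram
#'
#' Lower-level interface used by [auto_threshold()]: `counts[i]` pixels have
#' gray level `levels[i]`. Returns the level `t` such that levels above `t`
#' are foreground.
#'
#' @param counts Non-negative histogram counts.
#' @param levels Ascending gray levels, same length as `counts`.
#' @param method `"moments"` or `"maxentropy"`.
#' @export
threshold_from_hist <- function(counts, levels,
                                method = c("moments", "maxentropy")) {
  method <- match.arg(method)
  stopifnot(length(counts) == length(levels), all(counts >= 0))
  if (sum(counts > 0) < 2L) {
    stop("histogram needs at least two occupied gray levels")
  }
  p <- counts / sum(counts)
  k <- switch(method,
              moments = moments_threshold_index(p, levels),
              maxentropy = kapur_threshold_index(p))
  levels[k]
}

# median element of the tied optimum set: deterministic, and centred for the
# structurally tied (e.g. perfectly bimodal) case
tie_median <- function(idx) idx[ceiling(length(idx) / 2)]

# Kapur maximum-entropy criterion over background = levels 1..k
kapur_threshold_index <- function(p) {
  n <- length(p)
  cp <- cumsum(p)[-n]
  plogp <- ifelse(p > 0, -p * log(p), 0)
  ch <- cumsum(plogp)[-n]
  htot <- sum(plogp)
  valid <- cp > 0 & cp < 1
  obj <- rep(-Inf, n - 1L)
  obj[valid] <- log(cp[valid]) + ch[valid] / cp[valid] +
    log(1 - cp[valid]) + (htot - ch[valid]) / (1 - cp[valid])
  tie_median(which(obj == max(obj)))
}

# Tsai moment-preserving criterion: minimise the third-moment error of the
# two-level image whose levels match moments 1 and 2 exactly
moments_threshold_index <- function(p, z) {
  n <- length(p)
  m1 <- sum(p * z)
  m2 <- sum(p * z^2)
  m3 <- sum(p * z^3)
  v <- m2 - m1^2
  if (v <= 0) stop("degenerate histogram: zero gray-level variance")
  q0 <- cumsum(p)[-n]
  q1 <- 1 - q0
  valid <- q0 > 0 & q1 > 0
  err <- rep(Inf, n - 1L)
  a <- m1 - sqrt(v * q1[valid] / q0[valid])
  b <- m1 + sqrt(v * q0[valid] / q1[valid])
  err[valid] <- (q0[valid] * a^3 + q1[valid] * b^3 - m3)^2
  tie_median(which(err == min(err)))
}
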