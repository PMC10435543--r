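#' Total dendritic arbor length
#'
#' Sum of 3-D Euclidean lengths over all parent-child segments of the arbor,
#' soma-to-child segments included.
#'
#' @param arbor A [neuron_arbor()].
#' @return Length in micrometres.
#' @export
total_dendritic_length <- function(arbor) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  sum(arbor_edge_lengths(arbor))
}

#' Count dendritic branch tips
#'
#' Number of non-soma nodes with no children. A soma-only arbor has zero tips.
#'
#' @param arbor A [neuron_arbor()].
#' @return Integer tip count.
#' @export
count_branch_tips <- function(arbor) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  sum(arbor_child_counts(arbor) == 0L & arbor$label != "soma")
}

#' Sholl profile of a dendritic arbor
#'
#' Counts, for each radius, the crossings of the sphere of that radius centred
#' at the soma by the arbor's straight segments. Along a segment the distance
#' to the soma is the square root of a quadratic in the path parameter, so
#' crossings are counted exactly as the simple roots of that quadratic minus
#' the squared radius, within the segment; a segment that dips below a shell
#' and comes back out therefore counts twice, and a tangent touch counts zero.
#' Each root is attributed to the half-open parameter interval (0, 1] of its
#' segment so a crossing exactly at a shared node is counted once.
#'
#' @param arbor A [neuron_arbor()].
#' @param radii Strictly increasing positive radii in micrometres. The default
#'   10, 20, ..., 200 um spans typical tectal arbor extents.
#' @param projected If `TRUE`, use 2-D distances in the xy plane (z ignored)
#'   instead of the default 3-D distances.
#' @return A `sholl_profile`: data frame with columns `radius` and `crossings`.
#' @export
sholl_profile <- function(arbor, radii = seq(10, 200, by = 10),
                          projected = FALSE) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  if (length(radii) == 0L) stop("radii must be non-empty")
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("radii must be positive and strictly increasing")
  }
  root <- arbor_root_index(arbor)
  centre <- c(arbor$x[root], arbor$y[root], arbor$z[root])
  pidx <- match(arbor$parent_id, arbor$node_id)
  has <- which(!is.na(pidx))
  # segment from parent (P1) to node (P2), relative to the soma
  p1 <- cbind(arbor$x[pidx[has]] - centre[1],
              arbor$y[pidx[has]] - centre[2],
              arbor$z[pidx[has]] - centre[3])
  p2 <- cbind(arbor$x[has] - centre[1],
              arbor$y[has] - centre[2],
              arbor$z[has] - centre[3])
  if (projected) {
    p1[, 3] <- 0
    p2[, 3] <- 0
  }
  v <- p2 - p1
  a <- rowSums(v * v)
  b <- 2 * rowSums(p1 * v)
  c0 <- rowSums(p1 * p1)
  crossings <- vapply(radii, function(r) {
    cc <- c0 - r^2
    n <- 0L
    # quadratic segments
    quad <- a > 0
    disc <- b^2 - 4 * a * cc
    ok <- quad & disc > 0
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- (-b[ok] - sq) / (2 * a[ok])
      t2 <- (-b[ok] + sq) / (2 * a[ok])
      n <- n + sum(t1 > 0 & t1 <= 1) + sum(t2 > 0 & t2 <= 1)
    }
    # zero-length segments cannot cross; tangency (disc == 0) counts zero
    as.integer(n)
  }, integer(1))
  structure(data.frame(radius = radii, crossings = crossings),
            class = c("sholl_profile", "data.frame"))
}

#' Classify arbor maturity by total length
#'
#' Arbors with total dendritic length below the threshold are immature; the
#' boundary itself belongs to the mature class (a 500 um arbor is mature).
#'
#' @param arbor A [neuron_arbor()].
#' @param threshold Maturity cut in micrometres (default 500).
#' @return A `maturity_class` list with elements `value` (`"immature"` or
#'   `"mature"`), `threshold`, and `total_length`.
#' @export
classify_maturity <- function(arbor, threshold = 500) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive length in um")
  }
  len <- total_dendritic_length(arbor)
  structure(list(value = if (len < threshold) "immature" else "mature",
                 threshold = threshold, total_length = len),
            class = "maturity_class")
}

#' @export
print.maturity_class <- function(x, ...) {
  cat(sprintf("<maturity_class> %s (total length %.1f um, threshold %g um)\n",
              x$value, x$total_length, x$threshold))
  invisible(x)
}
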