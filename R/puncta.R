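#' Anatomical synapse density from a two-channel field
#'
#' Full counting pipeline for immunostained pre/postsynaptic marker fields:
#' each channel is background-subtracted (rolling ball), median filtered, and
#' binarised with the moment-preserving auto-threshold; the pixelwise AND of
#' the two masks marks colocalised (anatomical-synapse) pixels; connected
#' components within the 0.1-5.0 um^2 size criterion are counted.
#'
#' @param pre_channel,post_channel Registered intensity matrices of equal
#'   shape (e.g. presynaptic SV2 and postsynaptic GluA1).
#' @param pixel_size Micrometres per pixel (default 0.496).
#' @param ball_radius_px Rolling-ball radius in pixels (default 10).
#' @param median_radius_px Median-filter disk radius in pixels (default 2).
#' @param min_area,max_area Particle size criterion in um^2.
#' @param keep_masks If `TRUE`, the per-channel and AND masks are returned
#'   for audit.
#' @return A list with `count` (synapse count in the field),
#'   `density_per_um2`, `count_per_field` (count normalised to a standard
#'   20 x 20 um field), `field_area_um2`, and the retained `particles`.
#' @export
anatomical_synapse_density <- function(pre_channel, post_channel,
                                       pixel_size = 0.496,
                                       ball_radius_px = 10,
                                       median_radius_px = 2,
                                       min_area = 0.1, max_area = 5.0,
                                       keep_masks = FALSE) {
  if (!identical(dim(pre_channel), dim(post_channel))) {
    stop("channel shapes differ")
  }
  binarise <- function(img) {
    img <- rolling_ball_subtract(img, ball_radius_px)
    img <- median_filter(img, median_radius_px)
    img > auto_threshold(img, "moments")
  }
  mask_pre <- binarise(pre_channel)
  mask_post <- binarise(post_channel)
  coloc <- colocalization_mask(mask_pre, mask_post)
  ps <- find_particles(coloc, pixel_size, min_area, max_area)
  field_area <- prod(dim(pre_channel)) * pixel_size^2
  out <- list(count = ps$n,
              density_per_um2 = ps$n / field_area,
              count_per_field = ps$n / field_area * 400,
              field_area_um2 = field_area,
              particles = ps$particles)
  if (keep_masks) {
    out$masks <- list(pre = mask_pre, post = mask_post, coloc = coloc)
  }
  out
}

#' Synaptic puncta per dendritic volume from a two-channel z-stack
#'
#' Live-imaging pipeline: each slice of both channels is background-
#' subtracted and median filtered; a single threshold per channel is computed
#' from the whole preprocessed stack (maximum-entropy for the dendrite/
#' cytosolic channel, moment-preserving for the puncta channel). The
#' exclusion mask (somata, axons) is removed from the dendrite mask; puncta
#' are detected per slice within the dendrite mask using the particle size
#' criterion, and detections in adjacent slices whose pixel footprints
#' overlap are merged and counted once. Density is the merged punctum count
#' divided by the dendrite mask volume.
#'
#' @param dendrite_channel,puncta_channel 3-D arrays (rows x cols x slices)
#'   of equal shape (e.g. dsRed cell fill and PSD95-GFP).
#' @param pixel_size Micrometres per pixel in x/y (default 0.496).
#' @param z_step Micrometres between slices (default 1).
#' @param exclusion_mask Optional logical array, same shape, marking regions
#'   (soma, axon) excluded from the dendritic mask.
#' @param ball_radius_px,median_radius_px Preprocessing radii in pixels.
#' @param min_area,max_area Per-slice particle size criterion in um^2.
#' @param merge_slices If `FALSE`, per-slice counting without 3-D merging.
#' @return A list with `count`, `density_per_um3`, `dendrite_volume_um3`,
#'   and `per_slice` (detected particle count per slice before merging).
#' @export
dendritic_puncta_density <- function(dendrite_channel, puncta_channel,
                                     pixel_size = 0.496, z_step = 1,
                                     exclusion_mask = NULL,
                                     ball_radius_px = 10,
                                     median_radius_px = 2,
                                     min_area = 0.1, max_area = 5.0,
                                     merge_slices = TRUE) {
  if (!identical(dim(dendrite_channel), dim(puncta_channel))) {
    stop("channel stack shapes differ")
  }
  if (length(dim(dendrite_channel)) != 3L) stop("stacks must be 3-D arrays")
  if (z_step <= 0) stop("z_step must be positive")
  nz <- dim(dendrite_channel)[3]
  pre <- function(stack) {
    out <- stack
    for (z in seq_len(nz)) {
      sl <- rolling_ball_subtract(stack[, , z], ball_radius_px)
      out[, , z] <- median_filter(sl, median_radius_px)
    }
    out
  }
  dend <- pre(dendrite_channel)
  punc <- pre(puncta_channel)
  t_dend <- auto_threshold(dend, "maxentropy")
  t_punc <- auto_threshold(punc, "moments")
  dend_mask <- dend > t_dend
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(dendrite_channel))) {
      stop("exclusion mask shape differs from the stacks")
    }
    dend_mask <- dend_mask & !exclusion_mask
  }
  if (!any(dend_mask)) stop("dendrite mask is empty after thresholding")
  cand <- (punc > t_punc) & dend_mask
  per_slice <- vector("list", nz)
  for (z in seq_len(nz)) {
    ps <- find_particles(cand[, , z, drop = TRUE], pixel_size,
                         min_area, max_area)
    foot <- lapply(ps$kept_ids, function(id) which(ps$labels == id))
    per_slice[[z]] <- foot
  }
  counts <- vapply(per_slice, length, integer(1))
  if (merge_slices) {
    n <- merge_count_3d(per_slice)
  } else {
    n <- sum(counts)
  }
  vol <- sum(dend_mask) * pixel_size^2 * z_step
  list(count = n, density_per_um3 = n / vol, dendrite_volume_um3 = vol,
       per_slice = counts)
}

# union-find merge of per-slice particle footprints that overlap in pixel
# position between adjacent slices; returns the merged component count
merge_count_3d <- function(per_slice) {
  sizes <- vapply(per_slice, length, integer(1))
  total <- sum(sizes)
  if (total == 0L) return(0L)
  offset <- cumsum(c(0L, sizes[-length(sizes)]))
  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (z in seq_along(per_slice)[-1]) {
    for (a in seq_along(per_slice[[z]])) {
      for (b in seq_along(per_slice[[z - 1L]])) {
        if (length(intersect(per_slice[[z]][[a]],
                             per_slice[[z - 1L]][[b]])) > 0L) {
          ra <- find(offset[z] + a)
          rb <- find(offset[z - 1L] + b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  length(unique(vapply(seq_len(total), find, integer(1))))
}
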