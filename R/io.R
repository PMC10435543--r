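#' Read and write intensity images as TIFF
#'
#' Thin wrappers around the tiff package. Intensities are stored as 16-bit
#' samples scaled by `scale` (so the default round-trips integer intensities
#' up to 65535 exactly); multi-slice arrays become multi-page TIFFs.
#'
#' @param path File path.
#' @param scale Intensity corresponding to the maximal sample value.
#' @return `read_image_stack()` returns a matrix (single page) or a
#'   rows x cols x pages array; `write_image_stack()` returns `path`
#'   invisibly.
#' @export
read_image_stack <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples
    p * scale
  })
  if (length(pages) == 1L) return(pages[[1]])
  arr <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' @param image Numeric matrix or 3-D array of non-negative intensities.
#' @rdname read_image_stack
#' @export
write_image_stack <- function(image, path, scale = 65535) {
  clip <- function(m) pmin(pmax(m / scale, 0), 1)
  if (is.matrix(image)) {
    tiff::writeTIFF(clip(image), path, bits.per.sample = 16)
  } else {
    stopifnot(length(dim(image)) == 3L)
    pages <- lapply(seq_len(dim(image)[3]),
                    function(k) clip(image[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' Write or read an arbor time series as SWC files plus a JSON sidecar
#'
#' Each timepoint is written as `timepoint_<k>.swc`; `series.json` records
#' the imaging interval and the mapping from each timepoint's leaf nodes to
#' persistent process identities.
#'
#' @param series An `arbor_series` (see [generate_arbor_series()]).
#' @param dir Directory to write into (created if needed).
#' @return `write_arbor_series()` returns `dir` invisibly;
#'   `read_arbor_series()` returns the reconstructed `arbor_series`.
#' @export
write_arbor_series <- function(series, dir) {
  stopifnot(inherits(series, "arbor_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nt <- length(series$timepoints)
  files <- sprintf("timepoint_%03d.swc", seq_len(nt))
  id_maps <- vector("list", nt)
  for (k in seq_len(nt)) {
    a <- series$timepoints[[k]]
    write_morphology(a, file.path(dir, files[k]))
    if ("process_id" %in% names(a)) {
      keep <- !is.na(a$process_id)
      id_maps[[k]] <- data.frame(node_id = a$node_id[keep],
                                 process_id = a$process_id[keep])
    } else {
      id_maps[[k]] <- data.frame(node_id = integer(0),
                                 process_id = integer(0))
    }
  }
  jsonlite::write_json(
    list(interval_minutes = series$interval_minutes, files = files,
         process_ids = id_maps),
    file.path(dir, "series.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_arbor_series
#' @export
read_arbor_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  timepoints <- lapply(seq_along(meta$files), function(k) {
    a <- read_morphology(file.path(dir, meta$files[k]))
    map <- meta$process_ids[[k]]
    pid <- rep(NA_integer_, nrow(a))
    if (length(map) > 0 && nrow(map) > 0) {
      pid[match(map$node_id, a$node_id)] <- as.integer(map$process_id)
    }
    a$process_id <- pid
    neuron_arbor(a)
  })
  structure(list(timepoints = timepoints,
                 interval_minutes = meta$interval_minutes),
            class = "arbor_series")
}
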