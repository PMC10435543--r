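#' Construct a neuron arbor from a node table
#'
#' A `neuron_arbor` is a rooted tree of 3-D points in micrometres: one
#' parentless soma node plus dendrite nodes, each connected to its parent by a
#' straight segment. It is the unit of all morphometric analysis.
#'
#' @param nodes Data frame with columns `node_id` (unique integer),
#'   `parent_id` (integer, `NA` for the root), `x`, `y`, `z` (micrometres),
#'   `label` (`"soma"` or `"dendrite"`). Optional columns `radius` (um) and
#'   `process_id` (persistent terminal-process identity, used by the dynamics
#'   module) are carried along.
#' @return A `neuron_arbor` object (a validated data frame).
#' @examples
#' a <- neuron_arbor(data.frame(
#'   node_id = 1:2, parent_id = c(NA, 1),
#'   x = c(0, 30), y = c(0, 40), z = c(0, 0),
#'   label = c("soma", "dendrite")))
#' total_dendritic_length(a) # 50
#' @export
neuron_arbor <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  required <- c("node_id", "parent_id", "x", "y", "z", "label")
  missing <- setdiff(required, names(nodes))
  if (length(missing) > 0L) {
    stop("arbor node table lacks column(s): ", paste(missing, collapse = ", "))
  }
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  validate_arbor_nodes(nodes)
  structure(nodes, class = c("neuron_arbor", "data.frame"))
}

validate_arbor_nodes <- function(nodes) {
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id in arbor: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  }
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1L) {
    stop("arbor must have exactly one parentless (soma) node, found ",
         length(roots))
  }
  if (nodes$label[roots] != "soma") {
    stop("the parentless root node must be labelled 'soma'")
  }
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("arbor coordinates must all be finite")
  nonroot <- nodes$parent_id[!is.na(nodes$parent_id)]
  bad <- setdiff(nonroot, nodes$node_id)
  if (length(bad) > 0L) {
    stop("parent id(s) not defined as nodes: ", paste(bad, collapse = ", "))
  }
  # every node must reach the root (catches cycles among non-root nodes)
  known <- nodes$node_id[roots]
  repeat {
    add <- nodes$node_id[!is.na(nodes$parent_id) &
                           nodes$parent_id %in% known &
                           !(nodes$node_id %in% known)]
    if (length(add) == 0L) break
    known <- c(known, add)
  }
  if (length(known) < nrow(nodes)) {
    stop("arbor contains a cycle or disconnected nodes (ids: ",
         paste(setdiff(nodes$node_id, known), collapse = ", "), ")")
  }
  invisible(nodes)
}

#' @export
print.neuron_arbor <- function(x, ...) {
  cat(sprintf("<neuron_arbor> %d nodes, %d tips, total length %.2f um\n",
              nrow(x), count_branch_tips(x), total_dendritic_length(x)))
  invisible(x)
}

arbor_root_index <- function(arbor) which(is.na(arbor$parent_id))

# number of children per node, aligned with arbor rows
arbor_child_counts <- function(arbor) {
  idx <- match(arbor$parent_id, arbor$node_id)
  counts <- integer(nrow(arbor))
  tab <- table(idx[!is.na(idx)])
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

# length of the segment from each node to its parent (0 for the root)
arbor_edge_lengths <- function(arbor) {
  pidx <- match(arbor$parent_id, arbor$node_id)
  len <- numeric(nrow(arbor))
  has <- !is.na(pidx)
  dx <- arbor$x[has] - arbor$x[pidx[has]]
  dy <- arbor$y[has] - arbor$y[pidx[has]]
  dz <- arbor$z[has] - arbor$z[pidx[has]]
  len[has] <- sqrt(dx^2 + dy^2 + dz^2)
  len
}

#' Read a neuron reconstruction from an SWC file
#'
#' Parses the 7-column SWC dialect (`id type x y z radius parent`, one node
#' per line, `#` comments). Type 1 is mapped to `"soma"`, everything else to
#' `"dendrite"`; parent `-1` marks the root. Coordinates are in micrometres.
#'
#' @param path Path to an SWC text file.
#' @return A [neuron_arbor()].
#' @export
read_morphology <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no node lines found in ", path)
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 7L) {
      stop("malformed SWC line ", i, " in ", path,
           " (expected 7 fields, got ", length(fields), ")")
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop("non-numeric field on SWC line ", i, " in ", path)
    vals
  })
  m <- do.call(rbind, rows)
  parent <- as.integer(m[, 7L])
  parent[parent == -1L] <- NA_integer_
  nodes <- data.frame(
    node_id = as.integer(m[, 1L]),
    parent_id = parent,
    x = m[, 3L], y = m[, 4L], z = m[, 5L],
    label = ifelse(as.integer(m[, 2L]) == 1L, "soma", "dendrite"),
    radius = m[, 6L],
    stringsAsFactors = FALSE
  )
  neuron_arbor(nodes)
}

#' Write a neuron arbor to an SWC file
#'
#' Inverse of [read_morphology()]: coordinates are written with 17 significant
#' digits so that read-write-read round trips preserve the node table exactly.
#'
#' @param arbor A [neuron_arbor()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_morphology <- function(arbor, path) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  radius <- if ("radius" %in% names(arbor)) arbor$radius else rep(0.5, nrow(arbor))
  parent <- ifelse(is.na(arbor$parent_id), -1L, arbor$parent_id)
  type <- ifelse(arbor$label == "soma", 1L, 3L)
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   arbor$node_id, type, arbor$x, arbor$y, arbor$z,
                   radius, parent)
  writeLines(c("# SWC written by tectoquant", lines), path)
  invisible(path)
}
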