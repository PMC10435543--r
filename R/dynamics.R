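#' Classify terminal processes as filopodia or branches
#'
#' A terminal dendritic process shorter than the threshold is a filopodium;
#' a process at or above the threshold is a branch (a process of exactly
#' 10 um is a branch).
#'
#' @param length Process length(s) in micrometres (vectorised).
#' @param threshold Class boundary in micrometres (default 10).
#' @return Character vector, `"filopodium"` or `"branch"`.
#' @export
classify_process <- function(length, threshold = 10) {
  if (any(length < 0)) stop("process length must be non-negative")
  ifelse(length < threshold, "filopodium", "branch")
}

#' Extract terminal processes from an arbor
#'
#' One process per leaf: the path from the leaf back to the nearest ancestor
#' that is a branch point (more than one child) or the soma, with length
#' measured along that path. If the node table carries a `process_id` column
#' the leaf's value is used as the persistent identity; otherwise the leaf's
#' `node_id` is used.
#'
#' @param arbor A [neuron_arbor()].
#' @param threshold Filopodium/branch boundary passed to [classify_process()].
#' @return Data frame with columns `process_id`, `leaf_id`, `length_um`,
#'   `class`; zero rows for a soma-only arbor.
#' @export
extract_terminal_processes <- function(arbor, threshold = 10) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  nchild <- arbor_child_counts(arbor)
  elen <- arbor_edge_lengths(arbor)
  pidx <- match(arbor$parent_id, arbor$node_id)
  leaves <- which(nchild == 0L & arbor$label != "soma")
  if (length(leaves) == 0L) {
    return(data.frame(process_id = integer(0), leaf_id = integer(0),
                      length_um = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  lengths <- vapply(leaves, function(i) {
    len <- 0
    while (TRUE) {
      len <- len + elen[i]
      i <- pidx[i]
      if (is.na(i) || arbor$label[i] == "soma" || nchild[i] > 1L) break
    }
    len
  }, numeric(1))
  ids <- if ("process_id" %in% names(arbor)) {
    pid <- arbor$process_id[leaves]
    ifelse(is.na(pid), arbor$node_id[leaves], pid)
  } else {
    arbor$node_id[leaves]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate process identities within a timepoint: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(process_id = as.integer(ids),
             leaf_id = arbor$node_id[leaves],
             length_um = lengths,
             class = classify_process(lengths, threshold),
             stringsAsFactors = FALSE)
}

#' Compare terminal processes between two timepoints
#'
#' Matches terminal processes by their persistent identities. Identities only
#' present in the later arbor are additions, identities only in the earlier
#' arbor are losses, and shared identities report their signed length change.
#'
#' @param earlier,later [neuron_arbor()]s carrying persistent process
#'   identities (or data frames as returned by
#'   [extract_terminal_processes()]).
#' @param threshold Filopodium/branch boundary in micrometres.
#' @return List with data frames `added` (`process_id`, `length_um`, `class`),
#'   `lost` (idem), and `shared` (`process_id`, `length_earlier`,
#'   `length_later`, `delta_length`, `class` taken from the earlier length).
#' @export
diff_arbors <- function(earlier, later, threshold = 10) {
  pe <- if (inherits(earlier, "neuron_arbor")) {
    extract_terminal_processes(earlier, threshold)
  } else earlier
  pl <- if (inherits(later, "neuron_arbor")) {
    extract_terminal_processes(later, threshold)
  } else later
  if (anyDuplicated(pe$process_id) || anyDuplicated(pl$process_id)) {
    stop("duplicate process identities within a timepoint")
  }
  added <- pl[!(pl$process_id %in% pe$process_id), , drop = FALSE]
  lost <- pe[!(pe$process_id %in% pl$process_id), , drop = FALSE]
  shared_ids <- intersect(pe$process_id, pl$process_id)
  ie <- match(shared_ids, pe$process_id)
  il <- match(shared_ids, pl$process_id)
  shared <- data.frame(
    process_id = shared_ids,
    length_earlier = pe$length_um[ie],
    length_later = pl$length_um[il],
    delta_length = pl$length_um[il] - pe$length_um[ie],
    class = pe$class[ie],   # delta attributed to the earlier timepoint's class
    stringsAsFactors = FALSE
  )
  list(
    added = data.frame(process_id = added$process_id,
                       length_um = added$length_um, class = added$class,
                       stringsAsFactors = FALSE),
    lost = data.frame(process_id = lost$process_id,
                      length_um = lost$length_um, class = lost$class,
                      stringsAsFactors = FALSE),
    shared = shared
  )
}

#' Summarise terminal-process dynamics over a time series
#'
#' Aggregates, separately for filopodia (< 10 um) and branches (>= 10 um):
#' numbers of processes added and lost over all intervals, total elongation
#' (sum of positive length changes) and retraction (sum of absolute negative
#' changes), motility per interval (sum of absolute length changes), and mean
#' density (processes per micrometre of arbor, averaged over timepoints).
#' A length change is attributed to the class the process had at the earlier
#' timepoint; an added process is classified by its first observed length and
#' a lost process by its last.
#'
#' @param series An `arbor_series` (see [generate_arbor_series()]) or a plain
#'   list of [neuron_arbor()]s sharing process identities.
#' @param threshold Filopodium/branch boundary in micrometres.
#' @return A `dynamics_summary`: list with `per_class` (data frame of counts,
#'   totals, and mean density per class), `motility` (class x interval matrix
#'   of um moved), `n_timepoints`, and `interval_minutes`.
#' @export
summarize_dynamics <- function(series, threshold = 10) {
  timepoints <- if (inherits(series, "arbor_series")) series$timepoints else series
  interval_minutes <- if (inherits(series, "arbor_series")) {
    series$interval_minutes
  } else NA_real_
  nt <- length(timepoints)
  if (nt < 2L) stop("a dynamics series needs at least 2 timepoints")
  procs <- lapply(timepoints, extract_terminal_processes, threshold = threshold)
  total_len <- vapply(timepoints, total_dendritic_length, numeric(1))
  classes <- c("filopodium", "branch")
  zero <- stats::setNames(numeric(2), classes)
  n_added <- n_lost <- elong <- retr <- zero
  motility <- matrix(0, nrow = 2, ncol = nt - 1L,
                     dimnames = list(classes, NULL))
  for (k in seq_len(nt - 1L)) {
    d <- diff_arbors(procs[[k]], procs[[k + 1L]], threshold)
    for (cl in classes) {
      n_added[cl] <- n_added[cl] + sum(d$added$class == cl)
      n_lost[cl] <- n_lost[cl] + sum(d$lost$class == cl)
      del <- d$shared$delta_length[d$shared$class == cl]
      elong[cl] <- elong[cl] + sum(del[del > 0])
      retr[cl] <- retr[cl] + sum(-del[del < 0])
      motility[cl, k] <- sum(abs(del))
    }
  }
  density <- vapply(classes, function(cl) {
    mean(vapply(seq_len(nt), function(t) {
      if (total_len[t] <= 0) stop("zero-length arbor at timepoint ", t)
      sum(procs[[t]]$class == cl) / total_len[t]
    }, numeric(1)))
  }, numeric(1))
  per_class <- data.frame(
    class = classes,
    n_added = as.integer(n_added),
    n_lost = as.integer(n_lost),
    total_elongation = unname(elong),
    total_retraction = unname(retr),
    mean_density = unname(density),
    stringsAsFactors = FALSE
  )
  structure(list(per_class = per_class, motility = motility,
                 n_timepoints = nt, interval_minutes = interval_minutes),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("<dynamics_summary> %d timepoints (interval %s min)\n",
              x$n_timepoints,
              if (is.na(x$interval_minutes)) "?" else x$interval_minutes))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Density of terminal processes per unit arbor length
#'
#' Number of filopodia and branches divided by total dendritic arbor length.
#'
#' @param arbor A [neuron_arbor()].
#' @param threshold Filopodium/branch boundary in micrometres.
#' @return Named numeric vector `c(filopodia_per_um, branches_per_um)`.
#' @export
process_density <- function(arbor, threshold = 10) {
  len <- total_dendritic_length(arbor)
  if (len <= 0) stop("process density undefined for a zero-length arbor")
  p <- extract_terminal_processes(arbor, threshold)
  c(filopodia_per_um = sum(p$class == "filopodium") / len,
    branches_per_um = sum(p$class == "branch") / len)
}
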