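#' Build the epoch design table of the block paradigm
#'
#' One row per acquired volume, assigning it to a (condition, iteration)
#' cell. Iterations are outermost; within an iteration the conditions run in
#' their given order, each occupying `volumes_per_epoch` consecutive
#' volumes. Volume indices are 0-based (the on-disk TSV schema is explicit
#' per volume, so no indexing convention leaks to the user).
#'
#' @param conditions Ordered condition names.
#' @param n_iterations Number of task iterations.
#' @param volumes_per_epoch Volumes per (condition, iteration) epoch.
#' @return A data frame with columns `volume_index` (0-based), `condition`,
#'   `iteration` (1-based).
#' @export
epoch_design <- function(conditions = c("Encoding", "PostEncodingRest",
                                        "Retrieval", "PostRetrievalRest"),
                         n_iterations = 8L,
                         volumes_per_epoch = 9L) {
  grid <- expand.grid(condition = conditions,
                      iteration = seq_len(n_iterations),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- data.frame(
    volume_index = seq_len(nrow(grid) * volumes_per_epoch) - 1L,
    condition = rep(grid$condition, each = volumes_per_epoch),
    iteration = rep(as.integer(grid$iteration), each = volumes_per_epoch),
    stringsAsFactors = FALSE
  )
  validate_epoch_design(design)
}

#' Validate an epoch design table
#'
#' Every volume index `0 .. V-1` must be assigned exactly once and every
#' (condition, iteration) cell must contain the same number (>= 2) of
#' volumes.
#'
#' @param design A design data frame (`volume_index`, `condition`,
#'   `iteration`).
#' @return The design, invisibly unchanged, or an error naming the problem.
#' @export
validate_epoch_design <- function(design) {
  need <- c("volume_index", "condition", "iteration")
  if (!all(need %in% names(design))) {
    stop("design error: design table needs columns volume_index, condition, iteration",
         call. = FALSE)
  }
  v <- sort(design$volume_index)
  if (!identical(as.integer(v), seq_len(nrow(design)) - 1L)) {
    stop("design error: volume_index must cover 0..V-1 exactly once",
         call. = FALSE)
  }
  sizes <- table(design$condition, design$iteration)
  if (any(sizes == 0)) {
    bad <- which(sizes == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("design error: missing cell (condition %s, iteration %s)",
                 rownames(sizes)[bad[1]], colnames(sizes)[bad[2]]),
         call. = FALSE)
  }
  if (length(unique(as.vector(sizes))) != 1L) {
    stop("design error: all (condition, iteration) cells must have the same number of volumes",
         call. = FALSE)
  }
  if (sizes[1] < 2L) {
    stop("design error: each epoch must contain >= 2 volumes", call. = FALSE)
  }
  design
}

#' Cut a parcellated time series into (condition, iteration) windows
#'
#' Windows are the contiguous volume slices the design assigns to each cell,
#' optionally shifted forward by `lag_volumes` to account for hemodynamic
#' lag. At lag 0 the windows partition the acquisition exactly.
#'
#' @param x Regions x volumes numeric matrix; it may extend beyond the
#'   design's last volume (trailing volumes accommodate a positive lag).
#' @param design Epoch design table (see [epoch_design()]).
#' @param lag_volumes Non-negative forward shift, in volumes (default 0).
#'   On a series the design covers exactly, any positive lag pushes the
#'   final window out of bounds and is an error.
#' @return A named list (one entry per (condition, iteration) cell, keyed
#'   `"<condition>#<iteration>"`) of regions x window matrices, with
#'   attributes `conditions` and `iterations`.
#' @export
segment_epochs <- function(x, design, lag_volumes = 0L) {
  design <- validate_epoch_design(design)
  if (anyNA(x)) stop("time series contains missing values", call. = FALSE)
  if (ncol(x) < nrow(design)) {
    stop(sprintf("design error: design covers %d volumes but series has only %d",
                 nrow(design), ncol(x)), call. = FALSE)
  }
  if (lag_volumes < 0) {
    stop("design error: lag_volumes must be >= 0", call. = FALSE)
  }
  conditions <- unique(design$condition)
  iterations <- sort(unique(design$iteration))
  out <- list()
  for (iter in iterations) {
    for (cond in conditions) {
      vols <- design$volume_index[design$condition == cond &
                                  design$iteration == iter]
      idx <- sort(vols) + 1L + as.integer(lag_volumes)
      if (max(idx) > ncol(x)) {
        stop(sprintf(paste0("design error: lag of %d volumes pushes window ",
                            "(condition %s, iteration %d) out of bounds"),
                     as.integer(lag_volumes), cond, iter), call. = FALSE)
      }
      out[[cell_key(cond, iter)]] <- x[, idx, drop = FALSE]
    }
  }
  attr(out, "conditions") <- conditions
  attr(out, "iterations") <- iterations
  out
}

#' Percent signal change of every region
#'
#' Re-expresses each region's signal as percent change over that region's
#' mean across the entire acquisition:
#' `psc[r, t] = 100 * (x[r, t] - mean_r) / mean_r`. Each region's percent
#' series therefore has mean zero, and the transform is invariant to
#' positive rescaling of the raw series.
#'
#' @param x Regions x volumes numeric matrix with nonzero region means.
#' @return A matrix of the same shape, in percent units.
#' @export
percent_signal_change <- function(x) {
  if (anyNA(x)) stop("time series contains missing values", call. = FALSE)
  m <- rowMeans(x)
  bad <- which(m == 0)
  if (length(bad)) {
    lab <- rownames(x)[bad[1]] %||% as.character(bad[1])
    stop(sprintf("degenerate signal: region %s has zero acquisition-wide mean",
                 lab), call. = FALSE)
  }
  100 * sweep(sweep(x, 1, m, "-"), 1, m, "/")
}

#' Epoch-mean percent-signal-change trajectories
#'
#' Averages the percent-signal-change matrix within each (condition,
#' iteration) window, yielding for every region x condition an ordered
#' trajectory across iterations (the signal-amplitude analogue of the
#' betweenness-rank trajectories).
#'
#' @param psc Regions x volumes percent-signal-change matrix (see
#'   [percent_signal_change()]).
#' @param design Epoch design table.
#' @param lag_volumes Forward window shift in volumes.
#' @return A tibble with columns `region`, `condition`, `iteration`,
#'   `mean_psc`.
#' @export
epoch_mean_psc <- function(psc, design, lag_volumes = 0L) {
  seg <- segment_epochs(psc, design, lag_volumes)
  regions <- rownames(psc) %||% sprintf("R%03d", seq_len(nrow(psc)))
  rows <- lapply(names(seg), function(key) {
    parts <- strsplit(key, "#", fixed = TRUE)[[1]]
    tibble::tibble(region = regions,
                   condition = parts[1],
                   iteration = as.integer(parts[2]),
                   mean_psc = unname(rowMeans(seg[[key]])))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$region, .data$condition, .data$iteration)
}
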