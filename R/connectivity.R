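#' Full undirected weighted functional-connectivity graph for one epoch
#'
#' Computes the zero-lag Pearson correlation between every pair of regional
#' time series within one epoch window, Fisher-Z transforms it (`atanh`),
#' and returns the resulting symmetric weight matrix as a full,
#' unthresholded weighted graph: every one of the `n*(n-1)/2` unique edges
#' is retained (30,135 edges at 246 nodes). Correlations are clipped to
#' `[-r_clip, r_clip]` before the transform so that degenerate windows with
#' `|r| = 1` still yield finite (maximal) weights.
#'
#' @param window Regions x volumes numeric matrix (>= 3 volumes).
#' @param r_clip Clipping bound for correlations (default `1 - 1e-7`).
#' @param condition,iteration,participant_id Optional epoch metadata carried
#'   on the graph.
#' @return An object of class `"ufc_graph"`: a list with `weights` (the
#'   symmetric n x n Fisher-Z matrix, diagonal set to 0 and excluded from
#'   all edge enumerations), `n_nodes`, and the metadata fields.
#' @export
compute_ufc <- function(window, r_clip = 1 - 1e-7,
                        condition = NA_character_,
                        iteration = NA_integer_,
                        participant_id = NA_character_) {
  if (!is.matrix(window) || !is.numeric(window)) {
    stop("window must be a numeric regions x volumes matrix", call. = FALSE)
  }
  if (ncol(window) < 3L) {
    stop("window must contain >= 3 volumes", call. = FALSE)
  }
  if (anyNA(window)) stop("window contains missing values", call. = FALSE)
  v <- apply(window, 1, stats::var)
  bad <- which(v == 0)
  if (length(bad)) {
    lab <- rownames(window)[bad[1]] %||% as.character(bad[1])
    stop(sprintf(paste0("degenerate window: region %s has zero variance ",
                        "(condition %s, iteration %s); correlation undefined"),
                 lab, condition, iteration), call. = FALSE)
  }
  r <- stats::cor(t(window))
  r <- pmin(pmax(r, -r_clip), r_clip)
  z <- atanh(r)
  z <- (z + t(z)) / 2  # enforce exact symmetry
  diag(z) <- 0
  dimnames(z) <- list(rownames(window), rownames(window))
  structure(list(weights = z,
                 n_nodes = nrow(window),
                 condition = condition,
                 iteration = iteration,
                 participant_id = participant_id),
            class = "ufc_graph")
}

#' Long-format edge table of a connectivity graph
#'
#' Enumerates the `n*(n-1)/2` unique (unordered) node pairs with their
#' Fisher-Z edge weights; the diagonal is excluded.
#'
#' @param g A `"ufc_graph"` (or a symmetric weight matrix).
#' @return A tibble with columns `node_i`, `node_j` (1-based, `i < j`) and
#'   `z`.
#' @export
edge_table <- function(g) {
  z <- as_weight_matrix(g)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  tibble::tibble(node_i = as.integer(ut[, 1]),
                 node_j = as.integer(ut[, 2]),
                 z = z[ut])
}

# Accept either a ufc_graph or a bare symmetric weight matrix.
as_weight_matrix <- function(g) {
  z <- if (inherits(g, "ufc_graph")) g$weights else g
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    stop("expected a ufc_graph or a square weight matrix", call. = FALSE)
  }
  if (!isTRUE(all.equal(z, t(z), tolerance = 0))) {
    stop("weight matrix must be exactly symmetric", call. = FALSE)
  }
  z
}

#' @export
print.ufc_graph <- function(x, ...) {
  n <- x$n_nodes
  cat(sprintf("uFC graph: %d nodes, %d unique edges (Fisher-Z weights)\n",
              n, n * (n - 1) / 2))
  if (!is.na(x$condition)) {
    cat(sprintf("  condition %s, iteration %s, participant %s\n",
                x$condition, x$iteration, x$participant_id))
  }
  invisible(x)
}
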