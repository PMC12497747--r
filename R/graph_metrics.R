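#' Convert Fisher-Z edge weights to path distances
#'
#' Stronger functional connections are treated as shorter paths, so edge
#' weights are inverted before any shortest-path computation. Dijkstra's
#' algorithm requires non-negative distances, which full Fisher-Z graphs do
#' not guarantee, so three policies are offered:
#'
#' * `exclude_nonpositive` (default): `d = 1/z` for `z > 0`; non-positive
#'   edges get distance `+Inf` (excluded from paths). Preserves the
#'   "stronger = shorter" ordering without sign gymnastics.
#' * `absolute`: `d = 1/|z|` (`z = 0` maps to `+Inf`) -- treats magnitude as
#'   coupling strength regardless of sign.
#' * `clip_epsilon`: `z` floored at `epsilon` then inverted -- keeps every
#'   edge at a large but finite distance.
#'
#' All finite outputs are strictly positive; the diagonal is 0.
#'
#' @param g A `"ufc_graph"` or symmetric weight matrix.
#' @param policy One of `"exclude_nonpositive"`, `"absolute"`,
#'   `"clip_epsilon"`.
#' @param epsilon Floor used by the `clip_epsilon` policy (default `1e-6`).
#' @return A symmetric n x n distance matrix (entries in `(0, Inf]`,
#'   diagonal 0).
#' @export
to_distances <- function(g, policy = c("exclude_nonpositive", "absolute",
                                       "clip_epsilon"),
                         epsilon = 1e-6) {
  policy <- match.arg(policy)
  z <- as_weight_matrix(g)
  d <- switch(policy,
    exclude_nonpositive = ifelse(z > 0, 1 / z, Inf),
    absolute = ifelse(z != 0, 1 / abs(z), Inf),
    clip_epsilon = 1 / pmax(z, epsilon)
  )
  diag(d) <- 0
  d
}

# igraph graph over the finite-distance edges, keeping all n vertices.
distance_igraph <- function(d) {
  a <- d
  a[!is.finite(a)] <- 0
  igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted betweenness centrality of every node
#'
#' For node `i`, betweenness is the normalized count of all-pairs shortest
#' paths passing through it:
#' `BC_i = 1/((n-1)(n-2)) * sum over ordered pairs (h, j), h != j, both
#' != i, of sp_hj(i)/sp_hj`, where `sp_hj` counts shortest paths between
#' `h` and `j` on the inverted-weight distances and `sp_hj(i)` counts those
#' with `i` interior. Pairs with no finite path contribute 0. Values lie in
#' `[0, 1]`; a star-graph center attains 1.
#'
#' Path computations delegate to igraph's weighted Brandes algorithm on the
#' finite-distance edge set.
#'
#' @inheritParams to_distances
#' @return Numeric vector of per-node betweenness values in `[0, 1]`.
#' @export
betweenness_weighted <- function(g, policy = "exclude_nonpositive",
                                 epsilon = 1e-6) {
  d <- to_distances(g, policy, epsilon)
  n <- nrow(d)
  if (n < 3L) {
    stop("betweenness normalization (n-1)(n-2) undefined for n < 3",
         call. = FALSE)
  }
  ig <- distance_igraph(d)
  b <- igraph::betweenness(ig, directed = FALSE,
                           weights = igraph::E(ig)$weight)
  # igraph sums over unordered pairs; Eq-style ordered-pair normalization
  # doubles the sum and the denominator, so the two agree via 2/((n-1)(n-2)).
  as.numeric(2 * b / ((n - 1) * (n - 2)))
}

#' Betweenness rank order of the nodes
#'
#' Orders nodes by betweenness from most to least central: rank 1 is the
#' highest-betweenness node; tied values receive the average of the ranks
#' they span. With `n` distinct values the ranks are exactly `1..n`.
#'
#' @param bc Numeric vector of betweenness values.
#' @return Numeric vector of ranks in `[1, n]` (fractional on ties).
#' @export
rank_order <- function(bc) {
  rank(-bc, ties.method = "average")
}

#' Average shortest path length of the graph
#'
#' Mean Dijkstra shortest-path length over all ordered node pairs on the
#' inverted-weight distances: `ASPL = 1/(n(n-1)) * sum d(v_i, v_j)`.
#' Smaller values indicate a more efficiently integrated network; scaling
#' every positive weight by `c` divides ASPL by exactly `c`. Pairs with no
#' finite connecting path are excluded from the average (their count is
#' reported via the `finite_pairs` attribute); a graph with no finite path
#' at all is an error.
#'
#' @inheritParams to_distances
#' @return A length-one numeric (the ASPL) with attribute `finite_pairs`,
#'   the number of ordered pairs with finite distance.
#' @export
aspl <- function(g, policy = "exclude_nonpositive", epsilon = 1e-6) {
  d <- to_distances(g, policy, epsilon)
  n <- nrow(d)
  if (n < 2L) stop("ASPL needs >= 2 nodes", call. = FALSE)
  ig <- distance_igraph(d)
  D <- igraph::distances(ig, weights = igraph::E(ig)$weight)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  if (!any(finite)) {
    stop("fully disconnected graph: no finite shortest path between any pair",
         call. = FALSE)
  }
  structure(mean(off[finite]), finite_pairs = sum(finite))
}
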