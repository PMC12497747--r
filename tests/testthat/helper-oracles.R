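# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths (and igraph): betweenness by exhaustive
# simple-path enumeration, ASPL by Floyd-Warshall, the weak-monotonicity
# rule by existential enumeration of the dropped constraint, and Fisher's
# exact p by direct hypergeometric enumeration.

# All simple paths h -> j over the finite entries of distance matrix d,
# with their total lengths.
enumerate_simple_paths <- function(d, h, j) {
  n <- nrow(d)
  paths <- list()
  rec <- function(path, len) {
    last <- path[length(path)]
    if (last == j) {
      paths[[length(paths) + 1L]] <<- list(path = path, len = len)
      return(invisible())
    }
    for (k in seq_len(n)) {
      if (k %in% path) next
      if (!is.finite(d[last, k])) next
      rec(c(path, k), len + d[last, k])
    }
  }
  rec(h, 0)
  paths
}

# Betweenness by brute force: count minimal-length simple paths per pair
# (ties detected with a relative tolerance) and tally interior nodes.
# Ordered-pair normalization 1/((n-1)(n-2)); each unordered pair counts
# twice.
bc_oracle <- function(d, rel_tol = 1e-12) {
  n <- nrow(d)
  bc <- numeric(n)
  for (h in seq_len(n - 1)) {
    for (j in seq(h + 1, n)) {
      ps <- enumerate_simple_paths(d, h, j)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      mn <- min(lens)
      shortest <- ps[lens <= mn * (1 + rel_tol)]
      sp <- length(shortest)
      interior <- unlist(lapply(shortest, function(p) {
        setdiff(p$path, c(h, j))
      }))
      if (length(interior)) {
        tab <- table(interior)
        idx <- as.integer(names(tab))
        bc[idx] <- bc[idx] + 2 * as.numeric(tab) / sp
      }
    }
  }
  bc / ((n - 1) * (n - 2))
}

# ASPL by Floyd-Warshall on the distance matrix; mean over finite ordered
# off-diagonal pairs.
fw_aspl <- function(d) {
  D <- d
  n <- nrow(D)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  off <- D[row(D) != col(D)]
  if (!any(is.finite(off))) return(NA_real_)
  mean(off[is.finite(off)])
}

# Literal restatement of the weak-monotonicity rule: a direction holds if
# there EXISTS a set of at most max_viol adjacent positions whose removal
# leaves every remaining adjacent weak inequality satisfied, and the
# endpoints strictly agree with the direction.
mono_oracle <- function(v, max_viol = 1L) {
  n <- length(v)
  pos <- seq_len(n - 1)
  dropped_sets <- list(integer(0))
  if (max_viol >= 1L) dropped_sets <- c(dropped_sets, as.list(pos))
  holds <- function(cmp, dropped) {
    all(vapply(pos, function(t) {
      t %in% dropped || cmp(v[t], v[t + 1])
    }, logical(1)))
  }
  inc <- v[n] > v[1] &&
    any(vapply(dropped_sets, function(s) holds(`<=`, s), logical(1)))
  dec <- v[n] < v[1] &&
    any(vapply(dropped_sets, function(s) holds(`>=`, s), logical(1)))
  if (inc) "increasing" else if (dec) "decreasing" else "none"
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (tables as or less probable than the observed
# one, the convention of stats::fisher.test).
fisher_oracle <- function(k_control, n_control, k_patient, n_patient) {
  k <- k_control + k_patient
  support <- max(0, k - n_patient):min(n_control, k)
  probs <- dhyper(support, n_control, n_patient, k)
  p_obs <- dhyper(k_control, n_control, n_patient, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random symmetric Fisher-Z weight matrix with a controllable fraction of
# negative edges (which the default distance policy excludes from paths).
random_z_graph <- function(n, p_neg = 0.2) {
  m <- n * (n - 1) / 2
  vals <- runif(m, 0.1, 2)
  neg <- runif(m) < p_neg
  neg[1] <- FALSE  # keep at least one positive edge so the graph has a path
  vals[neg] <- -runif(sum(neg), 0.05, 0.5)
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- vals
  z <- z + t(z)
  z
}

# Small quick cohort configuration used by several pipeline tests;
# named arguments override the toy defaults.
toy_cohort_config <- function(seed = 42L, ...) {
  args <- utils::modifyList(
    list(n_regions = 8, n_iterations = 8,
         conditions = c("Encoding", "Retrieval"),
         volumes_per_epoch = 9,
         n_participants_per_group = 3,
         base_coupling = 0.4, coupling_spread = 0.2,
         group_coupling_offset = 0.1, noise_sd = 0.4,
         seed = seed),
    list(...))
  do.call(synth_config, args)
}
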