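#' Classify a trajectory for weak monotonicity
#'
#' A length-`T` trajectory `D_1..D_T` is weakly monotone increasing if
#' `D_1 <= D_2 <= ... <= D_T` with `D_1 != D_T` (and symmetrically for
#' decreasing). The relaxed variant used here additionally permits up to
#' `max_violations` adjacent-step violations of the trend (default 1), where
#' a violation is a single adjacent strict inequality against the trend,
#' regardless of magnitude; ties between adjacent points count against
#' neither direction. The relaxed classifier keeps a net-trend requirement:
#' the claimed direction must agree with the endpoint inequality
#' (`D_T > D_1` for increasing, `D_T < D_1` for decreasing), which rules out
#' ambiguous sequences such as `(5,1,1,1,1,1,1,6)` being labeled by
#' violation count alone. Equal endpoints always classify as `"none"`.
#'
#' The verdict is invariant under any strictly increasing transform of the
#' values, and reversing the trajectory swaps increasing and decreasing.
#'
#' @param values Numeric trajectory (length >= 2).
#' @param max_violations Maximum adjacent-step violations tolerated
#'   (0 = the strict weak-monotonicity definition).
#' @return A list of class `"monotonicity_verdict"`: `direction`
#'   (`"increasing"`, `"decreasing"` or `"none"`), `n_violations` (count in
#'   the claimed direction; `NA` when direction is `"none"`), and `strict`
#'   (whether the zero-violation definition is also met).
#' @export
classify_monotonicity <- function(values, max_violations = 1L) {
  if (length(values) < 2L) {
    stop("trajectory must have length >= 2", call. = FALSE)
  }
  if (anyNA(values)) stop("trajectory contains missing values", call. = FALSE)
  d <- diff(values)
  inc_viol <- sum(d < 0)
  dec_viol <- sum(d > 0)
  first <- values[1]
  last <- values[length(values)]
  inc_ok <- inc_viol <= max_violations && last > first
  dec_ok <- dec_viol <= max_violations && last < first
  if (inc_ok) {
    verdict <- list(direction = "increasing", n_violations = inc_viol,
                    strict = inc_viol == 0L)
  } else if (dec_ok) {
    verdict <- list(direction = "decreasing", n_violations = dec_viol,
                    strict = dec_viol == 0L)
  } else {
    verdict <- list(direction = "none", n_violations = NA_integer_,
                    strict = FALSE)
  }
  structure(verdict, class = "monotonicity_verdict")
}

#' @export
print.monotonicity_verdict <- function(x, ...) {
  cat(sprintf("monotonicity: %s (%s violations%s)\n", x$direction,
              ifelse(is.na(x$n_violations), "-", x$n_violations),
              if (isTRUE(x$strict)) ", strict" else ""))
  invisible(x)
}

# Cache of full permutation matrices, keyed by n.
.perm_env <- new.env(parent = emptyenv())

# All n! permutations of 1..n as an n! x n integer matrix.
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_env[[key]])) return(.perm_env[[key]])
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]), deparse.level = 0)
    }))
  }
  p <- rec(seq_len(n))
  storage.mode(p) <- "integer"
  .perm_env[[key]] <- p
  p
}

#' Spearman trend test for a short trajectory, with exact permutation p
#'
#' Correlates the trajectory values (average-ranked) against the iteration
#' index `1..T` with Pearson's formula on ranks (Spearman's rho). A
#' perfectly monotone trajectory attains `rho = +1` (increasing) or `-1`
#' (decreasing); non-monotone trajectories shrink toward 0. Because eight
#' points are far from any large-sample regime, the two-sided p-value is
#' taken from the exact permutation distribution: the proportion of all
#' `T!` orderings of the observed values whose `|rho|` is at least
#' `|rho_obs|` (40,320 orderings at `T = 8`). A Monte-Carlo fallback is
#' provided for longer trajectories (and as an independent cross-check).
#'
#' @param values Numeric trajectory (3--9 points for exact mode; the series
#'   must not be entirely tied).
#' @param method `"exact"` (full enumeration, `T <= 9`) or `"montecarlo"`.
#' @param n_perm Number of random permutations for the Monte-Carlo method.
#' @return A list: `rho`, `p_value` (two-sided), `method`, and `n_used`
#'   (permutations evaluated).
#' @export
spearman_trend <- function(values, method = c("exact", "montecarlo"),
                           n_perm = 1e5) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 3L) stop("trend test needs >= 3 points", call. = FALSE)
  if (anyNA(values)) stop("trajectory contains missing values", call. = FALSE)
  r <- rank(values)  # average ranks on ties
  if (max(r) == min(r)) {
    stop("Spearman's rho undefined: all trajectory values are tied",
         call. = FALSE)
  }
  s <- seq_len(n)
  rc <- r - mean(r)
  sc <- s - mean(s)
  denom <- sqrt(sum(rc^2) * sum(sc^2))
  rho <- sum(rc * sc) / denom
  tol <- 1e-12
  if (method == "exact") {
    if (n > 9L) {
      stop("exact permutation mode supports up to 9 points; use method = 'montecarlo'",
           call. = FALSE)
    }
    P <- all_permutations(n)
    rho_all <- as.numeric(matrix(rc[P], nrow(P)) %*% sc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - tol)
    n_used <- nrow(P)
  } else {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      rho_b <- sum(rc[sample.int(n)] * sc) / denom
      if (abs(rho_b) >= abs(rho) - tol) hits <- hits + 1L
    }
    # add-one correction keeps the Monte-Carlo p valid (never exactly 0)
    p <- (hits + 1) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  list(rho = rho, p_value = p, method = method, n_used = n_used)
}
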