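#' Group-averaged betweenness-rank trajectories
#'
#' Averages per-participant betweenness rank orders across the participants
#' of each group, for every node, condition and iteration — ranks are
#' averaged directly (not re-ranked), following the order of operations of
#' the screening procedure.
#'
#' @param bc_table Long tibble with columns `participant`, `group`, `node`,
#'   `condition`, `iteration`, `bc_ro` (as produced by
#'   [compute_participant_metrics()]).
#' @return A tibble with columns `group`, `node`, `condition`, `iteration`,
#'   `mean_bc_ro`, ordered by group, node, condition, iteration.
#' @export
group_average_trajectories <- function(bc_table) {
  need <- c("participant", "group", "node", "condition", "iteration", "bc_ro")
  if (!all(need %in% names(bc_table))) {
    stop("schema error: bc_table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  # all participants must share one node set and design grid
  per_part <- dplyr::summarise(
    dplyr::group_by(bc_table, .data$participant),
    key = paste(sort(unique(.data$node)), collapse = ","),
    .groups = "drop")
  if (length(unique(per_part$key)) != 1L) {
    stop("schema error: participants do not share a common node set",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(bc_table, .data$group, .data$node, .data$condition,
                    .data$iteration),
    mean_bc_ro = mean(.data$bc_ro), .groups = "drop")
  dplyr::arrange(out, .data$group, .data$node, .data$condition,
                 .data$iteration)
}

#' Screen group trajectories for monotone trends
#'
#' Applies the exact-permutation Spearman trend test ([spearman_trend()]) to
#' every (group, node, condition) trajectory of group-averaged betweenness
#' ranks, flagging trajectories with `p < alpha` (uncorrected by default,
#' matching the screening procedure; a multiplicity adjustment can be
#' requested). Trajectories whose values are entirely tied have no defined
#' rho and are reported with `NA` and not flagged.
#'
#' @param trajectories Output of [group_average_trajectories()] (or any
#'   tibble with `group`, `node`, `condition`, `iteration` and a value
#'   column named `mean_bc_ro`).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @param method Trend-test method, `"exact"` or `"montecarlo"`.
#' @return A tibble with one row per (group, node, condition): `rho`,
#'   `p_value`, `direction` (sign of rho, `"none"` if not significant or
#'   undefined), `significant`.
#' @export
node_trend_screen <- function(trajectories, alpha = 0.05,
                              p_adjust = "none", method = "exact") {
  need <- c("group", "node", "condition", "iteration", "mean_bc_ro")
  if (!all(need %in% names(trajectories))) {
    stop("schema error: trajectories need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  trajectories <- dplyr::arrange(trajectories, .data$group, .data$node,
                                 .data$condition, .data$iteration)
  res <- dplyr::group_modify(
    dplyr::group_by(trajectories, .data$group, .data$node, .data$condition),
    function(df, key) {
      tr <- tryCatch(spearman_trend(df$mean_bc_ro, method = method),
                     error = function(e) NULL)
      if (is.null(tr)) {
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_))
      }
      tibble::tibble(rho = tr$rho, p_value = tr$p_value)
    })
  res <- dplyr::ungroup(res)
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res$direction <- ifelse(!res$significant | is.na(res$rho), "none",
                          ifelse(res$rho > 0, "increasing", "decreasing"))
  res
}

#' Recovery of planted trends by the group screen
#'
#' Compares screen calls against a ground-truth hub set: a hub counts as
#' recovered when its trajectory is flagged significant in the expected
#' direction; a non-hub counts as a false positive when flagged significant
#' in any direction.
#'
#' @param screen Output of [node_trend_screen()].
#' @param hub_nodes Integer vector of planted hub nodes (1-based).
#' @param expected_direction `"increasing"` or `"decreasing"`: the
#'   betweenness-rank direction the planted drift implies (positive coupling
#'   drift lowers the rank number of a hub, i.e. `"decreasing"`).
#' @return A list with `hub_rate`, `nonhub_rate`, `n_hub_tests`,
#'   `n_nonhub_tests`.
#' @export
trend_recovery <- function(screen, hub_nodes, expected_direction) {
  expected_direction <- match.arg(expected_direction,
                                  c("increasing", "decreasing"))
  is_hub <- screen$node %in% hub_nodes
  hub <- screen[is_hub, , drop = FALSE]
  nonhub <- screen[!is_hub, , drop = FALSE]
  list(
    hub_rate = if (nrow(hub)) mean(hub$significant &
                                   hub$direction == expected_direction) else NA_real_,
    nonhub_rate = if (nrow(nonhub)) mean(nonhub$significant) else NA_real_,
    n_hub_tests = nrow(hub),
    n_nonhub_tests = nrow(nonhub)
  )
}

#' Compare monotone proportions between groups (Fisher's exact test)
#'
#' Two-sided Fisher's exact test on the 2x2 table of monotone vs
#' non-monotone participants in the control and patient groups, from the
#' hypergeometric distribution with fixed margins.
#'
#' @param k_control,n_control Monotone count and group size for controls.
#' @param k_patient,n_patient Monotone count and group size for patients.
#' @return A list: `odds_ratio` (conditional MLE, as reported by
#'   [stats::fisher.test()]), `p_value` (two-sided), and the input `table`.
#' @export
monotonic_proportion_test <- function(k_control, n_control,
                                      k_patient, n_patient) {
  if (n_control <= 0 || n_patient <= 0) {
    stop("input error: group sizes must be positive", call. = FALSE)
  }
  if (k_control > n_control || k_patient > n_patient ||
      k_control < 0 || k_patient < 0) {
    stop("input error: monotone counts must lie in [0, n]", call. = FALSE)
  }
  tab <- matrix(c(k_control, n_control - k_control,
                  k_patient, n_patient - k_patient),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("control", "patient"),
                                monotone = c("yes", "no")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Three-way mixed ANOVA for average shortest path length
#'
#' Classical univariate mixed ANOVA of per-epoch ASPL with Group as the
#' between-subjects factor and Condition and Time (iteration) as
#' within-subjects factors, using the standard error strata
#' `Error(participant/(condition * time))` and no sphericity correction.
#' With `N` participants, `g` groups, `c` conditions and `t` iterations the
#' degrees of freedom are the textbook shapes: Time `(t-1, (t-1)(N-g))` and
#' Group `(g-1, N-g)` — e.g. `(7, 602)` and `(1, 86)` for `N = 88`, `g = 2`,
#' `t = 8`.
#'
#' @param data Long data frame with columns `participant`, `group`,
#'   `condition`, `iteration`, `aspl`; the design must be balanced (every
#'   participant contributes every (condition, iteration) cell exactly
#'   once). Unbalanced input is an error — no imputation is attempted.
#' @return A tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `F`, `p_value`. If the response is constant the F and p columns are
#'   `NA` and the result carries attribute `zero_variance = TRUE`.
#' @export
aspl_anova <- function(data) {
  need <- c("participant", "group", "condition", "iteration", "aspl")
  if (!all(need %in% names(data))) {
    stop("schema error: data needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    participant = factor(data$participant),
    group = factor(data$group),
    condition = factor(data$condition),
    time = factor(data$iteration),
    aspl = as.numeric(data$aspl)
  )
  if (anyNA(d$aspl)) stop("ASPL values contain missing entries", call. = FALSE)
  cells <- table(d$participant, d$condition, d$time)
  if (any(cells != 1L)) {
    stop(paste0("unbalanced design: every participant must contribute every ",
                "(condition, iteration) cell exactly once"), call. = FALSE)
  }
  gmap <- table(d$participant, d$group)
  if (any(rowSums(gmap > 0) != 1L)) {
    stop("each participant must belong to exactly one group", call. = FALSE)
  }
  effects <- c(group = "Group", condition = "Condition", time = "Time",
               `group:condition` = "Group:Condition",
               `group:time` = "Group:Time",
               `condition:time` = "Condition:Time",
               `group:condition:time` = "Group:Condition:Time")
  if (stats::var(d$aspl) == 0) {
    n <- nlevels(d$participant); g <- nlevels(d$group)
    nc <- nlevels(d$condition); nt <- nlevels(d$time)
    out <- tibble::tibble(
      effect = unname(effects),
      df_num = c(g - 1, nc - 1, nt - 1, (g - 1) * (nc - 1),
                 (g - 1) * (nt - 1), (nc - 1) * (nt - 1),
                 (g - 1) * (nc - 1) * (nt - 1)),
      df_den = c(n - g, (nc - 1) * (n - g), (nt - 1) * (n - g),
                 (nc - 1) * (n - g), (nt - 1) * (n - g),
                 (nc - 1) * (nt - 1) * (n - g),
                 (nc - 1) * (nt - 1) * (n - g)),
      F = NA_real_, p_value = NA_real_)
    attr(out, "zero_variance") <- TRUE
    warning("response has zero variance: all F statistics undefined",
            call. = FALSE)
    return(out)
  }
  fit <- stats::aov(aspl ~ group * condition * time +
                      Error(participant / (condition * time)), data = d)
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    nm <- trimws(rownames(tab))
    resid <- which(nm == "Residuals")
    if (!length(resid)) next
    df_den <- tab[resid, "Df"]
    for (k in seq_along(nm)) {
      if (nm[k] == "Residuals") next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = unname(effects[nm[k]]),
        df_num = tab[k, "Df"],
        df_den = df_den,
        F = tab[k, "F value"],
        p_value = tab[k, "Pr(>F)"])
    }
  }
  out <- dplyr::bind_rows(rows)
  out[match(effects, out$effect), ]
}

#' Per-group edge-weight distribution summaries
#'
#' Pools the Fisher-Z edge weights of all participants and epochs within
#' each (group, condition) cell and summarizes the pooled distribution:
#' count, mean, SD, deciles, and an ECDF evaluated on a common grid. A
#' lower-coupling group appears as a leftward shift of its distribution
#' (lower mean), which is the distributional counterpart of its longer
#' average shortest paths.
#'
#' @param edges Long tibble with columns `group`, `condition`, `z` (one row
#'   per edge observation).
#' @param grid_points Number of grid points for the pooled-range ECDF.
#' @return A list with `summary` (tibble: `group`, `condition`, `n`,
#'   `mean`, `sd`, `d10`..`d90`) and `ecdf` (tibble: `group`, `condition`,
#'   `z`, `F`).
#' @export
edge_weight_summary <- function(edges, grid_points = 101L) {
  need <- c("group", "condition", "z")
  if (!all(need %in% names(edges))) {
    stop("schema error: edges need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  probs <- seq(0.1, 0.9, by = 0.1)
  summ <- dplyr::group_modify(
    dplyr::group_by(edges, .data$group, .data$condition),
    function(df, key) {
      q <- stats::quantile(df$z, probs = probs, names = FALSE)
      out <- tibble::tibble(n = nrow(df), mean = mean(df$z),
                            sd = stats::sd(df$z))
      for (i in seq_along(probs)) {
        out[[sprintf("d%02d", round(100 * probs[i]))]] <- q[i]
      }
      out
    })
  summ <- dplyr::ungroup(summ)
  grid <- seq(min(edges$z), max(edges$z), length.out = grid_points)
  ec <- dplyr::group_modify(
    dplyr::group_by(edges, .data$group, .data$condition),
    function(df, key) {
      tibble::tibble(z = grid, F = stats::ecdf(df$z)(grid))
    })
  list(summary = summ, ecdf = dplyr::ungroup(ec))
}
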