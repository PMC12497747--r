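#' Per-epoch graph metrics for one participant
#'
#' Runs the per-participant leg of the pipeline: cuts the time series into
#' (condition, iteration) windows, builds the full Fisher-Z connectivity
#' graph of each window, and computes weighted betweenness centrality, its
#' rank order, and the average shortest path length of every epoch graph.
#'
#' @param ts Regions x volumes matrix (attributes `participant_id` and
#'   `group` are picked up if present).
#' @param design Epoch design table (see [epoch_design()]).
#' @param policy Distance policy for shortest paths (see [to_distances()]).
#' @param lag_volumes Forward window shift in volumes.
#' @param r_clip Correlation clipping bound (see [compute_ufc()]).
#' @param epsilon Floor for the `clip_epsilon` policy.
#' @param keep_edges Also return the long edge table of every epoch graph
#'   (memory-heavy at full size; default `FALSE`).
#' @param participant_id,group Metadata overrides.
#' @return A list of tibbles: `bc` (`participant`, `group`, `node`,
#'   `condition`, `iteration`, `bc`, `bc_ro`), `aspl` (`participant`,
#'   `group`, `condition`, `iteration`, `aspl`, `finite_pairs`) and, when
#'   requested, `edges` (`participant`, `group`, `condition`, `iteration`,
#'   `node_i`, `node_j`, `z`).
#' @export
compute_participant_metrics <- function(ts, design,
                                        policy = "exclude_nonpositive",
                                        lag_volumes = 0L,
                                        r_clip = 1 - 1e-7,
                                        epsilon = 1e-6,
                                        keep_edges = FALSE,
                                        participant_id = NULL,
                                        group = NULL) {
  participant_id <- participant_id %||% attr(ts, "participant_id") %||% "P01"
  group <- group %||% attr(ts, "group") %||% NA_character_
  seg <- segment_epochs(ts, design, lag_volumes)
  n <- nrow(ts)
  bc_rows <- list()
  aspl_rows <- list()
  edge_rows <- list()
  for (key in names(seg)) {
    parts <- strsplit(key, "#", fixed = TRUE)[[1]]
    cond <- parts[1]
    iter <- as.integer(parts[2])
    g <- compute_ufc(seg[[key]], r_clip = r_clip, condition = cond,
                     iteration = iter, participant_id = participant_id)
    bc <- betweenness_weighted(g, policy = policy, epsilon = epsilon)
    a <- aspl(g, policy = policy, epsilon = epsilon)
    bc_rows[[key]] <- tibble::tibble(
      participant = participant_id, group = group,
      node = seq_len(n), condition = cond, iteration = iter,
      bc = bc, bc_ro = rank_order(bc))
    aspl_rows[[key]] <- tibble::tibble(
      participant = participant_id, group = group,
      condition = cond, iteration = iter,
      aspl = as.numeric(a), finite_pairs = attr(a, "finite_pairs"))
    if (keep_edges) {
      et <- edge_table(g)
      et$participant <- participant_id
      et$group <- group
      et$condition <- cond
      et$iteration <- iter
      edge_rows[[key]] <- et[, c("participant", "group", "condition",
                                 "iteration", "node_i", "node_j", "z")]
    }
  }
  out <- list(bc = dplyr::bind_rows(bc_rows),
              aspl = dplyr::bind_rows(aspl_rows))
  if (keep_edges) out$edges <- dplyr::bind_rows(edge_rows)
  out
}

# Proportion-correct trajectory of one behavioral record.
behavior_proportions <- function(behavior) {
  rowMeans(behavior)
}

#' Full cohort analysis
#'
#' Executes the whole pipeline on a synthetic (or equivalently structured)
#' cohort: epoch segmentation, per-epoch connectivity graphs, betweenness
#' rank and ASPL trajectories, weak-monotonicity classification at the
#' participant level, the exact-permutation Spearman screen on
#' group-averaged betweenness ranks, the three-way mixed ANOVA on ASPL, the
#' behavioral monotone-proportion comparison, and (optionally) pooled
#' edge-weight summaries.
#'
#' @param cohort A `"synth_cohort"` (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param policy,lag_volumes,r_clip,epsilon,keep_edges Passed to
#'   [compute_participant_metrics()].
#' @param max_violations Violations tolerated by the relaxed
#'   weak-monotonicity classifier.
#' @param alpha Significance level of the group trend screen.
#' @param trend_method `"exact"` or `"montecarlo"` (see [spearman_trend()]).
#' @param run_anova Run the mixed ANOVA on the ASPL table (requires a
#'   balanced design with both groups present).
#' @return A list of class `"monoconn_results"` with elements `bc`, `aspl`,
#'   `participant_verdicts`, `participant_summary`, `group_trajectories`,
#'   `screen`, `group_aspl_verdicts`, `anova`, `behavior`, `edge_summary`
#'   (when `keep_edges`), and `provenance`.
#' @export
run_cohort_analysis <- function(cohort,
                                policy = "exclude_nonpositive",
                                lag_volumes = 0L,
                                max_violations = 1L,
                                alpha = 0.05,
                                trend_method = "exact",
                                r_clip = 1 - 1e-7,
                                epsilon = 1e-6,
                                keep_edges = FALSE,
                                run_anova = TRUE) {
  stopifnot(inherits(cohort, "synth_cohort"))
  cfg <- cohort$config
  design <- epoch_design(cfg$conditions, cfg$n_iterations,
                         cfg$volumes_per_epoch)
  per <- lapply(cohort$participants, function(p) {
    compute_participant_metrics(p$timeseries, design, policy = policy,
                                lag_volumes = lag_volumes, r_clip = r_clip,
                                epsilon = epsilon, keep_edges = keep_edges,
                                participant_id = p$participant_id,
                                group = p$group)
  })
  bc <- dplyr::bind_rows(lapply(per, `[[`, "bc"))
  aspl_tab <- dplyr::bind_rows(lapply(per, `[[`, "aspl"))

  # participant-level weak-monotonicity verdicts on BC rank trajectories
  bc_sorted <- dplyr::arrange(bc, .data$participant, .data$node,
                              .data$condition, .data$iteration)
  verdicts <- dplyr::group_modify(
    dplyr::group_by(bc_sorted, .data$participant, .data$group, .data$node,
                    .data$condition),
    function(df, key) {
      v <- classify_monotonicity(df$bc_ro, max_violations = max_violations)
      tibble::tibble(direction = v$direction, n_violations = v$n_violations,
                     strict = v$strict)
    })
  verdicts <- dplyr::ungroup(verdicts)
  participant_summary <- dplyr::summarise(
    dplyr::group_by(verdicts, .data$group, .data$condition),
    n_tests = dplyr::n(),
    pct_monotone = 100 * mean(.data$direction != "none"),
    pct_nonmonotone = 100 * mean(.data$direction == "none"),
    .groups = "drop")

  # group-level screen on averaged rank trajectories
  group_traj <- group_average_trajectories(bc)
  screen <- node_trend_screen(group_traj, alpha = alpha,
                              method = trend_method)

  # group-averaged ASPL trajectories, classified for weak monotonicity
  aspl_group <- dplyr::summarise(
    dplyr::group_by(aspl_tab, .data$group, .data$condition, .data$iteration),
    mean_aspl = mean(.data$aspl), .groups = "drop")
  aspl_group <- dplyr::arrange(aspl_group, .data$group, .data$condition,
                               .data$iteration)
  group_aspl_verdicts <- dplyr::group_modify(
    dplyr::group_by(aspl_group, .data$group, .data$condition),
    function(df, key) {
      v <- classify_monotonicity(df$mean_aspl,
                                 max_violations = max_violations)
      tibble::tibble(direction = v$direction, n_violations = v$n_violations,
                     strict = v$strict)
    })
  group_aspl_verdicts <- dplyr::ungroup(group_aspl_verdicts)

  anova_tab <- NULL
  if (run_anova && length(unique(aspl_tab$group)) == 2L) {
    anova_tab <- aspl_anova(aspl_tab)
  }

  # behavioral monotonicity: proportion correct per Retrieval iteration
  beh_rows <- lapply(cohort$participants, function(p) {
    prop <- behavior_proportions(p$behavior)
    v <- classify_monotonicity(prop, max_violations = max_violations)
    tibble::tibble(participant = p$participant_id, group = p$group,
                   direction = v$direction,
                   monotone_increasing = v$direction == "increasing")
  })
  beh <- dplyr::bind_rows(beh_rows)
  beh_counts <- dplyr::summarise(
    dplyr::group_by(beh, .data$group),
    n = dplyr::n(), k_monotone = sum(.data$monotone_increasing),
    pct_monotone = 100 * mean(.data$monotone_increasing),
    .groups = "drop")
  fisher <- NULL
  if (all(c("control", "patient") %in% beh_counts$group)) {
    kc <- beh_counts$k_monotone[beh_counts$group == "control"]
    nc <- beh_counts$n[beh_counts$group == "control"]
    kp <- beh_counts$k_monotone[beh_counts$group == "patient"]
    np <- beh_counts$n[beh_counts$group == "patient"]
    fisher <- monotonic_proportion_test(kc, nc, kp, np)
  }

  edge_summary <- NULL
  if (keep_edges) {
    edges <- dplyr::bind_rows(lapply(per, `[[`, "edges"))
    edge_summary <- edge_weight_summary(
      edges[, c("group", "condition", "z")])
  }

  structure(list(
    bc = bc,
    aspl = aspl_tab,
    participant_verdicts = verdicts,
    participant_summary = participant_summary,
    group_trajectories = group_traj,
    screen = screen,
    group_aspl = aspl_group,
    group_aspl_verdicts = group_aspl_verdicts,
    anova = anova_tab,
    behavior = list(per_participant = beh, counts = beh_counts,
                    fisher = fisher),
    edge_summary = edge_summary,
    provenance = list(
      package_version = as.character(utils::packageVersion("monoconn")),
      seed = cfg$seed, policy = policy, lag_volumes = lag_volumes,
      max_violations = max_violations, alpha = alpha,
      trend_method = trend_method, timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "monoconn_results")
}

#' @export
print.monoconn_results <- function(x, ...) {
  cat("monoconn cohort analysis\n")
  cat(sprintf("  %d participants, %d nodes, policy '%s'\n",
              length(unique(x$bc$participant)),
              length(unique(x$bc$node)), x$provenance$policy))
  sig <- sum(x$screen$significant)
  cat(sprintf("  group trend screen: %d/%d trajectories significant at alpha = %g\n",
              sig, nrow(x$screen), x$provenance$alpha))
  if (!is.null(x$behavior$fisher)) {
    cat(sprintf("  behavioral monotone proportions: Fisher exact p = %.4g\n",
                x$behavior$fisher$p_value))
  }
  invisible(x)
}
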