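#' Write a synthetic cohort to plain-text files
#'
#' Serializes a cohort in the pipeline's on-disk schema: one tab-separated
#' matrix per participant (`<id>_timeseries.tsv`; volumes as rows, a header
#' row of region labels), a shared `design.tsv` (`volume_index`, `condition`,
#' `iteration`; volume indices 0-based), a long `behavior.tsv`
#' (`participant`, `iteration`, `item`, `correct`) and a `manifest.json`
#' holding group sizes, per-participant seeds and the planted ground truth.
#'
#' @param cohort A `"synth_cohort"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  cfg <- cohort$config
  design <- epoch_design(cfg$conditions, cfg$n_iterations,
                         cfg$volumes_per_epoch)
  utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  beh_rows <- list()
  for (p in cohort$participants) {
    m <- t(p$timeseries)  # volumes x regions, header = region labels
    utils::write.table(m, file.path(dir, paste0(p$participant_id,
                                                "_timeseries.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    b <- p$behavior
    beh_rows[[p$participant_id]] <- data.frame(
      participant = p$participant_id,
      iteration = rep(seq_len(nrow(b)), times = ncol(b)),
      item = rep(seq_len(ncol(b)), each = nrow(b)),
      correct = as.integer(b))
  }
  beh <- do.call(rbind, beh_rows)
  beh <- beh[order(beh$participant, beh$iteration, beh$item), ]
  utils::write.table(beh, file.path(dir, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- cohort$manifest
  manifest$config <- cfg[setdiff(names(cfg), "drift_conditions")]
  manifest$config$drift_conditions <- cfg$drift_conditions %||% cfg$conditions
  manifest$participants <- data.frame(
    participant = vapply(cohort$participants, `[[`, character(1),
                         "participant_id"),
    group = vapply(cohort$participants, `[[`, character(1), "group"),
    seed = vapply(cohort$participants, `[[`, integer(1), "seed"),
    nonmonotone = vapply(cohort$participants, `[[`, logical(1),
                         "nonmonotone"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort back from its on-disk representation
#'
#' Inverse of [write_cohort()]: reconstructs the `"synth_cohort"` object
#' (configuration, per-participant time series and behavior matrices, and
#' the ground-truth manifest) from the TSV/JSON files.
#'
#' @param dir Directory written by [write_cohort()] (or user-supplied files
#'   of the same schema).
#' @return A `"synth_cohort"` list.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop(sprintf("I/O error: no manifest.json under '%s'", dir),
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  ccfg <- manifest$config
  cfg <- synth_config(
    n_regions = ccfg$n_regions, n_iterations = ccfg$n_iterations,
    conditions = ccfg$conditions, volumes_per_epoch = ccfg$volumes_per_epoch,
    n_participants_per_group = unlist(ccfg$n_participants_per_group),
    hub_nodes = ccfg$hub_nodes %||% integer(0),
    drift_per_iteration = ccfg$drift_per_iteration,
    base_coupling = ccfg$base_coupling,
    group_coupling_offset = ccfg$group_coupling_offset,
    behavior_asymptote = unlist(ccfg$behavior_asymptote),
    behavior_rate = ccfg$behavior_rate, n_items = ccfg$n_items,
    p_nonmonotone = unlist(ccfg$p_nonmonotone),
    nonmono_dip = ccfg$nonmono_dip, noise_sd = ccfg$noise_sd,
    baseline = ccfg$baseline, ar_coef = ccfg$ar_coef,
    drift_conditions = ccfg$drift_conditions, seed = ccfg$seed)
  pt <- manifest$participants
  beh <- utils::read.delim(file.path(dir, "behavior.tsv"))
  participants <- vector("list", nrow(pt))
  for (i in seq_len(nrow(pt))) {
    id <- pt$participant[i]
    ts_path <- file.path(dir, paste0(id, "_timeseries.tsv"))
    if (!file.exists(ts_path)) {
      stop(sprintf("I/O error: missing time-series file for participant %s",
                   id), call. = FALSE)
    }
    m <- as.matrix(utils::read.delim(ts_path, check.names = FALSE))
    ts <- t(m)  # back to regions x volumes
    attr(ts, "participant_id") <- id
    attr(ts, "group") <- pt$group[i]
    bi <- beh[beh$participant == id, ]
    # column-major fill: iterations vary fastest within each item column
    bi <- bi[order(bi$item, bi$iteration), ]
    bm <- matrix(as.integer(bi$correct), nrow = cfg$n_iterations)
    dimnames(bm) <- list(iteration = seq_len(cfg$n_iterations),
                         item = seq_len(cfg$n_items))
    participants[[i]] <- list(participant_id = id, group = pt$group[i],
                              timeseries = ts, behavior = bm,
                              nonmonotone = pt$nonmonotone[i],
                              seed = pt$seed[i])
  }
  manifest$participants <- NULL
  manifest$config <- NULL
  manifest$hub_nodes <- as.integer(unlist(manifest$hub_nodes) %||% integer(0))
  structure(list(config = cfg, participants = participants,
                 manifest = manifest),
            class = "synth_cohort")
}

#' Write the analysis result tables as TSV + a JSON run report
#'
#' Writes each tabular element of a [run_cohort_analysis()] result as a
#' tab-separated file under `dir`, plus `report.json` with the run
#' provenance, the screen/behavior headline numbers and the ANOVA table.
#'
#' @param results A `"monoconn_results"` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "monoconn_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(results$bc, "bc_metrics.tsv")
  wt(results$aspl, "aspl_metrics.tsv")
  wt(results$participant_verdicts, "participant_verdicts.tsv")
  wt(results$participant_summary, "participant_summary.tsv")
  wt(results$screen, "group_trend_screen.tsv")
  wt(results$group_aspl_verdicts, "group_aspl_verdicts.tsv")
  if (!is.null(results$anova)) wt(results$anova, "aspl_anova.tsv")
  wt(results$behavior$per_participant, "behavior_verdicts.tsv")
  wt(results$behavior$counts, "behavior_counts.tsv")
  if (!is.null(results$edge_summary)) {
    wt(results$edge_summary$summary, "edge_weight_summary.tsv")
  }
  report <- list(
    provenance = results$provenance,
    screen_significant = sum(results$screen$significant),
    screen_total = nrow(results$screen),
    behavior = list(
      counts = results$behavior$counts,
      fisher_p = if (!is.null(results$behavior$fisher))
        results$behavior$fisher$p_value else NULL),
    anova = results$anova)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
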