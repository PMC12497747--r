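#' Configure a synthetic learning-task cohort
#'
#' Defines the block design and generative parameters of a simulated
#' associative-learning cohort: eight iterations of four 27-s conditions
#' (Encoding, Post-Encoding Rest, Retrieval, Post-Retrieval Rest) sampled at
#' TR = 3 s (9 volumes per epoch, 288 volumes in total at the defaults), two
#' groups, and optional planted monotone "hubness" drift in a chosen node
#' set.
#'
#' Regional signals follow a one-factor model: within each epoch a shared
#' latent factor (unit variance) is scaled per region by a coupling
#' ("loading") and added to a constant baseline plus independent Gaussian
#' noise. Hub nodes gain `drift_per_iteration` of coupling per task
#' iteration; the patient-like group loses `group_coupling_offset` of
#' coupling everywhere (lower connectivity, hence longer average shortest
#' paths) and has a lower behavioral asymptote with a larger fraction of
#' deliberately non-monotone performers.
#'
#' @param n_regions Number of parcels (nodes). Default 246.
#' @param n_iterations Number of task iterations. Default 8.
#' @param conditions Ordered condition names (4 at default).
#' @param volumes_per_epoch Volumes per condition epoch (27 s / 3 s TR = 9).
#' @param n_participants_per_group Participants per group; a single count
#'   (both groups) or a length-2 vector/named `c(control=, patient=)`.
#'   Default `c(control = 39, patient = 49)`.
#' @param hub_nodes Integer vector of 1-based node indices receiving planted
#'   coupling drift. Default none.
#' @param drift_per_iteration Coupling increment per iteration for hub nodes
#'   (unitless loading units).
#' @param base_coupling Central latent-factor loading, in `[0, 1)`.
#' @param coupling_spread Width of the deterministic per-node loading
#'   profile: node `k` of `n` loads at `base_coupling + coupling_spread *
#'   ((k-1)/(n-1) - 1/2)`, so loadings run evenly from `base - spread/2`
#'   (node 1) to `base + spread/2` (node `n`). Heterogeneous coupling is
#'   what lets a drifting hub climb *through* the pack, producing a gradual
#'   (rather than step-like) rank trajectory; 0 gives homogeneous loadings.
#' @param group_coupling_offset Loading decrement applied to every node of
#'   the patient-like group.
#' @param behavior_asymptote Asymptotic per-item success probability per
#'   group (scalar or length-2 as above).
#' @param behavior_rate Learning rate of the negatively accelerated learning
#'   curve `p_t = asymptote * (1 - exp(-rate * t))`.
#' @param n_items Object-location associations probed per Retrieval epoch.
#' @param p_nonmonotone Per-group probability that a participant is a
#'   designated non-monotone performer (their learning curve gets a mid-task
#'   dip).
#' @param nonmono_dip Multiplicative factor applied to the success
#'   probability of the two middle iterations for non-monotone performers.
#' @param noise_sd Standard deviation of the per-volume regional noise, in
#'   the same (arbitrary scanner) units as the latent factor.
#' @param baseline Constant signal baseline added to every volume (keeps
#'   region means positive so percent signal change is well defined).
#' @param ar_coef AR(1) coefficient applied within epochs to the factor and
#'   noise innovations (0 = white noise, the default; marginal variances are
#'   preserved).
#' @param drift_conditions Conditions in which hub drift applies; `NULL`
#'   (default) applies drift in all conditions.
#' @param seed Integer master seed for cohort generation.
#'
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_regions = 246L,
                         n_iterations = 8L,
                         conditions = c("Encoding", "PostEncodingRest",
                                        "Retrieval", "PostRetrievalRest"),
                         volumes_per_epoch = 9L,
                         n_participants_per_group = c(control = 39L, patient = 49L),
                         hub_nodes = integer(0),
                         drift_per_iteration = 0,
                         base_coupling = 0.45,
                         coupling_spread = 0.2,
                         group_coupling_offset = 0.12,
                         behavior_asymptote = c(control = 0.95, patient = 0.75),
                         behavior_rate = 0.8,
                         n_items = 9L,
                         p_nonmonotone = c(control = 0.1, patient = 0.4),
                         nonmono_dip = 0.5,
                         noise_sd = 0.5,
                         baseline = 1000,
                         ar_coef = 0,
                         drift_conditions = NULL,
                         seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    n_iterations = as.integer(n_iterations),
    conditions = as.character(conditions),
    volumes_per_epoch = as.integer(volumes_per_epoch),
    n_participants_per_group = per_group(n_participants_per_group,
                                         "n_participants_per_group"),
    hub_nodes = as.integer(hub_nodes),
    drift_per_iteration = drift_per_iteration,
    base_coupling = base_coupling,
    coupling_spread = coupling_spread,
    group_coupling_offset = group_coupling_offset,
    behavior_asymptote = per_group(behavior_asymptote, "behavior_asymptote"),
    behavior_rate = behavior_rate,
    n_items = as.integer(n_items),
    p_nonmonotone = per_group(p_nonmonotone, "p_nonmonotone"),
    nonmono_dip = nonmono_dip,
    noise_sd = noise_sd,
    baseline = baseline,
    ar_coef = ar_coef,
    drift_conditions = drift_conditions,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' Validate a synthetic cohort configuration
#'
#' Checks the design arithmetic (total volumes = conditions x iterations x
#' volumes per epoch), the validity of the latent-factor loadings (all
#' loadings must stay in `[0, 1)` for every group and iteration), and that
#' all probabilities lie in `[0, 1]`.
#'
#' @param cfg A `"synth_config"` object.
#' @return `cfg`, invisibly gaining a `total_volumes` field.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_regions < 2L) {
    stop("configuration error: 'n_regions' must be >= 2", call. = FALSE)
  }
  if (cfg$n_iterations < 2L || cfg$volumes_per_epoch < 2L ||
      length(cfg$conditions) < 1L) {
    stop("configuration error: design must have >= 2 iterations and >= 2 volumes per epoch",
         call. = FALSE)
  }
  if (anyDuplicated(cfg$conditions)) {
    stop("configuration error: 'conditions' must be distinct", call. = FALSE)
  }
  cfg$total_volumes <- cfg$volumes_per_epoch * cfg$n_iterations *
    length(cfg$conditions)
  if (length(cfg$hub_nodes) &&
      (any(cfg$hub_nodes < 1L) || any(cfg$hub_nodes > cfg$n_regions))) {
    stop("configuration error: 'hub_nodes' must be 1-based indices within n_regions",
         call. = FALSE)
  }
  if (cfg$coupling_spread < 0) {
    stop("configuration error: 'coupling_spread' must be >= 0", call. = FALSE)
  }
  max_load <- cfg$base_coupling + cfg$coupling_spread / 2 +
    cfg$n_iterations * cfg$drift_per_iteration
  if (!(max_load < 1)) {
    stop(paste0("configuration error: 'base_coupling' + coupling_spread/2 + ",
                "n_iterations * 'drift_per_iteration' must be < 1 (got ",
                signif(max_load, 4), ")"), call. = FALSE)
  }
  if (cfg$base_coupling < 0) {
    stop("configuration error: 'base_coupling' must be >= 0", call. = FALSE)
  }
  min_load <- cfg$base_coupling - cfg$coupling_spread / 2 -
    cfg$group_coupling_offset +
    min(0, cfg$n_iterations * cfg$drift_per_iteration)
  if (min_load < 0) {
    stop(paste0("configuration error: 'group_coupling_offset'/'coupling_spread' ",
                "drive loadings below 0"), call. = FALSE)
  }
  probs <- c(cfg$behavior_asymptote, cfg$p_nonmonotone)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities ('behavior_asymptote', 'p_nonmonotone') must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$nonmono_dip < 0 || cfg$nonmono_dip > 1) {
    stop("configuration error: 'nonmono_dip' must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("configuration error: 'noise_sd' must be >= 0", call. = FALSE)
  }
  if (abs(cfg$ar_coef) >= 1) {
    stop("configuration error: 'ar_coef' must lie in (-1, 1)", call. = FALSE)
  }
  if (!is.null(cfg$drift_conditions) &&
      !all(cfg$drift_conditions %in% cfg$conditions)) {
    stop("configuration error: 'drift_conditions' must be a subset of 'conditions'",
         call. = FALSE)
  }
  cfg
}

#' Latent-factor loadings for one epoch
#'
#' The per-region factor loadings of the generative model for a given
#' (group, condition, iteration) cell: the deterministic per-node profile
#' around `base_coupling` (see [synth_config()]), minus the group offset for
#' patients, plus the iteration-scaled drift for hub nodes (in drifting
#' conditions). Exposed so tests and diagnostics can evaluate the
#' closed-form correlation `c1*c2 / sqrt((c1^2 + s^2)(c2^2 + s^2))` implied
#' by the one-factor model.
#'
#' @inheritParams generate_participant_timeseries
#' @param iteration Task iteration (1-based).
#' @param condition Condition name.
#' @return Numeric vector of length `n_regions`, all entries in `[0, 1)`.
#' @export
region_loadings <- function(cfg, group, iteration, condition) {
  n <- cfg$n_regions
  lam <- cfg$base_coupling +
    cfg$coupling_spread * ((seq_len(n) - 1) / (n - 1) - 0.5)
  if (group == "patient") lam <- lam - cfg$group_coupling_offset
  drift_on <- is.null(cfg$drift_conditions) ||
    condition %in% cfg$drift_conditions
  if (length(cfg$hub_nodes) && drift_on) {
    lam[cfg$hub_nodes] <- lam[cfg$hub_nodes] +
      cfg$drift_per_iteration * iteration
  }
  bad <- which(lam < 0 | lam >= 1)
  if (length(bad)) {
    stop(sprintf(paste0("configuration error: loading out of [0, 1) for region %d ",
                        "(group %s, condition %s, iteration %d); check 'base_coupling', ",
                        "'group_coupling_offset' and 'drift_per_iteration'"),
                 bad[1], group, condition, iteration), call. = FALSE)
  }
  lam
}

# AR(1) process with unit marginal variance from iid N(0,1) innovations.
ar1_series <- function(n, phi) {
  e <- stats::rnorm(n)
  if (phi == 0) return(e)
  f <- numeric(n)
  f[1] <- e[1]
  scale <- sqrt(1 - phi^2)
  for (t in seq_len(n)[-1]) f[t] <- phi * f[t - 1] + scale * e[t]
  f
}

#' Generate one participant's parcellated time series
#'
#' Simulates a regions x volumes signal matrix under the epoch-wise
#' one-factor model: within each (condition, iteration) epoch all regions
#' share a unit-variance latent factor, scaled by each region's coupling,
#' plus independent Gaussian noise and a constant baseline. The epoch order
#' follows [epoch_design()]: iterations outermost, conditions in their
#' configured order within each iteration.
#'
#' The marginal correlation between regions with loadings `c1`, `c2` and
#' noise SD `s` is `c1*c2 / sqrt((c1^2 + s^2) * (c2^2 + s^2))`.
#'
#' @param cfg A `"synth_config"`.
#' @param group `"control"` or `"patient"`.
#' @param rng_seed Integer seed; identical seeds reproduce the matrix
#'   bit-for-bit.
#' @param participant_id Identifier stored as an attribute.
#' @return A numeric matrix (`n_regions` x `total_volumes`) with attributes
#'   `participant_id`, `group` and rownames giving region labels.
#' @export
generate_participant_timeseries <- function(cfg, group, rng_seed,
                                            participant_id = "sim") {
  cfg <- validate_synth_config(cfg)
  group <- match.arg(group, c("control", "patient"))
  design <- epoch_design(cfg$conditions, cfg$n_iterations,
                         cfg$volumes_per_epoch)
  x <- matrix(NA_real_, cfg$n_regions, nrow(design))
  withr::with_seed(as.integer(rng_seed), {
    for (iter in seq_len(cfg$n_iterations)) {
      for (cond in cfg$conditions) {
        idx <- which(design$condition == cond & design$iteration == iter)
        lam <- region_loadings(cfg, group, iter, cond)
        f <- ar1_series(length(idx), cfg$ar_coef)
        eps <- matrix(stats::rnorm(cfg$n_regions * length(idx),
                                   sd = cfg$noise_sd),
                      cfg$n_regions, length(idx))
        if (cfg$ar_coef != 0 && cfg$noise_sd > 0) {
          eps <- t(apply(eps, 1, function(e) {
            stats::filter(e * sqrt(1 - cfg$ar_coef^2), cfg$ar_coef,
                          method = "recursive", init = e[1])
          }))
        }
        x[, idx] <- cfg$baseline + outer(lam, f) + eps
      }
    }
  })
  rownames(x) <- sprintf("R%03d", seq_len(cfg$n_regions))
  attr(x, "participant_id") <- participant_id
  attr(x, "group") <- group
  x
}

# Per-iteration success probabilities of the learning curve, with the
# mid-task dip applied for designated non-monotone performers.
behavior_probs <- function(cfg, group, nonmonotone = FALSE) {
  t <- seq_len(cfg$n_iterations)
  p <- cfg$behavior_asymptote[[group]] * (1 - exp(-cfg$behavior_rate * t))
  if (nonmonotone) {
    mid <- floor(cfg$n_iterations / 2)
    dip <- unique(pmin(cfg$n_iterations, c(mid, mid + 1L)))
    p[dip] <- p[dip] * cfg$nonmono_dip
  }
  p
}

#' Generate one participant's behavioral retrieval record
#'
#' Draws per-item correct/incorrect outcomes for each task iteration under a
#' negatively accelerated learning curve, `p_t = asymptote * (1 -
#' exp(-rate * t))`; items are independent Bernoulli draws. Designated
#' non-monotone performers have the success probability of the two middle
#' iterations multiplied by `nonmono_dip`, planting a mid-task performance
#' slump.
#'
#' @inheritParams generate_participant_timeseries
#' @param nonmonotone Whether this participant is a designated non-monotone
#'   performer.
#' @return An `n_iterations` x `n_items` binary matrix with attribute
#'   `prob` (the per-iteration success probabilities).
#' @export
generate_behavior <- function(cfg, group, rng_seed, nonmonotone = FALSE) {
  cfg <- validate_synth_config(cfg)
  group <- match.arg(group, c("control", "patient"))
  p <- behavior_probs(cfg, group, nonmonotone)
  m <- withr::with_seed(as.integer(rng_seed), {
    matrix(stats::rbinom(cfg$n_iterations * cfg$n_items, 1L,
                         rep(p, times = cfg$n_items)),
           nrow = cfg$n_iterations)
  })
  dimnames(m) <- list(iteration = seq_len(cfg$n_iterations),
                      item = seq_len(cfg$n_items))
  attr(m, "prob") <- p
  m
}

#' Generate a full synthetic cohort
#'
#' Simulates time series and behavioral records for both groups, with
#' per-participant seeds derived deterministically from `cfg$seed` and a
#' ground-truth manifest recording the planted structure (hub nodes, drift
#' sign, the betweenness-rank direction it implies, and the designated
#' non-monotone performers).
#'
#' With positive drift a hub's coupling -- and hence its betweenness -- rises
#' across iterations, so its betweenness *rank* (1 = most central) falls:
#' the manifest's `expected_bcro_direction` is `"decreasing"` for positive
#' drift and `"increasing"` for negative drift.
#'
#' @param cfg A `"synth_config"`.
#' @return A list of class `"synth_cohort"` with elements `config`,
#'   `participants` (each a list with `participant_id`, `group`,
#'   `timeseries`, `behavior`, `nonmonotone`, `seed`) and `manifest`.
#' @export
generate_cohort <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  n_per <- cfg$n_participants_per_group
  groups <- rep(c("control", "patient"), times = n_per)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "HC", "PT"),
                 c(seq_len(n_per[["control"]]), seq_len(n_per[["patient"]])))
  nonmono <- withr::with_seed(cfg$seed, {
    stats::setNames(stats::rbinom(length(ids), 1L,
                                  cfg$p_nonmonotone[groups]) == 1L, ids)
  })
  participants <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    seed_i <- as.integer((as.numeric(cfg$seed) * 10007 + i * 7919) %% 2147483647)
    participants[[i]] <- list(
      participant_id = ids[i],
      group = groups[i],
      timeseries = generate_participant_timeseries(cfg, groups[i], seed_i,
                                                   participant_id = ids[i]),
      behavior = generate_behavior(cfg, groups[i], seed_i + 1L,
                                   nonmonotone = nonmono[[i]]),
      nonmonotone = nonmono[[i]],
      seed = seed_i
    )
  }
  manifest <- list(
    seed = cfg$seed,
    groups = stats::setNames(as.list(as.integer(n_per)), names(n_per)),
    hub_nodes = cfg$hub_nodes,
    drift_per_iteration = cfg$drift_per_iteration,
    drift_sign = sign(cfg$drift_per_iteration),
    expected_bcro_direction = if (cfg$drift_per_iteration > 0) "decreasing"
                              else if (cfg$drift_per_iteration < 0) "increasing"
                              else "none",
    drift_conditions = cfg$drift_conditions %||% cfg$conditions,
    nonmonotone_performers = ids[nonmono],
    participant_seeds = stats::setNames(
      vapply(participants, `[[`, integer(1), "seed"), ids)
  )
  structure(list(config = cfg, participants = participants,
                 manifest = manifest),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic cohort: %d control + %d patient participants\n",
              cfg$n_participants_per_group[["control"]],
              cfg$n_participants_per_group[["patient"]]))
  cat(sprintf("  %d regions x %d volumes (%d conditions x %d iterations x %d volumes)\n",
              cfg$n_regions, cfg$total_volumes, length(cfg$conditions),
              cfg$n_iterations, cfg$volumes_per_epoch))
  if (length(cfg$hub_nodes)) {
    cat(sprintf("  planted drift %+g/iteration on nodes {%s}\n",
                cfg$drift_per_iteration,
                paste(cfg$hub_nodes, collapse = ", ")))
  }
  invisible(x)
}
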