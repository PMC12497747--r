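make_bc_table <- function(n_part, n_nodes, n_iter = 8, conds = "Encoding",
                          group = "control", seed = 1) {
  set.seed(seed)
  grid <- expand.grid(participant = sprintf("P%02d", seq_len(n_part)),
                      node = seq_len(n_nodes), condition = conds,
                      iteration = seq_len(n_iter),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- group
  grid$bc_ro <- sample(seq_len(n_nodes), nrow(grid), replace = TRUE)
  tibble::as_tibble(grid)
}

test_that("group averaging reproduces direct column means", {
  # single participant: group trajectory is that participant's trajectory
  tab1 <- make_bc_table(1, 4)
  tr1 <- group_average_trajectories(tab1)
  merged <- merge(tr1, tab1, by = c("node", "condition", "iteration"))
  expect_equal(merged$mean_bc_ro, merged$bc_ro)

  # two participants with ranks 10 and 20 everywhere -> 15
  tab2 <- make_bc_table(2, 25)
  tab2$bc_ro <- ifelse(tab2$participant == "P01", 10, 20)
  expect_true(all(group_average_trajectories(tab2)$mean_bc_ro == 15))

  # 5 participants vs brute-force averaging
  tab5 <- make_bc_table(5, 6, seed = 3)
  tr5 <- group_average_trajectories(tab5)
  for (k in sample(nrow(tr5), 10)) {
    sel <- tab5$node == tr5$node[k] & tab5$condition == tr5$condition[k] &
      tab5$iteration == tr5$iteration[k]
    expect_equal(tr5$mean_bc_ro[k], mean(tab5$bc_ro[sel]))
  }

  # participants with different node sets are a schema error
  bad <- rbind(make_bc_table(1, 4), transform(make_bc_table(1, 5), participant = "P99"))
  expect_error(group_average_trajectories(tibble::as_tibble(bad)),
               "node set")
})

test_that("the trend screen flags planted monotone trajectories", {
  traj <- tibble::tibble(group = "control", node = 1L,
                         condition = "Encoding", iteration = 1:8,
                         mean_bc_ro = c(40, 35, 30, 28, 20, 15, 10, 5))
  res <- node_trend_screen(traj)
  expect_equal(res$rho, -1)
  expect_true(res$significant)
  expect_equal(res$direction, "decreasing")

  # an all-tied trajectory yields NA and is never flagged
  traj2 <- traj
  traj2$mean_bc_ro <- 7
  res2 <- node_trend_screen(traj2)
  expect_true(is.na(res2$rho))
  expect_false(res2$significant)
  expect_equal(res2$direction, "none")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  # identical proportions carry no evidence
  expect_equal(monotonic_proportion_test(10, 20, 10, 20)$p_value, 1)
  # extreme 5/5 vs 0/5 table: two point-mass tails of 1/252 each
  expect_equal(monotonic_proportion_test(5, 5, 0, 5)$p_value, 1 / 126,
               tolerance = 1e-12)
  # random tables against the enumeration oracle
  set.seed(8)
  for (rep in 1:20) {
    nc <- sample(5:40, 1); np <- sample(5:50, 1)
    kc <- sample(0:nc, 1); kp <- sample(0:np, 1)
    expect_equal(monotonic_proportion_test(kc, nc, kp, np)$p_value,
                 fisher_oracle(kc, nc, kp, np), tolerance = 1e-9)
  }
  expect_error(monotonic_proportion_test(1, 0, 1, 5), "positive")
  expect_error(monotonic_proportion_test(6, 5, 1, 5), "\\[0, n\\]")
})

make_aspl_table <- function(n_control, n_patient, n_cond = 4, n_iter = 8,
                            f = function(g, cond, t) 0, sd = 1, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("HC%02d", seq_len(n_control)),
           sprintf("PT%02d", seq_len(n_patient)))
  groups <- rep(c("control", "patient"), c(n_control, n_patient))
  grid <- expand.grid(participant = ids,
                      condition = paste0("C", seq_len(n_cond)),
                      iteration = seq_len(n_iter),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- groups[match(grid$participant, ids)]
  grid$aspl <- mapply(f, grid$group, grid$condition, grid$iteration) +
    rnorm(nrow(grid), sd = sd)
  grid
}

test_that("mixed ANOVA reports the textbook degrees of freedom", {
  tab <- make_aspl_table(3, 3, n_cond = 2, n_iter = 4)
  out <- aspl_anova(tab)
  expect_equal(out$df_num[out$effect == "Time"], 3)
  expect_equal(out$df_den[out$effect == "Time"], 3 * (6 - 2))
  expect_equal(out$df_num[out$effect == "Group"], 1)
  expect_equal(out$df_den[out$effect == "Group"], 6 - 2)
  expect_equal(out$df_num[out$effect == "Condition"], 1)
  expect_equal(out$df_num[out$effect == "Group:Condition:Time"], 3)
  expect_equal(nrow(out), 7)

  # unbalanced designs are rejected, not imputed
  expect_error(aspl_anova(tab[-5, ]), "unbalanced")
})

test_that("constant responses produce an explicit zero-variance report", {
  tab <- make_aspl_table(2, 2, n_cond = 2, n_iter = 3, sd = 0,
                         f = function(g, cond, t) 4)
  expect_warning(out <- aspl_anova(tab), "zero variance")
  expect_true(all(is.na(out$F)))
  expect_true(attr(out, "zero_variance"))
  expect_equal(out$df_den[out$effect == "Time"], 2 * (4 - 2))
})

test_that("a pure group offset drives Group F but not Time F", {
  time_F <- numeric(10)
  group_p <- numeric(10)
  for (s in 1:10) {
    tab <- make_aspl_table(8, 8, sd = 0.5, seed = 100 + s,
                           f = function(g, cond, t) ifelse(g == "patient", 2, 0))
    out <- aspl_anova(tab)
    time_F[s] <- out$F[out$effect == "Time"]
    group_p[s] <- out$p_value[out$effect == "Group"]
  }
  expect_true(all(group_p < 1e-6))
  # null F has expectation df2/(df2 - 2), about 1
  expect_gt(mean(time_F), 0.4)
  expect_lt(mean(time_F), 1.8)
})

test_that("edge-weight summaries are exact for a single graph and symmetric groups", {
  set.seed(12)
  z <- rnorm(300)
  edges <- tibble::tibble(group = rep(c("control", "patient"), each = 300),
                          condition = "Encoding", z = c(z, z))
  ews <- edge_weight_summary(edges)
  s <- ews$summary
  expect_equal(s$mean[1], s$mean[2])
  expect_equal(s$sd[1], s$sd[2])
  expect_equal(s$d50[1], median(z))
  expect_equal(s$mean[1], mean(z))
  expect_equal(s$d10[1], unname(quantile(z, 0.1)))
  # identical groups -> identical ECDFs on the shared grid
  ec <- ews$ecdf
  expect_equal(ec$F[ec$group == "control"], ec$F[ec$group == "patient"])
})

test_that("a coupling offset shifts the patient edge distribution left", {
  for (s in 1:3) {
    cfg <- synth_config(n_regions = 8, n_iterations = 8,
                        conditions = "Encoding", volumes_per_epoch = 9,
                        n_participants_per_group = 1, base_coupling = 0.45,
                        coupling_spread = 0.2, group_coupling_offset = 0.15,
                        noise_sd = 0.5, seed = s)
    design <- epoch_design(cfg$conditions, cfg$n_iterations,
                           cfg$volumes_per_epoch)
    pooled <- lapply(c("control", "patient"), function(grp) {
      ts <- generate_participant_timeseries(cfg, grp, 1000 + s)
      seg <- segment_epochs(ts, design)
      z <- unlist(lapply(seg, function(w) edge_table(compute_ufc(w))$z))
      mean(z)
    })
    expect_gt(pooled[[1]], pooled[[2]])
  }
})
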