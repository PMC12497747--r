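test_that("generated cohorts have the configured shape and are reproducible", {
  cfg <- toy_cohort_config(seed = 11)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)

  expect_length(co1$participants, 6L)
  expect_equal(sum(vapply(co1$participants, `[[`, character(1),
                          "group") == "control"), 3L)
  ts <- co1$participants[[1]]$timeseries
  expect_equal(dim(ts), c(8L, 8L * 2L * 9L))
  expect_equal(dim(co1$participants[[1]]$behavior), c(8L, 9L))

  # identical master seed => identical cohort, participant by participant
  for (i in seq_along(co1$participants)) {
    expect_identical(co1$participants[[i]]$timeseries,
                     co2$participants[[i]]$timeseries)
    expect_identical(co1$participants[[i]]$behavior,
                     co2$participants[[i]]$behavior)
  }
  # different seed => different draws
  co3 <- generate_cohort(toy_cohort_config(seed = 12))
  expect_false(identical(co1$participants[[1]]$timeseries,
                         co3$participants[[1]]$timeseries))
})

test_that("ground-truth manifest echoes the planted structure", {
  cfg <- toy_cohort_config(seed = 5, hub_nodes = 1:3,
                           drift_per_iteration = 0.02)
  co <- generate_cohort(cfg)
  expect_identical(co$manifest$hub_nodes, 1:3)
  expect_identical(co$manifest$drift_sign, 1)
  expect_identical(co$manifest$expected_bcro_direction, "decreasing")
  expect_identical(co$manifest$groups$control, 3L)
})

test_that("invalid configurations fail with named parameters", {
  expect_error(synth_config(base_coupling = 0.9, drift_per_iteration = 0.05,
                            hub_nodes = 1L),
               "drift_per_iteration")
  expect_error(synth_config(base_coupling = 0.1, coupling_spread = 0,
                            group_coupling_offset = 0.2),
               "group_coupling_offset|coupling_spread")
  expect_error(synth_config(behavior_asymptote = 1.2), "behavior_asymptote")
  expect_error(synth_config(n_regions = 10, hub_nodes = 11L), "hub_nodes")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("no-signal degenerate series are constant and flagged downstream", {
  cfg <- toy_cohort_config(seed = 2, base_coupling = 0, coupling_spread = 0,
                           group_coupling_offset = 0, noise_sd = 0)
  ts <- generate_participant_timeseries(cfg, "control", 1)
  expect_true(all(ts == cfg$baseline))
  design <- epoch_design(cfg$conditions, cfg$n_iterations,
                         cfg$volumes_per_epoch)
  win <- segment_epochs(ts, design)[[1]]
  expect_error(compute_ufc(win), "zero variance")
})

test_that("epoch-wise correlations match the one-factor closed form", {
  # long diagnostic run: 2 regions, 10,000 volumes, fixed loadings
  cfg <- synth_config(n_regions = 2, n_iterations = 2,
                      conditions = "Encoding", volumes_per_epoch = 2500,
                      n_participants_per_group = 1,
                      base_coupling = 0.7, coupling_spread = 0.2,
                      group_coupling_offset = 0, noise_sd = 0.5, seed = 1)
  lam <- region_loadings(cfg, "control", 1, "Encoding")
  expect_equal(lam, c(0.6, 0.8))
  s2 <- cfg$noise_sd^2
  r_expected <- prod(lam) / sqrt(prod(lam^2 + s2))

  # two independent draws, pooled to 10,000 volumes of the same loadings
  x1 <- generate_participant_timeseries(cfg, "control", 101)
  x2 <- generate_participant_timeseries(cfg, "control", 202)
  r_emp <- cor(c(x1[1, ], x2[1, ]), c(x1[2, ], x2[2, ]))
  expect_lt(abs(r_emp - r_expected), 0.02)
})

test_that("behavioral curves follow the saturating learning model", {
  # ceiling: infinite rate and unit asymptote => constant 1.0
  cfg_hi <- toy_cohort_config(behavior_rate = Inf,
                              behavior_asymptote = c(control = 1, patient = 1))
  b <- generate_behavior(cfg_hi, "control", 3)
  expect_true(all(b == 1L))
  expect_equal(rowMeans(b), rep(1, 8), ignore_attr = TRUE)

  # floor: zero asymptote => all incorrect
  cfg_lo <- toy_cohort_config(behavior_asymptote = c(control = 0, patient = 0))
  expect_true(all(generate_behavior(cfg_lo, "patient", 3) == 0L))

  # Monte-Carlo calibration: 10,000 simulated participants against the
  # closed-form p_t = asymptote * (1 - exp(-rate * t))
  cfg <- toy_cohort_config(behavior_rate = 0.5,
                           behavior_asymptote = c(control = 0.9, patient = 0.9))
  t <- 1:8
  p_t <- 0.9 * (1 - exp(-0.5 * t))
  expect_true(all(diff(p_t) >= 0))  # weakly monotone in expectation
  sums <- numeric(8)
  for (i in seq_len(10000)) {
    sums <- sums + rowMeans(generate_behavior(cfg, "control", i))
  }
  expect_true(all(abs(sums / 10000 - p_t) < 0.01))
})

test_that("designated non-monotone performers get a mid-task dip", {
  cfg <- toy_cohort_config()
  p_mono <- attr(generate_behavior(cfg, "control", 1), "prob")
  p_non <- attr(generate_behavior(cfg, "control", 1, nonmonotone = TRUE),
                "prob")
  expect_true(all(diff(p_mono) >= 0))
  expect_lt(p_non[4], p_non[3])  # the dip breaks monotonicity of p_t
  expect_equal(p_non[c(4, 5)], p_mono[c(4, 5)] * cfg$nonmono_dip)
  expect_equal(p_non[-c(4, 5)], p_mono[-c(4, 5)])
})
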