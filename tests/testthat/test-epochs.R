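test_that("the default block design yields 32 windows of 9 volumes", {
  design <- epoch_design()
  expect_equal(nrow(design), 288L)
  set.seed(1)
  x <- matrix(rnorm(5 * 288), 5, 288)
  seg <- segment_epochs(x, design)
  expect_length(seg, 32L)
  expect_true(all(vapply(seg, ncol, integer(1)) == 9L))
})

test_that("segmentation partitions the series and reassembles it exactly", {
  design <- epoch_design(conditions = "Encoding", n_iterations = 8,
                         volumes_per_epoch = 9)
  set.seed(7)
  x <- matrix(rnorm(3 * 72), 3, 72)
  seg <- segment_epochs(x, design)
  expect_length(seg, 8L)
  # windows are contiguous and ordered, so column-binding restores the input
  expect_identical(do.call(cbind, unname(seg)), x)
})

test_that("lag shifts windows and rejects out-of-bounds shifts", {
  design <- epoch_design(conditions = "Encoding", n_iterations = 8,
                         volumes_per_epoch = 9)
  set.seed(8)
  x <- matrix(rnorm(2 * 74), 2, 74)  # two trailing volumes beyond the design
  expect_identical(segment_epochs(x, design, 0)[["Encoding#1"]],
                   x[, 1:9, drop = FALSE])
  # a 1-volume lag shifts every window forward by one column
  expect_identical(segment_epochs(x, design, 1)[["Encoding#1"]],
                   x[, 2:10, drop = FALSE])
  expect_identical(segment_epochs(x, design, 2)[["Encoding#8"]],
                   x[, 66:74, drop = FALSE])
  # on a series the design covers exactly, a positive lag overruns the end
  x72 <- x[, 1:72, drop = FALSE]
  expect_error(segment_epochs(x72, design, lag_volumes = 2),
               "iteration 8.*out of bounds|out of bounds")
  expect_error(segment_epochs(x, design, lag_volumes = -1), "lag_volumes")
  expect_error(segment_epochs(x[, 1:71, drop = FALSE], design),
               "only 71")
})

test_that("designs with missing or unbalanced cells are rejected", {
  design <- epoch_design(conditions = c("A", "B"), n_iterations = 2,
                         volumes_per_epoch = 3)
  broken <- design
  broken$condition[broken$condition == "B" & broken$iteration == 2] <- "A"
  expect_error(validate_epoch_design(broken), "missing cell|same number")
  dup <- design
  dup$volume_index[2] <- 0L
  expect_error(validate_epoch_design(dup), "exactly once")
})

test_that("percent signal change matches its defining formula", {
  # constant series: psc identically 0
  x <- matrix(5, 2, 6)
  expect_true(all(percent_signal_change(x) == 0))

  # hand-computed toy: (100, 110, 90) around mean 100 -> (0, 10, -10)
  y <- matrix(c(100, 110, 90), 1, 3)
  expect_equal(as.numeric(percent_signal_change(y)), c(0, 10, -10))

  # a volume at 1.1x the region mean maps to exactly 10 percent:
  # nine volumes at 100 plus v with v = 1.1 * mean forces v = 990/8.9
  v <- 990 / 8.9
  row <- matrix(c(rep(100, 9), v), 1, 10)
  expect_equal(percent_signal_change(row)[1, 10], 10)

  # per-region mean of psc is 0 to numerical tolerance
  set.seed(2)
  m <- matrix(rexp(4 * 10) + 1, 4, 10)
  psc <- percent_signal_change(m)
  expect_equal(rowMeans(psc), rep(0, 4), tolerance = 1e-12)

  # invariance to positive rescaling of a region
  m2 <- m
  m2[3, ] <- m[3, ] * 7.5
  expect_equal(percent_signal_change(m2)[3, ], psc[3, ], tolerance = 1e-9)

  # zero-mean region is a named degenerate-signal error
  bad <- rbind(c(1, -1), c(2, 4))
  rownames(bad) <- c("R001", "R002")
  expect_error(percent_signal_change(bad), "R001.*zero")
})

test_that("epoch-mean trajectories equal brute-force window averages", {
  design <- epoch_design(conditions = c("A", "B"), n_iterations = 2,
                         volumes_per_epoch = 3)
  set.seed(3)
  x <- matrix(rexp(2 * 12) + 5, 2, 12)
  rownames(x) <- c("R001", "R002")
  psc <- percent_signal_change(x)
  tr <- epoch_mean_psc(psc, design)
  expect_equal(nrow(tr), 2L * 2L * 2L)
  for (k in seq_len(nrow(tr))) {
    vols <- design$volume_index[design$condition == tr$condition[k] &
                                design$iteration == tr$iteration[k]] + 1L
    expect_equal(tr$mean_psc[k], mean(psc[tr$region[k], vols]))
  }

  # psc identically zero -> all trajectories zero
  tr0 <- epoch_mean_psc(matrix(0, 2, 12,
                               dimnames = list(c("a", "b"), NULL)), design)
  expect_true(all(tr0$mean_psc == 0))
})
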