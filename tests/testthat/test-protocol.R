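# net projected weight at a node's centre cell at run-clock step t_run
projected_at_node <- function(config, node, t_run) {
  src <- experiment_sources(config)
  nc <- node_cells(config$array, node)
  t_abs <- config$warmup_steps + config$stabilize_steps + t_run
  act <- src[, "from"] <= t_abs & t_abs < src[, "to"] &
         src[, "x"] == nc$x & src[, "y"] == nc$y
  sum(src[act, "weight"])
}

test_that("node indexing follows column-major (col, row) order", {
  arr <- node_array()
  expect_equal(node_index(arr, 2, 2), 7)
  expect_equal(node_index(arr, 3, 5), 23)
  expect_equal(node_index(arr, 1, 4), 16)
  expect_equal(node_index(arr, 2, 4), 17)
  nc <- node_cells(arr, c(7, 23))
  expect_equal(nc$col, c(2, 3))
  expect_equal(nc$row, c(2, 5))
  expect_equal(nc$x, c(10 + 45, 10 + 2 * 45))
  expect_equal(nc$y, c(10 + 45, 10 + 4 * 45))
  expect_equal(node_neighbours(arr, 7), c(6, 8, 2, 12))
  expect_equal(sort(node_neighbours(arr, 23)), c(18, 22, 24))
})

test_that("grid mask size matches the analytic segment-union count", {
  # horizontal + vertical bands minus their overlap; edge segments overlap
  # the perpendicular bands over only (t+1)/2 cells, giving ((n-1)t+1)^2
  # double-counted cells in total
  union_count <- function(n, s, t) {
    L <- (n - 1) * s + 1
    2 * n * t * L - ((n - 1) * t + 1)^2
  }
  for (t in c(9, 13)) {
    m <- build_grid_mask(node_array(), t)
    expect_equal(nrow(m), union_count(5, 45, t))
    expect_equal(nrow(unique(m)), nrow(m))
  }
  # default mask must hold the default population
  expect_gte(nrow(build_grid_mask(node_array(), 13)), 8000)
})

test_that("degenerate masks reduce to a rectangle and a single block", {
  arr <- node_array(n_cols = 3, n_rows = 3, origin = c(20, 20), spacing = 10)
  m <- build_grid_mask(arr, 10)     # thickness = spacing tiles the square
  full <- expand.grid(x = 20:40, y = 20:40)   # node bounding square
  expect_true(all(paste(full$x, full$y) %in% paste(m[, 1], m[, 2])))

  one <- build_grid_mask(node_array(n_cols = 1, n_rows = 1,
                                    origin = c(50, 50)), 5)
  expect_equal(nrow(one), 25)
  expect_true(all(abs(one[, 1] - 50) <= 2 & abs(one[, 2] - 50) <= 2))
})

test_that("positive protocol projects the stated net levels", {
  cfg <- positive_experiment(experiment_config(run_steps = 3500))
  expect_equal(projected_at_node(cfg, 7, 1000), 500)
  expect_equal(projected_at_node(cfg, 23, 1000), 500)
  expect_equal(projected_at_node(cfg, 8, 1000), 5)
  expect_equal(projected_at_node(cfg, 7, 499), 5)    # before onset
  expect_equal(projected_at_node(cfg, 7, 2600), 5)   # after removal
  # during warm-up the mask confines instead: node cells sit on the mask
  src <- experiment_sources(cfg)
  nc <- node_cells(cfg$array, 7)
  act <- src[, "from"] <= 0 & 0 < src[, "to"] &
         src[, "x"] == nc$x & src[, "y"] == nc$y
  expect_equal(sum(src[act, "weight"]), cfg$mask_weight)
})

test_that("negative protocols project the stated net levels", {
  rel <- relative_negative_experiment(experiment_config(run_steps = 4500))
  expect_equal(projected_at_node(rel, 17, 1000), 1)
  expect_equal(projected_at_node(rel, 16, 1000), 1)
  expect_equal(projected_at_node(rel, 18, 1000), 5)
  expect_equal(projected_at_node(rel, 17, 3000), 5)  # restored to baseline

  rep_ <- repellent_experiment(experiment_config(run_steps = 4500))
  expect_equal(projected_at_node(rep_, 16, 1000), -500)
  expect_equal(projected_at_node(rep_, 16, 3000), 5)
  expect_equal(projected_at_node(rep_, 12, 1000), 5)

  # zero-magnitude repellent collapses onto the baseline protocol
  noop <- repellent_experiment(experiment_config(run_steps = 4500),
                               stim_weight = 5)
  expect_equal(projected_at_node(noop, 16, 1000), 5)
})

test_that("repeated protocol alternates on/off windows by arithmetic", {
  cfg <- repeated_stimulus_experiment(experiment_config(run_steps = 4000),
                                      n_cycles = 3, on_steps = 500,
                                      off_steps = 500)
  expect_equal(cfg$on_windows[, "from"], c(0, 1000, 2000))
  expect_equal(cfg$on_windows[, "to"], c(500, 1500, 2500))
  expect_equal(projected_at_node(cfg, 7, 250), 500)
  expect_equal(projected_at_node(cfg, 7, 750), 5)
  expect_equal(projected_at_node(cfg, 7, 1250), 500)
  expect_equal(projected_at_node(cfg, 8, 1250), 5)
  # single cycle reduces to one positive pulse
  one <- repeated_stimulus_experiment(experiment_config(run_steps = 2000),
                                      n_cycles = 1)
  expect_equal(nrow(one$on_windows), 1)
  expect_equal(projected_at_node(one, 7, 250), 500)
})

test_that("constructing experiments never mutates simulator state", {
  cfg <- experiment_config(run_steps = 100)
  snap <- unserialize(serialize(cfg, NULL))
  invisible(positive_experiment(cfg))
  invisible(repellent_experiment(cfg))
  expect_identical(cfg, snap)
  expect_s3_class(cfg$schedule, "stimulus_schedule")
})

test_that("runs conserve particles and are reproducible from the seed", {
  r1 <- run_experiment(small_config(seed = 5))
  r2 <- run_experiment(small_config(seed = 5))
  r3 <- run_experiment(small_config(seed = 6))
  expect_equal(length(r1$population$x), 800)
  expect_equal(sum(r1$env$occupancy), 800)
  expect_true(all(r1$series$counts >= 0))
  expect_true(all(colSums(r1$series$counts) <= 800))
  expect_identical(r1$series, r2$series)
  expect_identical(r1$population, r2$population)
  expect_false(identical(r1$series$counts, r3$series$counts))
})

test_that("invalid geometry is rejected before any stepping", {
  expect_error(experiment_config(array = node_array(origin = c(2, 10))),
               "window")
  expect_error(experiment_config(run_steps = 0))
})
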