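test_that("sensors sample the stated cells for the reference parameters", {
  env <- lattice_environment(100, 100)
  # mark the three cells the SA=60, SO=9 sensors should hit from (50,50), h=0
  env$attractant[51, 60] <- 1   # F  at cell (59, 50)
  env$attractant[58, 55] <- 2   # FL at cell (54, 57)
  env$attractant[43, 55] <- 4   # FR at cell (54, 42)
  v <- sense(particle(50, 50, 0), env, model_params())
  expect_equal(unname(v), c(1, 2, 4))
})

test_that("sensors agree on a uniform field and rank a gradient correctly", {
  env <- lattice_environment(100, 100)
  env$attractant[] <- 3
  v <- sense(particle(40.2, 61.7, 123), env, model_params())
  expect_equal(unname(v), c(3, 3, 3))

  # field = x coordinate: the forward sensor reaches furthest in +x
  env$attractant <- matrix(rep(0:99, each = 100), 100, 100)
  v <- sense(particle(50, 50, 0), env, model_params())
  expect_gt(v["F"], v["FL"])
  expect_gt(v["F"], v["FR"])
})

test_that("orientation follows the rule table", {
  p <- particle(10, 10, 90)
  prm <- model_params()
  expect_equal(orient(p, 5, 1, 1, prm)$heading, 90)        # forward wins
  expect_equal(orient(p, 2, 3, 1, prm)$heading, 150)       # left stronger
  expect_equal(orient(p, 2, 1, 3, prm)$heading, 30)        # right stronger
  expect_equal(orient(p, 2, 2, 2, prm)$heading, 90)        # exact tie
  expect_equal(orient(particle(0, 0, 350), 2, 3, 1, prm)$heading, 50)
})

test_that("a particle boxed in on both sides rotates randomly 50/50", {
  prm <- model_params()
  set.seed(81)
  h <- replicate(1e4, orient(particle(0, 0, 90), 1, 2, 2, prm)$heading)
  expect_setequal(unique(h), c(30, 150))
  expect_lt(abs(mean(h == 150) - 0.5), 0.05)
})

test_that("successful moves advance one step and deposit attractant", {
  env <- lattice_environment(30, 30)
  prm <- model_params(population_size = 1)
  p <- particle(10.5, 10.5, 0)
  env$occupancy[11, 11] <- 1L
  res <- attempt_move(p, env, prm)
  expect_true(res$moved)
  expect_equal(res$particle$x, 11.5)
  expect_equal(res$particle$y, 10.5)
  expect_equal(res$env$attractant[11, 12], 5)   # deposited at the new cell
  expect_equal(sum(res$env$attractant), 5)
  expect_equal(res$env$occupancy[11, 12], 1L)
  expect_equal(res$env$occupancy[11, 11], 0L)
})

test_that("blocked and out-of-bounds moves keep position and re-randomize", {
  env <- lattice_environment(30, 30)
  prm <- model_params(population_size = 2)
  env$occupancy[11, 11] <- 1L
  env$occupancy[11, 12] <- 1L    # candidate cell occupied
  set.seed(82)
  res <- attempt_move(particle(10.5, 10.5, 0), env, prm)
  expect_false(res$moved)
  expect_equal(res$particle$x, 10.5)
  expect_true(all(res$env$attractant == 0))
  expect_identical(res$env$occupancy, env$occupancy)

  env2 <- lattice_environment(30, 30)
  env2$occupancy[11, 1] <- 1L
  res2 <- attempt_move(particle(0.5, 10.5, 180), env2, prm)
  expect_false(res2$moved)       # candidate off-lattice counts as occupied
  expect_equal(res2$particle$x, 0.5)
})

test_that("an undisturbed particle walks a straight line to the boundary", {
  env <- lattice_environment(40, 40)
  prm <- model_params(deposition = 0, population_size = 1)
  pop <- population(10.5, 20.5, 0)
  env$occupancy[21, 11] <- 1L
  sch <- stimulus_schedule(list())
  for (t in 0:28) {
    st <- scheduler_step(pop, env, sch, prm, t)
    pop <- st$population; env <- st$env
    expect_equal(pop$x, 10.5 + t + 1)
    expect_equal(pop$y, 20.5)
  }
  st <- scheduler_step(pop, env, sch, prm, 29)  # next step would leave
  expect_equal(st$population$x, 39.5)           # blocked at the wall
})

test_that("scheduler steps conserve the population and its exclusion", {
  set.seed(83)
  env <- lattice_environment(50, 50)
  prm <- model_params(population_size = 300, sensor_offset = 5)
  mask <- as.matrix(expand.grid(x = 10:39, y = 10:39))
  ino <- inoculate(mask, prm, env)
  pop <- ino$population; env <- ino$env
  sch <- stimulus_schedule(stimulus_source(25, 25, 50, 0, 100))
  for (t in 0:19) {
    st <- scheduler_step(pop, env, sch, prm, t)
    pop <- st$population; env <- st$env
    expect_equal(length(pop$x), 300)
    expect_equal(sum(env$occupancy), 300)       # no doubled-up cells
    expect_identical(
      sort(unique(paste(floor(pop$x), floor(pop$y)))),
      sort(paste(floor(pop$x), floor(pop$y))))
  }
})

test_that("equal seeds give bit-identical trajectories", {
  run_once <- function() {
    set.seed(84)
    env <- lattice_environment(60, 60)
    prm <- model_params(population_size = 200)
    mask <- as.matrix(expand.grid(x = 20:39, y = 20:39))
    ino <- inoculate(mask, prm, env)
    pop <- ino$population; env <- ino$env
    sch <- stimulus_schedule(list())
    for (t in 0:99) {
      st <- scheduler_step(pop, env, sch, prm, t)
      pop <- st$population; env <- st$env
    }
    pop
  }
  a <- run_once(); b <- run_once()
  expect_identical(a, b)
})

test_that("inoculation fills masks exactly, reproducibly, within bounds", {
  env <- lattice_environment(30, 30)
  prm <- model_params(population_size = 25)
  mask <- as.matrix(expand.grid(x = 5:9, y = 5:9))
  set.seed(85)
  ino <- inoculate(mask, prm, env)
  expect_equal(sum(ino$env$occupancy), 25)      # pigeonhole: all cells used
  expect_true(all(ino$env$occupancy[6:10, 6:10] == 1L))
  expect_true(all(floor(ino$population$x) %in% 5:9))

  big <- as.matrix(expand.grid(x = 0:19, y = 0:19))
  set.seed(1); a <- inoculate(big, prm, env)
  set.seed(1); b <- inoculate(big, prm, env)
  set.seed(2); c <- inoculate(big, prm, env)
  expect_identical(a$population, b$population)
  expect_false(identical(a$population$x, c$population$x))

  expect_error(inoculate(mask, model_params(population_size = 26), env),
               "mask has")
})

test_that("free populations aggregate into heterogeneous patterns", {
  # emergent network formation: per-block counts become overdispersed
  # relative to a uniform random placement of the same population
  block_var <- function(occ) {
    blk <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      blk[i, j] <- sum(occ[((i - 1) * 10 + 1):(i * 10),
                           ((j - 1) * 10 + 1):(j * 10)])
    }
    stats::var(as.vector(blk))
  }
  prm <- model_params()
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    env <- lattice_environment(200, 200)
    cells <- as.matrix(expand.grid(x = 0:199, y = 0:199))
    ino <- inoculate(cells, prm, env)
    res <- physarum:::cpp_run(ino$population$x, ino$population$y,
                              ino$population$heading, ino$env$attractant,
                              ino$env$occupancy,
                              matrix(numeric(0), ncol = 5), 0L, 2000L,
                              60, 60, 9, 5, 1, 5L, 0.9,
                              matrix(integer(0), ncol = 4), 0L, 0L)
    set.seed(seed + 1000)
    unif <- lattice_environment(200, 200)
    unif <- inoculate(cells, prm, unif)$env
    if (block_var(res$occupancy) > block_var(unif$occupancy)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
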