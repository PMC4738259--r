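test_that("relative change is the end/start ratio and scale invariant", {
  expect_equal(relative_change(1e5, 2e5), 2)
  expect_equal(relative_change(123, 123), 1)
  expect_equal(relative_change(7 * 50, 3 * 50), relative_change(7, 3))
  expect_error(relative_change(0, 10), "positive")
  expect_error(relative_change(10, -1), "positive")
})

test_that("exact U test reproduces enumerated reference cases", {
  r <- mann_whitney_u_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)            # 2 of the 20 labelings are as extreme
  expect_identical(r$method, "exact")

  same <- mann_whitney_u_exact(c(2, 5, 9), c(9, 2, 5))
  expect_equal(same$p, 1)

  r2 <- mann_whitney_u_exact(c(1, 1, 2), c(1, 2, 2))  # heavy ties
  o2 <- brute_mw_exact(c(1, 1, 2), c(1, 2, 2))
  expect_equal(r2$U, o2$U)
  expect_equal(r2$p, o2$p)

  expect_error(mann_whitney_u_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals the permutation oracle for all n_a + n_b <= 10", {
  set.seed(101)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:3) {
        # small alphabet forces ties in most draws
        a <- sample(1:4, na, replace = TRUE) + 0.5 * rbinom(na, 1, 0.5)
        b <- sample(1:4, nb, replace = TRUE) + 0.5 * rbinom(nb, 1, 0.5)
        got <- mann_whitney_u_exact(a, b)
        want <- brute_mw_exact(a, b)
        expect_equal(got$U, want$U)
        expect_equal(got$p, want$p)
      }
    }
  }
})

test_that("the U statistic is invariant under monotone transforms", {
  set.seed(102)
  a <- rlnorm(6); b <- rlnorm(7, meanlog = 0.8)
  r0 <- mann_whitney_u_exact(a, b)
  for (f in list(log, sqrt, function(x) 3 * x + 2)) {
    r <- mann_whitney_u_exact(f(a), f(b))
    expect_equal(r$U, r0$U)
    expect_equal(r$p, r0$p)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(103)
  a <- rnorm(20); b <- rnorm(20, 1)
  r <- mann_whitney_u_exact(a, b)
  expect_identical(r$method, "normal approximation")
  w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
})

test_that("the synthetic generator is reproducible and well-formed", {
  d1 <- generate_synthetic_experiments("HAHF", 5, seed = 11)
  d2 <- generate_synthetic_experiments("HAHF", 5, seed = 11)
  d3 <- generate_synthetic_experiments("HAHF", 5, seed = 12)
  expect_identical(d1, d2)
  expect_false(identical(d1$r_end_ohm, d3$r_end_ohm))
  expect_equal(nrow(d1), 5 * 16)
  per <- tapply(d1$stimulated, d1$experiment_id, sum)
  expect_true(all(per == 1))        # exactly one stimulated pair each
  expect_true(all(d1$r_start_ohm > 0 & d1$r_end_ohm > 0))
  expect_length(attr(d1, "outcome"), 5)
})

test_that("LALF responders put every unstimulated pair 3-16x the stimulated", {
  for (seed in 1:25) {
    d <- generate_synthetic_experiments("LALF", 2, seed = seed)
    out <- attr(d, "outcome")
    for (e in which(out == "responding")) {
      de <- d[d$experiment_id == e, ]
      rc <- relative_change(de$r_start_ohm, de$r_end_ohm)
      ratio <- rc[!de$stimulated] / rc[de$stimulated]
      expect_true(all(ratio >= 3 & ratio <= 16))
    }
  }
})

test_that("HAHF responders double the stimulated pair's relative change", {
  for (seed in 1:25) {
    d <- generate_synthetic_experiments("HAHF", 2, seed = seed)
    out <- attr(d, "outcome")
    for (e in which(out == "responding")) {
      de <- d[d$experiment_id == e, ]
      rc <- relative_change(de$r_start_ohm, de$r_end_ohm)
      fold <- rc[de$stimulated] / mean(rc[!de$stimulated])
      expect_gt(fold, 1.5)
      expect_lt(fold, 2.6)
    }
  }
})

test_that("the analyzer flags separated groups and not identical ones", {
  # perfectly separated synthetic groups reach the minimal attainable p
  d <- generate_synthetic_experiments("HAHF", 6, seed = 21)
  d$r_end_ohm <- d$r_start_ohm * ifelse(d$stimulated, 5, 1.05)
  rep_sep <- analyze_experiment_set(d)
  expect_equal(rep_sep$U, 0)
  expect_equal(rep_sep$p, brute_mw_exact(rep(5, 6), rep(1.05, 6))$p)
  expect_true(rep_sep$significant)

  d$r_end_ohm <- d$r_start_ohm * 1.3     # all ratios equal
  rep_eq <- analyze_experiment_set(d)
  expect_equal(rep_eq$p, 1)
  expect_false(rep_eq$significant)
})

test_that("HAHF experiment sets test significant in most replicates", {
  hits <- 0
  for (seed in 1:10) {
    d <- generate_synthetic_experiments("HAHF", 10, seed = 300 + seed)
    if (analyze_experiment_set(d)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("the analyzer validates completeness of the pairing grid", {
  d <- generate_synthetic_experiments("HAHF", 3, seed = 31)
  expect_error(analyze_experiment_set(d[1:16, ]), "at least 2")
  broken <- d[!(d$experiment_id == 2 & d$left == 3 & d$right == 2), ]
  expect_error(analyze_experiment_set(broken), "missing pair")
  twice <- d; twice$stimulated[twice$experiment_id == 1][1:2] <- TRUE
  expect_error(analyze_experiment_set(twice), "exactly one stimulated")
})

test_that("resistance records round-trip through CSV", {
  d <- generate_synthetic_experiments("LALF", 4, seed = 41)
  f <- tempfile(fileext = ".csv")
  write_resistance_csv(d, f)
  back <- read_resistance_csv(f)
  expect_equal(back$r_start_ohm, d$r_start_ohm, tolerance = 1e-12)
  expect_identical(back$stimulated, d$stimulated)
  expect_identical(back$left, d$left)
})
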