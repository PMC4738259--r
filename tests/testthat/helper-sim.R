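# Shared fixtures and oracles for the simulation tests.

# Small, fast experiment geometry: 3x3 array on a 100x100 lattice, 800
# particles. Used wherever a property does not depend on the full-scale
# study conditions.
small_config <- function(seed = 1, ...) {
  experiment_config(
    width = 100, height = 100,
    params = model_params(population_size = 800),
    array = node_array(n_cols = 3, n_rows = 3, origin = c(20, 20),
                       spacing = 30),
    warmup_steps = 100, stabilize_steps = 100, run_steps = 200,
    mask_thickness = 9, seed = seed, sampling_interval = 10, ...)
}

# Brute-force mean-filter diffusion: direct window sums, absorbing boundary,
# fixed k^2 divisor. Independent of the package's separable implementation.
brute_diffuse <- function(field, k, damping) {
  h <- nrow(field); w <- ncol(field); r <- k %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      s <- 0
      for (di in -r:r) for (dj in -r:r) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) s <- s + field[ii, jj]
      }
      out[i, j] <- damping * s / (k * k)
    }
  }
  out
}

# Brute-force exact two-tailed Mann-Whitney p: enumerates group labelings
# and computes U by direct pair counting (no ranks), so it shares no code
# path with mann_whitney_u_exact.
brute_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  u_of <- function(idx) {
    A <- pool[idx]; B <- pool[-idx]
    ua <- sum(vapply(A, function(x) sum(x > B) + 0.5 * sum(x == B),
                     numeric(1)))
    min(ua, na * nb - ua)
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(na + nb, na), 2, u_of)
  list(U = u_obs, p = mean(us <= u_obs + 1e-9))
}

# OLS slope of a node's occupancy against run-clock time over [from, to)
trend_slope <- function(series, node, from, to) {
  sel <- series$times >= from & series$times < to
  fit <- stats::lm(y ~ t, data.frame(t = series$times[sel],
                                     y = series$counts[node, sel]))
  unname(stats::coef(fit)[2])
}

# Memoised full-scale experiment runs shared across acceptance tests.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(type, seed) {
  key <- paste(type, seed, sep = "_")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cfg <- switch(type,
    positive = positive_experiment(experiment_config(seed = seed,
                                                     run_steps = 3500)),
    repeated = repeated_stimulus_experiment(
      experiment_config(seed = seed, run_steps = 4000)),
    relative = relative_negative_experiment(
      experiment_config(seed = seed, run_steps = 4500)),
    repellent = repellent_experiment(
      experiment_config(seed = seed, run_steps = 4500)),
    stop("unknown run type: ", type))
  res <- run_experiment(cfg)
  .run_cache[[key]] <- res
  res
}
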