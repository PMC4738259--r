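#' Regular array of stimulus/measurement nodes
#'
#' The node array mirrors an electrode grid: \code{n_cols} x \code{n_rows}
#' points spaced \code{spacing} cells apart, each with a square measurement
#' window of half-width \code{window_half_width} (the default 6 gives the
#' 13 x 13 window). Node k maps to 1-based \code{(col, row) =
#' (((k-1) mod n_cols) + 1, (k-1) \%/\% n_cols + 1)}, so on the default 5 x 5
#' array node 7 sits at (2,2) and node 23 at (3,5).
#'
#' @param n_cols,n_rows Array dimensions; default 5 x 5.
#' @param origin 0-based \code{(x, y)} cell of node (1,1); default c(10, 10)
#'   centres the default array on a 200 x 200 lattice.
#' @param spacing Distance between adjacent nodes in cells; default 45, so
#'   13 x 13 windows can never overlap and the array footprint is large
#'   enough for the 8000-particle population to hold a reticulated network
#'   rather than condensing into a solid mass.
#' @param window_half_width Window half-width in cells; default 6.
#' @return An object of class \code{"node_array"}.
#' @export
node_array <- function(n_cols = 5, n_rows = 5, origin = c(10, 10),
                       spacing = 45, window_half_width = 6) {
  stopifnot(n_cols >= 1, n_rows >= 1, spacing >= 1, window_half_width >= 0)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 origin = as.integer(origin), spacing = as.integer(spacing),
                 window_half_width = as.integer(window_half_width)),
            class = "node_array")
}

#' Node index from (column, row), and node cell coordinates
#'
#' @param array A \code{node_array}.
#' @param col,row 1-based node column and row.
#' @return \code{node_index}: the linear node index.
#' @export
node_index <- function(array, col, row) {
  stopifnot(col >= 1, col <= array$n_cols, row >= 1, row <= array$n_rows)
  (row - 1L) * array$n_cols + col
}

#' @rdname node_index
#' @param k Linear node index (or vector of indices).
#' @return \code{node_cells}: data frame with \code{node}, 1-based
#'   \code{col}/\code{row}, and 0-based lattice cell \code{x}/\code{y}.
#' @export
node_cells <- function(array, k = seq_len(array$n_cols * array$n_rows)) {
  col <- (k - 1L) %% array$n_cols + 1L
  row <- (k - 1L) %/% array$n_cols + 1L
  data.frame(node = k, col = col, row = row,
             x = array$origin[1] + (col - 1L) * array$spacing,
             y = array$origin[2] + (row - 1L) * array$spacing)
}

# window bounds (xmin, xmax, ymin, ymax), 0-based inclusive, one row per node
node_windows <- function(array) {
  nc <- node_cells(array)
  hw <- array$window_half_width
  cbind(xmin = nc$x - hw, xmax = nc$x + hw,
        ymin = nc$y - hw, ymax = nc$y + hw)
}

validate_array <- function(array, width, height) {
  w <- node_windows(array)
  bad <- which(w[, "xmin"] < 0 | w[, "ymin"] < 0 |
               w[, "xmax"] >= width | w[, "ymax"] >= height)
  if (length(bad)) {
    stop(sprintf("measurement window of node %s extends outside the lattice",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Build the grid inoculation mask
#'
#' Returns the cells of the lattice-shaped mask: straight segments of the
#' given thickness connecting adjacent nodes horizontally and vertically
#' (for a single node, just a thickness x thickness block). The mask is where
#' the population is confined by strong attractant during warm-up; it must
#' hold at least one cell per particle.
#'
#' @param array A \code{node_array}.
#' @param thickness Segment thickness in cells; default 9, which gives the
#'   default 5 x 5 array (spacing 45) a union of 14921 cells, so the default
#'   8000-particle population is confined at a density that still lets
#'   particles rearrange.
#' @return Two-column integer matrix of 0-based \code{(x, y)} cells.
#' @export
build_grid_mask <- function(array, thickness = 9) {
  stopifnot(thickness >= 1)
  lo <- -((thickness - 1L) %/% 2L)
  hi <- thickness %/% 2L
  nc <- node_cells(array)
  xs <- sort(unique(nc$x)); ys <- sort(unique(nc$y))
  xspan <- seq(min(xs), max(xs)); yspan <- seq(min(ys), max(ys))
  cells <- list()
  for (y0 in ys) {                       # horizontal segments (or node blocks)
    xr <- if (length(xs) > 1) xspan else xs + seq(lo, hi)
    cells[[length(cells) + 1]] <- expand.grid(x = xr, y = y0 + seq(lo, hi))
  }
  if (length(ys) > 1) {
    for (x0 in xs) {                     # vertical segments
      cells[[length(cells) + 1]] <- expand.grid(x = x0 + seq(lo, hi), y = yspan)
    }
  }
  m <- unique(do.call(rbind, cells))
  as.matrix(m[order(m$y, m$x), , drop = FALSE])
}

#' Experiment configuration
#'
#' A declarative description of one simulated stimulation experiment: lattice
#' geometry, particle parameters, node array, warm-up confinement, and the
#' stimulus schedule. Stimulus times in \code{schedule} are on the run clock
#' (step 0 = first step after warm-up confinement plus stabilization); the
#' runner shifts them onto the absolute clock. Baseline
#' attractant of \code{baseline_weight} units/step is projected at every node
#' for the whole post-warm-up run; \code{schedule} holds only the per-node
#' deviations from baseline.
#'
#' @param width,height Lattice dimensions; default 200 x 200.
#' @param params A \code{model_params}.
#' @param array A \code{node_array}.
#' @param baseline_weight Attractant units/step at every node after warm-up;
#'   default 5, matching the particle deposition level.
#' @param warmup_steps Steps of mask confinement before the run; default 500.
#' @param stabilize_steps Baseline-only steps between mask removal and the
#'   start of the run clock, letting the released population settle into its
#'   stabilized network before any protocol stimulus; default 3000 (the
#'   slow drift of the default geometry has died out by then, so run-clock
#'   series start from a stationary baseline).
#' @param run_steps Run-clock steps; total steps = warmup + stabilize + run.
#' @param schedule A \code{stimulus_schedule} of deviations from baseline, on
#'   the run clock.
#' @param mask_weight Attractant units/step at every mask cell during
#'   warm-up; default 500 (strong confinement).
#' @param mask_thickness Grid-mask segment thickness; default 13, confining
#'   the default population at about 40\% of mask cells so the sheet can
#'   still rearrange.
#' @param stimulus_footprint Chebyshev radius of each node source's
#'   projection footprint in cells; default 1, i.e. stimuli and baseline are
#'   projected at their per-cell level over a 3 x 3 disc around the node
#'   cell (0 = single-cell point source). The footprint is what lets the
#'   weak 5-unit baseline anchor the network at the nodes against
#'   trail-driven coarsening.
#' @param seed Integer RNG seed, or NULL to use the current RNG state.
#' @param sampling_interval Steps between occupancy samples; default 10.
#' @param damping,kernel_size Diffusion parameters; defaults 0.9 and 5.
#' @return An object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(width = 200, height = 200,
                              params = model_params(),
                              array = node_array(),
                              baseline_weight = 5,
                              warmup_steps = 500, stabilize_steps = 3000,
                              run_steps = 4000,
                              schedule = stimulus_schedule(list()),
                              mask_weight = 500, mask_thickness = 13,
                              stimulus_footprint = 1,
                              seed = NULL, sampling_interval = 10,
                              damping = 0.9, kernel_size = 5) {
  stopifnot(warmup_steps >= 0, stabilize_steps >= 0, run_steps >= 1,
            sampling_interval >= 1)
  cfg <- structure(list(width = as.integer(width), height = as.integer(height),
                        params = params, array = array,
                        baseline_weight = baseline_weight,
                        warmup_steps = as.integer(warmup_steps),
                        stabilize_steps = as.integer(stabilize_steps),
                        run_steps = as.integer(run_steps),
                        total_steps = as.integer(warmup_steps + stabilize_steps
                                                 + run_steps),
                        schedule = schedule,
                        mask_weight = mask_weight,
                        mask_thickness = as.integer(mask_thickness),
                        stimulus_footprint = as.integer(stimulus_footprint),
                        seed = seed,
                        sampling_interval = as.integer(sampling_interval),
                        damping = damping, kernel_size = as.integer(kernel_size)),
                   class = "experiment_config")
  validate_array(array, cfg$width, cfg$height)
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config %dx%d lattice, %d particles>\n",
              x$width, x$height, x$params$population_size))
  cat(sprintf("  warm-up %d + stabilize %d steps (mask weight %g), run %d steps, baseline %g/step\n",
              x$warmup_steps, x$stabilize_steps, x$mask_weight, x$run_steps,
              x$baseline_weight))
  cat(sprintf("  %d schedule deviations, sampling every %d steps, seed %s\n",
              length(x$schedule$sources), x$sampling_interval,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# deviations from baseline at given node indices over [from, to) (run clock);
# each node projects over a (2r+1) x (2r+1) cell footprint at `weight` per cell
node_deviation_sources <- function(array, nodes, weight, from, to,
                                   footprint = 1) {
  nc <- node_cells(array, nodes)
  offs <- expand.grid(dx = -footprint:footprint, dy = -footprint:footprint)
  out <- vector("list", nrow(nc) * nrow(offs))
  k <- 0
  for (i in seq_len(nrow(nc))) {
    for (j in seq_len(nrow(offs))) {
      k <- k + 1
      out[[k]] <- stimulus_source(nc$x[i] + offs$dx[j], nc$y[i] + offs$dy[j],
                                  weight, from, to)
    }
  }
  out
}

#' Built-in stimulation experiments
#'
#' Constructors for the four canonical protocols, expressed as deviations
#' from the 5-units/step node baseline on the run clock:
#' \describe{
#'   \item{\code{positive_experiment}}{Nodes (2,2) and (3,5) (indices 7 and
#'     23) receive a net 500 units/step over steps [500, 2500), i.e. a +495
#'     deviation; afterwards every node is back at baseline.}
#'   \item{\code{relative_negative_experiment}}{Target nodes project a net 1
#'     unit/step (deviation -4) during the stimulus window, then return to
#'     baseline; all other nodes stay at 5. The targets are negative only
#'     relative to the rest of the array.}
#'   \item{\code{repellent_experiment}}{Target nodes project a net -500
#'     units/step (deviation -505) during the window: a true repellent that
#'     diffuses as a negative well.}
#'   \item{\code{repeated_stimulus_experiment}}{One node (default 7)
#'     alternates between net 500 (on) and net 5 (off) for \code{n_cycles}
#'     cycles.}
#' }
#' Default target nodes for the negative protocols are (1,4) and (2,4)
#' (indices 16 and 17).
#'
#' @param base An \code{experiment_config} to start from.
#' @param nodes Stimulated node indices.
#' @param stim_weight Net units/step at stimulated nodes while on.
#' @param from,to Stimulus window on the run clock, [from, to).
#' @return An \code{experiment_config} with the schedule filled in.
#' @export
positive_experiment <- function(base = experiment_config(),
                                nodes = c(7, 23), stim_weight = 500,
                                from = 500, to = 2500) {
  base$schedule <- stimulus_schedule(node_deviation_sources(
    base$array, nodes, stim_weight - base$baseline_weight, from, to,
    base$stimulus_footprint))
  base$stim_nodes <- nodes
  base$stim_window <- c(from, to)
  base
}

#' @rdname positive_experiment
#' @export
relative_negative_experiment <- function(base = experiment_config(run_steps = 4500),
                                         nodes = c(16, 17), stim_weight = 1,
                                         from = 500, to = 2500) {
  base$schedule <- stimulus_schedule(node_deviation_sources(
    base$array, nodes, stim_weight - base$baseline_weight, from, to,
    base$stimulus_footprint))
  base$stim_nodes <- nodes
  base$stim_window <- c(from, to)
  base
}

#' @rdname positive_experiment
#' @export
repellent_experiment <- function(base = experiment_config(run_steps = 4500),
                                 nodes = c(16, 17), stim_weight = -500,
                                 from = 500, to = 2500) {
  base$schedule <- stimulus_schedule(node_deviation_sources(
    base$array, nodes, stim_weight - base$baseline_weight, from, to,
    base$stimulus_footprint))
  base$stim_nodes <- nodes
  base$stim_window <- c(from, to)
  base
}

#' @rdname positive_experiment
#' @param node Single stimulated node for the repeated protocol.
#' @param n_cycles Number of on/off cycles (at least 1).
#' @param on_steps,off_steps Lengths of the on and off phases.
#' @param start First on-phase step on the run clock.
#' @export
repeated_stimulus_experiment <- function(base = experiment_config(run_steps = 4000),
                                         node = 7, stim_weight = 500,
                                         n_cycles = 4, on_steps = 500,
                                         off_steps = 500, start = 0) {
  stopifnot(n_cycles >= 1)
  on_from <- start + (seq_len(n_cycles) - 1) * (on_steps + off_steps)
  sources <- list()
  for (f in on_from) {
    sources <- c(sources, node_deviation_sources(
      base$array, node, stim_weight - base$baseline_weight, f, f + on_steps,
      base$stimulus_footprint))
  }
  base$schedule <- stimulus_schedule(sources)
  base$stim_nodes <- node
  base$on_windows <- cbind(from = on_from, to = on_from + on_steps)
  base
}

#' All stimulus sources of an experiment on the absolute clock
#'
#' Assembles the complete source table the runner projects: the grid-mask
#' confinement sources (active during warm-up), the per-node baseline
#' footprint (active from mask removal to the end), and the schedule's
#' deviations (shifted from the run clock onto the absolute clock). Useful
#' for checking the projected levels of a protocol without running it.
#'
#' @param config An \code{experiment_config}.
#' @param mask Optional precomputed grid mask (rebuilt from the config when
#'   omitted).
#' @return Numeric matrix with columns \code{x, y, weight, from, to}
#'   (0-based cells; absolute steps, active when \code{from <= t < to}).
#' @export
experiment_sources <- function(config,
                               mask = build_grid_mask(config$array,
                                                      config$mask_thickness)) {
  w <- config$warmup_steps
  run_start <- w + config$stabilize_steps
  mask_src <- cbind(mask[, 1], mask[, 2], config$mask_weight, 0, w)
  base_sources <- node_deviation_sources(
    config$array, seq_len(config$array$n_cols * config$array$n_rows),
    config$baseline_weight, 0, config$total_steps, config$stimulus_footprint)
  base_src <- schedule_matrix(stimulus_schedule(base_sources))
  base_src[, "from"] <- w                   # baseline starts at mask removal
  dev_src <- schedule_matrix(config$schedule, shift = run_start)
  out <- rbind(mask_src, base_src, dev_src[, 1:5, drop = FALSE])
  colnames(out) <- c("x", "y", "weight", "from", "to")
  out
}

#' Run a configured experiment
#'
#' The run has three phases. During warm-up the population is inoculated on
#' the grid mask and confined there by \code{mask_weight} units/step of
#' attractant at every mask cell. At the end of warm-up the mask sources
#' vanish, leaving only the node array projecting \code{baseline_weight}
#' units/step; the population settles into its stabilized network for
#' \code{stabilize_steps}. The run clock then starts: scheduled stimulus
#' deviations become eligible and node-window occupancies are recorded every
#' \code{sampling_interval} steps. The whole run is a pure function of
#' (config, seed).
#'
#' @param config An \code{experiment_config}.
#' @return An object of class \code{"physarum_run"}: the occupancy time
#'   series (\code{series}), final \code{population}, final \code{env}, and
#'   the \code{config}.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  env <- lattice_environment(config$width, config$height,
                             config$damping, config$kernel_size)
  validate_schedule(config$schedule, env)
  array <- config$array
  mask <- build_grid_mask(array, config$mask_thickness)
  ino <- inoculate(mask, config$params, env)
  pop <- ino$population; env <- ino$env

  run_start <- config$warmup_steps + config$stabilize_steps
  sources <- experiment_sources(config, mask)

  res <- cpp_run(pop$x, pop$y, pop$heading, env$attractant, env$occupancy,
                 sources, 0L, config$total_steps,
                 config$params$sensor_angle, config$params$rotation_angle,
                 config$params$sensor_offset, config$params$deposition,
                 config$params$step_length, env$kernel_size, env$damping,
                 node_windows(array), run_start, config$sampling_interval)

  env$attractant <- res$field
  env$occupancy <- res$occupancy
  series <- occupancy_series(res$times, res$counts)
  structure(list(series = series,
                 population = population(res$x, res$y, res$heading),
                 env = env, config = config),
            class = "physarum_run")
}

#' @export
print.physarum_run <- function(x, ...) {
  cat(sprintf("<physarum_run: %d particles, %d nodes x %d samples>\n",
              length(x$population$x), nrow(x$series$counts),
              length(x$series$times)))
  invisible(x)
}

#' @export
summary.physarum_run <- function(object, ...) {
  v <- node_variance(object$series)
  cat(sprintf("Run of %d steps (%d warm-up + %d), %d particles\n",
              object$config$total_steps, object$config$warmup_steps,
              object$config$run_steps, length(object$population$x)))
  cat(sprintf("Sampled %d time points at interval %d\n",
              length(object$series$times), object$config$sampling_interval))
  cat("Per-node mean occupancy:\n")
  print(round(rowMeans(object$series$counts), 1))
  cat("Highest-variance nodes:\n")
  print(utils::head(sort(v$variance, decreasing = TRUE), 5))
  invisible(object)
}

#' Plot node occupancy traces of a run
#'
#' Draws the occupancy time series of the selected nodes on the run clock.
#'
#' @param x A \code{physarum_run}.
#' @param nodes Node indices to draw; defaults to the stimulated nodes if
#'   recorded in the config, else all 25.
#' @param ... Passed to \code{matplot}.
#' @export
plot.physarum_run <- function(x, nodes = NULL, ...) {
  if (is.null(nodes)) {
    nodes <- if (!is.null(x$config$stim_nodes)) x$config$stim_nodes
             else seq_len(nrow(x$series$counts))
  }
  graphics::matplot(x$series$times, t(x$series$counts[nodes, , drop = FALSE]),
                    type = "l", lty = 1, xlab = "step (run clock)",
                    ylab = "window occupancy", ...)
  graphics::legend("topleft", legend = paste("node", nodes), lty = 1,
                   col = seq_along(nodes), bty = "n")
  invisible(x)
}
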