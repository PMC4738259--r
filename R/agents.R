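#' Particle model parameters
#'
#' The three sensory parameters of the multi-agent plasmodium model plus its
#' motor constants. Each particle carries three forward-facing sensors: one
#' straight ahead and one rotated by \code{sensor_angle} to either side, all
#' at distance \code{sensor_offset} from the particle. On each step the
#' particle turns by \code{rotation_angle} toward the strongest sensed
#' attractant, then tries to advance \code{step_length} cells along its
#' heading, depositing \code{deposition} units of attractant into its new
#' cell when the move succeeds.
#'
#' Defaults are the reference configuration for plasmodium network formation:
#' SA = 60 degrees, RA = 60 degrees, SO = 9 cells, deposition 5 units per
#' step, 8000 particles.
#'
#' @param sensor_angle Sensor angle SA in degrees, in (0, 180).
#' @param rotation_angle Rotation angle RA in degrees, in (0, 180).
#' @param sensor_offset Sensor offset SO in cells, at least 1.
#' @param deposition Attractant units deposited per successful move.
#' @param step_length Cells advanced per move; default 1.
#' @param population_size Fixed number of particles; default 8000.
#' @return An object of class \code{"model_params"}.
#' @export
model_params <- function(sensor_angle = 60, rotation_angle = 60,
                         sensor_offset = 9, deposition = 5,
                         step_length = 1, population_size = 8000) {
  stopifnot(sensor_angle > 0, sensor_angle < 180,
            rotation_angle > 0, rotation_angle < 180,
            sensor_offset >= 1, deposition >= 0, step_length > 0,
            population_size >= 1)
  structure(list(sensor_angle = sensor_angle, rotation_angle = rotation_angle,
                 sensor_offset = sensor_offset, deposition = deposition,
                 step_length = step_length,
                 population_size = as.integer(population_size)),
            class = "model_params")
}

#' A single particle
#'
#' Continuous position plus a heading in degrees; the particle inhabits the
#' lattice cell found by flooring its coordinates.
#'
#' @param x,y Continuous lattice coordinates.
#' @param heading Heading in degrees, wrapped into [0, 360).
#' @return An object of class \code{"particle"}.
#' @export
particle <- function(x, y, heading) {
  structure(list(x = x, y = y, heading = heading %% 360), class = "particle")
}

#' Particle population
#'
#' Parallel coordinate vectors representing the whole plasmodium; collective
#' particle positions are the model's body plan. The population size is fixed
#' for the lifetime of a run (no birth or death).
#'
#' @param x,y,heading Equal-length numeric vectors.
#' @return An object of class \code{"population"}.
#' @export
population <- function(x, y, heading) {
  stopifnot(length(x) == length(y), length(x) == length(heading))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 heading = as.numeric(heading) %% 360), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population of %d particles>\n", length(x$x)))
  invisible(x)
}

#' Sense the attractant at a particle's three sensors
#'
#' The forward sensor F samples the field at offset SO along the heading;
#' FL and FR sample at heading + SA and heading - SA. Sensors hanging off the
#' lattice read 0.
#'
#' @param p A \code{particle}.
#' @param env A \code{lattice_environment}.
#' @param params A \code{model_params}.
#' @return Named numeric vector \code{c(F =, FL =, FR =)}.
#' @export
sense <- function(p, env, params) {
  th <- p$heading * pi / 180
  sa <- params$sensor_angle * pi / 180
  so <- params$sensor_offset
  a <- c(th, th + sa, th - sa)
  v <- attractant_at(env, p$x + so * cos(a), p$y + so * sin(a))
  c(F = v[1], FL = v[2], FR = v[3])
}

#' Reorient a particle toward the strongest sensed attractant
#'
#' Rule table: if the forward reading beats both side readings the heading is
#' kept; if it is strictly below both, the particle rotates by RA in a
#' uniformly random direction; otherwise it rotates by RA toward the larger
#' side reading; an exact side tie keeps the heading.
#'
#' @param p A \code{particle}.
#' @param F,FL,FR Sensed attractant values.
#' @param params A \code{model_params}.
#' @return The particle with updated heading in [0, 360).
#' @export
orient <- function(p, F, FL, FR, params) {
  ra <- params$rotation_angle
  if (F > FL && F > FR) {
    # keep heading
  } else if (F < FL && F < FR) {
    p$heading <- p$heading + if (stats::runif(1) < 0.5) ra else -ra
  } else if (FL > FR) {
    p$heading <- p$heading + ra
  } else if (FR > FL) {
    p$heading <- p$heading - ra
  }
  p$heading <- p$heading %% 360
  p
}

#' Attempt to move a particle one step forward
#'
#' The candidate position lies \code{step_length} cells along the heading.
#' If its cell is in-bounds and unoccupied (or is the particle's own current
#' cell) the particle moves, occupancy transfers, and \code{deposition} units
#' of attractant are added to the new cell. A blocked particle (occupied
#' candidate cell or out-of-bounds candidate) stays put, deposits nothing,
#' and receives a fresh uniformly random heading.
#'
#' @param p A \code{particle}.
#' @param env A \code{lattice_environment}.
#' @param params A \code{model_params}.
#' @return List with the updated \code{particle}, updated \code{env}, and
#'   logical \code{moved}.
#' @export
attempt_move <- function(p, env, params) {
  th <- p$heading * pi / 180
  nx <- p$x + params$step_length * cos(th)
  ny <- p$y + params$step_length * sin(th)
  cxi <- floor(nx); cyi <- floor(ny)
  oxi <- floor(p$x); oyi <- floor(p$y)
  inb <- cxi >= 0 && cyi >= 0 && cxi < env$width && cyi < env$height
  if (inb && (env$occupancy[cyi + 1, cxi + 1] == 0L ||
              (cxi == oxi && cyi == oyi))) {
    env$occupancy[oyi + 1, oxi + 1] <- 0L
    env$occupancy[cyi + 1, cxi + 1] <- 1L
    env$attractant[cyi + 1, cxi + 1] <-
      env$attractant[cyi + 1, cxi + 1] + params$deposition
    p$x <- nx; p$y <- ny
    list(particle = p, env = env, moved = TRUE)
  } else {
    p$heading <- stats::runif(1) * 360
    list(particle = p, env = env, moved = FALSE)
  }
}

#' Advance the whole system by one scheduler step
#'
#' Order within a step: active stimuli are projected first (so sensors see a
#' stimulus on the step it activates), every particle is updated once in a
#' fresh uniformly random order (sense, orient, attempt move), and finally
#' the field diffuses once. Population size and the one-particle-per-cell
#' exclusion are preserved.
#'
#' @param pop A \code{population}.
#' @param env A \code{lattice_environment} whose occupancy matches \code{pop}.
#' @param schedule A \code{stimulus_schedule} (may be empty).
#' @param params A \code{model_params}.
#' @param t Current step index.
#' @return List with the updated \code{population} and \code{env}.
#' @export
scheduler_step <- function(pop, env, schedule, params, t) {
  stopifnot(inherits(pop, "population"), inherits(env, "lattice_environment"))
  if (sum(env$occupancy) != length(pop$x)) {
    stop("internal error: occupancy grid inconsistent with population")
  }
  validate_schedule(schedule, env)
  res <- cpp_run(pop$x, pop$y, pop$heading, env$attractant, env$occupancy,
                 schedule_matrix(schedule), as.integer(t), 1L,
                 params$sensor_angle, params$rotation_angle,
                 params$sensor_offset, params$deposition, params$step_length,
                 env$kernel_size, env$damping,
                 matrix(integer(0), ncol = 4), 0L, 0L)
  env$attractant <- res$field
  env$occupancy <- res$occupancy
  list(population = population(res$x, res$y, res$heading), env = env)
}

#' Inoculate a population onto a mask
#'
#' Places \code{population_size} particles on distinct, uniformly sampled
#' cells of the mask (positions at cell centres) with uniform random
#' headings, and marks those cells occupied.
#'
#' @param mask Two-column matrix of 0-based \code{(x, y)} cells.
#' @param params A \code{model_params}.
#' @param env A \code{lattice_environment} to receive the occupancy.
#' @return List with the new \code{population} and the updated \code{env}.
#' @export
inoculate <- function(mask, params, env) {
  n <- params$population_size
  if (nrow(mask) < n) {
    stop(sprintf("mask has %d cells but the population needs %d",
                 nrow(mask), n))
  }
  idx <- sample.int(nrow(mask), n)
  cells <- mask[idx, , drop = FALSE]
  env$occupancy[] <- 0L
  env$occupancy[cbind(cells[, 2] + 1, cells[, 1] + 1)] <- 1L
  pop <- population(cells[, 1] + 0.5, cells[, 2] + 0.5,
                    stats::runif(n) * 360)
  list(population = pop, env = env)
}
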