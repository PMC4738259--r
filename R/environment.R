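#' Create a diffusive lattice environment
#'
#' The lattice is the shared medium coupling the particles: a real-valued
#' chemoattractant field plus a boolean occupancy grid enforcing the
#' one-particle-per-cell exclusion rule. Cells are 0-based, addressed as
#' \code{(x, y)} = (column, row); a continuous position belongs to the cell
#' obtained by flooring both coordinates. The field is stored as a matrix with
#' \code{height} rows and \code{width} columns, element \code{[y + 1, x + 1]}.
#'
#' Diffusion is a mean filter of size \code{kernel_size} whose result is
#' multiplied by \code{damping}; out-of-bounds cells contribute 0 to the mean
#' but still count in the divisor (absorbing boundary), so attractant is lost
#' at the dish edge.
#'
#' @param width,height Lattice dimensions in cells (integers, at least 25).
#' @param damping Multiplier applied after the mean filter, in (0, 1].
#'   Default 0.9, limiting the diffusion distance of deposited attractant.
#' @param kernel_size Odd mean-filter size in cells, at least 3. Default 5.
#' @return An object of class \code{"lattice_environment"}: a list with the
#'   \code{attractant} matrix, integer \code{occupancy} matrix (0/1),
#'   \code{width}, \code{height}, \code{damping} and \code{kernel_size}.
#' @export
lattice_environment <- function(width, height, damping = 0.9, kernel_size = 5) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 25, height >= 25)
  if (!(damping > 0 && damping <= 1)) stop("damping must be in (0, 1]")
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3 || kernel_size %% 2 == 0) {
    stop("kernel_size must be an odd integer >= 3")
  }
  structure(list(
    attractant = matrix(0, nrow = height, ncol = width),
    occupancy  = matrix(0L, nrow = height, ncol = width),
    width = width, height = height,
    damping = damping, kernel_size = kernel_size
  ), class = "lattice_environment")
}

#' @export
print.lattice_environment <- function(x, ...) {
  cat(sprintf("<lattice_environment %d x %d cells>\n", x$width, x$height))
  cat(sprintf("  kernel %dx%d, damping %.3g\n", x$kernel_size, x$kernel_size, x$damping))
  cat(sprintf("  attractant mass %.6g, occupied cells %d\n",
              sum(x$attractant), sum(x$occupancy)))
  invisible(x)
}

#' One diffusion step of the attractant field
#'
#' Applies the \code{kernel_size} x \code{kernel_size} mean filter with
#' absorbing boundary and multiplies by the damping factor. Occupancy is
#' untouched. The operation is linear in the field, and any field whose
#' support stays \code{kernel_size \%/\% 2} cells away from every edge loses
#' exactly a factor \code{damping} of its total mass per step.
#'
#' @param env A \code{lattice_environment}.
#' @return The environment with the diffused attractant field.
#' @export
diffuse <- function(env) {
  stopifnot(inherits(env, "lattice_environment"))
  env$attractant <- cpp_diffuse(env$attractant, env$kernel_size, env$damping)
  env
}

#' Timed point stimulus source
#'
#' A weighted point source projected onto the lattice while active: on every
#' scheduler step \code{t} with \code{active_from <= t < active_to} its weight
#' is added to the attractant value of its cell. Positive weights are
#' attractants, negative weights repellents; the field is never clamped, so a
#' repellent carves a negative well that diffuses outward.
#'
#' @param col,row 0-based cell coordinates of the source.
#' @param weight Concentration units added per active step.
#' @param active_from First active step (inclusive).
#' @param active_to First inactive step (exclusive); must exceed
#'   \code{active_from}.
#' @return An object of class \code{"stimulus_source"}.
#' @export
stimulus_source <- function(col, row, weight, active_from, active_to) {
  if (active_from >= active_to) stop("empty active interval: active_from must be < active_to")
  structure(list(col = as.integer(col), row = as.integer(row),
                 weight = as.numeric(weight),
                 active_from = as.integer(active_from),
                 active_to = as.integer(active_to)),
            class = "stimulus_source")
}

#' Collection of stimulus sources
#'
#' Sources may share a cell; active weights simply add. A schedule is pure
#' data: building or inspecting one never touches simulator state.
#'
#' @param ... \code{stimulus_source} objects (or a single list of them).
#' @return An object of class \code{"stimulus_schedule"}.
#' @export
stimulus_schedule <- function(...) {
  sources <- list(...)
  if (length(sources) == 1L && is.list(sources[[1]]) &&
      !inherits(sources[[1]], "stimulus_source")) {
    sources <- sources[[1]]
  }
  ok <- vapply(sources, inherits, logical(1), "stimulus_source")
  if (!all(ok)) stop("all schedule entries must be stimulus_source objects")
  structure(list(sources = sources), class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule with %d sources>\n", length(x$sources)))
  invisible(x)
}

# schedule as a numeric matrix (x, y, weight, from, to); shift applied to times
schedule_matrix <- function(schedule, shift = 0L) {
  if (length(schedule$sources) == 0L) {
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, c("x", "y", "weight", "from", "to"))))
  }
  m <- t(vapply(schedule$sources, function(s) {
    c(s$col, s$row, s$weight, s$active_from + shift, s$active_to + shift)
  }, numeric(5)))
  colnames(m) <- c("x", "y", "weight", "from", "to")
  m
}

validate_schedule <- function(schedule, env) {
  for (s in schedule$sources) {
    if (s$col < 0 || s$row < 0 || s$col >= env$width || s$row >= env$height) {
      stop(sprintf("stimulus source at (%d, %d) lies outside the %d x %d lattice",
                   s$col, s$row, env$width, env$height))
    }
  }
  invisible(TRUE)
}

#' Project active stimuli onto the field
#'
#' Adds the weight of every source active at step \code{t} to the attractant
#' value of its cell. Before \code{active_from} and at or after
#' \code{active_to} a source is inert, so projection is the identity there.
#'
#' @param env A \code{lattice_environment}.
#' @param schedule A \code{stimulus_schedule}.
#' @param t Non-negative step index.
#' @return The environment with stimuli added.
#' @export
project_stimuli <- function(env, schedule, t) {
  stopifnot(inherits(env, "lattice_environment"),
            inherits(schedule, "stimulus_schedule"), t >= 0)
  validate_schedule(schedule, env)
  for (s in schedule$sources) {
    if (s$active_from <= t && t < s$active_to) {
      env$attractant[s$row + 1L, s$col + 1L] <-
        env$attractant[s$row + 1L, s$col + 1L] + s$weight
    }
  }
  env
}

#' Sample the attractant field at continuous coordinates
#'
#' Returns the value of the cell containing \code{(x, y)} (cell membership by
#' flooring); out-of-bounds coordinates read as 0, which is what a particle
#' sensor hanging over the dish edge reports. Vectorized over \code{x, y}.
#'
#' @param env A \code{lattice_environment}.
#' @param x,y Continuous lattice coordinates.
#' @return Numeric vector of attractant values.
#' @export
attractant_at <- function(env, x, y) {
  xi <- floor(x); yi <- floor(y)
  ok <- xi >= 0 & yi >= 0 & xi < env$width & yi < env$height
  out <- numeric(length(xi))
  out[ok] <- env$attractant[cbind(yi[ok] + 1, xi[ok] + 1)]
  out
}

#' Write a field snapshot as a plain (P2) PGM image
#'
#' Min-max normalizes the field to 0..255 grey levels; a constant field maps
#' to 0. Row 0 of the lattice is the top image row.
#'
#' @param field Numeric matrix (e.g. \code{env$attractant}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_field_pgm <- function(field, path) {
  rng <- range(field)
  g <- if (diff(rng) == 0) matrix(0L, nrow(field), ncol(field)) else
    matrix(as.integer(round(255 * (field - rng[1]) / diff(rng))),
           nrow(field), ncol(field))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(field), nrow(field)), "255"), con)
  apply(g, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Write a field snapshot as CSV (row-major, one line per lattice row)
#'
#' @param field Numeric matrix.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_field_csv <- function(field, path) {
  utils::write.table(field, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
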