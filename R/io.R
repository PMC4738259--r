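#' Parse an experiment configuration file
#'
#' Reads a YAML configuration into an \code{experiment_config}. Recognized
#' sections: \code{lattice} (width, height, damping, kernel_size),
#' \code{params} (sa, ra, so, deposition, step_length, population),
#' \code{array} (n_cols, n_rows, origin, spacing, window_half_width),
#' scalars \code{baseline_weight}, \code{warmup_steps}, \code{run_steps},
#' \code{mask_weight}, \code{mask_thickness}, \code{seed},
#' \code{sampling_interval}, and a \code{schedule} list whose entries give
#' \code{node} (linear index) or \code{col}/\code{row} (1-based array
#' coordinates), a \code{weight} deviation from baseline in units/step, and
#' the active window \code{from}/\code{to} on the run clock. Missing keys
#' take the package defaults. Validation is collected: every problem found
#' (unknown keys included) is reported in one error message.
#'
#' @param path Path to a YAML file.
#' @return An \code{experiment_config}.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  known_top <- c("lattice", "params", "array", "baseline_weight",
                 "warmup_steps", "stabilize_steps", "run_steps",
                 "mask_weight", "mask_thickness", "stimulus_footprint",
                 "seed", "sampling_interval", "schedule")
  for (k in setdiff(names(raw), known_top)) {
    note(sprintf("unknown key '%s'", k))
  }
  check_keys <- function(section, known) {
    for (k in setdiff(names(raw[[section]]), known)) {
      note(sprintf("unknown key '%s.%s'", section, k))
    }
  }
  check_keys("lattice", c("width", "height", "damping", "kernel_size"))
  check_keys("params", c("sa", "ra", "so", "deposition", "step_length",
                         "population"))
  check_keys("array", c("n_cols", "n_rows", "origin", "spacing",
                        "window_half_width"))

  gv <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  gt <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]

  pop <- gv("params", "population", 8000)
  if (pop < 1) note("params.population must be >= 1")
  warmup <- gt("warmup_steps", 500)
  run_steps <- gt("run_steps", 4000)
  if (run_steps < 1) note("run_steps must be >= 1")

  sched <- list()
  arr <- tryCatch(
    node_array(n_cols = gv("array", "n_cols", 5),
               n_rows = gv("array", "n_rows", 5),
               origin = unlist(gv("array", "origin", c(10, 10))),
               spacing = gv("array", "spacing", 45),
               window_half_width = gv("array", "window_half_width", 6)),
    error = function(e) { note(conditionMessage(e)); NULL })
  if (!is.null(arr)) {
    n_nodes <- arr$n_cols * arr$n_rows
    for (i in seq_along(raw$schedule)) {
      e <- raw$schedule[[i]]
      for (k in setdiff(names(e), c("node", "col", "row", "weight",
                                    "from", "to"))) {
        note(sprintf("unknown key 'schedule[%d].%s'", i, k))
      }
      node <- if (!is.null(e$node)) e$node
              else if (!is.null(e$col) && !is.null(e$row)) {
                if (e$col < 1 || e$col > arr$n_cols ||
                    e$row < 1 || e$row > arr$n_rows) {
                  note(sprintf("schedule[%d]: (col, row) outside the array", i))
                  next
                }
                node_index(arr, e$col, e$row)
              } else {
                note(sprintf("schedule[%d] needs 'node' or 'col'+'row'", i))
                next
              }
      if (node < 1 || node > n_nodes) {
        note(sprintf("schedule[%d]: node %s outside 1..%d", i, node, n_nodes))
        next
      }
      if (is.null(e$weight) || is.null(e$from) || is.null(e$to)) {
        note(sprintf("schedule[%d] needs weight, from, to", i))
        next
      }
      if (e$from >= e$to) {
        note(sprintf("schedule[%d]: empty window [%s, %s)", i, e$from, e$to))
        next
      }
      sched <- c(sched, node_deviation_sources(arr, node, e$weight,
                                               e$from, e$to,
                                               gt("stimulus_footprint", 1)))
    }
  }
  if (length(errors)) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  }
  cfg <- tryCatch(
    experiment_config(
      width = gv("lattice", "width", 200),
      height = gv("lattice", "height", 200),
      damping = gv("lattice", "damping", 0.9),
      kernel_size = gv("lattice", "kernel_size", 5),
      params = model_params(sensor_angle = gv("params", "sa", 60),
                            rotation_angle = gv("params", "ra", 60),
                            sensor_offset = gv("params", "so", 9),
                            deposition = gv("params", "deposition", 5),
                            step_length = gv("params", "step_length", 1),
                            population_size = pop),
      array = arr,
      baseline_weight = gt("baseline_weight", 5),
      warmup_steps = warmup,
      stabilize_steps = gt("stabilize_steps", 3000),
      run_steps = run_steps,
      schedule = stimulus_schedule(sched),
      mask_weight = gt("mask_weight", 500),
      mask_thickness = gt("mask_thickness", 13),
      stimulus_footprint = gt("stimulus_footprint", 1),
      seed = gt("seed", NULL),
      sampling_interval = gt("sampling_interval", 10)),
    error = function(e) stop("invalid configuration:\n  ", conditionMessage(e),
                             call. = FALSE))
  cfg
}

#' Write an occupancy series as CSV
#'
#' Header \code{time,node01..nodeNN}; one row per sampled step. Integer
#' counts round-trip losslessly through \code{read_occupancy_csv}.
#'
#' @param series An \code{occupancy_series}.
#' @param path Output path.
#' @export
write_occupancy_csv <- function(series, path) {
  m <- spacetime_matrix(series)
  d <- data.frame(time = series$times, m, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_csv
#' @return \code{read_occupancy_csv}: the reconstructed
#'   \code{occupancy_series}.
#' @export
read_occupancy_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  occupancy_series(d$time, t(as.matrix(d[, -1, drop = FALSE])))
}

#' Write all artefacts of a run to a directory
#'
#' Writes the occupancy CSV, the space-time CSV, final-state snapshots
#' (attractant field as PGM and CSV, particle positions as CSV), and last a
#' JSON manifest echoing the configuration with seed, step counts, package
#' version, and an MD5-checksummed inventory of every file written. The
#' output directory is created if needed; re-running overwrites in place.
#'
#' @param run A \code{physarum_run}.
#' @param out_dir Output directory.
#' @return Character vector of files written (manifest last), invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write-test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  files <- c(occupancy = "occupancy.csv", spacetime = "spacetime.csv",
             field_pgm = "field.pgm", field_csv = "field.csv",
             particles = "particles.csv")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_occupancy_csv(run$series, paths["occupancy"])
  utils::write.table(spacetime_matrix(run$series), paths["spacetime"],
                     sep = ",", row.names = FALSE, col.names = TRUE)
  write_field_pgm(run$env$attractant, paths["field_pgm"])
  write_field_csv(run$env$attractant, paths["field_csv"])
  utils::write.csv(data.frame(id = seq_along(run$population$x),
                              x = run$population$x, y = run$population$y,
                              heading = run$population$heading),
                   paths["particles"], row.names = FALSE)

  cfg <- run$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("physarum")),
    seed = cfg$seed,
    warmup_steps = cfg$warmup_steps, run_steps = cfg$run_steps,
    total_steps = cfg$total_steps,
    sampling_interval = cfg$sampling_interval,
    lattice = list(width = cfg$width, height = cfg$height,
                   damping = cfg$damping, kernel_size = cfg$kernel_size),
    params = unclass(cfg$params),
    array = unclass(cfg$array),
    baseline_weight = cfg$baseline_weight,
    mask_weight = cfg$mask_weight, mask_thickness = cfg$mask_thickness,
    stimulus_footprint = cfg$stimulus_footprint,
    n_schedule_sources = length(cfg$schedule$sources),
    files = lapply(seq_along(paths), function(i) {
      list(name = unname(files[i]),
           md5 = unname(tools::md5sum(paths[i])))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, manifest = manifest_path))
}
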