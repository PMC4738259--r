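#' Node occupancy time series
#'
#' Particle counts inside each node's measurement window over time: the
#' substrate for every figure-level analysis (space-time plots, baseline
#' traces, per-node variance).
#'
#' @param times Integer vector of sampled step indices (run clock).
#' @param counts Integer matrix, nodes x times.
#' @return An object of class \code{"occupancy_series"}.
#' @export
occupancy_series <- function(times, counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(times))
  structure(list(times = as.integer(times), counts = counts),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("<occupancy_series: %d nodes x %d samples>\n",
              nrow(x$counts), length(x$times)))
  invisible(x)
}

#' Count particles inside each node window
#'
#' Counts particles whose cell (floored position) lies within the closed
#' 13 x 13 (by default) window centred on each node. Containment is
#' inclusive on all four edges; the count is invariant to particle order.
#'
#' @param x,y Particle coordinate vectors (or a \code{population} as
#'   \code{x}).
#' @param array A \code{node_array}.
#' @return Integer vector of counts, one per node.
#' @export
measure_occupancy <- function(x, y = NULL, array = node_array()) {
  if (inherits(x, "population")) { y <- x$y; x <- x$x }
  w <- node_windows(array)
  cx <- floor(x); cy <- floor(y)
  vapply(seq_len(nrow(w)), function(k) {
    sum(cx >= w[k, "xmin"] & cx <= w[k, "xmax"] &
        cy >= w[k, "ymin"] & cy <= w[k, "ymax"])
  }, integer(1))
}

#' Space-time matrix of a run
#'
#' Reshapes the occupancy series into the space-time layout: one row per
#' sampled time (time proceeding downward), one column per node in linear
#' node-index order. Values are exactly the series counts, unsmoothed.
#'
#' @param series An \code{occupancy_series}.
#' @return Integer matrix, times x nodes, with node columns named.
#' @export
spacetime_matrix <- function(series) {
  m <- t(series$counts)
  colnames(m) <- sprintf("node%02d", seq_len(ncol(m)))
  rownames(m) <- series$times
  m
}

#' Rebuild a series from its space-time matrix
#'
#' @param m Matrix from \code{spacetime_matrix}.
#' @return An \code{occupancy_series} (exact round-trip).
#' @export
series_from_spacetime <- function(m) {
  occupancy_series(as.integer(rownames(m)), t(m))
}

#' Render a space-time matrix as a greyscale image
#'
#' @param series An \code{occupancy_series}.
#' @param ... Passed to \code{image}.
#' @export
plot_spacetime <- function(series, ...) {
  m <- spacetime_matrix(series)
  graphics::image(x = seq_len(ncol(m)), y = series$times,
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "node", ylab = "step (time downwards)", ...)
  invisible(series)
}

#' Stimulus on-windows of a configured experiment
#'
#' Extracts the [from, to) windows (run clock) during which a node's
#' scheduled deviation is active, merged and sorted.
#'
#' @param config An \code{experiment_config}.
#' @param node Node index.
#' @return Two-column matrix \code{(from, to)}; zero rows if unscheduled.
#' @export
stimulus_on_windows <- function(config, node) {
  nc <- node_cells(config$array, node)
  w <- lapply(config$schedule$sources, function(s) {
    if (s$col == nc$x && s$row == nc$y) c(s$active_from, s$active_to) else NULL
  })
  w <- do.call(rbind, w[!vapply(w, is.null, logical(1))])
  if (is.null(w)) w <- matrix(numeric(0), ncol = 2)
  colnames(w) <- c("from", "to")
  w[order(w[, 1]), , drop = FALSE]
}

#' Baseline activity across stimulation cycles
#'
#' For a repeated-stimulation run, computes the mean window occupancy during
#' each on-phase and each following off-phase (the baseline). The first
#' \code{settle} steps of every phase are discarded so decay transients after
#' stimulus switching do not contaminate the means; an off-phase shorter than
#' its settle margin is dropped with a warning. A rising off-phase baseline
#' over cycles is the model's spatially implemented memory of the stimulus.
#'
#' @param series An \code{occupancy_series}.
#' @param config An \code{experiment_config} (its schedule defines the
#'   on-windows), or a two-column \code{(from, to)} matrix of on-windows.
#' @param node Node index to trace.
#' @param settle Settling margin in steps; default 20\% of each phase length.
#' @return Data frame with \code{cycle}, \code{on_mean}, \code{off_mean}.
#' @export
baseline_activity <- function(series, config, node, settle = NULL) {
  on <- if (is.matrix(config)) config else stimulus_on_windows(config, node)
  if (nrow(on) < 1) stop("node has no stimulation windows")
  horizon <- max(series$times) + 1L
  off <- cbind(from = on[, 2],
               to = c(on[-1, 1], horizon))
  phase_mean <- function(from, to, margin) {
    sel <- series$times >= from + margin & series$times < to
    if (!any(sel)) NA_real_ else mean(series$counts[node, sel])
  }
  out <- data.frame(cycle = seq_len(nrow(on)), on_mean = NA_real_,
                    off_mean = NA_real_)
  drop <- logical(nrow(on))
  for (i in seq_len(nrow(on))) {
    s_on <- if (is.null(settle)) 0.2 * (on[i, 2] - on[i, 1]) else settle
    s_off <- if (is.null(settle)) 0.2 * (off[i, 2] - off[i, 1]) else settle
    out$on_mean[i] <- phase_mean(on[i, 1], on[i, 2], s_on)
    if (off[i, 2] - off[i, 1] <= s_off) {
      warning(sprintf("off-window of cycle %d shorter than its settle margin; omitted", i))
      drop[i] <- TRUE
    } else {
      out$off_mean[i] <- phase_mean(off[i, 1], off[i, 2], s_off)
    }
  }
  out[!drop, , drop = FALSE]
}

#' Per-node variance of an occupancy series
#'
#' Sample variance and standard deviation (divisor n - 1) of each node's
#' count series. Directly stimulated nodes show much larger variance than
#' unstimulated ones, which localizes the stimulus in the array.
#'
#' @param series An \code{occupancy_series}.
#' @return Data frame with \code{node}, \code{variance}, \code{sd}.
#' @export
node_variance <- function(series) {
  stopifnot(length(series$times) >= 2)
  v <- apply(series$counts, 1, stats::var)
  data.frame(node = seq_len(nrow(series$counts)), variance = v, sd = sqrt(v))
}

#' Mean occupancy of nodes over a time window
#'
#' Convenience accessor: mean of each requested node's counts over run-clock
#' steps in [from, to).
#'
#' @param series An \code{occupancy_series}.
#' @param nodes Node indices.
#' @param from,to Window bounds on the run clock, [from, to).
#' @return Named numeric vector, one mean per node.
#' @export
window_mean <- function(series, nodes, from, to) {
  sel <- series$times >= from & series$times < to
  if (!any(sel)) stop(sprintf("no samples in window [%s, %s)", from, to))
  out <- rowMeans(series$counts[nodes, sel, drop = FALSE])
  names(out) <- nodes
  out
}

#' Four-neighbour nodes of a node in the array
#'
#' @param array A \code{node_array}.
#' @param node Node index.
#' @return Integer vector of the existing orthogonal neighbour indices.
#' @export
node_neighbours <- function(array, node) {
  nc <- node_cells(array, node)
  cand <- rbind(c(nc$col - 1, nc$row), c(nc$col + 1, nc$row),
                c(nc$col, nc$row - 1), c(nc$col, nc$row + 1))
  keep <- cand[, 1] >= 1 & cand[, 1] <= array$n_cols &
          cand[, 2] >= 1 & cand[, 2] <= array$n_rows
  cand <- cand[keep, , drop = FALSE]
  vapply(seq_len(nrow(cand)), function(i) {
    node_index(array, cand[i, 1], cand[i, 2])
  }, numeric(1))
}
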