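#' Relative resistance change of an electrode pair
#'
#' The end-to-start resistance ratio, the readout of tube-network
#' strengthening (ratio near 1, or modestly above due to tube aging) versus
#' abandonment (large ratio). A ratio is used rather than a difference
#' because outcomes are compared as fold-levels; it is invariant to scaling
#' both resistances by any positive constant.
#'
#' @param r_start,r_end Resistances in ohms, both positive.
#' @return \code{r_end / r_start}, dimensionless.
#' @export
relative_change <- function(r_start, r_end) {
  if (any(r_start <= 0) || any(r_end <= 0)) {
    stop("resistances must be positive")
  }
  r_end / r_start
}

#' Exact two-tailed Mann-Whitney U test
#'
#' Computes U from midranks of the pooled sample (ties averaged) and, for
#' combined sizes up to \code{exact_limit}, an exact two-tailed p by full
#' enumeration of all choose(n_a + n_b, n_a) group labelings:
#' p = P(min(U_a, U_b) <= observed min) under the permutation null. For
#' larger samples the normal approximation with tie correction and
#' continuity correction is used (reported in \code{method}).
#'
#' @param a,b Numeric samples, both non-empty.
#' @param exact_limit Largest combined size for exact enumeration; default 25.
#' @return List with \code{U} (the smaller of U_a, U_b), \code{p}, and
#'   \code{method} ("exact" or "normal approximation").
#' @export
mann_whitney_u_exact <- function(a, b, exact_limit = 25) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))                      # midranks
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  u <- min(u_a, u_b)
  if (n <= exact_limit) {
    idx <- utils::combn(n, na)
    ua_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    u_all <- pmin(ua_all, na * nb - ua_all)
    p <- mean(u_all <= u + 1e-9)
    list(U = u, p = p, method = "exact")
  } else {
    ties <- table(r)
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    list(U = u, p = p, method = "normal approximation")
  }
}

#' Control parameters of the synthetic resistance generator
#'
#' All distribution parameters of \code{generate_synthetic_experiments}.
#' Relative changes are drawn log-normally. Defaults encode the observed
#' outcome structure: under HAHF stimulation 8/10 experiments respond with
#' the stimulated pair's relative change about twice the unstimulated pairs';
#' under LALF 7/10 respond with every unstimulated pair changing 3-16 times
#' more than the stimulated pair, 1/10 show no differences and 2/10 show a
#' general increase. The mild unstimulated drift above 1 reflects tube
#' aging/drying affecting all pairs.
#'
#' @param hahf_respond_prob Probability a HAHF experiment responds.
#' @param hahf_fold Stimulated/unstimulated fold change in responders.
#' @param lalf_respond_prob,lalf_similar_prob Probabilities of the LALF
#'   responding and all-similar outcomes (remainder: all-increased).
#' @param lalf_ratio_range Unstimulated/stimulated fold range in LALF
#'   responders (log-uniform).
#' @param base_change,base_sdlog Baseline relative-change level and log-sd.
#' @param stim_sdlog Log-sd of the stimulated pair's draw.
#' @param increase_fold,increase_sdlog All-increased outcome level/log-sd.
#' @param r_start_meanlog,r_start_sdlog Log-normal start resistance (ohms).
#' @return Named list of generator parameters.
#' @export
resistance_sim_control <- function(hahf_respond_prob = 0.8, hahf_fold = 2,
                                   lalf_respond_prob = 0.7,
                                   lalf_similar_prob = 0.1,
                                   lalf_ratio_range = c(3, 16),
                                   base_change = 1.1, base_sdlog = 0.08,
                                   stim_sdlog = 0.05,
                                   increase_fold = 2, increase_sdlog = 0.2,
                                   r_start_meanlog = log(1e5),
                                   r_start_sdlog = 0.3) {
  list(hahf_respond_prob = hahf_respond_prob, hahf_fold = hahf_fold,
       lalf_respond_prob = lalf_respond_prob,
       lalf_similar_prob = lalf_similar_prob,
       lalf_ratio_range = lalf_ratio_range,
       base_change = base_change, base_sdlog = base_sdlog,
       stim_sdlog = stim_sdlog,
       increase_fold = increase_fold, increase_sdlog = increase_sdlog,
       r_start_meanlog = r_start_meanlog, r_start_sdlog = r_start_sdlog)
}

#' Generate synthetic electrode-resistance experiments
#'
#' Emulates the outcome structure of the voltage-stimulation experiments on
#' the 4 x 4 electrode pairing grid (left electrodes X1..X4 against right
#' electrodes Y1..Y4, 16 pairs, exactly one stimulated per experiment).
#' HAHF (high-amplitude high-frequency, 2.5 Vpp at 1000 Hz): responding
#' experiments show the stimulated pair's relative resistance change about
#' twice the unstimulated pairs' (tube abandonment). LALF (low-amplitude
#' low-frequency, 0.5 Vpp at 10 Hz): responding experiments show every
#' unstimulated pair changing 3-16 times more than the stimulated pair
#' (unstimulated tubes abandoned, the stimulated one maintained).
#'
#' @param stim_type "HAHF" or "LALF".
#' @param n_experiments Number of experiments (at least 1).
#' @param seed Optional integer seed.
#' @param control Generator parameters from \code{resistance_sim_control}.
#' @return Data frame with columns \code{experiment_id}, \code{stim_type},
#'   \code{left}, \code{right}, \code{r_start_ohm}, \code{r_end_ohm},
#'   \code{stimulated}; the per-experiment outcome class ("responding",
#'   "similar", or "increased") is attached as attribute \code{"outcome"}.
#' @export
generate_synthetic_experiments <- function(stim_type = c("HAHF", "LALF"),
                                           n_experiments,
                                           seed = NULL,
                                           control = resistance_sim_control()) {
  stim_type <- match.arg(stim_type)
  stopifnot(n_experiments >= 1)
  if (!is.null(seed)) set.seed(seed)
  ctl <- control
  pairs <- expand.grid(left = 1:4, right = 1:4)
  out <- vector("list", n_experiments)
  outcome <- character(n_experiments)
  for (e in seq_len(n_experiments)) {
    stim_pair <- sample.int(16, 1)
    base <- stats::rlnorm(16, log(ctl$base_change), ctl$base_sdlog)
    if (stim_type == "HAHF") {
      responding <- stats::runif(1) < ctl$hahf_respond_prob
      outcome[e] <- if (responding) "responding" else "similar"
      change <- base
      if (responding) {
        change[stim_pair] <- stats::rlnorm(
          1, log(ctl$hahf_fold * ctl$base_change), ctl$stim_sdlog)
      }
    } else {
      u <- stats::runif(1)
      outcome[e] <- if (u < ctl$lalf_respond_prob) "responding"
                    else if (u < ctl$lalf_respond_prob + ctl$lalf_similar_prob) "similar"
                    else "increased"
      if (outcome[e] == "responding") {
        stim_change <- stats::rlnorm(1, log(1.05), ctl$stim_sdlog)
        lr <- log(ctl$lalf_ratio_range)
        ratio <- exp(stats::runif(15, lr[1], lr[2]))
        change <- numeric(16)
        change[stim_pair] <- stim_change
        change[-stim_pair] <- stim_change * ratio
      } else if (outcome[e] == "similar") {
        change <- stats::rlnorm(16, log(1.05), ctl$base_sdlog)
      } else {
        change <- stats::rlnorm(16, log(ctl$increase_fold), ctl$increase_sdlog)
      }
    }
    r_start <- stats::rlnorm(16, ctl$r_start_meanlog, ctl$r_start_sdlog)
    out[[e]] <- data.frame(experiment_id = e, stim_type = stim_type,
                           left = pairs$left, right = pairs$right,
                           r_start_ohm = r_start,
                           r_end_ohm = r_start * change,
                           stimulated = seq_len(16) == stim_pair)
  }
  res <- do.call(rbind, out)
  attr(res, "outcome") <- outcome
  res
}

#' Analyze a set of resistance experiments
#'
#' Computes the relative resistance change of every electrode pair, then
#' compares the stimulated pairs against the unstimulated ones with the
#' exact two-tailed Mann-Whitney U test. With \code{pooling = "means"}
#' (default) each experiment contributes its stimulated pair's change and
#' the mean change of its 15 unstimulated pairs (one value per experiment
#' per group); \code{pooling = "all"} pools every unstimulated pair
#' individually.
#'
#' @param experiments Data frame in the format of
#'   \code{generate_synthetic_experiments} (or \code{read_resistance_csv}).
#' @param pooling "means" or "all".
#' @param alpha Significance level flagged in the report; default 0.05.
#' @return An object of class \code{"resistance_report"}: per-pair changes,
#'   per-experiment group summaries, \code{U}, \code{p}, \code{significant}.
#' @export
analyze_experiment_set <- function(experiments, pooling = c("means", "all"),
                                   alpha = 0.05) {
  pooling <- match.arg(pooling)
  req <- c("experiment_id", "left", "right", "r_start_ohm", "r_end_ohm",
           "stimulated")
  missing_cols <- setdiff(req, names(experiments))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ids <- unique(experiments$experiment_id)
  if (length(ids) < 2) stop("need at least 2 experiments")
  experiments$rel_change <- relative_change(experiments$r_start_ohm,
                                            experiments$r_end_ohm)
  per_exp <- lapply(ids, function(id) {
    e <- experiments[experiments$experiment_id == id, ]
    have <- paste(e$left, e$right)
    want <- with(expand.grid(left = 1:4, right = 1:4), paste(left, right))
    absent <- setdiff(want, have)
    if (length(absent)) {
      stop(sprintf("experiment %s is missing pair(s) (i, j): %s",
                   id, paste(absent, collapse = "; ")))
    }
    if (sum(e$stimulated) != 1) {
      stop(sprintf("experiment %s must have exactly one stimulated pair", id))
    }
    data.frame(experiment_id = id,
               stim_change = e$rel_change[e$stimulated],
               unstim_mean = mean(e$rel_change[!e$stimulated]))
  })
  per_exp <- do.call(rbind, per_exp)
  a <- per_exp$stim_change
  b <- if (pooling == "means") per_exp$unstim_mean
       else experiments$rel_change[!experiments$stimulated]
  test <- mann_whitney_u_exact(a, b)
  structure(list(pairs = experiments[, c(req, "rel_change")],
                 summary = per_exp, pooling = pooling,
                 U = test$U, p = test$p, method = test$method,
                 alpha = alpha, significant = test$p < alpha),
            class = "resistance_report")
}

#' @export
print.resistance_report <- function(x, ...) {
  cat(sprintf("Resistance analysis of %d experiments (pooling: %s)\n",
              nrow(x$summary), x$pooling))
  cat(sprintf("  stimulated median relative change:   %.3f\n",
              stats::median(x$summary$stim_change)))
  cat(sprintf("  unstimulated median relative change: %.3f\n",
              stats::median(x$summary$unstim_mean)))
  cat(sprintf("  Mann-Whitney U = %g, two-tailed p = %.4g (%s)\n",
              x$U, x$p, x$method))
  cat(sprintf("  %s at alpha = %g\n",
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Read / write resistance records as CSV
#'
#' @param path CSV path with columns \code{experiment_id}, \code{stim_type},
#'   \code{left}, \code{right}, \code{r_start_ohm}, \code{r_end_ohm},
#'   \code{stimulated}.
#' @return Data frame of records.
#' @export
read_resistance_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("experiment_id", "stim_type", "left", "right", "r_start_ohm",
           "r_end_ohm", "stimulated")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d$stimulated <- as.logical(d$stimulated)
  d
}

#' @rdname read_resistance_csv
#' @param experiments Data frame of records.
#' @export
write_resistance_csv <- function(experiments, path) {
  utils::write.csv(experiments, path, row.names = FALSE)
  invisible(path)
}

#' Write a resistance report to CSV + JSON
#'
#' @param report A \code{resistance_report}.
#' @param csv_path Per-pair relative changes (CSV).
#' @param json_path Group summary and test result (JSON).
#' @export
write_resistance_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$pairs, csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    n_experiments = nrow(report$summary),
    pooling = report$pooling,
    stimulated_median = stats::median(report$summary$stim_change),
    unstimulated_median = stats::median(report$summary$unstim_mean),
    U = report$U, p = report$p, method = report$method,
    significant = report$significant
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
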