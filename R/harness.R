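#' Monte-Carlo rejection rate of the five statistics under a scenario
#'
#' Replicates the full study `reps` times: simulate both groups from the
#' scenario's group SEMs, run the joint permutation test (all requested
#' statistics on one shared permutation stream), and record whether each
#' permutation p-value is at or below `alpha`.  Under the `"null"` scenario
#' this estimates the type-I error; under any other scenario, the power.
#'
#' @param scenario a [build_scenario()] result (see also
#'   [fixture_scenarios()])
#' @param n_per_group subjects simulated per group per replicate
#' @param reps Monte-Carlo replicates
#' @param B permutations per replicate
#' @param alpha nominal level
#' @param seed integer seed governing the whole run (replicate r uses
#'   derived seeds, so runs are reproducible and replicates independent)
#' @param statistics subset of `c("WNES","NES","NS","ES","RT")` or `"all"`
#' @param scheme,standardize_rt,p_mode passed to
#'   [network_permutation_test()]
#' @return a `calibration_report` data frame: one row per statistic with
#'   `rejections`, `rate`, Monte-Carlo `se = sqrt(rate (1-rate) / reps)` and
#'   the run metadata
#' @export
rejection_rate <- function(scenario, n_per_group = 100, reps = 500, B = 500,
                           alpha = 0.05, seed = 1, statistics = "all",
                           scheme = weight_scheme(), standardize_rt = FALSE,
                           p_mode = "empirical") {
  stopifnot(reps >= 1, B >= 1)
  stats_all <- c("WNES", "NES", "NS", "ES", "RT")
  if (identical(statistics, "all")) statistics <- stats_all
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 3L * reps)

  reject <- matrix(0L, nrow = reps, ncol = length(statistics),
                   dimnames = list(NULL, statistics))
  for (r in seq_len(reps)) {
    xD <- simulate_sem(scenario$sem_D, n_per_group,
                       seed = rep_seeds[3L * r - 2L])
    xC <- simulate_sem(scenario$sem_C, n_per_group,
                       seed = rep_seeds[3L * r - 1L])
    fit <- network_permutation_test(
      xD, xC, scenario$net_D, scenario$net_C,
      statistics = statistics, B = B, seed = rep_seeds[3L * r],
      scheme = scheme, collapse_reversed = scenario$collapse_reversed,
      standardize_rt = standardize_rt, p_mode = p_mode)
    reject[r, ] <- as.integer(fit$p_values[statistics] <= alpha)
  }
  rate <- colMeans(reject)
  out <- data.frame(
    scenario = scenario$scenario,
    statistic = statistics,
    n_per_group = n_per_group,
    reps = reps,
    B = B,
    alpha = alpha,
    rejections = colSums(reject),
    rate = unname(rate),
    se = unname(sqrt(rate * (1 - rate) / reps)),
    seed = seed,
    row.names = NULL,
    stringsAsFactors = FALSE)
  class(out) <- c("calibration_report", class(out))
  out
}

#' Type-I-error calibration grid
#'
#' Runs the null-scenario calibration for every requested fixture network
#' and per-group sample size, mirroring the layout of a type-I-error table
#' (five statistics by sample sizes, one block per network).
#'
#' @param sample_sizes per-group sample sizes
#' @param networks named list of [directed_network()] objects (defaults to
#'   the `upr12` and `wnt35` fixtures)
#' @param reps,B,alpha,seed,statistics see [rejection_rate()]
#' @return a `calibration_report` data frame with an extra `network` column
#' @export
type1_table <- function(sample_sizes = c(100, 200, 300, 400, 500),
                        networks = NULL, reps = 500, B = 500, alpha = 0.05,
                        seed = 1, statistics = "all") {
  if (is.null(networks)) {
    f <- fixture_networks()
    networks <- list(upr12 = f$upr12, wnt35 = f$wnt35)
  }
  rows <- list()
  i <- 0L
  for (net_name in names(networks)) {
    scen <- build_scenario(fixture_sem(networks[[net_name]]), "null")
    for (n in sample_sizes) {
      i <- i + 1L
      row <- rejection_rate(scen, n_per_group = n, reps = reps, B = B,
                            alpha = alpha, seed = seed + i,
                            statistics = statistics)
      row$network <- net_name
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_report", "data.frame")
  out
}

#' Power curves across sample sizes
#'
#' @param scenario a [build_scenario()] result
#' @param sample_sizes per-group sample sizes to sweep
#' @param ... passed to [rejection_rate()]
#' @return a `calibration_report` data frame stacked over sample sizes
#' @export
power_curve <- function(scenario, sample_sizes = c(50, 100, 200), ...) {
  rows <- lapply(seq_along(sample_sizes), function(i) {
    rejection_rate(scenario, n_per_group = sample_sizes[i], ...)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_report", "data.frame")
  out
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Monte-Carlo calibration report\n")
  NextMethod()
  invisible(x)
}
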