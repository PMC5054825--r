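#' Permutation p-value for an arbitrary two-group statistic
#'
#' Recomputes `stat_fn` on `B` random reassignments of the group labels
#' (group sizes preserved) and reports the proportion of permuted values at
#' least as large as the observed one.  In the default `"empirical"` mode the
#' p-value is exactly `count / B`, so p = 0 is possible; `"conservative"`
#' mode reports `(count + 1) / (B + 1)`, which is never zero and is the
#' usual finite-sample-valid estimate.
#'
#' @param stat_fn function of `(data_D, data_C)` returning a scalar; it must
#'   recompute the full statistic pipeline on each relabelled split
#' @param pooled numeric matrix of all subjects (rows), both groups stacked
#' @param labels vector with exactly two distinct values, one per row of
#'   `pooled`; the first label in order of appearance is group D
#' @param B number of permutations (>= 1)
#' @param seed optional integer seed (caller's RNG restored afterwards)
#' @param p_mode `"empirical"` (proportion of permuted >= observed) or
#'   `"conservative"` (add-one correction)
#' @return object of class `permutation_result`: `observed`, `B`,
#'   `count_ge`, `p_value`, `perm_values`, `p_mode`, `seed`
#' @export
permutation_test <- function(stat_fn, pooled, labels, B = 1000, seed = NULL,
                             p_mode = c("empirical", "conservative")) {
  p_mode <- match.arg(p_mode)
  pooled <- as.matrix(pooled)
  split <- split_labels(labels, nrow(pooled))
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  observed <- stat_fn(pooled[split$idx_D, , drop = FALSE],
                      pooled[split$idx_C, , drop = FALSE])
  n <- nrow(pooled)
  perm_values <- vapply(seq_len(B), function(b) {
    d <- sample.int(n, split$n1)
    stat_fn(pooled[d, , drop = FALSE], pooled[-d, , drop = FALSE])
  }, numeric(1))
  count <- sum(perm_values >= observed)
  p <- if (p_mode == "empirical") count / B else (count + 1) / (B + 1)
  structure(list(observed = observed, B = B, count_ge = count, p_value = p,
                 perm_values = perm_values, p_mode = p_mode, seed = seed),
            class = "permutation_result")
}

#' Exhaustive permutation p-value (enumeration oracle)
#'
#' Enumerates every split of the pooled rows into groups of the observed
#' sizes and reports the exact proportion of splits whose statistic is at
#' least the observed one.  Intended as a small-sample oracle; refuses more
#' than `max_total` subjects.
#'
#' @inheritParams permutation_test
#' @param max_total guard on `choose(n, n1)` blow-up
#' @return a `permutation_result` with `B = choose(n, n1)`
#' @export
permutation_test_exact <- function(stat_fn, pooled, labels, max_total = 12) {
  pooled <- as.matrix(pooled)
  split <- split_labels(labels, nrow(pooled))
  n <- nrow(pooled)
  if (n > max_total) {
    stop("exhaustive enumeration limited to ", max_total, " subjects",
         call. = FALSE)
  }
  observed <- stat_fn(pooled[split$idx_D, , drop = FALSE],
                      pooled[split$idx_C, , drop = FALSE])
  combos <- utils::combn(n, split$n1)
  perm_values <- apply(combos, 2L, function(d) {
    stat_fn(pooled[d, , drop = FALSE], pooled[-d, , drop = FALSE])
  })
  count <- sum(perm_values >= observed)
  structure(list(observed = observed, B = ncol(combos), count_ge = count,
                 p_value = count / ncol(combos), perm_values = perm_values,
                 p_mode = "empirical", seed = NULL),
            class = "permutation_result")
}

split_labels <- function(labels, n) {
  if (length(labels) != n) {
    stop("labels must have one entry per pooled row", call. = FALSE)
  }
  lev <- unique(labels)
  if (length(lev) != 2L) {
    stop("labels must contain exactly two groups, found ", length(lev),
         call. = FALSE)
  }
  idx_D <- which(labels == lev[1L])
  idx_C <- which(labels == lev[2L])
  list(idx_D = idx_D, idx_C = idx_C, n1 = length(idx_D), n2 = length(idx_C),
       lev = lev)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation test: observed =", signif(x$observed, 6),
      "; p =", x$p_value, "(", x$count_ge, "of", x$B, "permutations >=,",
      x$p_mode, "mode )\n")
  invisible(x)
}

#' Joint permutation test of the five network statistics
#'
#' Computes WNES, NES, NS, ES and RT for an observed two-group dataset and
#' their permutation p-values on **one shared permutation stream**: every
#' statistic is evaluated on the same `B` relabelled splits, so the five
#' p-values are directly comparable.  The per-split recomputation (group
#' means/variances, per-child OLS in each group's own network, weighting,
#' aligned-rank distance) runs in compiled code.
#'
#' @inheritParams network_statistics
#' @param statistics character subset of
#'   `c("WNES", "NES", "NS", "ES", "RT")` or `"all"`
#' @param B number of permutations
#' @param seed optional integer seed for the permutation stream
#' @param p_mode see [permutation_test()]
#' @return object of class `network_test`: `observed` (named vector),
#'   `p_values` (named vector), `perm_values` (B x statistics matrix),
#'   `result` (the observed [network_statistics()] decomposition), plus the
#'   run metadata (`B`, `seed`, `p_mode`, `n1`, `n2`, `K`, `M`)
#' @examples
#' nets <- fixture_networks()
#' sem <- fixture_sem(nets$upr12)
#' d <- simulate_sem(sem, 40, seed = 1)
#' c <- simulate_sem(sem, 40, seed = 2)
#' network_permutation_test(d, c, nets$upr12, B = 99, seed = 7)
#' @export
network_permutation_test <- function(data_D, data_C, net_D, net_C = net_D,
                                     statistics = "all", B = 1000,
                                     seed = NULL,
                                     scheme = weight_scheme(),
                                     collapse_reversed = FALSE,
                                     standardize_rt = FALSE,
                                     weight_mode = "descendants",
                                     p_mode = c("empirical",
                                                "conservative")) {
  p_mode <- match.arg(p_mode)
  stats_all <- c("WNES", "NES", "NS", "ES", "RT")
  if (identical(statistics, "all")) statistics <- stats_all
  statistics <- match.arg(statistics, stats_all, several.ok = TRUE)
  if (B < 1) stop("B must be at least 1", call. = FALSE)

  xD <- as_group_matrix(data_D)
  xC <- as_group_matrix(data_C)
  n1 <- nrow(xD); n2 <- nrow(xC)
  if (n1 < 3L || n2 < 3L) stop("need n >= 3 per group", call. = FALSE)

  observed <- network_statistics(xD, xC, net_D, net_C, scheme,
                                 collapse_reversed, standardize_rt,
                                 weight_mode)
  merged <- merge_structures(net_D, net_C, collapse_reversed)
  plan <- permutation_plan(merged, net_D, net_C)
  cols <- merged$nodes
  pooled <- rbind(xD[, cols, drop = FALSE], xC[, cols, drop = FALSE])

  do_rt <- "RT" %in% statistics && merged$K >= 2L
  ranks <- if (do_rt) rt_rank_matrix(pooled, standardize_rt)
           else matrix(0, 0L, 0L)
  do_nes <- any(statistics != "RT")
  w <- merged_node_weights(merged, net_D, scheme, mode = weight_mode)

  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  splits <- t(vapply(seq_len(B), function(b) sample.int(n1 + n2, n1),
                     integer(n1)))

  perm <- .cpp_joint_stats(pooled, splits - 1L, plan$regs_D, plan$regs_C,
                           plan$edge_map, merged$node_in_D,
                           merged$node_in_C, w, ranks, do_nes, do_rt)
  if (do_nes && anyNA(perm[, "WNES"])) {
    stop("degenerate zero-variance difference encountered during ",
         "permutation", call. = FALSE)
  }

  obs_vec <- c(WNES = observed$WNES, NES = observed$NES, NS = observed$NS,
               ES = observed$ES,
               RT = if (is.null(observed$RT)) NA_real_ else observed$RT)
  obs_vec <- obs_vec[statistics]
  perm <- perm[, statistics, drop = FALSE]
  count <- colSums(sweep(perm, 2L, obs_vec, ">="))
  p <- if (p_mode == "empirical") count / B else (count + 1) / (B + 1)

  structure(list(observed = obs_vec, p_values = p, perm_values = perm,
                 result = observed, B = B, seed = seed, p_mode = p_mode,
                 n1 = n1, n2 = n2, K = merged$K, M = merged$M,
                 statistics = statistics),
            class = "network_test")
}

# Regression bookkeeping consumed by the compiled joint loop: one OLS per
# child per group (child regressed on its full parent set in that group's
# network), and for each union edge slot the (regression, coefficient)
# address in each group (-1 when absent).
permutation_plan <- function(merged, net_D, net_C) {
  cols <- merged$nodes
  build_group <- function(which) {
    parent <- merged$edges[[paste0("parent_", which)]]
    child <- merged$edges[[paste0("child_", which)]]
    present <- merged$edges[[paste0("in_", which)]]
    regs <- list()
    addr <- matrix(-1L, nrow = merged$M, ncol = 2L)
    if (any(present)) {
      for (ch in unique(child[present])) {
        rows <- which(present & child == ch)
        parents <- parent[rows]
        reg_id <- length(regs)  # 0-based for C++
        regs[[reg_id + 1L]] <- c(match(ch, cols),
                                 match(parents, cols)) - 1L
        addr[rows, 1L] <- reg_id
        addr[rows, 2L] <- seq_along(parents) - 1L
      }
    }
    list(regs = regs, addr = addr)
  }
  gD <- build_group("D")
  gC <- build_group("C")
  list(regs_D = gD$regs, regs_C = gC$regs,
       edge_map = cbind(gD$addr, gC$addr))
}

#' @export
print.network_test <- function(x, ...) {
  cat("two-group network permutation test (K =", x$K, ", M =", x$M,
      "; n1 =", x$n1, ", n2 =", x$n2, ", B =", x$B, ")\n")
  tab <- data.frame(statistic = names(x$observed),
                    value = signif(unname(x$observed), 6),
                    p_value = unname(x$p_values))
  print(tab, row.names = FALSE)
  invisible(x)
}
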