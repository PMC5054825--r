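#' Squared standardized node differences
#'
#' For each union node k, `U_k = (mean_D - mean_C)^2 / (var_D/n1 + var_C/n2)`
#' — the square of the Welch two-sample t statistic for that node, with
#' zero-filled summaries for nodes absent from one group.  A zero denominator
#' with a zero numerator gives `U_k = 0` (nothing varies, nothing differs); a
#' zero denominator with a nonzero difference is a data pathology and raises
#' an error naming the node.
#'
#' @param summ_D,summ_C [group_summaries()] objects aligned to the same
#'   merged structure
#' @param n1,n2 group sample sizes (defaulting to those recorded in the
#'   summaries)
#' @return named numeric vector `U_k` over the union nodes
#' @export
node_terms <- function(summ_D, summ_C, n1 = summ_D$n, n2 = summ_C$n) {
  check_aligned(summ_D, summ_C)
  num <- (summ_D$node$mean - summ_C$node$mean)^2
  den <- summ_D$node$var / n1 + summ_C$node$var / n2
  squared_ratio(num, den, summ_D$node$node, "node")
}

#' Squared standardized edge differences
#'
#' For each union edge slot m, `V_m = (beta_D - beta_C)^2 /
#' (var_beta_D + var_beta_C)`, with the same zero-fill and zero-denominator
#' conventions as [node_terms()].
#'
#' @inheritParams node_terms
#' @return named numeric vector `V_m` over the union edge slots
#' @export
edge_terms <- function(summ_D, summ_C) {
  check_aligned(summ_D, summ_C)
  num <- (summ_D$edge$beta - summ_C$edge$beta)^2
  den <- summ_D$edge$var_beta + summ_C$edge$var_beta
  lab <- paste(summ_D$edge$parent, summ_D$edge$child, sep = "->")
  squared_ratio(num, den, lab, "edge")
}

squared_ratio <- function(num, den, labels, what) {
  out <- stats::setNames(rep(0, length(num)), labels)
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  bad <- !pos & num != 0
  if (any(bad)) {
    stop("degenerate ", what, " with zero variance but nonzero difference: ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  out
}

check_aligned <- function(summ_D, summ_C) {
  stopifnot(inherits(summ_D, "group_summaries"),
            inherits(summ_C, "group_summaries"))
  if (!identical(summ_D$node$node, summ_C$node$node) ||
      !identical(summ_D$edge$parent, summ_C$edge$parent) ||
      !identical(summ_D$edge$child, summ_C$edge$child)) {
    stop("group summaries are not aligned to the same merged structure",
         call. = FALSE)
  }
}

#' Combine node and edge terms into the four network statistics
#'
#' `NS = sum(U)`, `ES = sum(V)`, `NES = NS + ES`, and
#' `WNES = sum(w_k U_k) + ES`: the topological weights act on the node terms
#' only, so WNES equals NES whenever all weights are one, and
#' `WNES >= NES` whenever all weights are at least one.
#'
#' @param U node terms from [node_terms()] (length K)
#' @param V edge terms from [edge_terms()] (length M, possibly zero)
#' @param weights node weights from [node_weights()] (length K)
#' @return object of class `statistic_result` with fields `WNES`, `NES`,
#'   `NS`, `ES`, the decompositions `U`, `V`, `weights`, and `K`, `M`
#' @export
combine_statistics <- function(U, V, weights) {
  if (length(weights) != length(U)) {
    stop("weights and node terms differ in length", call. = FALSE)
  }
  NS <- sum(U)
  ES <- sum(V)
  structure(list(
    WNES = sum(weights * U) + ES,
    NES = NS + ES,
    NS = NS,
    ES = ES,
    U = U, V = V, weights = weights,
    K = length(U), M = length(V)),
    class = "statistic_result")
}

#' @export
print.statistic_result <- function(x, ...) {
  cat("network difference statistics (K =", x$K, ", M =", x$M, ")\n")
  vals <- c(WNES = x$WNES, NES = x$NES, NS = x$NS, ES = x$ES)
  if (!is.null(x$RT)) vals <- c(vals, RT = x$RT)
  print(signif(vals, 6))
  invisible(x)
}

#' Aligned-rank two-sample statistic (RT)
#'
#' A rank-based multivariate two-sample test over the K shared variables.
#' Each column is optionally standardized over the pooled sample (advisable
#' when the nodes carry different units), then aligned by subtracting its
#' pooled median.  Within every subject the K aligned values are ranked
#' (midranks for ties); `RT = n1 n2 / (n1 + n2) * ||rbar_D - rbar_C||^2`,
#' the scaled squared Euclidean distance between the group mean rank
#' vectors.  The leading scalar is immaterial under permutation testing.
#'
#' @param data_D,data_C numeric matrices (or [group_data()]) with the same K
#'   columns in the same order
#' @param standardize logical; scale each column to pooled mean 0, sd 1
#'   before aligning
#' @return the RT value (non-negative scalar)
#' @export
rt_statistic <- function(data_D, data_C, standardize = FALSE) {
  xD <- as_group_matrix(data_D)
  xC <- as_group_matrix(data_C)
  if (!identical(colnames(xD), colnames(xC))) {
    stop("the two groups must share the same columns for RT", call. = FALSE)
  }
  if (ncol(xD) < 2L) stop("RT needs at least 2 variables", call. = FALSE)
  n1 <- nrow(xD); n2 <- nrow(xC)
  ranks <- rt_rank_matrix(rbind(xD, xC), standardize)
  rbar_D <- colMeans(ranks[seq_len(n1), , drop = FALSE])
  rbar_C <- colMeans(ranks[n1 + seq_len(n2), , drop = FALSE])
  (n1 * n2 / (n1 + n2)) * sum((rbar_D - rbar_C)^2)
}

# pooled alignment + within-subject ranks; label-invariant, so it can be
# precomputed once per dataset and reused across permutations
rt_rank_matrix <- function(pooled, standardize = FALSE) {
  if (isTRUE(standardize)) {
    pooled <- scale(pooled)
    if (anyNA(pooled)) {
      stop("cannot standardize a constant column for RT", call. = FALSE)
    }
  }
  med <- apply(pooled, 2L, stats::median)
  aligned <- sweep(pooled, 2L, med)
  t(apply(aligned, 1L, rank))
}

#' All five statistics for an observed two-group dataset
#'
#' Runs the full pipeline once: merges the two group structures, computes
#' per-group node/edge summaries, the topological weights, the four
#' nodes-and-edges statistics and (when both groups share all union nodes)
#' the aligned-rank RT statistic.
#'
#' @param data_D,data_C per-group data matrices ([group_data()] or numeric
#'   matrices with node-label columns)
#' @param net_D,net_C per-group [directed_network()] structures (`net_C`
#'   defaults to `net_D`)
#' @param scheme a [weight_scheme()]
#' @param collapse_reversed see [merge_structures()]
#' @param standardize_rt see [rt_statistic()]
#' @param weight_mode passed to [descendant_counts()]
#' @return a `statistic_result` with the additional field `RT` (or `NULL`
#'   when the groups do not share all union nodes) and metadata `n1`, `n2`
#' @examples
#' net <- directed_network(rbind(c("A", "B"), c("B", "C")))
#' sem <- linear_sem(net)
#' d <- simulate_sem(sem, 50, seed = 1)
#' c <- simulate_sem(sem, 50, seed = 2)
#' network_statistics(d, c, net)
#' @export
network_statistics <- function(data_D, data_C, net_D, net_C = net_D,
                               scheme = weight_scheme(),
                               collapse_reversed = FALSE,
                               standardize_rt = FALSE,
                               weight_mode = "descendants") {
  merged <- merge_structures(net_D, net_C, collapse_reversed)
  summ_D <- group_summaries(data_D, merged, "D")
  summ_C <- group_summaries(data_C, merged, "C")
  w <- merged_node_weights(merged, net_D, scheme, mode = weight_mode)
  U <- node_terms(summ_D, summ_C)
  V <- edge_terms(summ_D, summ_C)
  res <- combine_statistics(U, V, w)
  xD <- as_group_matrix(data_D)
  xC <- as_group_matrix(data_C)
  res$RT <- if (all(merged$nodes %in% colnames(xD)) &&
                all(merged$nodes %in% colnames(xC)) && merged$K >= 2L) {
    rt_statistic(xD[, merged$nodes, drop = FALSE],
                 xC[, merged$nodes, drop = FALSE], standardize_rt)
  } else NULL
  res$n1 <- nrow(xD)
  res$n2 <- nrow(xC)
  res$scheme <- scheme
  res
}
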