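# Independent brute-force oracles used to pin expected values.  These stay
# deliberately naive and share no code with the package internals.

# descendant counts by depth-first search launched from every node
oracle_descendants <- function(net) {
  vapply(net$nodes, function(v) {
    seen <- character(0)
    stack <- net$edges[net$edges[, 1L] == v, 2L]
    while (length(stack) > 0L) {
      w <- stack[[1L]]
      stack <- stack[-1L]
      if (w %in% seen) next
      seen <- c(seen, w)
      stack <- c(stack, net$edges[net$edges[, 1L] == w, 2L])
    }
    length(seen)
  }, numeric(1))
}

# squared Welch two-sample t statistic, via stats::t.test
oracle_welch_t2 <- function(x, y) {
  unname(stats::t.test(x, y, var.equal = FALSE)$statistic^2)
}

# OLS coefficients and sampling variances by raw normal equations
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  xtx_inv <- solve(t(X1) %*% X1)
  beta <- xtx_inv %*% t(X1) %*% y
  resid <- y - X1 %*% beta
  sigma2 <- sum(resid^2) / (nrow(X1) - ncol(X1))
  list(beta = drop(beta)[-1L], var_beta = (sigma2 * diag(xtx_inv))[-1L])
}

# random labelled DAG: permute labels, draw forward edges over the
# permuted order so acyclicity holds by construction
random_dag <- function(n_nodes, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  labs <- sample(paste0("n", seq_len(n_nodes)))
  edges <- NULL
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, labs[c(i, j)])
    }
  }
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)
  directed_network(edges, nodes = labs)
}

chain_net <- function() directed_network(rbind(c("A", "B"), c("B", "C")))

diamond_net <- function() {
  directed_network(rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
}

upr_nets <- function() fixture_networks()
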