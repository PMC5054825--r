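fake_summaries <- function(merged, means, vars, betas = NULL,
                           var_betas = NULL, n = 100, group = "D") {
  node <- data.frame(node = merged$nodes, mean = means, var = vars,
                     present = TRUE, stringsAsFactors = FALSE)
  M <- merged$M
  edge <- data.frame(parent = merged$edges$parent,
                     child = merged$edges$child,
                     beta = if (is.null(betas)) rep(0, M) else betas,
                     var_beta = if (is.null(var_betas)) rep(0, M)
                                else var_betas,
                     present = TRUE, stringsAsFactors = FALSE)
  structure(list(node = node, edge = edge, n = n, group = group),
            class = "group_summaries")
}

test_that("node terms follow the squared Welch form with zero-fill", {
  net <- directed_network(rbind(c("A", "B")))
  m <- merge_structures(net, net)
  sD <- fake_summaries(m, means = c(1, 2), vars = c(1, 1))
  sC <- fake_summaries(m, means = c(0, 2), vars = c(1, 1), group = "C")
  U <- node_terms(sD, sC, 100, 100)
  expect_equal(unname(U), c(1 / 0.02, 0))

  # node observed only in group D: group C contributes zeros
  sC0 <- fake_summaries(m, means = c(0, 0), vars = c(0, 0), group = "C")
  sD2 <- fake_summaries(m, means = c(2, 0), vars = c(1, 0))
  U2 <- node_terms(sD2, sC0, 100, 100)
  expect_equal(unname(U2), c(4 / 0.01, 0))

  # identical summaries: all zero
  expect_equal(unname(node_terms(sD, sD, 100, 100)), c(0, 0))
})

test_that("zero variance with nonzero difference is surfaced as an error", {
  net <- directed_network(rbind(c("A", "B")))
  m <- merge_structures(net, net)
  sD <- fake_summaries(m, means = c(5, 0), vars = c(0, 1))
  sC <- fake_summaries(m, means = c(3, 0), vars = c(0, 1), group = "C")
  expect_error(node_terms(sD, sC, 10, 10), "degenerate node.*A")
})

test_that("edge terms standardize coefficient differences", {
  net <- directed_network(rbind(c("A", "B")))
  m <- merge_structures(net, net)
  sD <- fake_summaries(m, means = c(0, 0), vars = c(1, 1),
                       betas = 0.5, var_betas = 0.01)
  sC <- fake_summaries(m, means = c(0, 0), vars = c(1, 1),
                       betas = 0, var_betas = 0, group = "C")
  expect_equal(unname(edge_terms(sD, sC)), 0.25 / 0.01)
  expect_equal(unname(edge_terms(sD, sD)), 0)  # 0/0 convention on equals
})

test_that("the statistics combine with weights on node terms only", {
  U <- c(A = 1, B = 1, C = 1)
  V <- c("A->B" = 2)
  res <- combine_statistics(U, V, weights = c(3, 2, 1))
  expect_equal(res$WNES, 8)
  expect_equal(res$NES, 5)
  expect_equal(res$NS, 3)
  expect_equal(res$ES, 2)

  unit <- combine_statistics(U, V, weights = c(1, 1, 1))
  expect_equal(unit$WNES, unit$NES)

  empty <- combine_statistics(U, numeric(0), weights = c(1, 1, 1))
  expect_equal(empty$ES, 0)
  expect_equal(empty$NES, empty$NS)

  expect_error(combine_statistics(U, V, weights = c(1, 1)), "length")
})

test_that("U_k equals the squared Welch t of an independent oracle", {
  set.seed(31)
  nets <- fixture_networks()
  sem <- fixture_sem(nets$upr12)
  xD <- simulate_sem(sem, 40, seed = 1)$x
  xC <- simulate_sem(sem, 60, seed = 2)$x
  m <- merge_structures(nets$upr12, nets$upr12)
  U <- node_terms(group_summaries(xD, m, "D"), group_summaries(xC, m, "C"))
  for (v in m$nodes) {
    expect_equal(unname(U[v]), oracle_welch_t2(xD[, v], xC[, v]),
                 tolerance = 1e-12)
  }
})

test_that("statistics are symmetric in the two groups", {
  nets <- fixture_networks()
  sem <- fixture_sem(nets$upr12)
  xD <- simulate_sem(sem, 30, seed = 5)
  xC <- simulate_sem(sem, 45, seed = 6)
  a <- network_statistics(xD, xC, nets$upr12)
  b <- network_statistics(xC, xD, nets$upr12)
  for (f in c("WNES", "NES", "NS", "ES", "RT")) {
    expect_equal(a[[f]], b[[f]])
  }
})

test_that("WNES dominates NES whenever weights exceed one", {
  nets <- fixture_networks()
  sem <- fixture_sem(nets$upr12)
  for (seed in 1:5) {
    xD <- simulate_sem(sem, 25, seed = seed)
    xC <- simulate_sem(sem, 25, seed = seed + 50)
    res <- network_statistics(xD, xC, nets$upr12)
    expect_true(all(res$weights >= 1))
    expect_gte(res$WNES, res$NES)
  }
})

test_that("statistics survive node relabeling and row shuffling", {
  nets <- fixture_networks()
  sem <- fixture_sem(nets$upr12)
  xD <- simulate_sem(sem, 30, seed = 9)$x
  xC <- simulate_sem(sem, 30, seed = 10)$x
  base <- network_statistics(xD, xC, nets$upr12)

  # consistent relabeling of network and columns
  relab <- stats::setNames(paste0("g", seq_along(nets$upr12$nodes)),
                           nets$upr12$nodes)
  net2 <- directed_network(cbind(relab[nets$upr12$edges[, 1]],
                                 relab[nets$upr12$edges[, 2]]),
                           nodes = unname(relab[nets$upr12$nodes]))
  xD2 <- xD; colnames(xD2) <- unname(relab[colnames(xD)])
  xC2 <- xC; colnames(xC2) <- unname(relab[colnames(xC)])
  rel <- network_statistics(xD2, xC2, net2)
  expect_equal(rel$WNES, base$WNES)
  expect_equal(rel$RT, base$RT)

  # permuting subject rows within a group changes nothing
  shuf <- network_statistics(xD[sample(30), ], xC, nets$upr12)
  expect_equal(shuf$NES, base$NES)
  expect_equal(shuf$RT, base$RT)
})

test_that("RT matches hand-computed rank distances", {
  x <- cbind(a = c(1, 5), b = c(2, 4), c = c(3, 3))
  expect_equal(rt_statistic(x, x), 0)

  # one subject per group with opposite orderings over two columns
  d <- cbind(a = 1, b = 2)
  c2 <- cbind(a = 2, b = 1)
  expect_equal(rt_statistic(d, c2), 1)

  expect_error(rt_statistic(cbind(a = 1:3), cbind(a = 1:3)),
               "at least 2")
})

test_that("per-subject rank vectors ignore monotone transformations", {
  set.seed(12)
  pooled <- matrix(rnorm(50), 10, dimnames = list(NULL, paste0("v", 1:5)))
  r1 <- wnes:::rt_rank_matrix(pooled)
  # a strictly increasing map applied after alignment preserves the ranks
  aligned <- sweep(pooled, 2, apply(pooled, 2, stats::median))
  r2 <- t(apply(exp(aligned), 1, rank))
  expect_equal(unname(r1), unname(r2))
})

test_that("RT standardization handles heterogeneous units", {
  set.seed(4)
  xD <- cbind(a = rnorm(20), b = rnorm(20, sd = 1000))
  xC <- cbind(a = rnorm(20), b = rnorm(20, sd = 1000))
  raw <- rt_statistic(xD, xC)
  std <- rt_statistic(xD, xC, standardize = TRUE)
  expect_true(is.finite(raw) && is.finite(std))
  expect_error(rt_statistic(cbind(a = rep(1, 3), b = 1:3),
                            cbind(a = rep(1, 3), b = 1:3),
                            standardize = TRUE),
               "constant")
})
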