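test_that("construction validates structure", {
  expect_error(directed_network(rbind(c("A", "A"))), "self-loop")
  expect_error(directed_network(rbind(c("A", "B"), c("A", "B"))),
               "duplicate edges")
  expect_error(directed_network(rbind(c("A", "B"), c("B", "A"))), "cycle")
  expect_error(directed_network(rbind(c("A", "B"), c("B", "C"),
                                      c("C", "A"))),
               "cycle")
  expect_error(directed_network(rbind(c("A", "B")), nodes = "A"),
               "not in node set")
  expect_error(directed_network(rbind(c("A", "B")),
                                nodes = c("A", "B", "B")),
               "duplicate node labels")
  net <- directed_network(rbind(c("A", "B")), nodes = c("A", "B", "Z"))
  expect_setequal(net$nodes, c("A", "B", "Z"))
})

test_that("topological order puts every parent before its children", {
  expect_equal(validate_and_order(chain_net()), c("A", "B", "C"))
  for (seed in 1:5) {
    net <- random_dag(12, 0.3, seed = seed)
    ord <- validate_and_order(net)
    pos <- match(net$nodes, ord)
    names(pos) <- net$nodes
    ok <- apply(net$edges, 1L, function(e) pos[e[1L]] < pos[e[2L]])
    expect_true(all(ok))
  }
})

test_that("descendant counts match hand enumeration on small motifs", {
  expect_equal(descendant_counts(chain_net()), c(A = 2L, B = 1L, C = 0L))
  star <- directed_network(rbind(c("A", "B"), c("A", "C"), c("A", "D")))
  expect_equal(descendant_counts(star),
               c(A = 3L, B = 0L, C = 0L, D = 0L))
  # diamond: D reachable from A along two paths but counted once
  expect_equal(descendant_counts(diamond_net()),
               c(A = 3L, B = 1L, C = 1L, D = 0L))
  expect_equal(descendant_counts(diamond_net(), mode = "children"),
               c(A = 2L, B = 1L, C = 1L, D = 0L))
})

test_that("descendant counts agree with DFS-from-every-node oracle", {
  for (seed in 1:30) {
    net <- random_dag(sample(3:12, 1), stats::runif(1, 0.1, 0.6),
                      seed = seed)
    expect_equal(unname(descendant_counts(net)[net$nodes]),
                 unname(oracle_descendants(net)))
  }
})

test_that("relative weights are proportions of total downstream reach", {
  expect_equal(relative_weights(descendant_counts(chain_net())),
               c(A = 2 / 3, B = 1 / 3, C = 0))
  edgeless <- directed_network(NULL, nodes = c("A", "B", "C"))
  expect_equal(relative_weights(descendant_counts(edgeless)),
               c(A = 0, B = 0, C = 0))
  # diamond counts (3,1,1,0), total 5
  expect_equal(relative_weights(descendant_counts(diamond_net())),
               c(A = 3 / 5, B = 1 / 5, C = 1 / 5, D = 0))
  for (seed in 1:10) {
    net <- random_dag(8, 0.4, seed = seed)
    r <- relative_weights(descendant_counts(net))
    expect_true(all(r >= 0 & r <= 1))
    if (nrow(net$edges) > 0) expect_equal(sum(r), 1)
  }
})

test_that("node weights are >= 1, exactly 1 for childless, relabel-stable", {
  r <- relative_weights(descendant_counts(chain_net()))
  expect_equal(node_weights(r, 3, weight_scheme("additive", 1)),
               c(A = 3, B = 2, C = 1))
  expect_equal(node_weights(r, 3, weight_scheme("unit")),
               c(A = 1, B = 1, C = 1))
  pw <- node_weights(r, 3, weight_scheme("power", 2))
  expect_equal(unname(pw), sqrt(1 + 3 * unname(r)))
  expect_equal(unname(pw["C"]), 1)
  expect_error(weight_scheme("additive", 0), "positive")
  expect_error(weight_scheme("power", -1), "positive")

  for (seed in 1:5) {
    net <- random_dag(9, 0.35, seed = seed)
    r <- relative_weights(descendant_counts(net))
    for (fam in list(weight_scheme("additive", 0.5),
                     weight_scheme("power", 3), weight_scheme("unit"))) {
      w <- node_weights(r, length(r), fam)
      expect_true(all(w >= 1))
      expect_equal(unname(w[descendant_counts(net) == 0]),
                   rep(1, sum(descendant_counts(net) == 0)))
    }
    # relabeling: permute labels consistently, weights follow labels
    perm <- sample(net$nodes)
    relab <- stats::setNames(perm, net$nodes)
    net2 <- directed_network(cbind(relab[net$edges[, 1]],
                                   relab[net$edges[, 2]]),
                             nodes = unname(relab[net$nodes]))
    w1 <- node_weights(relative_weights(descendant_counts(net)),
                       length(r), weight_scheme())
    w2 <- node_weights(relative_weights(descendant_counts(net2)),
                       length(r), weight_scheme())
    expect_equal(unname(w2[unname(relab[names(w1)])]), unname(w1))
  }
})

test_that("smaller tuning inflates the topological contribution", {
  r <- relative_weights(descendant_counts(chain_net()))
  w_small <- node_weights(r, 3, weight_scheme("additive", 0.5))
  w_large <- node_weights(r, 3, weight_scheme("additive", 2))
  expect_true(all(w_small[r > 0] > w_large[r > 0]))
  p_small <- node_weights(r, 3, weight_scheme("power", 1))
  p_large <- node_weights(r, 3, weight_scheme("power", 4))
  expect_true(all(p_small[r > 0] > p_large[r > 0]))
})

test_that("merging reproduces the union bookkeeping worked example", {
  nets <- upr_nets()
  same <- merge_structures(nets$upr12, nets$upr12)
  expect_equal(same$K, 12L)
  expect_equal(same$M, 15L)

  rev <- merge_structures(nets$upr12, nets$upr12_rev)
  expect_equal(rev$K, 12L)
  expect_equal(rev$M, 16L)

  col <- merge_structures(nets$upr12, nets$upr12_rev,
                          collapse_reversed = TRUE)
  expect_equal(col$M, 15L)
  shared <- col$edges[which(col$edges$parent_D == "IRE1" &
                              col$edges$child_D == "TRAF2"), ]
  expect_equal(shared$parent_C, "TRAF2")
  expect_equal(shared$child_C, "IRE1")
  expect_true(shared$in_D && shared$in_C)
})

test_that("merge is symmetric up to flag swap and M is bounded below", {
  for (seed in 1:5) {
    a <- random_dag(8, 0.3, seed = seed)
    b <- random_dag(8, 0.3, seed = seed + 100)
    ab <- merge_structures(a, b)
    ba <- merge_structures(b, a)
    expect_equal(ab$K, ba$K)
    expect_equal(ab$M, ba$M)
    key <- function(m) sort(paste(m$edges$parent, m$edges$child))
    expect_equal(key(ab), key(ba))
    expect_equal(ab$node_in_D[sort(ab$nodes)], ba$node_in_C[sort(ba$nodes)])
    expect_equal(ab$node_in_C[sort(ab$nodes)], ba$node_in_D[sort(ba$nodes)])
    expect_true(ab$M >= max(nrow(a$edges), nrow(b$edges)))
  }
})

test_that("labels are case-sensitive and near-collisions are refused", {
  a <- directed_network(rbind(c("abc", "xyz")))
  b <- directed_network(rbind(c("ABC", "xyz")))
  expect_error(merge_structures(a, b), "case")
})

test_that("weights over a merged structure default to 1 off the D network", {
  a <- chain_net()
  b <- directed_network(rbind(c("A", "B"), c("B", "C"), c("C", "Q")))
  m <- merge_structures(a, b)
  w <- merged_node_weights(m, a)
  expect_equal(unname(w["Q"]), 1)
  expect_equal(unname(w["A"]), 1 + 4 * (2 / 3))
})
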