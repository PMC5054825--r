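#' Built-in synthetic benchmark networks
#'
#' Three synthetic DAGs used throughout the simulation studies and tests.
#' `upr12` is a 12-node / 15-edge network shaped like the three-branch
#' unfolded-protein-response signalling cascade (one root chaperone,
#' `GRP78`, activating the `ATF6`, `PERK` and `IRE1` branches, with shared
#' downstream targets); `upr12_rev` is the same network with the single
#' designated edge `IRE1 -> TRAF2` reversed; `wnt35` is a 35-node / 79-edge
#' DAG over canonical Wnt-pathway gene symbols, generated by a fixed
#' deterministic scheme.  All three are synthetic stand-ins wired for this
#' package — topologically plausible, but not transcriptions of any curated
#' pathway — sized so that the node-weight distribution is heterogeneous
#' (hub nodes with many descendants down to childless sinks).
#'
#' @return named list of [directed_network()] objects `upr12`, `upr12_rev`,
#'   `wnt35`
#' @examples
#' nets <- fixture_networks()
#' length(nets$wnt35$nodes)   # 35
#' nrow(nets$wnt35$edges)     # 79
#' @export
fixture_networks <- function() {
  upr_edges <- rbind(
    c("GRP78", "ATF6"), c("GRP78", "PERK"), c("GRP78", "IRE1"),
    c("PERK", "EIF2A"), c("EIF2A", "ATF4"), c("ATF4", "CHOP"),
    c("CHOP", "GADD34"),
    c("IRE1", "XBP1"), c("IRE1", "TRAF2"), c("TRAF2", "JNK"),
    c("JNK", "BCL2"),
    c("ATF6", "XBP1"), c("ATF6", "CHOP"),
    c("XBP1", "CHOP"), c("CHOP", "BCL2"))
  upr12 <- directed_network(upr_edges)

  rev_edges <- upr_edges
  i <- which(rev_edges[, 1L] == "IRE1" & rev_edges[, 2L] == "TRAF2")
  rev_edges[i, ] <- c("TRAF2", "IRE1")
  upr12_rev <- directed_network(rev_edges, nodes = upr12$nodes)

  list(upr12 = upr12, upr12_rev = upr12_rev, wnt35 = wnt35_network())
}

# 35-node/79-edge DAG over Wnt-pathway gene symbols: nodes are kept in a
# fixed topological order and edges drawn forward-only by a seeded,
# degree-biased scheme (a backbone tree for weak connectivity plus extra
# forward edges), so the fixture is identical on every call and platform.
wnt35_network <- function() {
  genes <- c(
    "WNT1", "WNT5A", "SFRP1", "WIF1", "DKK1", "FZD1", "FZD2", "LRP5",
    "LRP6", "ROR2", "RYK", "DVL1", "DVL2", "DVL3", "CSNK1A1", "CSNK2A1",
    "GSK3B", "APC", "AXIN1", "AXIN2", "PPP2CA", "CTNNB1", "PSEN1", "TCF7",
    "LEF1", "NFATC1", "PLCB1", "PRKCA", "CAMK2A", "RAC1", "RHOA", "MAPK9",
    "JUN", "MYC", "CCND1")
  K <- length(genes)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(35079L)
  # backbone: every non-root node gets one parent among the 5 preceding it
  edges <- t(vapply(2:K, function(j) {
    i <- sample(max(1L, j - 5L):(j - 1L), 1L)
    c(genes[i], genes[j])
  }, character(2)))
  have <- paste(edges[, 1L], edges[, 2L])
  # fill to 79 with distinct extra forward edges
  while (nrow(edges) < 79L) {
    i <- sample.int(K - 1L, 1L)
    j <- sample((i + 1L):K, 1L)
    key <- paste(genes[i], genes[j])
    if (!key %in% have) {
      edges <- rbind(edges, c(genes[i], genes[j]))
      have <- c(have, key)
    }
  }
  directed_network(edges, nodes = genes)
}

#' Default benchmark SEM on a fixture network
#'
#' The simulation studies place one fixed linear Gaussian SEM on each
#' fixture: every edge coefficient 0.5, every error variance 1, intercept 2
#' on the first root node and 0 elsewhere.  The root intercept propagates
#' down the graph, giving the nodes heterogeneous means — the regime in
#' which the aligned-rank statistic is sensitive to covariance changes such
#' as edge reversals.
#'
#' @param network a [directed_network()], e.g. one of [fixture_networks()]
#' @param beta,sigma2,root_mean scalar defaults, overridable
#' @return a [linear_sem()]
#' @export
fixture_sem <- function(network, beta = 0.5, sigma2 = 1, root_mean = 2) {
  topo <- validate_and_order(network)
  roots <- setdiff(network$nodes, network$edges[, 2L])
  delta <- stats::setNames(rep(0, length(network$nodes)), network$nodes)
  if (length(roots) > 0L) delta[topo[topo %in% roots][1L]] <- root_mean
  linear_sem(network, coefficients = beta, error_variances = sigma2,
             mean_shifts = delta)
}

#' Build a pair of group SEMs for a perturbation scenario
#'
#' Starting from one baseline SEM (the group-D generative model), constructs
#' the group-C model for a named two-group scenario:
#' \describe{
#'   \item{null}{no change: `sem_C` is the baseline.}
#'   \item{I}{node-only change: listed node means are shifted; the shift
#'     propagates downstream (no rectification).}
#'   \item{II}{edge-only change: listed coefficients are altered and the SEM
#'     is rectified so every node keeps its baseline marginal mean and
#'     variance — only the joint (edge) structure differs.}
#'   \item{III}{scenario II plus a mean shift on a node with descendants
#'     (topological weight above one), rectified elsewhere.}
#'   \item{IV}{scenario II plus a mean shift on a childless node (weight
#'     exactly one), rectified elsewhere.}
#'   \item{dir-I}{one designated edge is reversed in group C; the reversed
#'     SEM is rectified so all marginal means and variances match the
#'     baseline and the difference is purely directional.}
#'   \item{dir-II}{as dir-I, but the analysis is flagged to collapse the
#'     reversed pair into one shared edge slot whose group coefficients are
#'     compared directly.}
#' }
#'
#' @param baseline a [linear_sem()] for group D
#' @param scenario one of `"null"`, `"I"`, `"II"`, `"III"`, `"IV"`,
#'   `"dir-I"`, `"dir-II"`
#' @param node_shifts named numeric vector of node mean shifts (scenarios I,
#'   III, IV)
#' @param edge_deltas named numeric vector of coefficient changes keyed
#'   `"parent->child"` (scenarios II, III, IV)
#' @param reverse_edge length-2 character vector `c(parent, child)` naming
#'   the edge reversed in group C (dir scenarios)
#' @return list with `sem_D`, `sem_C`, `net_D`, `net_C`,
#'   `collapse_reversed` (logical) and the echoed `scenario`
#' @export
build_scenario <- function(baseline,
                           scenario = c("null", "I", "II", "III", "IV",
                                        "dir-I", "dir-II"),
                           node_shifts = numeric(0),
                           edge_deltas = numeric(0),
                           reverse_edge = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(baseline, "linear_sem"))
  net <- baseline$network
  out <- list(sem_D = baseline, net_D = net, net_C = net,
              collapse_reversed = FALSE, scenario = scenario)

  if (scenario == "null") {
    out$sem_C <- baseline
    return(out)
  }
  if (scenario %in% c("dir-I", "dir-II")) {
    if (is.null(reverse_edge) || length(reverse_edge) != 2L) {
      stop("direction scenarios need reverse_edge = c(parent, child)",
           call. = FALSE)
    }
    key <- paste(reverse_edge[1L], reverse_edge[2L], sep = "->")
    if (!key %in% names(baseline$coefficients)) {
      stop("reverse_edge ", key, " is not a baseline edge", call. = FALSE)
    }
    edges_C <- net$edges
    i <- which(edges_C[, 1L] == reverse_edge[1L] &
               edges_C[, 2L] == reverse_edge[2L])
    edges_C[i, ] <- rev(reverse_edge)
    net_C <- directed_network(edges_C, nodes = net$nodes)
    beta_C <- baseline$coefficients
    names(beta_C)[names(beta_C) == key] <-
      paste(reverse_edge[2L], reverse_edge[1L], sep = "->")
    sem_C <- linear_sem(net_C, beta_C, baseline$error_variances,
                        baseline$mean_shifts)
    # means are held at baseline (else the reversal would read as a node
    # change); the variance consequences of the reversal are the change
    out$sem_C <- rectify_sem(sem_C, baseline, match_variance = FALSE)
    out$net_C <- net_C
    out$collapse_reversed <- scenario == "dir-II"
    return(out)
  }

  shifts <- if (scenario %in% c("I", "III", "IV")) node_shifts else numeric(0)
  deltas <- if (scenario %in% c("II", "III", "IV")) edge_deltas else numeric(0)
  if (scenario == "I" && length(node_shifts) == 0L) {
    stop("scenario I needs node_shifts", call. = FALSE)
  }
  if (scenario %in% c("II", "III", "IV") && length(edge_deltas) == 0L) {
    stop("scenario ", scenario, " needs edge_deltas", call. = FALSE)
  }
  if (scenario %in% c("III", "IV")) {
    if (length(node_shifts) == 0L) {
      stop("scenario ", scenario, " needs node_shifts", call. = FALSE)
    }
    cnt <- descendant_counts(net)
    childless <- names(cnt)[cnt == 0L]
    if (scenario == "III" && all(names(node_shifts) %in% childless)) {
      stop("scenario III shifts must target a node with descendants",
           call. = FALSE)
    }
    if (scenario == "IV" && !all(names(node_shifts) %in% childless)) {
      stop("scenario IV shifts must target childless nodes", call. = FALSE)
    }
  }

  beta_C <- baseline$coefficients
  if (length(deltas) > 0L) {
    unknown <- setdiff(names(deltas), names(beta_C))
    if (length(unknown) > 0L) {
      stop("edge_deltas name unknown edges: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    beta_C[names(deltas)] <- beta_C[names(deltas)] + deltas
  }

  if (scenario == "I") {
    # unrectified: the shift enters the structural equation and propagates
    delta_C <- baseline$mean_shifts
    delta_C[names(shifts)] <- delta_C[names(shifts)] + shifts
    out$sem_C <- linear_sem(net, beta_C, baseline$error_variances, delta_C)
  } else {
    sem_C <- linear_sem(net, beta_C, baseline$error_variances,
                        baseline$mean_shifts)
    out$sem_C <- rectify_sem(sem_C, baseline, shift_nodes = shifts)
  }
  out
}

#' Canned fixture scenarios for the power study
#'
#' The power scenarios used by the evaluation harness on the `upr12`
#' fixture, with one fixed set of effect sizes chosen for mid-range power at
#' moderate sample sizes: node shift 0.5 on the root `GRP78` (11
#' descendants, the largest topological weight) or on the childless
#' `GADD34` (weight exactly one), and coefficient change -0.4 on the edge
#' `GRP78->ATF6`; direction scenarios reverse `IRE1->TRAF2`.
#'
#' @param sem baseline [linear_sem()] (default: [fixture_sem()] on `upr12`)
#' @param node_shift,edge_delta effect sizes
#' @param shift_node the node shifted in scenarios I and III
#' @return named list of [build_scenario()] results: `null`, `I`, `II`,
#'   `III`, `IV`, `dir-I`, `dir-II`
#' @export
fixture_scenarios <- function(sem = fixture_sem(fixture_networks()$upr12),
                              node_shift = 0.5, edge_delta = -0.4,
                              shift_node = "GRP78") {
  shifts <- stats::setNames(node_shift, shift_node)
  list(
    "null" = build_scenario(sem, "null"),
    "I"    = build_scenario(sem, "I", node_shifts = shifts),
    "II"   = build_scenario(sem, "II",
                            edge_deltas = c("GRP78->ATF6" = edge_delta)),
    "III"  = build_scenario(sem, "III",
                            node_shifts = shifts,
                            edge_deltas = c("GRP78->ATF6" = edge_delta)),
    "IV"   = build_scenario(sem, "IV",
                            node_shifts = c(GADD34 = node_shift),
                            edge_deltas = c("GRP78->ATF6" = edge_delta)),
    "dir-I"  = build_scenario(sem, "dir-I",
                              reverse_edge = c("IRE1", "TRAF2")),
    "dir-II" = build_scenario(sem, "dir-II",
                              reverse_edge = c("IRE1", "TRAF2")))
}
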