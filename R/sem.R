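#' Specify a linear Gaussian structural equation model on a DAG
#'
#' Each node X_j satisfies `X_j = delta_j + sum_{i in pa(j)} beta_ij X_i +
#' e_j` with independent Gaussian errors `e_j ~ N(0, sigma2_j)`.  Root nodes
#' reduce to `N(delta, sigma2)`.  This is the generative model under which
#' the edge-strength OLS estimates recover the structural coefficients.
#'
#' @param network a [directed_network()]
#' @param coefficients edge coefficients `beta`: a single number recycled to
#'   every edge, or a named vector keyed `"parent->child"`, or a numeric
#'   vector in the order of `network$edges`
#' @param error_variances per-node error variances `sigma2 > 0`: single
#'   number or named vector over nodes
#' @param mean_shifts per-node intercepts `delta`: single number or named
#'   vector over nodes
#' @return object of class `linear_sem`
#' @export
linear_sem <- function(network, coefficients = 0.5, error_variances = 1,
                       mean_shifts = 0) {
  stopifnot(inherits(network, "directed_network"))
  ekeys <- edge_labels(network$edges)
  beta <- expand_param(coefficients, ekeys, "coefficients")
  sigma2 <- expand_param(error_variances, network$nodes, "error_variances")
  delta <- expand_param(mean_shifts, network$nodes, "mean_shifts")
  if (any(sigma2 < 0)) {
    stop("error variances must be non-negative: ",
         paste(names(sigma2)[sigma2 < 0], collapse = ", "), call. = FALSE)
  }
  structure(list(network = network, coefficients = beta,
                 error_variances = sigma2, mean_shifts = delta,
                 topo = validate_and_order(network)),
            class = "linear_sem")
}

edge_labels <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = "->")
}

expand_param <- function(value, keys, what) {
  if (length(value) == 1L && is.null(names(value))) {
    return(stats::setNames(rep(as.numeric(value), length(keys)), keys))
  }
  if (!is.null(names(value))) {
    out <- stats::setNames(rep(0, length(keys)), keys)
    unknown <- setdiff(names(value), keys)
    if (length(unknown) > 0L) {
      stop("unknown ", what, " entries: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[names(value)] <- as.numeric(value)
    # unnamed-default semantics: named partial vectors override a 0 default,
    # except variances where omitting a node would be invalid
    return(out)
  }
  if (length(value) != length(keys)) {
    stop(what, " must be length 1, named, or match length ", length(keys),
         call. = FALSE)
  }
  stats::setNames(as.numeric(value), keys)
}

#' @export
print.linear_sem <- function(x, ...) {
  cat("linear Gaussian SEM:", length(x$network$nodes), "nodes,",
      length(x$coefficients), "edges\n")
  invisible(x)
}

sem_parents <- function(sem) {
  split(data.frame(parent = sem$network$edges[, 1L],
                   beta = unname(sem$coefficients),
                   stringsAsFactors = FALSE),
        factor(sem$network$edges[, 2L], levels = sem$network$nodes))
}

#' Simulate subjects from a linear SEM
#'
#' Walks the nodes in topological order: root nodes are drawn
#' `N(delta, sigma2)`, every other node is its linear parent combination
#' plus `delta` plus fresh `N(0, sigma2)` noise.
#'
#' @param sem a [linear_sem()]
#' @param n number of subjects
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is restored afterwards
#' @return a [group_data()] matrix of `n` rows in the network's node order
#' @export
simulate_sem <- function(sem, n, seed = NULL) {
  stopifnot(inherits(sem, "linear_sem"), n >= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  nodes <- sem$network$nodes
  x <- matrix(0, nrow = n, ncol = length(nodes),
              dimnames = list(NULL, nodes))
  pa <- sem_parents(sem)
  for (v in sem$topo) {
    mu <- rep(sem$mean_shifts[[v]], n)
    pv <- pa[[v]]
    if (!is.null(pv) && nrow(pv) > 0L) {
      mu <- mu + drop(x[, pv$parent, drop = FALSE] %*% pv$beta)
    }
    sd_v <- sqrt(sem$error_variances[[v]])
    x[, v] <- mu + if (sd_v > 0) stats::rnorm(n, 0, sd_v) else 0
  }
  group_data(x[, nodes, drop = FALSE])
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Model-implied moments of a linear SEM
#'
#' Exact mean vector and covariance matrix of the joint Gaussian
#' distribution, accumulated in topological order:
#' `Cov(X_j, .) = sum_parents beta * Cov(X_parent, .)` and
#' `Var(X_j) = beta' Cov(parents) beta + sigma2_j`.  Used as the oracle for
#' the simulator and as the engine of variance rectification.
#'
#' @param sem a [linear_sem()]
#' @return list with `mean` (named vector) and `cov` (K x K matrix)
#' @export
implied_moments <- function(sem) {
  nodes <- sem$network$nodes
  K <- length(nodes)
  S <- matrix(0, K, K, dimnames = list(nodes, nodes))
  m <- stats::setNames(rep(0, K), nodes)
  pa <- sem_parents(sem)
  for (v in sem$topo) {
    pv <- pa[[v]]
    if (is.null(pv) || nrow(pv) == 0L) {
      m[v] <- sem$mean_shifts[[v]]
      S[v, v] <- sem$error_variances[[v]]
    } else {
      b <- pv$beta
      p <- pv$parent
      m[v] <- sem$mean_shifts[[v]] + sum(b * m[p])
      cross <- drop(b %*% S[p, , drop = FALSE])
      S[v, ] <- cross
      S[, v] <- cross
      S[v, v] <- drop(b %*% S[p, p, drop = FALSE] %*% b) +
        sem$error_variances[[v]]
    }
  }
  list(mean = m, cov = S)
}

#' Model-implied covariance matrix
#'
#' @param sem a [linear_sem()]
#' @return K x K covariance matrix in node order
#' @export
implied_covariance <- function(sem) implied_moments(sem)$cov

#' Rectify a perturbed SEM against its baseline
#'
#' After a scenario changes coefficients (or network structure), downstream
#' nodes would drift in marginal mean and variance, so a comparison would
#' confound the intended change with incidental marginal changes.
#' Rectification walks the perturbed SEM in topological order and resets each
#' node's intercept and error variance so that its implied marginal mean and
#' variance equal the baseline values — except that nodes listed in
#' `shift_nodes` keep an additional mean offset of the given magnitude.  The
#' result: only explicitly shifted nodes differ in mean, no node differs in
#' marginal variance, and coefficient changes survive purely as
#' joint-distribution (edge) changes.
#'
#' @param sem a perturbed [linear_sem()] (its node set must equal the
#'   baseline's; edges may differ, e.g. after reversing an edge)
#' @param baseline the reference [linear_sem()]
#' @param shift_nodes named numeric vector of explicit node mean shifts
#'   (empty by default)
#' @param match_variance logical; when `FALSE` only the marginal means are
#'   rectified and every error variance is left as supplied (used by the
#'   edge-direction scenarios, where the variance consequences of the
#'   reversal are part of the change under study)
#' @return a rectified `linear_sem`
#' @section Infeasibility: if a coefficient change pumps more variance into a
#'   node through its parents than the node's baseline marginal variance, no
#'   positive error variance can restore the baseline and an error naming the
#'   node is raised.
#' @export
rectify_sem <- function(sem, baseline, shift_nodes = numeric(0),
                        match_variance = TRUE) {
  stopifnot(inherits(sem, "linear_sem"), inherits(baseline, "linear_sem"))
  if (!setequal(sem$network$nodes, baseline$network$nodes)) {
    stop("perturbed and baseline SEMs must share one node set", call. = FALSE)
  }
  unknown <- setdiff(names(shift_nodes), sem$network$nodes)
  if (length(unknown) > 0L) {
    stop("shift on unknown nodes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- implied_moments(baseline)
  nodes <- sem$network$nodes
  K <- length(nodes)
  S <- matrix(0, K, K, dimnames = list(nodes, nodes))
  m <- stats::setNames(rep(0, K), nodes)
  pa <- sem_parents(sem)
  sigma2 <- sem$error_variances
  delta <- sem$mean_shifts
  tol <- 1e-12
  for (v in sem$topo) {
    shift <- if (v %in% names(shift_nodes)) shift_nodes[[v]] else 0
    target_mean <- base$mean[[v]] + shift
    target_var <- base$cov[v, v]
    pv <- pa[[v]]
    if (is.null(pv) || nrow(pv) == 0L) {
      delta[v] <- target_mean
      m[v] <- target_mean
      if (match_variance) sigma2[v] <- target_var
      S[v, v] <- sigma2[[v]]
    } else {
      b <- pv$beta
      p <- pv$parent
      parent_var <- drop(b %*% S[p, p, drop = FALSE] %*% b)
      if (match_variance) {
        s2 <- target_var - parent_var
        if (s2 <= tol) {
          stop("infeasible scenario: node ", v,
               " would need error variance ", signif(s2, 4),
               " to keep its baseline marginal variance", call. = FALSE)
        }
        sigma2[v] <- s2
      }
      delta[v] <- target_mean - sum(b * m[p])
      m[v] <- target_mean
      cross <- drop(b %*% S[p, , drop = FALSE])
      S[v, ] <- cross
      S[, v] <- cross
      S[v, v] <- parent_var + sigma2[[v]]
    }
  }
  linear_sem(sem$network, sem$coefficients, sigma2, delta)
}
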