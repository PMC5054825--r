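#' Construct a directed network
#'
#' A `directed_network` is a labelled directed acyclic graph (DAG): the node
#' set of one group's biological network together with its directed edges
#' (parent regulates child).  Construction validates the structure: labels
#' must be unique non-empty strings, edges must join known labels, self-loops
#' and duplicate edges are rejected, and the graph must admit a topological
#' order (no directed cycle).
#'
#' @param edges two-column character matrix or data frame, one directed edge
#'   per row as (parent, child).  May have zero rows for an edgeless network.
#' @param nodes optional character vector of node labels.  Defaults to the
#'   labels appearing in `edges`; when supplied it must cover all edge
#'   endpoints and may add isolated nodes.  Labels are case-sensitive and
#'   matched exactly.
#' @return an object of class `directed_network` with elements
#'   `nodes` (character vector, the label order) and `edges`
#'   (two-column character matrix with columns `parent`, `child`).
#' @examples
#' net <- directed_network(rbind(c("A", "B"), c("B", "C")))
#' topological_order(net)
#' @seealso [topological_order()], [descendant_counts()], [merge_structures()]
#' @export
directed_network <- function(edges, nodes = NULL) {
  edges <- as_edge_matrix(edges)
  if (any(edges == "" | is.na(edges))) {
    stop("edge endpoints must be non-empty labels", call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- unique(as.vector(t(edges)))
  } else {
    nodes <- as.character(nodes)
    missing <- setdiff(as.vector(edges), nodes)
    if (length(missing) > 0L) {
      stop("edge endpoints not in node set: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (anyDuplicated(nodes)) {
    stop("duplicate node labels: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] == edges[, 2L])) {
      bad <- edges[edges[, 1L] == edges[, 2L], 1L]
      stop("self-loop on node ", bad[1L], call. = FALSE)
    }
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate edges: ",
           paste(gsub("\r", "->", unique(key[duplicated(key)])), collapse = ", "),
           call. = FALSE)
    }
  }
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "directed_network")
  validate_and_order(net)  # errors on cycles
  net
}

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("edges must be a two-column (parent, child) matrix", call. = FALSE)
  }
  storage.mode(edges) <- "character"
  dimnames(edges) <- list(NULL, c("parent", "child"))
  edges
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges[, 1L], to = net$edges[, 2L],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' @export
print.directed_network <- function(x, ...) {
  cat("directed network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Validate a DAG and return a topological node order
#'
#' Checks that the directed network is acyclic and returns an ordering of the
#' node labels in which every parent precedes all of its children.  The test
#' statistics and the structural-equation simulator are only defined for
#' DAGs; cyclic (feedback) networks are rejected with an error that names one
#' offending cycle.
#'
#' @param network a [directed_network()]
#' @return character vector of node labels in topological order
#' @export
validate_and_order <- function(network) {
  stopifnot(inherits(network, "directed_network"))
  g <- as_igraph(network)
  ord <- tryCatch(
    igraph::topo_sort(g, mode = "out"),
    error = function(e) NULL,
    warning = function(w) NULL)
  if (is.null(ord) || length(ord) < length(network$nodes)) {
    stop("network contains a directed cycle: ",
         paste(find_cycle(network), collapse = " -> "), call. = FALSE)
  }
  igraph::V(g)$name[as.integer(ord)]
}

# iterative DFS naming one directed cycle (error-path diagnostics only)
find_cycle <- function(network) {
  adj <- split(network$edges[, 2L],
               factor(network$edges[, 1L], levels = network$nodes))
  state <- stats::setNames(rep(0L, length(network$nodes)), network$nodes)
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (!is.null(found)) break
      if (state[w] == 1L) {
        found <<- c(path[which(path == w)[1L]:length(path)], w)
      } else if (state[w] == 0L) visit(w)
    }
    if (is.null(found)) path <<- path[-length(path)]
    state[v] <<- 2L
  }
  for (v in network$nodes) {
    if (state[v] == 0L) visit(v)
    if (!is.null(found)) break
  }
  found %||% "unknown"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count the descendants of every node
#'
#' For each node k, counts the distinct nodes reachable from k along directed
#' paths of length at least one ("children nodes" in the topological-weight
#' sense, found by exhaustively walking downstream).  Sink nodes have count
#' zero.  `mode = "children"` counts direct children only, an alternative
#' reading of topological importance that is exposed but not the default.
#'
#' @param network a [directed_network()]
#' @param mode `"descendants"` (default) or `"children"`
#' @return named integer vector `c_k` in node order
#' @examples
#' net <- directed_network(rbind(c("A", "B"), c("B", "C")))
#' descendant_counts(net)  # A=2, B=1, C=0
#' @export
descendant_counts <- function(network, mode = c("descendants", "children")) {
  mode <- match.arg(mode)
  validate_and_order(network)
  if (mode == "children") {
    cnt <- table(factor(network$edges[, 1L], levels = network$nodes))
    return(stats::setNames(as.integer(cnt), network$nodes))
  }
  g <- as_igraph(network)
  # subcomponent(mode = "out") includes the node itself; subtract it
  cnt <- vapply(seq_along(network$nodes), function(i) {
    length(igraph::subcomponent(g, i, mode = "out")) - 1L
  }, integer(1))
  stats::setNames(cnt, network$nodes)
}

#' Relative topological weights
#'
#' The relative weight of node k is its descendant count divided by the total
#' descendant count over all nodes: the proportion of downstream reach that
#' node k holds.  For an edgeless network (all counts zero) every relative
#' weight is zero by convention.
#'
#' @param counts named integer vector from [descendant_counts()]
#' @return named numeric vector `r_k`, summing to 1 whenever any edge exists
#' @export
relative_weights <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(rep(0, length(counts)), names(counts)))
  counts / tot
}

#' Specify a node-weight family
#'
#' The weight multiplies a node's squared standardized mean difference inside
#' WNES.  All families give weight exactly 1 to childless nodes.  For a node
#' with relative weight r_k in a K-node merged structure:
#' \describe{
#'   \item{unit}{w_k = 1 (WNES reduces to NES);}
#'   \item{additive}{w_k = 1 + K r_k / a (default a = 1: the descendant count
#'     divided by the mean descendant count is added to the baseline);}
#'   \item{power}{w_k = (1 + K r_k)^(1/b).}
#' }
#' Smaller tuning values `a`, `b` give topology a larger say in the statistic.
#'
#' @param family `"additive"` (default), `"power"`, or `"unit"`
#' @param tuning positive real; `a` for additive, `b` for power, ignored for
#'   unit
#' @return object of class `weight_scheme`
#' @export
weight_scheme <- function(family = c("additive", "power", "unit"), tuning = 1) {
  family <- match.arg(family)
  if (!is.numeric(tuning) || length(tuning) != 1L || is.na(tuning) ||
      tuning <= 0) {
    stop("weight tuning must be a positive number", call. = FALSE)
  }
  structure(list(family = family, tuning = as.numeric(tuning)),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight scheme:", x$family,
      if (x$family != "unit") paste0("(tuning = ", x$tuning, ")"), "\n")
  invisible(x)
}

#' Node weights from relative weights
#'
#' @param r named numeric vector of relative weights (see
#'   [relative_weights()])
#' @param K number of nodes in the merged structure
#' @param scheme a [weight_scheme()]
#' @return named numeric vector `w_k >= 1`, with `w_k = 1` exactly for every
#'   node without descendants
#' @examples
#' net <- directed_network(rbind(c("A", "B"), c("B", "C")))
#' r <- relative_weights(descendant_counts(net))
#' node_weights(r, K = 3, weight_scheme("additive"))  # 3, 2, 1
#' @export
node_weights <- function(r, K, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  w <- switch(scheme$family,
    unit     = rep(1, length(r)),
    additive = 1 + (K * r) / scheme$tuning,
    power    = (1 + K * r)^(1 / scheme$tuning))
  stats::setNames(as.numeric(w), names(r))
}

#' Merge the two group networks into the union bookkeeping
#'
#' The statistics compare the two groups over the union node set (size K) and
#' union directed-edge set (size M): a node or edge present in only one group
#' contributes a zero-filled summary for the other group.  By default edge
#' direction matters, so i->j in one group and j->i in the other count as two
#' distinct union edges (two identical networks give M edges; reversing one
#' edge in one group gives M + 1).  With `collapse_reversed = TRUE` such an
#' oppositely oriented pair is treated as one shared edge slot whose
#' group-specific coefficients (each estimated in that group's own
#' orientation) are compared directly.
#'
#' @param net_D,net_C [directed_network()] objects for the two groups
#' @param collapse_reversed logical; collapse oppositely oriented edge pairs
#'   into one slot
#' @return object of class `merged_structure`: `nodes` (union labels, K of
#'   them), `node_in_D`/`node_in_C` logical flags, and `edges`, a data frame
#'   with one row per union edge slot (M rows) holding the orientation used
#'   in each group (`parent_D`/`child_D`, `parent_C`/`child_C`, `NA` when the
#'   group lacks the edge) and presence flags `in_D`, `in_C`.
#' @examples
#' d <- directed_network(rbind(c("A", "B"), c("B", "C")))
#' c <- directed_network(rbind(c("A", "B"), c("C", "B")))
#' merge_structures(d, c)$M                          # 3
#' merge_structures(d, c, collapse_reversed = TRUE)$M  # 2
#' @export
merge_structures <- function(net_D, net_C, collapse_reversed = FALSE) {
  stopifnot(inherits(net_D, "directed_network"),
            inherits(net_C, "directed_network"))
  nodes <- union(net_D$nodes, net_C$nodes)
  folded <- tolower(nodes)
  if (anyDuplicated(folded)) {
    clash <- nodes[folded %in% folded[duplicated(folded)]]
    stop("node labels collide across groups up to letter case (labels are ",
         "case-sensitive, exact-match): ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  key_D <- edge_keys(net_D$edges)
  key_C <- edge_keys(net_C$edges)
  all_edges <- rbind(net_D$edges, net_C$edges)
  all_keys <- c(key_D, key_C)
  keep <- !duplicated(all_keys)
  uedges <- all_edges[keep, , drop = FALSE]
  ukeys <- all_keys[keep]

  edges <- data.frame(
    parent   = uedges[, 1L], child   = uedges[, 2L],
    parent_D = uedges[, 1L], child_D = uedges[, 2L],
    parent_C = uedges[, 1L], child_C = uedges[, 2L],
    in_D = ukeys %in% key_D, in_C = ukeys %in% key_C,
    stringsAsFactors = FALSE)
  edges$parent_D[!edges$in_D] <- NA_character_
  edges$child_D[!edges$in_D] <- NA_character_
  edges$parent_C[!edges$in_C] <- NA_character_
  edges$child_C[!edges$in_C] <- NA_character_

  if (isTRUE(collapse_reversed)) {
    rev_keys <- edge_keys(uedges[, 2:1, drop = FALSE])
    pair_key <- ifelse(ukeys < rev_keys, ukeys, rev_keys)
    drop <- logical(nrow(edges))
    for (grp in split(seq_len(nrow(edges)), pair_key)) {
      if (length(grp) == 2L) {
        # opposite orientations of one node pair: fold into the first slot
        a <- grp[1L]; b <- grp[2L]
        if (edges$in_D[b]) {
          edges$parent_D[a] <- edges$parent_D[b]
          edges$child_D[a] <- edges$child_D[b]
          edges$in_D[a] <- TRUE
        }
        if (edges$in_C[b]) {
          edges$parent_C[a] <- edges$parent_C[b]
          edges$child_C[a] <- edges$child_C[b]
          edges$in_C[a] <- TRUE
        }
        drop[b] <- TRUE
      }
    }
    edges <- edges[!drop, , drop = FALSE]
    rownames(edges) <- NULL
  }

  structure(list(
    nodes = nodes,
    K = length(nodes),
    M = nrow(edges),
    node_in_D = stats::setNames(nodes %in% net_D$nodes, nodes),
    node_in_C = stats::setNames(nodes %in% net_C$nodes, nodes),
    edges = edges,
    collapse_reversed = isTRUE(collapse_reversed)),
    class = "merged_structure")
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = "\r")
}

#' @export
print.merged_structure <- function(x, ...) {
  cat("merged structure: K =", x$K, "nodes, M =", x$M, "edge slots",
      if (x$collapse_reversed) "(reversed pairs collapsed)", "\n")
  invisible(x)
}

#' Merged-structure node weights
#'
#' Convenience wrapper computing the WNES node weights on the union node set:
#' descendant counts and relative weights are taken from the group-D network
#' (the reference structure for weighting); union nodes absent from it get
#' relative weight zero, hence weight one.
#'
#' @param merged a [merge_structures()] result
#' @param net_D the group-D [directed_network()]
#' @param scheme a [weight_scheme()]
#' @param mode passed to [descendant_counts()]
#' @return named numeric vector over the union nodes
#' @export
merged_node_weights <- function(merged, net_D, scheme = weight_scheme(),
                                mode = "descendants") {
  r_D <- relative_weights(descendant_counts(net_D, mode = mode))
  r <- stats::setNames(rep(0, merged$K), merged$nodes)
  r[names(r_D)] <- r_D
  node_weights(r, merged$K, scheme)
}
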