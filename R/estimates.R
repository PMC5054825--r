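#' Assemble one group's data matrix
#'
#' @param x numeric matrix (or data frame of numerics), one subject per row,
#'   with column names equal to node labels
#' @param group tag for reporting, conventionally `"D"` or `"C"`
#' @return object of class `group_data`
#' @export
group_data <- function(x, group = "D") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data matrix must be numeric", call. = FALSE)
  if (is.null(colnames(x)) || any(colnames(x) == "")) {
    stop("data matrix must have node labels as column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate data columns: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x)) stop("data matrix contains missing values", call. = FALSE)
  structure(list(x = x, group = group, n = nrow(x)), class = "group_data")
}

as_group_matrix <- function(data) {
  if (inherits(data, "group_data")) data$x else group_data(data)$x
}

#' Per-group node and edge summaries over the merged structure
#'
#' Computes, for one group, the sample mean and unbiased variance of every
#' union node and the ordinary-least-squares edge coefficients of every union
#' edge, in the alignment the test statistics consume.  Elements absent from
#' this group's network are zero-filled (mean, variance, coefficient and its
#' variance all 0), the convention under which an absent node or edge still
#' contributes its full squared difference.
#'
#' Edge strengths are estimated child-by-child: each child node is regressed
#' on **all** of its parents in this group's network, plus an intercept; the
#' coefficient (and its usual OLS sampling variance, residual mean square
#' times the corresponding diagonal of the inverted normal-equations matrix,
#' on n - p - 1 degrees of freedom) of parent i in child j's fit is the
#' strength of edge i->j.
#'
#' @param data a [group_data()] object or numeric matrix with node columns
#' @param merged a [merge_structures()] result
#' @param group `"D"` or `"C"`: which group's presence flags and edge
#'   orientations to use
#' @return object of class `group_summaries`: `node` data frame (`node`,
#'   `mean`, `var`, `present`; K rows) and `edge` data frame (`parent`,
#'   `child`, `beta`, `var_beta`, `present`; M rows), plus `n`
#' @export
group_summaries <- function(data, merged, group = c("D", "C")) {
  group <- match.arg(group)
  x <- as_group_matrix(data)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects per group", call. = FALSE)

  node_in <- if (group == "D") merged$node_in_D else merged$node_in_C
  present_nodes <- merged$nodes[node_in]
  missing <- setdiff(present_nodes, colnames(x))
  if (length(missing) > 0L) {
    stop("nodes flagged present for group ", group,
         " but absent from the data matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  mu <- v <- stats::setNames(rep(0, merged$K), merged$nodes)
  mu[present_nodes] <- colMeans(x[, present_nodes, drop = FALSE])
  v[present_nodes] <- apply(x[, present_nodes, drop = FALSE], 2L, stats::var)
  node <- data.frame(node = merged$nodes, mean = unname(mu), var = unname(v),
                     present = unname(node_in), stringsAsFactors = FALSE)

  ed <- merged$edges
  e_parent <- if (group == "D") ed$parent_D else ed$parent_C
  e_child <- if (group == "D") ed$child_D else ed$child_C
  e_in <- if (group == "D") ed$in_D else ed$in_C

  beta <- var_beta <- rep(0, merged$M)
  if (merged$M > 0L && any(e_in)) {
    for (ch in unique(e_child[e_in])) {
      rows <- which(e_in & e_child == ch)
      parents <- e_parent[rows]
      fit <- ols_edge_fit(x, ch, parents, n)
      beta[rows] <- fit$beta[parents]
      var_beta[rows] <- fit$var_beta[parents]
    }
  }
  edge <- data.frame(parent = ed$parent, child = ed$child,
                     beta = beta, var_beta = var_beta,
                     present = e_in, stringsAsFactors = FALSE)

  structure(list(node = node, edge = edge, n = n, group = group),
            class = "group_summaries")
}

# OLS of one child on its full parent set (plus intercept)
ols_edge_fit <- function(x, child, parents, n) {
  p <- length(parents)
  if (n <= p + 1L) {
    stop("group has n = ", n, " subjects but child ", child, " has ", p,
         " parents; need n > parents + 1", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x[, parents, drop = FALSE])
  y <- x[, child]
  xtx <- crossprod(X)
  xtx_inv <- tryCatch(chol2inv(chol(xtx)), error = function(e) NULL)
  if (is.null(xtx_inv)) {
    stop("collinear parent design for child ", child, call. = FALSE)
  }
  coefs <- stats::setNames(drop(xtx_inv %*% crossprod(X, y)), colnames(X))
  resid <- y - drop(X %*% coefs)
  rss <- sum(resid^2)
  sigma2 <- rss / (n - p - 1L)
  vb <- sigma2 * diag(xtx_inv)
  list(beta = stats::setNames(coefs[-1L], parents),
       var_beta = stats::setNames(vb[-1L], parents))
}
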