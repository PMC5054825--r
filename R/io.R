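#' Read a directed network from a file
#'
#' Two formats are supported.  Edge-list TSV: two tab-separated columns
#' `parent<TAB>child`, one edge per line, `#`-prefixed comment lines and
#' blank lines ignored, UTF-8.  GraphML: read through igraph, with edge
#' direction taken from source -> target.  Duplicate edges are collapsed
#' with a warning; cycles and self-loops are structural errors.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"tsv"` or `"graphml"`
#' @param nodes optional label universe (adds isolated nodes)
#' @return a validated [directed_network()]
#' @export
read_network <- function(path, format = c("auto", "tsv", "graphml"),
                         nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!igraph::is_directed(g)) {
      stop("GraphML graph in ", path, " is not directed", call. = FALSE)
    }
    labs <- igraph::V(g)$name
    if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(g)))
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- cbind(labs[el[, 1L]], labs[el[, 2L]])
    all_nodes <- union(labs, nodes)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- which(keep)
    if (length(rows) == 0L) {
      edges <- matrix(character(0), ncol = 2L)
    } else {
      parts <- strsplit(lines[rows], "\t", fixed = TRUE)
      bad <- which(lengths(parts) != 2L |
                     vapply(parts, function(p) any(p == ""), logical(1)))
      if (length(bad) > 0L) {
        stop("malformed edge line ", rows[bad[1L]], " in ", path, ": ",
             lines[rows[bad[1L]]], call. = FALSE)
      }
      edges <- do.call(rbind, parts)
    }
    all_nodes <- union(unique(as.vector(t(edges))), nodes)
  }
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edges in ", path, " collapsed: ",
            paste(gsub("\r", "->", unique(key[duplicated(key)])),
                  collapse = ", "), call. = FALSE)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  directed_network(edges, nodes = all_nodes)
}

#' Write a directed network
#'
#' @param network a [directed_network()]
#' @param path output file
#' @param format `"tsv"` (edge-list) or `"graphml"`
#' @return `path`, invisibly
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "directed_network"))
  if (format == "tsv") {
    writeLines(c("# parent\tchild",
                 paste(network$edges[, 1L], network$edges[, 2L],
                       sep = "\t")),
               path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a two-group data matrix
#'
#' Reads a delimited (comma or tab, auto-detected) numeric matrix with a
#' header row of node labels and one subject per row, and splits it into the
#' two groups.  Group membership comes either from a designated column of
#' the matrix (`label_column`) or from a separate single-column label file
#' (`label_file`, one label per subject in the same row order).  Exactly two distinct labels must occur; the first label in file order is
#' reported as group D (the statistics are group-swap symmetric, so the
#' choice is cosmetic).  Missing or non-numeric cells are errors.
#'
#' @param path data file
#' @param label_column name of the group column inside the data file
#' @param label_file path of a one-column label file
#' @return list with [group_data()] objects `D` and `C` (identical column
#'   order) and `labels` (the two labels, D first)
#' @export
read_dataset <- function(path, label_column = NULL, label_file = NULL) {
  if (is.null(label_column) == is.null(label_file)) {
    stop("give exactly one of label_column or label_file", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column ", label_column, " not found in ", path,
           call. = FALSE)
    }
    labels <- as.character(df[[label_column]])
    df[[label_column]] <- NULL
  } else {
    labels <- as.character(utils::read.table(label_file, header = FALSE,
                                             stringsAsFactors = FALSE)[[1L]])
    if (length(labels) != nrow(df)) {
      stop("label file has ", length(labels), " entries for ", nrow(df),
           " subjects", call. = FALSE)
    }
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(df)[bad][1L]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
    stop("non-numeric value in column '", col, "', row ",
         if (is.na(row)) "?" else row, call. = FALSE)
  }
  x <- as.matrix(df)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", idx[1L], ", column '",
         colnames(x)[idx[2L]], "' (no imputation is performed)",
         call. = FALSE)
  }
  split <- split_labels(labels, nrow(x))
  list(D = group_data(x[split$idx_D, , drop = FALSE], group = "D"),
       C = group_data(x[split$idx_C, , drop = FALSE], group = "C"),
       labels = as.character(split$lev))
}

#' Write a joint test result
#'
#' Writes either a JSON document (observed statistics, p-values, per-node
#' and per-edge decomposition, weights, run metadata) or a pair of
#' tab-delimited tables (`<path>` for the statistic/p-value summary and
#' `<path>.decomposition.tsv` for the per-node/per-edge terms).
#'
#' @param fit a [network_permutation_test()] result
#' @param path output file
#' @param format `"json"` or `"tsv"`
#' @param config optional list echoed into the JSON output so a run can be
#'   reproduced from its result file
#' @return `path`, invisibly
#' @export
write_test_result <- function(fit, path, format = c("json", "tsv"),
                              config = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(fit, "network_test"))
  res <- fit$result
  if (format == "json") {
    doc <- list(
      statistics = as.list(fit$observed),
      p_values = as.list(fit$p_values),
      B = fit$B, p_mode = fit$p_mode, seed = fit$seed,
      n1 = fit$n1, n2 = fit$n2, K = fit$K, M = fit$M,
      node_terms = as.list(res$U),
      node_weights = as.list(res$weights),
      edge_terms = as.list(res$V),
      package_version = as.character(utils::packageVersion("wnes")))
    if (!is.null(config)) doc$config <- config
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    tab <- data.frame(statistic = names(fit$observed),
                      value = unname(fit$observed),
                      p_value = unname(fit$p_values))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    dec <- data.frame(
      term = c(names(res$U), names(res$V)),
      kind = c(rep("node", length(res$U)), rep("edge", length(res$V))),
      value = c(unname(res$U), unname(res$V)),
      weight = c(unname(res$weights), rep(NA_real_, length(res$V))))
    utils::write.table(dec, paste0(path, ".decomposition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a two-group dataset as delimited text
#'
#' One header row of node labels, one subject per row, with the group label
#' in a leading `group` column.
#'
#' @param data_D,data_C [group_data()] or matrices
#' @param path output file
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_dataset <- function(data_D, data_C, path, sep = "\t") {
  xD <- as_group_matrix(data_D)
  xC <- as_group_matrix(data_C)
  stopifnot(identical(colnames(xD), colnames(xC)))
  df <- data.frame(group = c(rep("D", nrow(xD)), rep("C", nrow(xC))),
                   rbind(xD, xC), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
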