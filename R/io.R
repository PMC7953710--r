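# File I/O for networks, expression matrices, labels; preprocessing steps
# (quantile normalization, non-negativity shift) and dataset alignment.

#' Read a network from an edge-list TSV or a GraphML file
#'
#' Edge lists are tab-separated with a header naming at least \code{source}
#' and \code{target}; an optional \code{weight} column defaults to 1.
#' Files ending in \code{.graphml} (or with \code{format = "graphml"}) are
#' parsed as GraphML.  Directed input edges are symmetrized by maximum weight,
#' duplicate edges collapsed by maximum weight, self-loops dropped.
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"tsv"}, \code{"graphml"}.
#' @return a \code{gsc_graph} with sorted-unique vertex names (edge-list
#'   input) or the file's vertex order (GraphML).
#' @export
read_network <- function(path, format = c("auto", "tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("network file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    return(gsc_from_igraph(ig))
  }
  tab <- tryCatch(
    read.delim(path, header = TRUE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stopf("cannot parse edge list %s: %s", path,
                              conditionMessage(e)))
  if (!all(c("source", "target") %in% names(tab)))
    stopf("%s: header must contain 'source' and 'target'", path)
  n_fields <- lengths(strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE))
  bad <- which(n_fields != n_fields[1])
  if (length(bad))
    stopf("%s: malformed line %d (expected %d tab-separated fields, got %d)",
          path, bad[1], n_fields[1], n_fields[bad[1]])
  if ("weight" %in% names(tab)) {
    w <- suppressWarnings(as.numeric(tab$weight))
    if (anyNA(w)) stopf("%s: non-numeric weight at line %d", path,
                        which(is.na(w))[1] + 1L)
    if (any(w < 0)) stopf("%s: negative weight at line %d", path,
                          which(w < 0)[1] + 1L)
    tab$weight <- w
  }
  graph_from_edges(tab)
}

gsc_from_igraph <- function(ig) {
  nm <- igraph::vertex_attr(ig, "name")
  if (is.null(nm)) nm <- paste0("v", seq_len(igraph::vcount(ig)))
  A <- igraph::as_adjacency_matrix(ig, attr =
        if ("weight" %in% igraph::edge_attr_names(ig)) "weight" else NULL,
        sparse = TRUE)
  graph_from_adjacency(A, nm)
}

#' Write a network
#'
#' @param graph a \code{gsc_graph}.
#' @param path output file.
#' @param format \code{"tsv"} (edge list with header) or \code{"graphml"}.
#' @param node_attrs optional data.frame of per-vertex attributes (rows in
#'   vertex order) carried into GraphML output.
#' @return invisibly, \code{path}.
#' @export
write_network <- function(graph, path, format = c("tsv", "graphml"),
                          node_attrs = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    A <- methods::as(Matrix::triu(graph$adjacency), "TsparseMatrix")
    tab <- data.frame(source = graph$vertex_names[A@i + 1L],
                      target = graph$vertex_names[A@j + 1L],
                      weight = A@x)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ig <- as_igraph(graph)
    if (!is.null(node_attrs)) {
      for (a in names(node_attrs))
        ig <- igraph::set_vertex_attr(ig, a, value = node_attrs[[a]])
    }
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' The file must have a header; the first column holds row identifiers.  By
#' default rows are samples and columns are genes; with
#' \code{genes_as_rows = TRUE} the matrix is transposed after reading.
#' When several columns map to the same gene name, only the column with the
#' highest mean value is kept (the usual probe-collapsing rule for
#' microarray data).
#'
#' @param path TSV file path.
#' @param genes_as_rows logical; set TRUE if rows are genes.
#' @return numeric matrix, samples x genes, with unique dimnames.
#' @export
read_expression <- function(path, genes_as_rows = FALSE) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  tab <- read.delim(path, header = TRUE, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  gene_names <- names(tab)[-1]   # data.frame subsetting would mangle duplicates
  body <- tab[, -1, drop = FALSE]
  names(body) <- gene_names
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v) && !all(is.na(body[[j]])))
      stopf("%s: non-numeric value at row %d, column '%s'", path,
            which(is.na(v))[1], names(body)[j])
    if (anyNA(v)) stopf("%s: non-numeric column '%s'", path, names(body)[j])
    body[[j]] <- v
  }
  X <- as.matrix(body)
  rownames(X) <- ids
  if (genes_as_rows) X <- t(X)
  if (anyDuplicated(rownames(X))) stopf("%s: duplicate sample ids", path)
  X <- collapse_duplicate_genes(X)
  X
}

# Keep, among duplicate gene columns, the one with the highest mean.
collapse_duplicate_genes <- function(X) {
  gn <- colnames(X)
  if (!anyDuplicated(gn)) return(X)
  keep <- vapply(split(seq_along(gn), gn), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[which.max(colMeans(X[, idx, drop = FALSE]))]
  }, integer(1))
  keep <- sort(unname(keep))
  X[, keep, drop = FALSE]
}

#' Read binary labels
#'
#' @param path 2-column TSV (\code{sample_id}, \code{label} in \{0,1\}) with
#'   header.
#' @return named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stopf("%s: need sample_id and label columns", path)
  y <- as.integer(tab[[2]])
  if (!all(y %in% c(0L, 1L))) stopf("%s: labels must be 0/1", path)
  names(y) <- as.character(tab[[1]])
  y
}

#' Quantile-normalization reference distribution
#'
#' @param X numeric matrix, samples as rows.
#' @return numeric vector: the mean of the row-wise order statistics, i.e. the
#'   reference distribution every row is mapped onto.
#' @export
quantile_reference <- function(X) {
  sorted <- apply(X, 1L, sort)      # ncol(X) x nrow(X)
  rowMeans(sorted)
}

#' Quantile normalization across samples
#'
#' Maps every row (sample) onto a common reference distribution so that all
#' rows share the same sorted value multiset.  By default the reference is
#' fitted on \code{X} itself (the mean order-statistic distribution); pass a
#' \code{reference} fitted on training data to normalize held-out samples
#' without information leakage.  Ties within a row receive the average of the
#' reference values at their rank positions.
#'
#' @param X numeric matrix, samples as rows.
#' @param reference optional reference distribution from
#'   \code{\link{quantile_reference}} (length \code{ncol(X)}).
#' @return matrix of the same shape as \code{X}.
#' @export
quantile_normalize <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 1L && is.null(reference)) {
    warnf("single sample: quantile normalization returns input unchanged")
    return(X)
  }
  if (is.null(reference)) reference <- quantile_reference(X)
  if (length(reference) != ncol(X))
    stopf("reference length %d != %d genes", length(reference), ncol(X))
  reference <- sort(reference)
  out <- X
  for (s in seq_len(nrow(X))) {
    o <- order(X[s, ])
    v <- numeric(ncol(X))
    v[o] <- reference
    # tied input values share the mean of their reference slots
    out[s, ] <- stats::ave(v, match(X[s, ], X[s, ]), FUN = mean)
  }
  out
}

#' Shift a matrix to be non-negative
#'
#' Subtracts the global minimum from every cell so the smallest value becomes
#' zero.  Keeping inputs non-negative preserves local expression patterns
#' (unlike per-gene standardization) and is required by the z+ relevance rule
#' used at the input layer.
#'
#' @param X finite numeric matrix.
#' @return list with \code{X_shifted} and \code{shift_value} (the subtracted
#'   minimum, recorded for round-tripping).
#' @export
shift_nonnegative <- function(X) {
  if (!all(is.finite(X))) stopf("matrix contains non-finite values")
  mn <- min(X)
  list(X_shifted = X - mn, shift_value = mn)
}

#' Graph-signal dataset constructor
#'
#' @param X non-negative numeric matrix, samples x vertices, columns in graph
#'   vertex order.
#' @param y binary labels (0/1), length \code{nrow(X)}.
#' @param graph the \code{gsc_graph} the columns are aligned to.
#' @param sample_ids unique sample identifiers; default rownames of X.
#' @return object of class \code{gsc_dataset}.
#' @export
graph_signal_dataset <- function(X, y, graph, sample_ids = rownames(X)) {
  X <- as.matrix(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  if (anyDuplicated(sample_ids)) stopf("sample ids must be unique")
  if (ncol(X) != graph_order(graph))
    stopf("X has %d columns but graph has %d vertices", ncol(X),
          graph_order(graph))
  if (!is.null(colnames(X)) && !identical(colnames(X), graph$vertex_names))
    stopf("X column order does not match graph vertex order")
  if (min(X) < 0) stopf("X must be non-negative (apply shift_nonnegative)")
  y <- as.integer(y)
  if (length(y) != nrow(X) || !all(y %in% c(0L, 1L)))
    stopf("y must be 0/1 of length nrow(X)")
  colnames(X) <- graph$vertex_names
  rownames(X) <- sample_ids
  structure(list(X = X, y = y, graph = graph,
                 sample_ids = as.character(sample_ids)),
            class = "gsc_dataset")
}

#' @export
print.gsc_dataset <- function(x, ...) {
  cat(sprintf("gsc_dataset: %d samples x %d vertices (%d / %d class 0/1)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 0), sum(x$y == 1)))
  invisible(x)
}

#' Align an expression table to a graph
#'
#' Restricts genes to the intersection of expression columns and graph
#' vertices, restricts the graph to the mapped vertices and then to its
#' largest connected component, and reorders the expression columns to the
#' graph's vertex order.
#'
#' @param X samples x genes matrix with gene column names.
#' @param graph a \code{gsc_graph}.
#' @param y binary labels, length \code{nrow(X)} (named vectors are matched
#'   against rownames of \code{X}).
#' @return a \code{gsc_dataset} on the mapped main-component graph.
#' @export
align_dataset <- function(X, graph, y) {
  genes <- colnames(X)
  if (is.null(genes)) stopf("expression matrix must have gene column names")
  mapped <- intersect(graph$vertex_names, genes)
  if (length(mapped) == 0L) stopf("no genes map to graph vertices")
  log_info("mapped %d of %d genes to the network (%d dropped)",
           length(mapped), length(genes), length(genes) - length(mapped))
  sub <- induced_subgraph_gsc(graph, mapped)
  sub <- largest_connected_component(sub)$graph
  log_info("main connected component: %d vertices", graph_order(sub))
  if (!is.null(names(y))) {
    if (!all(rownames(X) %in% names(y))) stopf("labels missing for some samples")
    y <- y[rownames(X)]
  }
  Xa <- X[, sub$vertex_names, drop = FALSE]
  graph_signal_dataset(Xa, y, sub, rownames(X))
}
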