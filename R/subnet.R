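# Patient-specific molecular subnetworks.
#
# A relevance map is turned into an induced subgraph over the k most relevant
# vertices (default k = 140, a visualization-driven limit, not a
# methodological one); vertices isolated within the selection are pruned, and
# each remaining vertex is annotated with its relevance, expression value and
# an expression level (LOW / NORMAL / HIGH by cohort 25%/75% quantiles).

#' Top-k most relevant vertices
#'
#' @param rmap a \code{relevance_map} (or a named relevance vector).
#' @param k number of vertices to select (default 140); if \code{k} exceeds
#'   the vertex count all vertices are returned.
#' @return character vector of vertex names, highest relevance first.  Ties
#'   are broken by lexicographic vertex name, making the selection
#'   deterministic.
#' @export
top_relevant_vertices <- function(rmap, k = 140) {
  stopifnot(k >= 1)
  rel <- if (inherits(rmap, "relevance_map")) rmap$relevance else rmap
  if (is.null(names(rel))) stopf("relevance vector must be named")
  ord <- order(-rel, names(rel))
  names(rel)[ord][seq_len(min(k, length(rel)))]
}

#' Induce a subnetwork and prune singletons
#'
#' @param graph the parent \code{gsc_graph}.
#' @param vertices selected vertex names (subset of the graph).
#' @return a \code{gsc_subnetwork}: the induced graph with vertices of induced
#'   degree 0 removed, plus empty attribute slots to be filled by
#'   \code{\link{annotate_subnetwork}}.  Pruning is idempotent: a vertex keeps
#'   its neighbours inside the selection, so no second-round singletons arise.
#' @export
induce_and_prune <- function(graph, vertices) {
  if (length(vertices) == 0L) stopf("empty vertex selection")
  sub <- induced_subgraph_gsc(graph, vertices)
  keep <- sub$degrees > 0
  if (!any(keep)) stopf("all selected vertices are singletons")
  pruned <- induced_subgraph_gsc(sub, sub$vertex_names[keep])
  structure(list(graph = pruned,
                 attributes = data.frame(vertex = pruned$vertex_names,
                                         relevance = NA_real_,
                                         expression_value = NA_real_,
                                         expression_level = NA_character_),
                 provenance = list()),
            class = "gsc_subnetwork")
}

#' @export
print.gsc_subnetwork <- function(x, ...) {
  cat(sprintf("gsc_subnetwork: %d vertices, %d edges\n",
              graph_order(x$graph), graph_size(x$graph)))
  invisible(x)
}

#' Categorize an expression value against a cohort
#'
#' LOW if below the cohort 25% quantile, HIGH if above the 75% quantile,
#' NORMAL otherwise.  Quantiles use linear interpolation between order
#' statistics (\code{stats::quantile} type 7), fixed so levels are
#' reproducible.
#'
#' @param value numeric value(s) to classify.
#' @param cohort numeric vector of cohort values for the same gene (>= 4
#'   values).
#' @return character vector in \{"LOW", "NORMAL", "HIGH"\}.
#' @export
categorize_expression <- function(value, cohort) {
  if (length(cohort) < 4L) stopf("cohort needs at least 4 values")
  q <- quantile(cohort, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    warnf("constant cohort quantiles: all values categorized NORMAL")
    return(rep("NORMAL", length(value)))
  }
  ifelse(value < q[1], "LOW", ifelse(value > q[2], "HIGH", "NORMAL"))
}

#' Annotate a subnetwork with relevance and expression levels
#'
#' @param subnet a \code{gsc_subnetwork}.
#' @param rmap the \code{relevance_map} it was derived from.
#' @param sample_expression named expression vector of the explained sample.
#' @param cohort_expression samples x genes matrix used as the quantile
#'   cohort (typically the whole dataset).
#' @param k the top-k used for the selection (recorded as provenance).
#' @return the annotated \code{gsc_subnetwork}.
#' @export
annotate_subnetwork <- function(subnet, rmap, sample_expression,
                                cohort_expression, k = 140) {
  v <- subnet$graph$vertex_names
  lev <- vapply(v, function(g)
    categorize_expression(sample_expression[[g]], cohort_expression[, g]),
    character(1))
  subnet$attributes <- data.frame(
    vertex = v,
    relevance = unname(rmap$relevance[v]),
    expression_value = unname(sample_expression[v]),
    expression_level = unname(lev))
  subnet$provenance <- list(sample_id = rmap$sample_id,
                            model_hash = rmap$model_hash, k = k,
                            class_index = rmap$class_index)
  subnet
}

#' Extract an annotated subnetwork from a relevance map
#'
#' Convenience wrapper: top-k selection, induction, singleton pruning and
#' annotation in one call.
#'
#' @param rmap a \code{relevance_map}.
#' @param dataset the \code{gsc_dataset} the model was trained/evaluated on
#'   (provides the graph and the quantile cohort).
#' @param k top-k cutoff (default 140).
#' @return a \code{gsc_subnetwork}.
#' @export
extract_subnetwork <- function(rmap, dataset, k = 140) {
  top <- top_relevant_vertices(rmap, k)
  sn <- induce_and_prune(dataset$graph, top)
  xs <- dataset$X[rmap$sample_id, ]
  names(xs) <- colnames(dataset$X)
  annotate_subnetwork(sn, rmap, xs, dataset$X, k)
}

#' Write a subnetwork to file
#'
#' GraphML output carries the node attributes \code{relevance},
#' \code{expression_value} and \code{expression_level}; SIF output holds edges
#' only, with a sidecar \code{<path>.attrs.tsv} node-attribute table; TSV
#' output writes \code{<path>} as an edge table plus the same sidecar.
#'
#' @param subnet a \code{gsc_subnetwork}.
#' @param path output path.
#' @param format \code{"graphml"}, \code{"sif"}, or \code{"tsv"}.
#' @return invisibly, \code{path}.
#' @export
write_subnetwork <- function(subnet, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  g <- subnet$graph
  if (graph_size(g) == 0L) stopf("refusing to write an edgeless subnetwork")
  if (format == "graphml") {
    write_network(g, path, "graphml",
                  node_attrs = subnet$attributes[, -1, drop = FALSE])
  } else {
    A <- methods::as(Matrix::triu(g$adjacency), "TsparseMatrix")
    if (format == "sif") {
      writeLines(sprintf("%s\tpp\t%s", g$vertex_names[A@i + 1L],
                         g$vertex_names[A@j + 1L]), path)
    } else {
      tab <- data.frame(source = g$vertex_names[A@i + 1L],
                        target = g$vertex_names[A@j + 1L], weight = A@x)
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    attrs <- subnet$attributes
    attrs$relevance <- format(attrs$relevance, digits = 15, trim = TRUE)
    attrs$expression_value <- format(attrs$expression_value, digits = 15,
                                     trim = TRUE)
    write.table(attrs, paste0(path, ".attrs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a subnetwork written by \code{\link{write_subnetwork}}
#'
#' @param path file path (GraphML, or SIF/TSV with its sidecar).
#' @param format as in \code{\link{write_subnetwork}}.
#' @return a \code{gsc_subnetwork} (provenance is not round-tripped).
#' @export
read_subnetwork <- function(path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    g <- gsc_from_igraph(ig)
    ord <- match(g$vertex_names, igraph::vertex_attr(ig, "name"))
    attrs <- data.frame(
      vertex = g$vertex_names,
      relevance = igraph::vertex_attr(ig, "relevance")[ord],
      expression_value = igraph::vertex_attr(ig, "expression_value")[ord],
      expression_level = igraph::vertex_attr(ig, "expression_level")[ord])
  } else {
    if (format == "sif") {
      lines <- strsplit(readLines(path), "\t")
      tab <- data.frame(source = vapply(lines, `[[`, "", 1),
                        target = vapply(lines, `[[`, "", 3))
    } else {
      tab <- read.delim(path, stringsAsFactors = FALSE)
    }
    g <- graph_from_edges(tab)
    attrs <- read.delim(paste0(path, ".attrs.tsv"), stringsAsFactors = FALSE)
    attrs <- attrs[match(g$vertex_names, attrs$vertex), ]
    rownames(attrs) <- NULL
  }
  structure(list(graph = g, attributes = attrs, provenance = list()),
            class = "gsc_subnetwork")
}
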