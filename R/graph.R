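# Graph container and basic graph algebra.
#
# A gsc_graph is a plain list holding an ordered vertex-name vector and a
# sparse symmetric adjacency matrix with a zero diagonal.  All modules accept
# and return this type; igraph objects are only used transiently for I/O and
# component analysis.

#' Construct a graph from an adjacency matrix
#'
#' Builds the package's graph container: an undirected, weighted graph with
#' named vertices.  The adjacency is symmetrized (by the elementwise maximum,
#' appropriate for binary / confidence-scored molecular interactions), the
#' diagonal is stripped, and negative weights are rejected.
#'
#' @param adjacency square matrix or sparse \code{Matrix}; weights must be
#'   non-negative.
#' @param vertex_names character vector of unique vertex identifiers; defaults
#'   to rownames of \code{adjacency} or \code{"v1"..."vm"}.
#' @return an object of class \code{gsc_graph} with fields
#'   \code{vertex_names}, \code{adjacency} (a \code{dgCMatrix}), and
#'   \code{degrees} (weighted degrees \eqn{D_{ii} = \sum_j A_{ij}}).
#' @export
graph_from_adjacency <- function(adjacency, vertex_names = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stopf("adjacency must be square")
  m <- nrow(A)
  if (is.null(vertex_names)) {
    vertex_names <- rownames(adjacency)
    if (is.null(vertex_names)) vertex_names <- paste0("v", seq_len(m))
  }
  if (length(vertex_names) != m) stopf("need %d vertex names, got %d", m,
                                       length(vertex_names))
  if (anyDuplicated(vertex_names)) stopf("vertex names must be unique")
  if (any(A@x < 0)) stopf("negative edge weights are not allowed")
  # symmetrize by max and strip the diagonal
  A <- pmax_sparse(A, Matrix::t(A))
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  dimnames(A) <- list(vertex_names, vertex_names)
  g <- list(vertex_names = as.character(vertex_names),
            adjacency = A,
            degrees = Matrix::rowSums(A))
  class(g) <- "gsc_graph"
  g
}

# Elementwise max of two sparse matrices with identical dims.
pmax_sparse <- function(a, b) {
  d <- (a + b + abs(a - b)) / 2
  Matrix::drop0(d)
}

#' Construct a graph from an edge table
#'
#' @param edges data.frame with columns \code{source}, \code{target} and
#'   optionally \code{weight} (default 1).  Duplicate edges (in either
#'   orientation) are collapsed keeping the maximum weight; self-loops are
#'   dropped with a warning.
#' @param vertices optional character vector of vertex names to include even
#'   if isolated; vertex order is sorted-unique.
#' @return a \code{gsc_graph}.
#' @export
graph_from_edges <- function(edges, vertices = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "target") %in% names(edges)))
    stopf("edge table needs 'source' and 'target' columns")
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
       else rep(1, nrow(edges))
  if (any(!is.finite(w))) stopf("non-finite edge weight")
  if (any(w < 0)) stopf("negative edge weight")
  loops <- src == tgt
  if (any(loops)) {
    warnf("dropping %d self-loop(s)", sum(loops))
    src <- src[!loops]; tgt <- tgt[!loops]; w <- w[!loops]
  }
  names_all <- sort(unique(c(src, tgt, vertices)))
  m <- length(names_all)
  if (m == 0L) stopf("empty graph")
  i <- match(src, names_all)
  j <- match(tgt, names_all)
  # collapse duplicates by max weight, both orientations at once
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (length(lo)) {
    key <- paste(lo, hi)
    w <- tapply(w, key, max)
    ij <- do.call(rbind, strsplit(names(w), " "))
    lo <- as.integer(ij[, 1]); hi <- as.integer(ij[, 2])
    w <- as.numeric(w)
  }
  A <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                            dims = c(m, m))
  graph_from_adjacency(A, names_all)
}

#' @export
print.gsc_graph <- function(x, ...) {
  cat(sprintf("gsc_graph: %d vertices, %d edges\n",
              graph_order(x), graph_size(x)))
  invisible(x)
}

#' Number of vertices of a graph
#' @param graph a \code{gsc_graph}.
#' @return integer vertex count.
#' @export
graph_order <- function(graph) length(graph$vertex_names)

#' Number of edges of a graph
#' @param graph a \code{gsc_graph}.
#' @return integer edge count (undirected, loops excluded).
#' @export
graph_size <- function(graph) as.integer(Matrix::nnzero(graph$adjacency) / 2)

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                      weighted = TRUE)
}

#' Largest connected component
#'
#' Graph convolutions require a connected graph, so molecular networks are
#' restricted to their main connected component before model construction.
#'
#' @param graph a \code{gsc_graph}.
#' @return list with \code{graph} (the component, vertex order preserved) and
#'   \code{index_map}, an integer vector of length \code{graph_order(graph)}
#'   mapping old vertex index to new index (NA for dropped vertices).
#'   Ties in component size are broken toward the component containing the
#'   lexicographically smallest vertex name.
#' @export
largest_connected_component <- function(graph) {
  m <- graph_order(graph)
  if (m == 0L) stopf("empty graph")
  comp <- connected_components(graph$adjacency)
  sizes <- tabulate(comp)
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    # tie-break: component holding the smallest vertex name
    first_name <- vapply(cand, function(cc)
      min(graph$vertex_names[comp == cc]), character(1))
    cand <- cand[order(first_name)][1]
  }
  keep <- which(comp == cand[1])
  index_map <- rep(NA_integer_, m)
  index_map[keep] <- seq_along(keep)
  sub <- graph_from_adjacency(graph$adjacency[keep, keep, drop = FALSE],
                              graph$vertex_names[keep])
  list(graph = sub, index_map = index_map)
}

# Connected components by sparse BFS over the adjacency pattern.
connected_components <- function(A) {
  m <- nrow(A)
  comp <- integer(m)
  Ap <- methods::as(A, "CsparseMatrix")
  nxt <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    nxt <- nxt + 1L
    frontier <- s
    comp[s] <- nxt
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v) {
        idx <- (Ap@p[v] + 1L):Ap@p[v + 1L]
        if (Ap@p[v + 1L] > Ap@p[v]) Ap@i[idx] + 1L else integer(0)
      })))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- nxt
      frontier <- nb
    }
  }
  comp
}

#' Induced subgraph
#'
#' @param graph a \code{gsc_graph}.
#' @param vertices character vector of vertex names (subset of the graph).
#' @return the induced \code{gsc_graph}, vertex order following the parent
#'   graph's order.
#' @export
induced_subgraph_gsc <- function(graph, vertices) {
  idx <- match(vertices, graph$vertex_names)
  if (anyNA(idx)) stopf("unknown vertices: %s",
                        paste(vertices[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  graph_from_adjacency(graph$adjacency[idx, idx, drop = FALSE],
                       graph$vertex_names[idx])
}

#' 8-nearest-neighbour grid graph
#'
#' Builds the unit-weight graph connecting every pixel of a
#' \code{height x width} image to its Moore neighbourhood (the 8 surrounding
#' pixels), the construction used to apply graph convolutions to image data.
#' Vertex names are \code{"px<r>_<c>"} in row-major order.
#'
#' @param height,width grid dimensions, both >= 2.
#' @param k neighbourhood size; only \code{k = 8} is supported.
#' @return a \code{gsc_graph} with \code{height * width} vertices, all edge
#'   weights 1; interior vertices have degree 8, corners degree 3.
#' @export
grid_knn_graph <- function(height, width, k = 8) {
  if (!identical(as.numeric(k), 8)) stopf("only k = 8 (Moore neighbourhood) is supported")
  if (height < 2 || width < 2) stopf("grid must be at least 2x2")
  height <- as.integer(height); width <- as.integer(width)
  rc <- expand.grid(c = seq_len(width), r = seq_len(height))  # row-major ids
  id <- function(r, c) (r - 1L) * width + c
  src <- integer(0); tgt <- integer(0)
  # connect each pixel to E, SW, S, SE neighbours (covers all 8 undirected)
  offs <- list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (o in offs) {
    r2 <- rc$r + o[1]; c2 <- rc$c + o[2]
    ok <- r2 >= 1L & r2 <= height & c2 >= 1L & c2 <= width
    src <- c(src, id(rc$r[ok], rc$c[ok]))
    tgt <- c(tgt, id(r2[ok], c2[ok]))
  }
  nm <- sprintf("px%d_%d", rc$r, rc$c)
  m <- height * width
  A <- Matrix::sparseMatrix(i = c(src, tgt), j = c(tgt, src),
                            x = 1, dims = c(m, m))
  g <- graph_from_adjacency(A, nm)
  attr(g, "grid_dim") <- c(height = height, width = width)
  g
}
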