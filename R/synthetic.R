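# Seeded synthetic data generators.
#
# These stand in for the real cohorts: a preferential-attachment network
# emulates the scale-free degree distribution of protein-protein interaction
# networks (power-law tail exponent around 2.7-3); two-class graph signals
# carry their discriminative pattern on a planted connected module, emulating
# the premise that class-discriminative expression is localized on the
# network; grid bar patterns replace hand-written digits for the image-like
# sanity check.  Every generator is a pure function of (seed, parameters).

#' Scale-free random graph (preferential attachment)
#'
#' @param m number of vertices (>= 10).
#' @param attachment edges added per new vertex (default 2).
#' @param seed RNG seed.
#' @return a connected \code{gsc_graph} with unit weights and vertex names
#'   \code{"g1"..."gm"}; attribute \code{tail_exponent} holds the maximum-
#'   likelihood power-law exponent of the degree tail (Hill/Clauset estimator
#'   with \code{xmin = attachment}).
#' @export
make_scale_free_graph <- function(m, attachment = 2, seed = 1L) {
  stopifnot(m >= 10)
  set.seed(as.integer(seed))
  ig <- igraph::sample_pa(m, power = 1, m = attachment, directed = FALSE)
  ig <- igraph::simplify(ig)
  igraph::V(ig)$name <- paste0("g", seq_len(m))
  g <- gsc_from_igraph(ig)
  attr(g, "tail_exponent") <- fit_tail_exponent(g$degrees, xmin = attachment)
  g
}

#' Maximum-likelihood power-law tail exponent
#'
#' Discrete Hill/Clauset estimator
#' \eqn{\hat\alpha = 1 + n / \sum \log(d_i / (x_{min} - 1/2))} over degrees
#' \eqn{d_i \ge x_{min}}.
#'
#' @param degrees integer degree vector.
#' @param xmin lower cutoff of the tail.
#' @return estimated exponent.
#' @export
fit_tail_exponent <- function(degrees, xmin = 2) {
  d <- degrees[degrees >= xmin]
  if (length(d) < 2L) stopf("too few tail degrees for the estimate")
  1 + length(d) / sum(log(d / (xmin - 0.5)))
}

#' Grow a connected vertex set by breadth-first search
#'
#' @param graph a \code{gsc_graph}.
#' @param size module size.
#' @param start start vertex name (default: seeded random choice).
#' @return character vector of vertex names inducing a connected subgraph.
#' @export
bfs_module <- function(graph, size, start = NULL) {
  m <- graph_order(graph)
  stopifnot(size >= 1, size <= m)
  if (is.null(start)) start <- graph$vertex_names[sample.int(m, 1L)]
  Ap <- methods::as(graph$adjacency, "CsparseMatrix")
  sel <- match(start, graph$vertex_names)
  frontier <- sel
  while (length(sel) < size && length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(v)
      if (Ap@p[v + 1L] > Ap@p[v]) Ap@i[(Ap@p[v] + 1L):Ap@p[v + 1L]] + 1L
      else integer(0))))
    nb <- setdiff(nb, sel)
    if (!length(nb)) break
    take <- head(sort(nb), size - length(sel))
    sel <- c(sel, take)
    frontier <- take
  }
  if (length(sel) < size)
    stopf("could not grow a connected module of size %d from %s", size, start)
  graph$vertex_names[sort(sel)]
}

#' Two-class graph signals with a planted discriminative module
#'
#' Baseline signals are folded normal, \eqn{|N(\mu_0, \sigma)|} i.i.d. per
#' vertex (non-negative, emulating min-shifted expression values); class-1
#' samples additionally receive \eqn{+\delta} on every planted vertex.  The
#' planted set induces a connected subgraph (grown by BFS when not supplied).
#'
#' @param graph a \code{gsc_graph}.
#' @param n_per_class samples per class.
#' @param module_size planted module size (ignored if \code{planted} given).
#' @param planted optional character vector of planted vertex names (must
#'   induce a connected subgraph).
#' @param delta additive class effect on planted vertices (> 0; default 2).
#' @param sigma baseline noise sd (> 0; default 1).
#' @param mu0 baseline mean before folding (default 2).
#' @param seed RNG seed.
#' @return list with \code{dataset} (a \code{gsc_dataset}; class 0 samples
#'   first) and \code{truth} (planted vertex names, delta, sigma, mu0, seed).
#' @export
plant_class_signals <- function(graph, n_per_class, module_size = 50,
                                planted = NULL, delta = 2, sigma = 1,
                                mu0 = 2, seed = 1L) {
  stopifnot(delta > 0, sigma > 0, n_per_class >= 1)
  set.seed(as.integer(seed))
  m <- graph_order(graph)
  if (is.null(planted)) {
    planted <- bfs_module(graph, module_size)
  } else {
    if (!all(planted %in% graph$vertex_names)) stopf("planted set not in graph")
    sub <- induced_subgraph_gsc(graph, planted)
    if (max(connected_components(sub$adjacency)) != 1L)
      stopf("planted set must induce a connected subgraph")
  }
  n <- 2L * n_per_class
  X <- abs(matrix(rnorm(n * m, mu0, sigma), n, m))
  y <- rep(c(0L, 1L), each = n_per_class)
  pid <- match(planted, graph$vertex_names)
  X[y == 1L, pid] <- X[y == 1L, pid] + delta
  colnames(X) <- graph$vertex_names
  rownames(X) <- sprintf("s%03d", seq_len(n))
  ds <- graph_signal_dataset(X, y, graph)
  list(dataset = ds,
       truth = list(planted = planted, delta = delta, sigma = sigma,
                    mu0 = mu0, seed = as.integer(seed)))
}

#' Image-like two-class bar patterns on a pixel grid
#'
#' Class 0 samples contain a horizontal bar, class 1 a vertical bar
#' (full-length, \code{thickness} pixels wide, uniformly random position),
#' with amplitude \code{amplitude} plus i.i.d. folded-normal background noise
#' \eqn{|N(0, noise)|} on every pixel.  The per-sample bar pixel mask is
#' retained as ground truth.
#'
#' @param height,width grid size (>= 8 each).
#' @param n_per_class samples per class.
#' @param noise background noise sd (default 0.1; amplitude is 1, i.e. a
#'   clean-background regime comparable to digit images).
#' @param amplitude bar intensity (default 1).
#' @param thickness bar thickness in pixels (default 2).
#' @param seed RNG seed.
#' @return list with \code{dataset} (a \code{gsc_dataset} on
#'   \code{\link{grid_knn_graph}}; class 0 first) and \code{truth} (list of
#'   per-sample logical masks over vertices, plus the parameters).
#' @export
make_grid_patterns <- function(height, width, n_per_class, noise = 0.1,
                               amplitude = 1, thickness = 2, seed = 1L) {
  stopifnot(height >= 8, width >= 8, n_per_class >= 1)
  set.seed(as.integer(seed))
  g <- grid_knn_graph(height, width)
  m <- height * width
  n <- 2L * n_per_class
  X <- abs(matrix(rnorm(n * m, 0, noise), n, m))
  y <- rep(c(0L, 1L), each = n_per_class)
  masks <- vector("list", n)
  pix <- function(r, c) (r - 1L) * width + c   # row-major, matches grid graph
  for (s in seq_len(n)) {
    mask <- logical(m)
    if (y[s] == 0L) {
      r0 <- sample.int(height - thickness + 1L, 1L)
      for (t in seq_len(thickness)) mask[pix(r0 + t - 1L, seq_len(width))] <- TRUE
    } else {
      c0 <- sample.int(width - thickness + 1L, 1L)
      for (t in seq_len(thickness)) mask[pix(seq_len(height), c0 + t - 1L)] <- TRUE
    }
    X[s, mask] <- X[s, mask] + amplitude
    masks[[s]] <- mask
  }
  colnames(X) <- g$vertex_names
  rownames(X) <- sprintf("s%03d", seq_len(n))
  ds <- graph_signal_dataset(X, y, g)
  list(dataset = ds,
       truth = list(masks = masks, noise = noise, amplitude = amplitude,
                    thickness = thickness, seed = as.integer(seed)))
}

#' Synthetic pathway collection with one causal set
#'
#' Generates \code{n_sets} gene sets over the graph's vertices: the first
#' ("causal") set overlaps the planted module by \code{overlap_fraction} of
#' its size, the remaining sets are uniform random draws.
#'
#' @param graph a \code{gsc_graph}.
#' @param planted planted vertex names (the ground-truth module).
#' @param n_sets number of sets (>= 2).
#' @param set_size genes per set.
#' @param overlap_fraction fraction of the causal set drawn from the planted
#'   module (in [0, 1]).
#' @param seed RNG seed.
#' @return a \code{gene_set_collection}; the causal set is named
#'   \code{"causal"}, the others \code{"random01"}...
#' @export
make_pathways <- function(graph, planted, n_sets, set_size,
                          overlap_fraction = 1.0, seed = 1L) {
  stopifnot(n_sets >= 2, set_size >= 1, overlap_fraction >= 0,
            overlap_fraction <= 1)
  set.seed(as.integer(seed))
  verts <- graph$vertex_names
  others <- setdiff(verts, planted)
  k_in <- round(overlap_fraction * set_size)
  if (k_in > length(planted))
    stopf("overlap infeasible: need %d planted genes, module has %d",
          k_in, length(planted))
  if (set_size - k_in > length(others))
    stopf("overlap infeasible: not enough non-planted genes")
  causal <- c(sample(planted, k_in),
              if (set_size > k_in) sample(others, set_size - k_in))
  sets <- c(list(causal = sort(causal)),
            lapply(seq_len(n_sets - 1L), function(i)
              sort(sample(verts, min(set_size, length(verts))))))
  names(sets) <- c("causal", sprintf("random%02d", seq_len(n_sets - 1L)))
  class(sets) <- "gene_set_collection"
  attr(sets, "descriptions") <- rep("synthetic", n_sets)
  sets
}
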