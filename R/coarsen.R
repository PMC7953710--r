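# Multilevel graph coarsening for pooling.
#
# Max pooling of size 2 on a graph requires pairing vertices.  Each level is
# built by greedy heavy-edge matching (Graclus-style, score w_uv(1/d_u+1/d_v));
# unmatched vertices become singleton clusters.  A permutation is then
# computed, inserting edgeless "fake" vertices, so that every coarse vertex
# corresponds to a contiguous pair of fine positions and pooling reduces to a
# 1-D pairwise max.  Fake vertices carry zero signal, so they never win a max
# against a real non-negative activation.

#' Coarsen a graph for hierarchical pooling
#'
#' @param graph a \code{gsc_graph}.
#' @param levels number of coarsening levels (>= 0); each level supports one
#'   pooling of size 2.
#' @param seed integer seed controlling the vertex visiting order of the
#'   matching; the result is deterministic given the seed.
#' @return object of class \code{gsc_hierarchy}: \code{graphs} (length
#'   \code{levels + 1}, finest first), \code{parents} (per level, fine vertex
#'   -> coarse vertex index), \code{perms} (per level, padded position -> fine
#'   vertex id; ids greater than the level's vertex count are fake), and
#'   \code{m_real} (true vertex counts per level).
#' @export
coarsen_graph <- function(graph, levels, seed = 1L) {
  stopifnot(is_count(levels), levels >= 0)
  graphs <- list(graph)
  parents <- list()
  if (levels > 0) {
    set.seed(as.integer(seed))
    for (l in seq_len(levels)) {
      g <- graphs[[l]]
      mt <- heavy_edge_matching(g)
      parents[[l]] <- mt$parent
      graphs[[l + 1L]] <- coarse_graph(g, mt$parent, mt$n_coarse, l)
    }
  }
  m_real <- vapply(graphs, graph_order, integer(1))
  perms <- vector("list", levels + 1L)
  perms[[levels + 1L]] <- seq_len(m_real[levels + 1L])
  if (levels > 0) {
    for (l in rev(seq_len(levels))) {
      children <- split(seq_len(m_real[l]), parents[[l]])
      next_fake <- m_real[l]
      p_fine <- integer(0)
      for (cc in perms[[l + 1L]]) {
        if (cc <= m_real[l + 1L]) {
          ch <- children[[as.character(cc)]]
          if (length(ch) == 1L) {
            next_fake <- next_fake + 1L
            ch <- c(ch, next_fake)
          }
        } else {
          ch <- c(next_fake + 1L, next_fake + 2L)
          next_fake <- next_fake + 2L
        }
        p_fine <- c(p_fine, ch)
      }
      perms[[l]] <- p_fine
    }
  }
  structure(list(graphs = graphs, parents = parents, perms = perms,
                 m_real = m_real, levels = levels, seed = as.integer(seed)),
            class = "gsc_hierarchy")
}

# Greedy heavy-edge matching with a seeded random visiting order.
heavy_edge_matching <- function(graph) {
  A <- graph$adjacency
  m <- graph_order(graph)
  d <- graph$degrees
  ord <- sample.int(m)
  parent <- integer(m)
  nxt <- 0L
  Ap <- methods::as(A, "CsparseMatrix")
  for (v in ord) {
    if (parent[v] > 0L) next
    nxt <- nxt + 1L
    parent[v] <- nxt
    p0 <- Ap@p[v]; p1 <- Ap@p[v + 1L]
    if (p1 > p0) {
      nb <- Ap@i[(p0 + 1L):p1] + 1L
      wt <- Ap@x[(p0 + 1L):p1]
      free <- parent[nb] == 0L
      if (any(free)) {
        nb <- nb[free]; wt <- wt[free]
        score <- wt * (1 / max(d[v], 1e-12) + 1 / pmax(d[nb], 1e-12))
        best <- nb[order(-score, nb)][1]   # tie -> smallest index
        parent[best] <- nxt
      }
    }
  }
  list(parent = parent, n_coarse = nxt)
}

coarse_graph <- function(graph, parent, n_coarse, level) {
  m <- graph_order(graph)
  S <- Matrix::sparseMatrix(i = seq_len(m), j = parent, x = 1,
                            dims = c(m, n_coarse))
  Ac <- Matrix::t(S) %*% graph$adjacency %*% S
  Ac <- methods::as(methods::as(Ac, "generalMatrix"), "CsparseMatrix")
  Matrix::diag(Ac) <- 0
  Ac <- Matrix::drop0(Ac)
  graph_from_adjacency(Ac, sprintf("c%d_%d", level, seq_len(n_coarse)))
}

#' Padded, permuted graph at a hierarchy level
#'
#' Returns the level-\code{level} graph with vertices reordered by the pooling
#' permutation and fake (edgeless) vertices inserted, plus the mask of real
#' positions.  This is the operand graph of the convolution layer sitting at
#' that level.
#'
#' @param hierarchy a \code{gsc_hierarchy}.
#' @param level 0-based level index (0 = finest).
#' @return list with \code{graph} (padded \code{gsc_graph}), \code{real_mask}
#'   (logical, padded positions holding real vertices) and \code{fine_index}
#'   (for real positions, the vertex index in the unpadded level graph).
#' @export
hierarchy_padded_graph <- function(hierarchy, level) {
  l <- level + 1L
  perm <- hierarchy$perms[[l]]
  m_real <- hierarchy$m_real[l]
  mp <- length(perm)
  real <- perm <= m_real
  g <- hierarchy$graphs[[l]]
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(mp, mp))
  pos <- which(real)
  A[pos, pos] <- g$adjacency[perm[pos], perm[pos], drop = FALSE]
  nm <- character(mp)
  nm[pos] <- g$vertex_names[perm[pos]]
  nm[!real] <- sprintf("..fake%d_%d", level, which(!real))
  pg <- graph_from_adjacency(A, nm)
  list(graph = pg, real_mask = real, fine_index = ifelse(real, perm, NA_integer_))
}

#' Pad and permute sample signals for a hierarchy
#'
#' @param X samples x vertices matrix aligned to the finest graph.
#' @param hierarchy a \code{gsc_hierarchy} built on that graph.
#' @return samples x padded-vertices matrix: column \code{p} holds the signal
#'   of fine vertex \code{perms[[1]][p]}, or 0 for fake positions.
#' @export
pad_signals <- function(X, hierarchy) {
  perm <- hierarchy$perms[[1L]]
  m_real <- hierarchy$m_real[1L]
  Xp <- matrix(0, nrow(X), length(perm))
  real <- perm <= m_real
  Xp[, real] <- X[, perm[real], drop = FALSE]
  rownames(Xp) <- rownames(X)
  Xp
}

#' Map padded-position values back to finest-graph vertices
#'
#' @param v numeric vector over padded positions (length of \code{perms[[1]]}).
#' @param hierarchy a \code{gsc_hierarchy}.
#' @return numeric vector over the original vertices (fake positions dropped).
#' @export
unpad_signal <- function(v, hierarchy) {
  perm <- hierarchy$perms[[1L]]
  m_real <- hierarchy$m_real[1L]
  out <- numeric(m_real)
  real <- perm <= m_real
  out[perm[real]] <- v[real]
  out
}
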