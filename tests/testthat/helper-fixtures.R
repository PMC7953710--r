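# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# Random weighted undirected graph (Erdos-Renyi style), connected not
# guaranteed.
random_graph <- function(m, p = 0.3, seed = NULL, names = paste0("v", seq_len(m))) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(m * m) < p, m, m) * matrix(runif(m * m), m, m)
  A[lower.tri(A, diag = TRUE)] <- 0
  A <- A + t(A)
  graph_from_adjacency(A, names)
}

# Random connected graph: random graph plus a spanning path.
random_connected_graph <- function(m, p = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- random_graph(m, p)
  A <- as.matrix(g$adjacency)
  for (i in seq_len(m - 1)) if (A[i, i + 1] == 0) A[i, i + 1] <- A[i + 1, i] <- runif(1, 0.5, 1)
  graph_from_adjacency(A, g$vertex_names)
}

# Spectral (dense eigendecomposition) oracle for Chebyshev filtering:
# y = U h_theta(Lambda~) U^T x.
spectral_filter_oracle <- function(lap, x, theta) {
  eig <- eigen(as.matrix(lap$L_rescaled), symmetric = TRUE)
  lam <- pmin(pmax(eig$values, -1), 1)
  h <- rowSums(vapply(seq_along(theta) - 1, function(k)
    theta[k + 1] * cos(k * acos(lam)), numeric(length(lam))))
  as.numeric(eig$vectors %*% (h * crossprod(eig$vectors, x)))
}

# Small non-negative dataset on a given graph with both classes.
tiny_dataset <- function(graph, n = 8, seed = 1) {
  set.seed(seed)
  m <- graph_order(graph)
  X <- abs(matrix(rnorm(n * m, 1, 0.5), n, m))
  colnames(X) <- graph$vertex_names
  y <- rep_len(c(0L, 1L), n)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + 2   # separable signal on two vertices
  graph_signal_dataset(X, y, graph)
}

# A small trained model reused by glrp/subnet tests (cheap: few epochs).
tiny_trained_model <- function(seed = 3, with_pool = TRUE, bias_free = FALSE) {
  g <- random_connected_graph(14, 0.25, seed = seed)
  ds <- tiny_dataset(g, n = 10, seed = seed)
  spec <- if (with_pool)
    model_spec(layer_gconv(6, 4), layer_pool(2), layer_dense(16), layer_output(2))
  else
    model_spec(layer_gconv(6, 4), layer_dense(16), layer_output(2))
  hy <- chebnet_hyperparams(epochs = 120, batch_size = 10, learning_rate = 0.1,
                            decay = 0.99)
  m <- train_chebnet(spec, ds, hy, seed = seed)
  if (bias_free)
    for (li in seq_along(m$layers))
      if (!is.null(m$layers[[li]]$bias)) m$layers[[li]]$bias[] <- 0
  list(model = m, dataset = ds, graph = g)
}

# Direct hypergeometric tail-sum oracle for the one-sided Fisher test,
# computed from binomial coefficients on the log scale.
hypergeom_tail_oracle <- function(hits, set_size, pathway_size, N) {
  xs <- hits:min(set_size, pathway_size)
  if (hits > min(set_size, pathway_size)) return(0)
  sum(exp(lchoose(pathway_size, xs) + lchoose(N - pathway_size, set_size - xs) -
            lchoose(N, set_size)))
}

# z+ LRP on an explicit dense layer (independent of the package's lrp_dense):
# slow, index-wise reference implementation.
dense_zplus_oracle <- function(r_out, a_in, w, eps = 1e-10) {
  r_in <- numeric(length(a_in))
  for (j in seq_along(r_out)) {
    z <- pmax(w[j, ], 0) * a_in
    denom <- sum(z) + eps
    r_in <- r_in + z / denom * r_out[j]
  }
  r_in
}
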