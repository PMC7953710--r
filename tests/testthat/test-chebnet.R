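# Chebyshev filtering, convolution layers, coarsening, pooling, training.

test_that("cheb_filter matches trivial filters and the spectral oracle", {
  g <- random_connected_graph(12, 0.35, seed = 1)
  lap <- build_laplacians(g)
  x <- rnorm(12)
  expect_equal(cheb_filter(x, lap, c(1, 0, 0)), x)
  expect_equal(cheb_filter(x, lap, c(0, 1, 0)),
               as.numeric(lap$L_rescaled %*% x))
  for (s in 1:3) {
    set.seed(200 + s)
    theta <- rnorm(5)
    x <- rnorm(12)
    expect_lt(max(abs(cheb_filter(x, lap, theta) -
                        spectral_filter_oracle(lap, x, theta))), 1e-8)
  }
  expect_error(cheb_filter(rnorm(5), lap, c(1, 0)), "length")
})

test_that("locality: a K=2 filter only reaches the 1-hop neighbourhood", {
  g <- random_connected_graph(15, 0.15, seed = 8)
  lap <- build_laplacians(g)
  v <- 6L
  x <- numeric(15); x[v] <- 1
  y <- cheb_filter(x, lap, c(0.3, 0.7))
  nb <- which(as.matrix(g$adjacency)[v, ] > 0)
  outside <- setdiff(which(abs(y) > 1e-12), c(v, nb))
  expect_length(outside, 0)
})

test_that("graph_conv_forward reduces to cheb_filter and is positively linear", {
  g <- random_connected_graph(10, 0.3, seed = 2)
  lap <- build_laplacians(g)
  theta <- rnorm(4)
  bank1 <- cheb_coeff_bank(theta, bias = 0.5)
  x <- abs(rnorm(10))
  fw <- graph_conv_forward(matrix(x), lap, bank1)
  expect_equal(fw$pre[, 1], cheb_filter(x, lap, theta) + 0.5)
  expect_equal(fw$post, pmax(fw$pre, 0))

  # zero input -> ReLU(bias)
  bank2 <- cheb_coeff_bank(array(rnorm(4 * 2 * 3), c(4, 2, 3)),
                           bias = c(-1, 0.2, 2))
  fw0 <- graph_conv_forward(matrix(0, 10, 2), lap, bank2)
  expect_equal(fw0$post[1, ], c(0, 0.2, 2))

  # bias-free positive homogeneity: f(a x) = a f(x)
  bank0 <- cheb_coeff_bank(array(rnorm(4 * 2 * 3), c(4, 2, 3)))
  feats <- abs(matrix(rnorm(20), 10, 2))
  f1 <- graph_conv_forward(feats, lap, bank0)$post
  f3 <- graph_conv_forward(3 * feats, lap, bank0)$post
  expect_equal(f3, 3 * f1, tolerance = 1e-12)

  expect_error(graph_conv_forward(matrix(1, 10, 3), lap, bank2), "channels")
})

test_that("coarsening builds a valid hierarchy", {
  g <- random_connected_graph(11, 0.3, seed = 5)
  h0 <- coarsen_graph(g, 0)
  expect_equal(h0$perms[[1]], 1:11)          # identity hierarchy

  # path a-b-c: one level -> 2 coarse vertices, 1 fake fine vertex appended
  p <- graph_from_edges(data.frame(source = c("a", "b"), target = c("b", "c")))
  h1 <- coarsen_graph(p, 1, seed = 1)
  expect_equal(h1$m_real, c(3L, 2L))
  expect_equal(length(h1$perms[[1]]), 4L)    # 2 coarse x pair
  expect_equal(sum(h1$perms[[1]] > 3), 1L)   # exactly one fake
  expect_setequal(h1$perms[[1]][h1$perms[[1]] <= 3], 1:3)

  # parent maps are total on real vertices; determinism per seed
  h2 <- coarsen_graph(g, 2, seed = 9)
  for (l in 1:2) {
    expect_true(all(h2$parents[[l]] >= 1))
    expect_length(h2$parents[[l]], h2$m_real[l])
  }
  h2b <- coarsen_graph(g, 2, seed = 9)
  expect_identical(h2$perms, h2b$perms)

  # padded graph: fake vertices are edgeless, real block preserved
  pg <- hierarchy_padded_graph(h2, 0)
  expect_true(all(pg$graph$degrees[!pg$real_mask] == 0))
  expect_equal(sum(pg$real_mask), 11L)
  # pooling pairs share a parent: consecutive real pairs at level 0
  perm <- h2$perms[[1]]
  for (t in seq_len(length(perm) / 2)) {
    pair <- perm[c(2 * t - 1, 2 * t)]
    real <- pair[pair <= h2$m_real[1]]
    if (length(real) == 2)
      expect_equal(h2$parents[[1]][real[1]], h2$parents[[1]][real[2]])
  }
})

test_that("max pooling and unpooling behave as specified", {
  mp <- max_pool(c(3, 1, 0, 5))
  expect_equal(mp$pooled, c(3, 5))
  expect_equal(mp$argmax_first, c(TRUE, FALSE))

  # tie -> first index wins
  mpt <- max_pool(c(2, 2))
  expect_true(mpt$argmax_first[1])

  expect_error(max_pool(c(1, 2, 3)), "odd")

  # brute force on random input, and scatter conserves the maxima
  set.seed(31)
  x <- matrix(rnorm(48), 12, 4)
  mp2 <- max_pool(x)
  for (t in 1:6) for (j in 1:4)
    expect_equal(mp2$pooled[t, j], max(x[2 * t - 1, j], x[2 * t, j]))
  up <- glrpnet:::max_unpool(mp2$pooled, mp2$argmax_first)
  expect_equal(apply(up, 2, function(col) col[col != 0]),
               apply(mp2$pooled, 2, identity), ignore_attr = TRUE)
  expect_equal(colSums(up), colSums(mp2$pooled))
})

test_that("training gradients match finite differences", {
  g <- random_connected_graph(10, 0.4, seed = 6)
  ds <- tiny_dataset(g, n = 6, seed = 6)
  spec <- model_spec(layer_gconv(3, 4), layer_pool(2), layer_dense(5),
                     layer_output(2))
  m <- train_chebnet(spec, ds, chebnet_hyperparams(epochs = 1, batch_size = 6,
                                                   learning_rate = 0),
                     seed = 7)
  Xp <- glrpnet:::pad_signals(ds$X, m$hierarchy)
  lossfun <- function(mm) {
    P <- glrpnet:::softmax_cols(glrpnet:::chebnet_forward(mm, Xp)$logits)
    -mean(log(P[cbind(ds$y + 1, seq_along(ds$y))]))
  }
  fw <- glrpnet:::chebnet_forward(m, Xp, keep_cache = TRUE)
  grads <- glrpnet:::chebnet_backward(m, fw, ds$y)
  h <- 1e-6
  # spot-check every parameter family
  for (li in c(1, 3, 4)) {
    field <- if (m$layers[[li]]$type == "gconv") "theta" else "W"
    v <- m$layers[[li]][[field]]
    idx <- sample(length(v), min(8, length(v)))
    for (i in idx) {
      ma <- m; ma$layers[[li]][[field]][i] <- v[i] + h
      mb <- m; mb$layers[[li]][[field]][i] <- v[i] - h
      gnum <- (lossfun(ma) - lossfun(mb)) / (2 * h)
      expect_equal(grads[[li]][[field]][i], gnum, tolerance = 1e-4)
    }
  }
})

test_that("training solves a separable toy problem deterministically", {
  g <- random_connected_graph(8, 0.4, seed = 10)
  ds <- tiny_dataset(g, n = 12, seed = 10)
  spec <- model_spec(layer_gconv(6, 3), layer_dense(8), layer_output(2))
  hy <- chebnet_hyperparams(epochs = 60, batch_size = 12, learning_rate = 0.1)
  m <- train_chebnet(spec, ds, hy, seed = 11)
  expect_equal(mean(predict(m, ds$X, type = "class") == ds$y), 1.0)
  expect_lt(tail(m$loss_log, 1), 0.3)

  # bit-reproducible given the seed
  m2 <- train_chebnet(spec, ds, hy, seed = 11)
  expect_identical(m$loss_log, m2$loss_log)
  expect_identical(m$layers[[1]]$theta, m2$layers[[1]]$theta)

  # both classes required
  ds0 <- graph_signal_dataset(ds$X[ds$y == 0, ], rep(0L, sum(ds$y == 0)),
                              g, ds$sample_ids[ds$y == 0])
  expect_error(train_chebnet(spec, ds0, hy), "both classes")
})

test_that("classification metrics match a hand confusion-matrix oracle", {
  y <- c(0, 0, 0, 1, 1, 0, 1, 0)
  sc <- c(0.1, 0.8, 0.3, 0.9, 0.4, 0.2, 0.7, 0.6)
  met <- classification_metrics(y, sc)
  # hand: pred = (0,1,0,1,0,0,1,1); TP1=2 FP1=2 FN1=1; TP0=3 FP0=1 FN0=2
  expect_equal(unname(met["accuracy"]), 5 / 8)
  f1_1 <- 2 * 2 / (2 * 2 + 2 + 1)
  f1_0 <- 2 * 3 / (2 * 3 + 1 + 2)
  expect_equal(unname(met["f1_weighted"]), (5 / 8) * f1_0 + (3 / 8) * f1_1)
  # AUC by pair counting
  pos <- sc[y == 1]; neg <- sc[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(unname(met["auc"]), mean(pairs))
  # perfect scores
  expect_equal(unname(classification_metrics(y, y)["auc"]), 1)
})

test_that("cross_validate stratifies and aggregates", {
  g <- random_connected_graph(8, 0.4, seed = 14)
  ds <- tiny_dataset(g, n = 16, seed = 14)
  spec <- model_spec(layer_gconv(6, 3), layer_dense(8), layer_output(2))
  hy <- chebnet_hyperparams(epochs = 40, batch_size = 16, learning_rate = 0.1)
  cv <- cross_validate(spec, ds, folds = 4, hyper = hy, seed = 2)
  expect_equal(nrow(cv$per_fold), 4L)
  expect_equal(cv$summary$metric, c("auc", "accuracy", "f1_weighted"))
  expect_equal(cv$summary$sem,
               vapply(cv$summary$metric,
                      function(m) sd(cv$per_fold[[m]]) / 2, numeric(1)),
               ignore_attr = TRUE)
  # separable data: good mean AUC
  expect_gt(cv$summary$mean[1], 0.9)
  # stratification error when a fold cannot hold both classes
  yk <- c(rep(0L, 9), 1L)
  expect_error(stratified_folds(yk, folds = 5), "single class")
})
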