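# Graph construction, Laplacians, grid graphs, expression I/O, preprocessing.

test_that("read_network parses edge lists, collapses duplicates, drops loops", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "a\tb", "b\tc"), tf)
  g <- read_network(tf)
  expect_equal(g$vertex_names, c("a", "b", "c"))
  expect_equal(graph_size(g), 2L)
  expect_equal(unname(g$degrees), c(1, 2, 1))

  writeLines(c("source\ttarget\tweight", "a\tb\t1.0", "b\ta\t2.0", "a\ta\t1.0"), tf)
  expect_warning(g2 <- read_network(tf), "self-loop")
  expect_equal(graph_size(g2), 1L)
  expect_equal(g2$adjacency["a", "b"], 2.0)   # max-weight collapse

  writeLines(c("source\ttarget\tweight", "a\tb\t1.0", "b\tc"), tf)
  expect_error(read_network(tf), "line 3")
  writeLines(c("source\ttarget\tweight", "a\tb\t-1"), tf)
  expect_error(read_network(tf), "negative")
})

test_that("GraphML round trip preserves structure and weights", {
  g <- random_connected_graph(9, 0.3, seed = 21)
  tf <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, tf, "graphml")
  g2 <- read_network(tf)
  expect_equal(sort(g2$vertex_names), sort(g$vertex_names))
  idx <- match(g$vertex_names, g2$vertex_names)
  expect_equal(as.matrix(g2$adjacency)[idx, idx], as.matrix(g$adjacency),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("largest_connected_component picks the main component", {
  # components of size 5 (path) and 2
  e <- data.frame(source = c("a", "b", "c", "d", "x"),
                  target = c("b", "c", "d", "e", "y"))
  g <- graph_from_edges(e)
  lcc <- largest_connected_component(g)
  expect_equal(sort(lcc$graph$vertex_names), c("a", "b", "c", "d", "e"))
  expect_true(all(is.na(lcc$index_map[match(c("x", "y"), g$vertex_names)])))

  # identity on a connected graph, and idempotence
  gc <- random_connected_graph(8, 0.3, seed = 4)
  lcc2 <- largest_connected_component(gc)
  expect_equal(lcc2$index_map, seq_len(8))
  lcc3 <- largest_connected_component(lcc2$graph)
  expect_equal(lcc3$graph$adjacency, lcc2$graph$adjacency)
})

test_that("largest component size matches an independent flood-fill oracle", {
  # many components emulated: disjoint random blocks of varying size
  set.seed(77)
  sizes <- c(40, 25, 12, 7, 3, 3, 1, 1)
  blocks <- lapply(seq_along(sizes), function(i) {
    m <- sizes[i]
    if (m == 1) return(matrix(0, 1, 1))
    as.matrix(random_connected_graph(m, 0.3)$adjacency)
  })
  A <- Matrix::bdiag(blocks)
  nm <- paste0("n", seq_len(sum(sizes)))
  g <- graph_from_adjacency(A, nm)
  # flood-fill oracle on the dense adjacency
  Ad <- as.matrix(A) > 0
  seen <- logical(nrow(Ad)); comp_sizes <- integer(0)
  for (s in seq_len(nrow(Ad))) {
    if (seen[s]) next
    q <- s; members <- s; seen[s] <- TRUE
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(Ad[v, ] & !seen)
      seen[nb] <- TRUE; members <- c(members, nb); q <- c(q, nb)
    }
    comp_sizes <- c(comp_sizes, length(members))
  }
  lcc <- largest_connected_component(g)
  expect_equal(graph_order(lcc$graph), max(comp_sizes))
})

test_that("build_laplacians matches closed forms and the dense eigen oracle", {
  # K2: single unit edge
  g <- graph_from_edges(data.frame(source = "a", target = "b"))
  lap <- build_laplacians(g)
  expect_equal(as.matrix(lap$L), matrix(c(1, -1, -1, 1), 2),
               ignore_attr = TRUE)
  expect_equal(lap$lambda_max, 2, tolerance = 1e-6)
  # L/lambda_max - I for K2: all entries -1/2, spectrum {-1, 0}
  expect_equal(as.matrix(lap$L_rescaled), matrix(-0.5, 2, 2),
               tolerance = 1e-6, ignore_attr = TRUE)

  # edgeless graph: degenerate lambda_max guard
  g0 <- graph_from_adjacency(matrix(0, 3, 3), c("a", "b", "c"))
  expect_error(build_laplacians(g0), "degenerate")

  # random graphs: lambda_max vs dense eigensolver, row sums, spectrum bounds
  for (s in 1:5) {
    g <- random_connected_graph(12, 0.35, seed = 100 + s)
    lap <- build_laplacians(g)
    ev <- eigen(as.matrix(lap$L), symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(lap$lambda_max - max(ev)), 1e-6)
    expect_lt(max(abs(Matrix::rowSums(lap$L))), 1e-10)
    evr <- eigen(as.matrix(lap$L_rescaled), symmetric = TRUE,
                 only.values = TRUE)$values
    expect_true(all(evr <= 1 + 1e-6) && all(evr >= -1 - 1e-6))
  }
})

test_that("grid_knn_graph builds the Moore-neighbourhood graph", {
  g3 <- grid_knn_graph(3, 3)
  expect_equal(unname(g3$degrees[5]), 8)           # centre pixel
  expect_equal(unname(g3$degrees[1]), 3)           # corner
  g2 <- grid_knn_graph(2, 2)
  expect_equal(graph_size(g2), 6L)                 # K4
  expect_error(grid_knn_graph(3, 3, k = 4), "k = 8")

  # edge count formula 4hw - 3(h+w) + 2 vs brute-force pairwise scan
  h <- 28; w <- 28
  gg <- grid_knn_graph(h, w)
  expect_equal(graph_size(gg), 4 * h * w - 3 * (h + w) + 2)
  # brute force on a smaller grid (pairwise Chebyshev distance 1)
  h <- 6; w <- 5
  gs <- grid_knn_graph(h, w)
  coords <- expand.grid(c = seq_len(w), r = seq_len(h))
  cnt <- 0L
  for (i in seq_len(h * w - 1)) for (j in (i + 1):(h * w)) {
    if (max(abs(coords$r[i] - coords$r[j]), abs(coords$c[i] - coords$c[j])) == 1)
      cnt <- cnt + 1L
  }
  expect_equal(graph_size(gs), cnt)
})

test_that("read_expression handles duplicates and orientation", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "s1\t1\t4", "s2\t2\t5", "s3\t3\t6"), tf)
  X <- read_expression(tf)
  expect_equal(dim(X), c(3L, 2L))
  expect_equal(X["s2", "g2"], 5)

  # duplicate gene columns: highest mean kept
  writeLines(c("id\tg1\tg1", "s1\t1\t4", "s2\t3\t6"), tf)
  Xd <- read_expression(tf)
  expect_equal(ncol(Xd), 1L)
  expect_equal(unname(Xd[, "g1"]), c(4, 6))

  # transposed file with genes_as_rows gives the same matrix
  writeLines(c("gene\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t4\t5\t6"), tf)
  Xt <- read_expression(tf, genes_as_rows = TRUE)
  expect_equal(Xt, X)

  writeLines(c("id\tg1", "s1\tNaNopsis"), tf)
  expect_error(read_expression(tf), "non-numeric")
})

test_that("quantile_normalize maps rows onto the mean order-statistic reference", {
  # hand example: rows (1,2,3) and (4,5,6) -> both (2.5,3.5,4.5)
  X <- rbind(c(1, 2, 3), c(4, 5, 6))
  Q <- quantile_normalize(X)
  expect_equal(Q[1, ], c(2.5, 3.5, 4.5))
  expect_equal(Q[2, ], c(2.5, 3.5, 4.5))

  # identical rows unchanged; rank order preserved; shared sorted vector
  set.seed(9)
  X2 <- matrix(rexp(60), 5, 12)
  Q2 <- quantile_normalize(X2)
  for (s in 1:5) expect_equal(rank(Q2[s, ]), rank(X2[s, ]))
  sorted <- apply(Q2, 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  Xsame <- rbind(c(2, 7, 4), c(2, 7, 4))
  expect_equal(quantile_normalize(Xsame), Xsame)

  expect_warning(quantile_normalize(matrix(1:3, 1)), "single sample")

  # independent oracle: limma's quantile normalization (columns = samples)
  skip_if_not_installed("limma")
  Q_limma <- t(limma::normalizeQuantiles(t(X2), ties = TRUE))
  expect_equal(unname(Q2), unname(Q_limma), tolerance = 1e-12)

  # fit/apply split: held-out row mapped onto the training reference
  ref <- quantile_reference(X2)
  held <- matrix(rexp(12), 1)
  Qh <- quantile_normalize(held, reference = ref)
  expect_equal(sort(Qh[1, ]), sort(ref))
})

test_that("shift_nonnegative subtracts the global minimum", {
  # the documented microarray case: [5.84847, 14.2014] -> [0, 8.3529]
  X <- matrix(c(5.84847, 10, 14.2014, 7), 2)
  sh <- shift_nonnegative(X)
  expect_equal(min(sh$X_shifted), 0)
  expect_equal(round(max(sh$X_shifted), 4), 8.3529)
  expect_equal(sh$shift_value, 5.84847)

  Z <- matrix(0, 2, 2)
  expect_equal(shift_nonnegative(Z)$X_shifted, Z)
  expect_equal(shift_nonnegative(Z)$shift_value, 0)

  # translation invariance
  expect_equal(shift_nonnegative(X + 3.7)$X_shifted, sh$X_shifted)
})

test_that("align_dataset restricts to mapped genes in graph order", {
  g <- graph_from_edges(data.frame(source = c("g1", "g2", "g2"),
                                   target = c("g2", "g3", "g1")))
  X <- matrix(abs(rnorm(10)), 2, 5,
              dimnames = list(c("s1", "s2"), c("g9", "g3", "g1", "g8", "g2")))
  suppressMessages(ds <- align_dataset(X, g, c(0, 1)))
  expect_equal(colnames(ds$X), ds$graph$vertex_names)
  expect_equal(ncol(ds$X), 3L)
  expect_equal(ds$X[, "g3"], X[, "g3"])

  # column order invariance
  suppressMessages(ds2 <- align_dataset(X[, sample(5)], g, c(0, 1)))
  expect_equal(ds2$X, ds$X)

  # mapped count equals set-intersection oracle on a larger synthetic case
  set.seed(42)
  big <- make_scale_free_graph(150, seed = 13)
  genes <- c(sample(big$vertex_names, 120), paste0("x", 1:80))
  Xb <- matrix(abs(rnorm(3 * 200)), 3, 200,
               dimnames = list(paste0("s", 1:3), genes))
  suppressMessages(dsb <- align_dataset(Xb, big, c(0, 1, 0)))
  mapped <- intersect(genes, big$vertex_names)
  expect_true(all(dsb$graph$vertex_names %in% mapped))

  expect_error(suppressMessages(
    align_dataset(matrix(1, 1, 1, dimnames = list("s", "zz")), g, 0)),
    "no genes")
})
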