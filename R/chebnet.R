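# Chebyshev spectral graph convolutional network.
#
# A graph convolution filters each input channel with a K-term Chebyshev
# polynomial in the rescaled Laplacian,
#   y_j = sum_i sum_{k=0}^{K-1} theta_{i,j,k} T_k(L~) x_i + b_j,
# evaluated by the sparse recurrence xbar_k = 2 L~ xbar_{k-1} - xbar_{k-2}.
# The polynomial order K-1 bounds the hop-neighbourhood a filter can see.
# Training is plain momentum SGD on the softmax cross-entropy, with
# hand-derived gradients (including the adjoint of the Chebyshev recurrence).

#' Chebyshev coefficient bank
#'
#' @param theta numeric array of dim \code{(K, F_in, F_out)}; a numeric vector
#'   is treated as \code{(K, 1, 1)}.
#' @param bias numeric vector of length \code{F_out} (default zeros).
#' @return object of class \code{cheb_bank}.
#' @export
cheb_coeff_bank <- function(theta, bias = NULL) {
  if (is.null(dim(theta))) theta <- array(theta, c(length(theta), 1L, 1L))
  stopifnot(length(dim(theta)) == 3L, all(is.finite(theta)), dim(theta)[1] >= 1L)
  f_out <- dim(theta)[3]
  if (is.null(bias)) bias <- numeric(f_out)
  stopifnot(length(bias) == f_out, all(is.finite(bias)))
  structure(list(theta = theta, bias = as.numeric(bias),
                 K = dim(theta)[1], F_in = dim(theta)[2], F_out = f_out),
            class = "cheb_bank")
}

#' Apply a Chebyshev polynomial filter to one graph signal
#'
#' Computes \eqn{y = \sum_{k=0}^{K-1} \theta_k T_k(\tilde L) x} with exactly
#' \eqn{K-1} sparse matrix-vector products.
#'
#' @param x numeric signal vector (length m).
#' @param laplacian a \code{gsc_laplacian}.
#' @param theta numeric vector of K Chebyshev coefficients.
#' @return filtered signal, length m.
#' @export
cheb_filter <- function(x, laplacian, theta) {
  if (length(x) != laplacian$m) stopf("signal length %d != m = %d",
                                      length(x), laplacian$m)
  if (!all(is.finite(x))) stopf("non-finite signal")
  Tx <- cheb_basis(laplacian$L_rescaled, matrix(x, ncol = 1), length(theta))
  y <- numeric(length(x))
  for (k in seq_along(theta)) y <- y + theta[k] * Tx[[k]][, 1]
  unname(y)
}

# T_k(Lr) %*% Xmat for k = 0..K-1, as a list of dense matrices.
cheb_basis <- function(Lr, Xmat, K) {
  out <- vector("list", K)
  out[[1]] <- as.matrix(Xmat)
  if (K >= 2L) out[[2]] <- as.matrix(Lr %*% Xmat)
  if (K >= 3L) for (k in 3:K)
    out[[k]] <- as.matrix(2 * (Lr %*% out[[k - 1]]) - out[[k - 2]])
  out
}

#' Graph convolution forward pass (single sample)
#'
#' @param features m x F_in non-negative feature map.
#' @param laplacian a \code{gsc_laplacian}.
#' @param bank a \code{cheb_bank} with matching \code{F_in}.
#' @return list with \code{pre} (m x F_out pre-activation, bias included) and
#'   \code{post} (ReLU of \code{pre}); \code{pre} is retained for relevance
#'   propagation.
#' @export
graph_conv_forward <- function(features, laplacian, bank) {
  features <- as.matrix(features)
  if (ncol(features) != bank$F_in)
    stopf("feature map has %d channels, bank expects %d", ncol(features),
          bank$F_in)
  Xarr <- array(features, c(nrow(features), bank$F_in, 1L))
  fw <- gconv_forward_core(laplacian, bank$theta, bank$bias, Xarr,
                           fake_mask = NULL)
  pre <- fw$Z[, , 1, drop = TRUE]
  pre <- matrix(pre, nrow(features), bank$F_out)
  list(pre = pre, post = relu(pre))
}

# ---- batched convolution core -------------------------------------------
# Xarr: (mp, F_in, B).  Returns Z (mp, F_out, B) pre-activation and the
# cached design matrix bigM ((mp*B) x (K*F_in), columns ordered k-fast within
# input channel) used for gradients.
gconv_forward_core <- function(lap, theta, bias, Xarr, fake_mask = NULL) {
  mp <- dim(Xarr)[1]; f_in <- dim(Xarr)[2]; B <- dim(Xarr)[3]
  K <- dim(theta)[1]
  Xmat <- matrix(Xarr, mp, f_in * B)           # column i + (b-1)*F_in
  Tk <- cheb_basis(lap$L_rescaled, Xmat, K)
  bigM <- matrix(0, mp * B, K * f_in)
  bcols <- function(i) i + (seq_len(B) - 1L) * f_in
  for (i in seq_len(f_in)) for (k in seq_len(K))
    bigM[, (i - 1L) * K + k] <- Tk[[k]][, bcols(i)]
  thetaMat <- matrix(theta, K * f_in, dim(theta)[3])  # rows: k fast, i slow
  Y <- bigM %*% thetaMat
  Y <- sweep(Y, 2L, bias, "+")
  f_out <- ncol(Y)
  Z <- array(0, c(mp, f_out, B))
  for (j in seq_len(f_out)) Z[, j, ] <- matrix(Y[, j], mp, B)
  if (!is.null(fake_mask) && any(!fake_mask)) Z[!fake_mask, , ] <- 0
  list(Z = Z, bigM = bigM, thetaMat = thetaMat)
}

# Backward pass of the convolution core.  dZ: (mp, F_out, B).
gconv_backward_core <- function(lap, theta, cache, dZ, fake_mask = NULL) {
  mp <- dim(dZ)[1]; f_out <- dim(dZ)[2]; B <- dim(dZ)[3]
  K <- dim(theta)[1]; f_in <- dim(theta)[2]
  if (!is.null(fake_mask) && any(!fake_mask)) dZ[!fake_mask, , ] <- 0
  dY <- matrix(0, mp * B, f_out)
  for (j in seq_len(f_out)) dY[, j] <- dZ[, j, ]
  db <- colSums(dY)
  dThetaMat <- crossprod(cache$bigM, dY)
  dTheta <- array(dThetaMat, dim(theta))
  dbigM <- dY %*% t(cache$thetaMat)
  # gradients w.r.t. the Chebyshev basis vectors xbar_k, in Xmat layout
  G <- vector("list", K)
  bcols <- function(i) i + (seq_len(B) - 1L) * f_in
  for (k in seq_len(K)) {
    Gk <- matrix(0, mp, f_in * B)
    for (i in seq_len(f_in))
      Gk[, bcols(i)] <- matrix(dbigM[, (i - 1L) * K + k], mp, B)
    G[[k]] <- Gk
  }
  # adjoint of xbar_k = 2 L~ xbar_{k-1} - xbar_{k-2} (L~ symmetric)
  Lr <- lap$L_rescaled
  if (K >= 3L) for (k in K:3) {
    G[[k - 1]] <- G[[k - 1]] + as.matrix(2 * (Lr %*% G[[k]]))
    G[[k - 2]] <- G[[k - 2]] - G[[k]]
  }
  if (K >= 2L) G[[1]] <- G[[1]] + as.matrix(Lr %*% G[[2]])
  dXarr <- array(G[[1]], c(mp, f_in, B))
  list(dTheta = dTheta, db = db, dX = dXarr)
}

#' Pairwise max pooling over a permuted feature map
#'
#' Pools consecutive vertex pairs (the coarsening permutation guarantees that
#' pairs sharing a coarse parent are contiguous).  Ties are broken toward the
#' lower index so the argmax used by relevance propagation is deterministic.
#'
#' @param x numeric vector, matrix (vertices x channels), or 3-d array
#'   (vertices x channels x batch) with an even vertex count.
#' @return list with \code{pooled} (halved along the vertex dimension) and
#'   \code{argmax_first} (logical, same shape as \code{pooled}; TRUE when the
#'   first element of the pair won).
#' @export
max_pool <- function(x) {
  v <- if (is.null(dim(x))) length(x) else dim(x)[1]
  if (v %% 2L != 0L) stopf("internal error: odd vertex count %d in max_pool", v)
  odd <- seq(1L, v, 2L); even <- seq(2L, v, 2L)
  if (is.null(dim(x))) {
    a <- x[odd]; b <- x[even]
  } else if (length(dim(x)) == 2L) {
    a <- x[odd, , drop = FALSE]; b <- x[even, , drop = FALSE]
  } else {
    a <- x[odd, , , drop = FALSE]; b <- x[even, , , drop = FALSE]
  }
  win_first <- a >= b
  pooled <- pmax(a, b)
  list(pooled = pooled, argmax_first = win_first)
}

# Scatter pooled gradients/relevances back to the winners.
max_unpool <- function(pooled, argmax_first) {
  d <- dim(pooled)
  if (is.null(d)) {
    out <- numeric(2L * length(pooled))
    odd <- seq(1L, length(out), 2L)
    out[odd] <- ifelse(argmax_first, pooled, 0)
    out[odd + 1L] <- ifelse(argmax_first, 0, pooled)
    return(out)
  }
  d2 <- d; d2[1] <- 2L * d[1]
  out <- array(0, d2)
  odd <- seq(1L, d2[1], 2L)
  if (length(d) == 2L) {
    out[odd, ] <- ifelse(argmax_first, pooled, 0)
    out[odd + 1L, ] <- ifelse(argmax_first, 0, pooled)
  } else {
    out[odd, , ] <- ifelse(argmax_first, pooled, 0)
    out[odd + 1L, , ] <- ifelse(argmax_first, 0, pooled)
  }
  out
}

# ---- model specification --------------------------------------------------

#' Model architecture specification
#'
#' @param ... layer descriptors from \code{\link{layer_gconv}},
#'   \code{\link{layer_pool}}, \code{\link{layer_dense}},
#'   \code{\link{layer_output}}, in network order.
#' @return object of class \code{chebnet_spec}.
#' @export
model_spec <- function(...) {
  layers <- list(...)
  types <- vapply(layers, `[[`, "", "type")
  if (sum(types == "output") != 1L || types[length(types)] != "output")
    stopf("spec needs exactly one trailing output layer")
  if (layers[[length(layers)]]$units != 2L)
    stopf("output layer must have 2 units (binary classification)")
  for (l in layers[types == "pool"])
    if (log2(l$p) %% 1 != 0) stopf("pool sizes must be powers of 2")
  gc_pos <- which(types == "gconv")
  dn_pos <- which(types %in% c("dense", "output"))
  if (length(gc_pos) && length(dn_pos) && max(gc_pos) > min(dn_pos))
    stopf("graph-conv layers must precede dense layers")
  structure(list(layers = layers), class = "chebnet_spec")
}

#' @rdname model_spec
#' @param f_out number of filters (output channels).
#' @param k Chebyshev polynomial length K (covers a (K-1)-hop neighbourhood).
#' @export
layer_gconv <- function(f_out, k) {
  stopifnot(is_count(f_out), f_out >= 1, is_count(k), k >= 1)
  list(type = "gconv", f_out = as.integer(f_out), k = as.integer(k))
}

#' @rdname model_spec
#' @param p pooling size (power of 2).
#' @export
layer_pool <- function(p = 2) {
  stopifnot(is_count(p), p >= 2)
  list(type = "pool", p = as.integer(p))
}

#' @rdname model_spec
#' @param units number of hidden units.
#' @export
layer_dense <- function(units) {
  stopifnot(is_count(units), units >= 1)
  list(type = "dense", units = as.integer(units))
}

#' @rdname model_spec
#' @export
layer_output <- function(units = 2) {
  stopifnot(is_count(units))
  list(type = "output", units = as.integer(units))
}

#' Training hyperparameters
#'
#' Defaults: momentum SGD, learning rate 0.01 with multiplicative decay 0.95
#' per epoch, 100 epochs, batch size 64.
#'
#' @param learning_rate,momentum,decay,epochs,batch_size optimizer settings.
#' @param clip_norm global gradient-norm ceiling per update (default 5);
#'   oversized updates are rescaled, which keeps momentum SGD stable across
#'   layers whose gradient norms differ by orders of magnitude.  \code{Inf}
#'   disables clipping.
#' @param init_sd weight initialisation sd (truncated normal).  The default
#'   \code{NULL} uses fan-in scaling (He), \code{sd = sqrt(2 / fan_in)},
#'   which keeps activations and gradients at unit scale for wide layers; a
#'   numeric value fixes the sd for every layer instead.
#' @return a named list of class \code{chebnet_hyper}.
#' @export
chebnet_hyperparams <- function(learning_rate = 0.01, momentum = 0.9,
                                decay = 0.95, epochs = 100L, batch_size = 64L,
                                clip_norm = 5, init_sd = NULL) {
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 decay = decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 init_sd = init_sd),
            class = "chebnet_hyper")
}

# Compile a spec against a graph: build hierarchy, per-level laplacians and
# initialised parameters.  Returns the realized layer list.
compile_chebnet <- function(spec, graph, init_sd = NULL, seed = 1L) {
  init <- function(n, fan_in) {
    sdv <- if (is.null(init_sd)) sqrt(2 / fan_in) else init_sd
    rtruncnorm(n, sdv)
  }
  types <- vapply(spec$layers, `[[`, "", "type")
  levels_total <- sum(vapply(spec$layers[types == "pool"],
                             function(l) as.integer(log2(l$p)), integer(1)))
  hier <- coarsen_graph(graph, levels_total, seed)
  level <- 0L
  f_in <- 1L
  mp <- length(hier$perms[[1]])
  realized <- list()
  for (ls in spec$layers) {
    if (ls$type == "gconv") {
      pg <- hierarchy_padded_graph(hier, level)
      lap <- build_laplacians(pg$graph)
      theta <- array(init(ls$k * f_in * ls$f_out, ls$k * f_in),
                     c(ls$k, f_in, ls$f_out))
      realized[[length(realized) + 1L]] <-
        list(type = "gconv", level = level, lap = lap,
             fake_mask = pg$real_mask, theta = theta,
             bias = rep(0.01, ls$f_out), K = ls$k, F_in = f_in,
             F_out = ls$f_out, mp = mp)
      f_in <- ls$f_out
    } else if (ls$type == "pool") {
      steps <- as.integer(log2(ls$p))
      realized[[length(realized) + 1L]] <-
        list(type = "pool", steps = steps, mp_in = mp)
      mp <- mp / ls$p
      level <- level + steps
    } else {
      # input width: previous dense layer's units, else the flattened map
      prev <- if (length(realized)) realized[[length(realized)]] else NULL
      n_in <- if (!is.null(prev) && prev$type %in% c("dense", "output"))
        prev$units else mp * f_in
      W <- matrix(init(ls$units * n_in, n_in), ls$units, n_in)
      realized[[length(realized) + 1L]] <-
        list(type = ls$type, W = W, bias = rep(0.01, ls$units),
             units = ls$units, n_in = n_in)
    }
  }
  list(layers = realized, hierarchy = hier, levels = levels_total)
}

# Forward pass over a batch.  Xp: B x mp padded signal matrix.
# Returns logits (2 x B) and, if keep_cache, per-layer caches for backprop
# and relevance propagation.
chebnet_forward <- function(model, Xp, keep_cache = FALSE) {
  B <- nrow(Xp)
  cur <- array(t(Xp), c(ncol(Xp), 1L, B))      # (mp, F=1, B)
  caches <- vector("list", length(model$layers))
  flat <- NULL
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "gconv") {
      fw <- gconv_forward_core(ly$lap, ly$theta, ly$bias, cur, ly$fake_mask)
      if (keep_cache)
        caches[[li]] <- list(X = cur, Z = fw$Z, bigM = fw$bigM,
                             thetaMat = fw$thetaMat)
      cur <- relu(fw$Z)
    } else if (ly$type == "pool") {
      am <- vector("list", ly$steps)
      for (s in seq_len(ly$steps)) {
        mp_res <- max_pool(cur)
        am[[s]] <- mp_res$argmax_first
        cur <- mp_res$pooled
      }
      if (keep_cache) caches[[li]] <- list(argmax = am)
    } else {
      if (is.null(flat)) {           # flatten (mf, F, B) -> (mf*F, B)
        d <- dim(cur)
        flat <- matrix(cur, d[1] * d[2], d[3])
        flat_dim <- d
      }
      Z <- ly$W %*% flat + ly$bias
      if (keep_cache) caches[[li]] <- list(a_in = flat, Z = Z)
      flat <- if (ly$type == "dense") relu(Z) else Z
    }
  }
  logits <- flat                      # 2 x B
  list(logits = logits,
       caches = if (keep_cache) caches else NULL,
       flat_dim = if (exists("flat_dim", inherits = FALSE)) flat_dim else NULL)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Backward pass: returns list of gradients parallel to model$layers.
chebnet_backward <- function(model, fw, y) {
  B <- length(y)
  P <- softmax_cols(fw$logits)
  onehot <- matrix(0, 2L, B); onehot[cbind(y + 1L, seq_len(B))] <- 1
  dflat <- (P - onehot) / B
  grads <- vector("list", length(model$layers))
  darr <- NULL
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    ch <- fw$caches[[li]]
    if (ly$type %in% c("dense", "output")) {
      if (ly$type == "dense") dflat <- dflat * (ch$Z > 0)
      grads[[li]] <- list(W = dflat %*% t(ch$a_in), bias = rowSums(dflat))
      dflat <- t(ly$W) %*% dflat
    } else if (ly$type == "pool") {
      if (is.null(darr)) darr <- array(dflat, fw$flat_dim)
      for (s in rev(seq_len(ly$steps)))
        darr <- max_unpool(darr, ch$argmax[[s]])
    } else {
      if (is.null(darr)) darr <- array(dflat, dim(ch$Z))
      darr <- darr * (ch$Z > 0)
      bw <- gconv_backward_core(ly$lap, ly$theta, ch, darr, ly$fake_mask)
      grads[[li]] <- list(theta = bw$dTheta, bias = bw$db)
      darr <- bw$dX
    }
  }
  grads
}

#' Train a Chebyshev graph-CNN
#'
#' Minimizes softmax cross-entropy with momentum SGD.  Deterministic given
#' \code{seed} (weight initialisation, coarsening order and batch shuffling
#' all draw from the seeded RNG).
#'
#' @param spec a \code{chebnet_spec}.
#' @param dataset a \code{gsc_dataset} (both classes present).
#' @param hyper a \code{chebnet_hyperparams()} list.
#' @param seed integer seed.
#' @param verbose log loss every few epochs.
#' @return object of class \code{gsc_chebnet} holding the realized layers,
#'   coarsening hierarchy, training log (loss per epoch) and the hash of the
#'   training graph.
#' @export
train_chebnet <- function(spec, dataset, hyper = chebnet_hyperparams(),
                          seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "chebnet_spec"), inherits(dataset, "gsc_dataset"))
  if (length(unique(dataset$y)) < 2L)
    stopf("training data must contain both classes")
  set.seed(as.integer(seed))
  compiled <- compile_chebnet(spec, dataset$graph, hyper$init_sd, seed)
  model <- structure(list(layers = compiled$layers,
                          hierarchy = compiled$hierarchy,
                          spec = spec, hyper = hyper, seed = as.integer(seed),
                          graph = dataset$graph,
                          graph_hash = object_hash(list(
                            dataset$graph$vertex_names,
                            Matrix::nnzero(dataset$graph$adjacency))),
                          version = as.character(packageVersion("glrpnet"))),
                     class = "gsc_chebnet")
  Xp <- pad_signals(dataset$X, model$hierarchy)
  y <- dataset$y
  n <- nrow(Xp)
  vel <- lapply(model$layers, function(ly) {
    if (ly$type == "gconv") list(theta = array(0, dim(ly$theta)),
                                 bias = numeric(length(ly$bias)))
    else if (ly$type %in% c("dense", "output"))
      list(W = matrix(0, nrow(ly$W), ncol(ly$W)),
           bias = numeric(length(ly$bias)))
    else NULL
  })
  lr <- hyper$learning_rate
  loss_log <- numeric(hyper$epochs)
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, hyper$batch_size)) {
      idx <- ord[start:min(start + hyper$batch_size - 1L, n)]
      fw <- chebnet_forward(model, Xp[idx, , drop = FALSE], keep_cache = TRUE)
      P <- softmax_cols(fw$logits)
      loss <- -mean(log(pmax(P[cbind(y[idx] + 1L, seq_along(idx))], 1e-15)))
      if (!is.finite(loss))
        stopf("training diverged (non-finite loss) at epoch %d; lower the learning rate", ep)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      grads <- chebnet_backward(model, fw, y[idx])
      if (is.finite(hyper$clip_norm)) {
        gnorm <- sqrt(sum(vapply(grads, function(g)
          if (is.null(g)) 0 else sum(g[[1]]^2) + sum(g[[2]]^2), numeric(1))))
        if (gnorm > hyper$clip_norm) {
          sc <- hyper$clip_norm / gnorm
          grads <- lapply(grads, function(g) {
            if (!is.null(g)) for (nm in names(g)) g[[nm]] <- g[[nm]] * sc
            g
          })
        }
      }
      for (li in seq_along(model$layers)) {
        g <- grads[[li]]
        if (is.null(g)) next
        ly <- model$layers[[li]]
        if (ly$type == "gconv") {
          vel[[li]]$theta <- hyper$momentum * vel[[li]]$theta - lr * g$theta
          vel[[li]]$bias <- hyper$momentum * vel[[li]]$bias - lr * g$bias
          model$layers[[li]]$theta <- ly$theta + vel[[li]]$theta
          model$layers[[li]]$bias <- ly$bias + vel[[li]]$bias
        } else {
          vel[[li]]$W <- hyper$momentum * vel[[li]]$W - lr * g$W
          vel[[li]]$bias <- hyper$momentum * vel[[li]]$bias - lr * g$bias
          model$layers[[li]]$W <- ly$W + vel[[li]]$W
          model$layers[[li]]$bias <- ly$bias + vel[[li]]$bias
        }
      }
    }
    loss_log[ep] <- ep_loss / nb
    if (verbose && (ep %% 10L == 0L || ep == 1L))
      log_info("epoch %d/%d loss %.4f", ep, hyper$epochs, loss_log[ep])
    lr <- lr * hyper$decay
  }
  model$loss_log <- loss_log
  model
}

#' @export
print.gsc_chebnet <- function(x, ...) {
  cat(sprintf("gsc_chebnet: %d layers, graph %d vertices, final loss %.4f\n",
              length(x$layers), graph_order(x$graph),
              if (length(x$loss_log)) tail(x$loss_log, 1) else NA))
  invisible(x)
}

#' Predict from a trained graph-CNN
#'
#' @param object a \code{gsc_chebnet}.
#' @param newdata samples x vertices matrix aligned to the model graph, or a
#'   \code{gsc_dataset}.
#' @param type \code{"prob"} (class-1 probability), \code{"class"}, or
#'   \code{"logit"} (2 x n matrix of pre-softmax outputs).
#' @param ... unused.
#' @return numeric vector or matrix depending on \code{type}.
#' @export
predict.gsc_chebnet <- function(object, newdata, type = c("prob", "class",
                                                          "logit"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "gsc_dataset")) newdata$X else as.matrix(newdata)
  if (ncol(X) != graph_order(object$graph))
    stopf("newdata has %d columns, model graph has %d vertices", ncol(X),
          graph_order(object$graph))
  Xp <- pad_signals(X, object$hierarchy)
  logits <- chebnet_forward(object, Xp)$logits
  if (type == "logit") return(logits)
  p1 <- softmax_cols(logits)[2L, ]
  if (type == "prob") p1 else as.integer(p1 >= 0.5)
}

# ---- metrics and cross-validation -----------------------------------------

#' Classification metrics
#'
#' @param y true 0/1 labels.
#' @param score class-1 scores (probabilities).
#' @param threshold decision threshold on \code{score}.
#' @return named vector: \code{auc} (rank-based, ties at 0.5),
#'   \code{accuracy}, and \code{f1_weighted} (support-weighted mean of the
#'   per-class F1 scores).
#' @export
classification_metrics <- function(y, score, threshold = 0.5) {
  stopifnot(length(y) == length(score))
  pos <- score[y == 1]; neg <- score[y == 0]
  auc <- if (length(pos) && length(neg)) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  } else NA_real_
  pred <- as.integer(score >= threshold)
  acc <- mean(pred == y)
  f1 <- vapply(c(0L, 1L), function(cl) {
    tp <- sum(pred == cl & y == cl)
    fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  w <- c(mean(y == 0), mean(y == 1))
  c(auc = auc, accuracy = acc, f1_weighted = sum(w * f1))
}

#' Stratified fold assignment
#'
#' @param y 0/1 labels.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return integer fold id per sample; errors if any fold would miss a class.
#' @export
stratified_folds <- function(y, folds = 10L, seed = 1L) {
  if (length(y) < folds) stopf("fewer samples than folds")
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  for (f in seq_len(folds))
    if (length(unique(y[fold == f])) < 2L)
      stopf("stratification failed: fold %d has a single class", f)
  fold
}

#' Stratified train/test split
#'
#' @param y 0/1 labels.
#' @param test_fraction held-out fraction (default 0.1, i.e. a 90/10 split).
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(y, test_fraction = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    k <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, k))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' k-fold cross-validation of a graph-CNN
#'
#' Stratified folds; reports AUC, accuracy and weighted F1 per fold plus the
#' across-fold mean and standard error of the mean (\code{sd/sqrt(folds)}).
#'
#' @param spec a \code{chebnet_spec}.
#' @param dataset a \code{gsc_dataset}.
#' @param folds number of folds (default 10).
#' @param hyper hyperparameters for every fold's training run.
#' @param seed RNG seed (fold assignment and per-fold training).
#' @return list with \code{per_fold} (data.frame) and \code{summary}
#'   (data.frame with mean and sem per metric).
#' @export
cross_validate <- function(spec, dataset, folds = 10L,
                           hyper = chebnet_hyperparams(), seed = 1L) {
  fold <- stratified_folds(dataset$y, folds, seed)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    dtr <- graph_signal_dataset(dataset$X[tr, , drop = FALSE], dataset$y[tr],
                                dataset$graph, dataset$sample_ids[tr])
    mod <- train_chebnet(spec, dtr, hyper, seed = seed + f)
    sc <- predict(mod, dataset$X[te, , drop = FALSE], type = "prob")
    rows[[f]] <- c(fold = f, classification_metrics(dataset$y[te], sc))
  }
  per_fold <- as.data.frame(do.call(rbind, rows))
  metr <- c("auc", "accuracy", "f1_weighted")
  summ <- data.frame(metric = metr,
                     mean = vapply(metr, function(m) mean(per_fold[[m]]),
                                   numeric(1)),
                     sem = vapply(metr, function(m)
                       sd(per_fold[[m]]) / sqrt(folds), numeric(1)))
  list(per_fold = per_fold, summary = summ)
}
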