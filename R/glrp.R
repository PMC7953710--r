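# Graph Layer-wise Relevance Propagation.
#
# The z+ rule
#   R_i = sum_j a_i w_ij^+ / (sum_i a_i w_ij^+ + eps) R_j
# redistributes relevance through ReLU layers with non-negative inputs,
# keeping every relevance non-negative.  To apply it to a graph-convolutional
# layer, the Chebyshev filter for output channel j is rewritten as an explicit
# dense weight matrix
#   W^_j = [Lbar_0 theta_1j, ..., Lbar_{K-1} theta_{F_in j}],
#   Lbar_k = 2 L~ Lbar_{k-1} - Lbar_{k-2},  Lbar_0 = I, Lbar_1 = L~,
# so that y_j = W^_j x^ (x^ the stacked input channels) and the layer can be
# treated as fully connected.  Per-channel relevances are then summed.
# Relevance starts at the pre-softmax logit of the explained class and is
# propagated down to the input vertices; the same z+ rule is used at the
# input layer because the input signals are non-negative.

#' GLRP configuration
#'
#' @param epsilon denominator stabilizer of the z+ rule (default 1e-10).
#' @param class_selection \code{"predicted"} (explain the argmax class) or
#'   \code{"specified"} (explain \code{class_index} passed to
#'   \code{\link{explain_prediction}}).
#' @param retain_layerwise keep full per-layer relevance tensors (for audits;
#'   memory heavy).
#' @param memory_budget maximum bytes a single dense conv weight matrix
#'   \eqn{\hat W_j} may occupy (default 4 GiB).
#' @return list of class \code{glrp_config}.
#' @export
glrp_config <- function(epsilon = 1e-10,
                        class_selection = c("predicted", "specified"),
                        retain_layerwise = FALSE,
                        memory_budget = 4 * 1024^3) {
  stopifnot(epsilon > 0)
  structure(list(epsilon = epsilon,
                 class_selection = match.arg(class_selection),
                 retain_layerwise = isTRUE(retain_layerwise),
                 memory_budget = memory_budget),
            class = "glrp_config")
}

#' z+ relevance propagation through a dense layer
#'
#' @param r_out relevance of the output neurons: vector (length units) or
#'   matrix (units x batch).
#' @param a_in non-negative input activations: vector (length n_in) or matrix
#'   (n_in x batch).
#' @param w weight matrix, units x n_in (biases are excluded from the rule by
#'   construction).
#' @param epsilon stabilizer.
#' @return relevance over the inputs, same shape as \code{a_in}.  When a
#'   neuron has no positive contributions its relevance is absorbed (the
#'   corresponding inputs receive 0).
#' @export
lrp_dense <- function(r_out, a_in, w, epsilon = 1e-10) {
  vec_in <- is.null(dim(a_in))
  A <- if (vec_in) matrix(a_in, ncol = 1) else as.matrix(a_in)
  R <- if (is.null(dim(r_out))) matrix(r_out, ncol = ncol(A)) else
    as.matrix(r_out)
  if (nrow(R) != nrow(w) || nrow(A) != ncol(w))
    stopf("dimension mismatch: w is %d x %d, r_out %d, a_in %d",
          nrow(w), ncol(w), nrow(R), nrow(A))
  if (min(A) < 0) stopf("z+ rule requires non-negative input activations")
  Wp <- pmax(w, 0)
  denom <- Wp %*% A + epsilon
  A * crossprod(Wp, R / denom)
}

# Dense Chebyshev polynomial matrices Lbar_k of the rescaled Laplacian,
# k = 0..K-1.  These densify quickly (support is the k-hop neighbourhood), so
# they are computed once per layer and reused across channels and samples.
cheb_Lbar <- function(lap, K) {
  m <- lap$m
  out <- vector("list", K)
  out[[1]] <- diag(m)
  if (K >= 2L) out[[2]] <- as.matrix(lap$L_rescaled)
  if (K >= 3L) for (k in 3:K)
    out[[k]] <- as.matrix(2 * (lap$L_rescaled %*% out[[k - 1]])) - out[[k - 2]]
  out
}

#' Materialize the dense weight matrix of one convolution output channel
#'
#' Builds \eqn{\hat W_j \in R^{m \times m F_{in}}} such that
#' \eqn{\hat W_j \hat x} equals the channel-j forward pre-activation minus
#' bias, turning the graph convolution into an explicit fully connected layer
#' for relevance propagation.
#'
#' @param laplacian a \code{gsc_laplacian}.
#' @param bank a \code{cheb_bank}.
#' @param channel output channel index j (1-based).
#' @param memory_budget refuse allocations above this many bytes.
#' @param Lbar optional precomputed result of the internal Chebyshev matrix
#'   recurrence (reused across channels).
#' @return dense matrix m x (m * F_in), input channels in consecutive blocks.
#' @export
build_conv_weight_matrix <- function(laplacian, bank, channel,
                                     memory_budget = 4 * 1024^3,
                                     Lbar = NULL) {
  stopifnot(inherits(bank, "cheb_bank"), channel >= 1, channel <= bank$F_out)
  m <- laplacian$m
  bytes <- 8 * m * m * bank$F_in
  if (bytes > memory_budget)
    stopf("dense conv weight matrix needs %.2f GiB > budget %.2f GiB",
          bytes / 1024^3, memory_budget / 1024^3)
  if (is.null(Lbar)) Lbar <- cheb_Lbar(laplacian, bank$K)
  W <- matrix(0, m, m * bank$F_in)
  for (i in seq_len(bank$F_in)) {
    blk <- matrix(0, m, m)
    for (k in seq_len(bank$K))
      blk <- blk + bank$theta[k, i, channel] * Lbar[[k]]
    W[, ((i - 1) * m + 1):(i * m)] <- blk
  }
  W
}

#' z+ relevance propagation through a graph-convolutional layer
#'
#' Applies the z+ rule per output channel, treating each \eqn{\hat W_j} as the
#' weight matrix of a fully connected layer, then sums the per-channel input
#' relevances.
#'
#' @param r_out relevance over the layer output: m x F_out matrix (single
#'   sample) or array (m, F_out, B).
#' @param x_in the layer's input feature map: m x F_in matrix or array
#'   (m, F_in, B); must be non-negative.
#' @param laplacian,bank the layer's operator and coefficients.
#' @param epsilon stabilizer.
#' @param memory_budget see \code{\link{build_conv_weight_matrix}}.
#' @return relevance over the input map, same shape as \code{x_in}.
#' @export
lrp_graph_conv <- function(r_out, x_in, laplacian, bank, epsilon = 1e-10,
                           memory_budget = 4 * 1024^3) {
  single <- length(dim(x_in)) < 3L
  m <- laplacian$m
  Xarr <- if (single) array(as.matrix(x_in), c(m, bank$F_in, 1L)) else x_in
  Rarr <- if (single) array(as.matrix(r_out), c(m, bank$F_out, 1L)) else r_out
  B <- dim(Xarr)[3]
  if (min(Xarr) < 0) stopf("z+ rule requires non-negative input feature map")
  Xhat <- matrix(Xarr, m * bank$F_in, B)   # stacked channels per sample
  Rhat <- matrix(0, m * bank$F_in, B)
  Lbar <- cheb_Lbar(laplacian, bank$K)
  for (j in seq_len(bank$F_out)) {
    Wp <- pmax(build_conv_weight_matrix(laplacian, bank, j,
                                        memory_budget, Lbar), 0)
    denom <- Wp %*% Xhat + epsilon
    Rj <- matrix(Rarr[, j, ], m, B)
    Rhat <- Rhat + Xhat * crossprod(Wp, Rj / denom)
  }
  out <- array(Rhat, c(m, bank$F_in, B))
  if (single) matrix(out[, , 1], m, bank$F_in) else out
}

#' Winner-take-all relevance propagation through max pooling
#'
#' Each pooled unit's relevance is assigned entirely to the input that won the
#' forward max (ties were broken toward the lower index in the forward pass),
#' conserving relevance exactly.
#'
#' @param r_pooled relevance over pooled units (vector, matrix or array).
#' @param argmax_first the \code{argmax_first} cache from \code{\link{max_pool}}.
#' @return relevance over the unpooled units (twice as long on the vertex
#'   dimension).
#' @export
lrp_max_pool <- function(r_pooled, argmax_first) {
  if (is.null(argmax_first)) stopf("missing argmax cache from the forward pass")
  max_unpool(r_pooled, argmax_first)
}

#' Explain predictions of a trained graph-CNN
#'
#' Runs a forward pass caching all activations, initializes relevance at the
#' pre-softmax logit of the selected output neuron, and propagates it with the
#' z+ rule through dense, pooling and graph-convolutional layers down to the
#' input vertices (the z+ rule is used at the input layer as well, which is
#' valid because the inputs are non-negative).  Fake (padding) vertices carry
#' zero activation, receive zero relevance, and are dropped from the result.
#'
#' @param model a trained \code{gsc_chebnet}.
#' @param X samples x vertices matrix aligned to the model graph (a single
#'   sample may be given as a vector), or a \code{gsc_dataset}.
#' @param config a \code{\link{glrp_config}}.
#' @param class_index 0/1 class(es) to explain when
#'   \code{class_selection = "specified"}; recycled over samples.
#' @return a list of \code{relevance_map} objects (one per sample), each with
#'   fields \code{sample_id}, \code{class_index}, \code{logit},
#'   \code{relevance} (named non-negative vector over graph vertices) and
#'   \code{layer_sums} (per-layer total relevance, for conservation audits).
#' @export
explain_prediction <- function(model, X, config = glrp_config(),
                               class_index = NULL) {
  stopifnot(inherits(model, "gsc_chebnet"), inherits(config, "glrp_config"))
  if (inherits(X, "gsc_dataset")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != graph_order(model$graph))
    stopf("X has %d columns, model graph has %d vertices", ncol(X),
          graph_order(model$graph))
  if (min(X) < 0) stopf("inputs must be non-negative")
  B <- nrow(X)
  sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(B))
  Xp <- pad_signals(X, model$hierarchy)
  fw <- chebnet_forward(model, Xp, keep_cache = TRUE)
  logits <- fw$logits
  if (config$class_selection == "predicted") {
    cls <- as.integer(apply(logits, 2L, which.max) - 1L)
  } else {
    if (is.null(class_index)) stopf("class_selection='specified' needs class_index")
    cls <- as.integer(rep_len(class_index, B))
    stopifnot(all(cls %in% c(0L, 1L)))
  }
  expl_logit <- logits[cbind(cls + 1L, seq_len(B))]
  if (any(expl_logit <= 0))
    warnf("%d sample(s) have non-positive explained logit; relevance may be ~0",
          sum(expl_logit <= 0))
  R <- matrix(0, 2L, B)
  R[cbind(cls + 1L, seq_len(B))] <- expl_logit
  eps <- config$epsilon
  n_layers <- length(model$layers)
  layer_sums <- matrix(NA_real_, n_layers + 1L, B)
  layer_names <- character(n_layers + 1L)
  layer_sums[n_layers + 1L, ] <- colSums(R)
  layer_names[n_layers + 1L] <- "output_logit"
  layerwise <- if (config$retain_layerwise) vector("list", n_layers) else NULL
  Rarr <- NULL
  for (li in rev(seq_len(n_layers))) {
    ly <- model$layers[[li]]
    ch <- fw$caches[[li]]
    if (ly$type %in% c("dense", "output")) {
      R <- lrp_dense(R, ch$a_in, ly$W, eps)
    } else if (ly$type == "pool") {
      if (is.null(dim(R)) || length(dim(R)) == 2L) R <- array(R, fw$flat_dim)
      for (s in rev(seq_len(ly$steps))) R <- lrp_max_pool(R, ch$argmax[[s]])
    } else {
      if (length(dim(R)) == 2L) R <- array(R, c(ly$mp, ly$F_out, B))
      bank <- cheb_coeff_bank(ly$theta, ly$bias)
      R <- lrp_graph_conv(R, ch$X, ly$lap, bank, eps, config$memory_budget)
    }
    layer_sums[li, ] <- if (length(dim(R)) == 3L) apply(R, 3L, sum) else
      colSums(as.matrix(R))
    layer_names[li] <- ly$type
    if (config$retain_layerwise) layerwise[[li]] <- R
  }
  # R is now (mp, 1, B) over padded input positions
  Rin <- matrix(R, dim(R)[1], B)
  maps <- vector("list", B)
  for (b in seq_len(B)) {
    rel <- unpad_signal(Rin[, b], model$hierarchy)
    names(rel) <- model$graph$vertex_names
    ls <- data.frame(layer = c(layer_names), total = layer_sums[, b])
    maps[[b]] <- structure(list(sample_id = sample_ids[b],
                                class_index = cls[b],
                                logit = expl_logit[b],
                                relevance = rel,
                                layer_sums = ls,
                                layerwise = if (config$retain_layerwise)
                                  lapply(layerwise, slice_batch, b) else NULL,
                                model_hash = model$graph_hash),
                           class = "relevance_map")
  }
  maps
}

slice_batch <- function(x, b) {
  if (length(dim(x)) == 3L) x[, , b, drop = TRUE] else x[, b]
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("relevance_map: sample %s, class %d, logit %.4f, total R %.4f\n",
              x$sample_id, x$class_index, x$logit, sum(x$relevance)))
  invisible(x)
}

#' Relevance conservation report
#'
#' Summarizes the per-layer relevance totals of a \code{relevance_map}.  With
#' all biases zero the z+ rule conserves relevance up to the epsilon leak; a
#' positive leak at a layer indicates relevance absorbed at bias-dominated
#' neurons (reported, not redistributed, since the rule excludes bias terms).
#'
#' @param rmap a \code{relevance_map} from \code{\link{explain_prediction}}.
#' @param tolerance leak fraction above which a layer is flagged.
#' @return data.frame with per-layer totals, the ratio of each layer's total
#'   to the layer above, and a \code{flagged} column.
#' @export
conservation_report <- function(rmap, tolerance = 1e-6) {
  stopifnot(inherits(rmap, "relevance_map"))
  ls <- rmap$layer_sums
  n <- nrow(ls)
  ratio <- c(ls$total[-n] / ls$total[-1][seq_len(n - 1)], NA)
  out <- data.frame(layer = ls$layer, total = ls$total, ratio_to_above = ratio)
  out$flagged <- !is.na(ratio) & abs(ratio - 1) > tolerance
  out
}

#' Stack relevance maps into a samples x vertices matrix
#'
#' @param maps list of \code{relevance_map} objects over the same graph.
#' @return numeric matrix, rownames = sample ids, colnames = vertex names.
#' @export
relevance_matrix <- function(maps) {
  stopifnot(length(maps) > 0)
  M <- do.call(rbind, lapply(maps, `[[`, "relevance"))
  rownames(M) <- vapply(maps, `[[`, "", "sample_id")
  M
}

#' Write relevance maps to TSV
#'
#' Writes one combined samples x genes relevance matrix; header comment lines
#' record the model hash for provenance.
#'
#' @param maps list of \code{relevance_map} objects.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_relevances <- function(maps, path) {
  M <- relevance_matrix(maps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# glrpnet %s relevance matrix; model_hash=%s",
                     as.character(packageVersion("glrpnet")),
                     maps[[1]]$model_hash), con)
  writeLines(paste(c("sample_id", colnames(M)), collapse = "\t"), con)
  for (i in seq_len(nrow(M)))
    writeLines(paste(c(rownames(M)[i], format(M[i, ], digits = 15,
                                              scientific = TRUE, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
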