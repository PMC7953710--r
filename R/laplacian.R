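# Combinatorial graph Laplacian and its rescaled form.
#
# Chebyshev polynomial filters require the operator spectrum inside [-1, 1],
# so the Laplacian L = D - A is rescaled to L~ = 2 L / lambda_max - I (with
# the convention lambda_max >= largest eigenvalue of L; here the plain
# L / lambda_max - I form is used, matching the filter definition in the
# spectral graph-CNN literature).

#' Build graph Laplacians
#'
#' Computes the combinatorial Laplacian \eqn{L = D - A}, estimates its largest
#' eigenvalue by power iteration, and forms the rescaled Laplacian
#' \eqn{\tilde L = L/\lambda_{max} - I} whose spectrum lies in \eqn{[-1, 1]}
#' as required by the Chebyshev recurrence.
#'
#' @param graph a \code{gsc_graph}.
#' @param normalized if TRUE use the symmetric normalized Laplacian
#'   \eqn{I - D^{-1/2} A D^{-1/2}} instead of \eqn{D - A}; off by default.
#' @param margin multiplicative safety factor applied to the estimated
#'   \eqn{\lambda_{max}} (default 1: the power-iteration tolerance of 1e-10
#'   already keeps the rescaled spectrum within the documented 1e-6 band).
#' @return object of class \code{gsc_laplacian}: list with \code{L} (sparse
#'   symmetric), \code{lambda_max}, \code{L_rescaled}, and \code{m}.
#' @export
build_laplacians <- function(graph, normalized = FALSE, margin = 1.0) {
  m <- graph_order(graph)
  if (m == 0L) stopf("empty graph")
  A <- graph$adjacency
  if (normalized) {
    d <- graph$degrees
    dh <- ifelse(d > 0, 1 / sqrt(d), 0)
    Dh <- Matrix::Diagonal(m, dh)
    L <- Matrix::Diagonal(m, as.numeric(d > 0)) - Dh %*% A %*% Dh
  } else {
    L <- Matrix::Diagonal(m, graph$degrees) - A
  }
  L <- methods::as(methods::as(L, "generalMatrix"), "CsparseMatrix")
  lmax <- estimate_lambda_max(L)
  if (lmax < 1e-12)
    stopf("degenerate graph: lambda_max ~ 0 (edgeless graph?)")
  lmax <- lmax * margin
  Lr <- L / lmax - Matrix::Diagonal(m)
  Lr <- methods::as(methods::as(Lr, "generalMatrix"), "CsparseMatrix")
  structure(list(L = L, lambda_max = lmax, L_rescaled = Lr, m = m),
            class = "gsc_laplacian")
}

# Power iteration for the dominant eigenvalue of a symmetric PSD sparse
# matrix.  Relative tolerance 1e-10, capped at 1000 iterations.
estimate_lambda_max <- function(L, tol = 1e-10, max_iter = 1000L) {
  m <- nrow(L)
  if (m == 1L) return(0)
  v <- rep(1 / sqrt(m), m) + seq_len(m) * 1e-4  # deterministic non-eigen start
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(0)
    v_new <- w / nw
    lam_new <- sum(v_new * as.numeric(L %*% v_new))
    if (abs(lam_new - lam) <= tol * max(abs(lam_new), 1e-30)) {
      return(lam_new)
    }
    lam <- lam_new
    v <- v_new
  }
  lam
}

#' @export
print.gsc_laplacian <- function(x, ...) {
  cat(sprintf("gsc_laplacian: m = %d, lambda_max = %.6g\n", x$m, x$lambda_max))
  invisible(x)
}
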