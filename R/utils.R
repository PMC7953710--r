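# Internal helpers shared across modules.

#' @importFrom stats rnorm runif quantile median sd phyper p.adjust fisher.test
#' @importFrom utils read.delim write.table packageVersion head
NULL

log_info <- function(...) {
  message(sprintf("[glrpnet %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

#' Stable content hash of an R object
#'
#' Used to stamp checkpoints and output files so that a relevance map can be
#' traced back to the exact graph and model that produced it.
#'
#' @param x any serializable R object.
#' @return a character scalar (xxhash64 hex digest).
#' @keywords internal
object_hash <- function(x) {
  digest::digest(x, algo = "xxhash64")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# ReLU, kept in one place so forward pass and LRP caches agree on semantics.
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Truncated normal initialiser (resample beyond 2 sd), matching common
# graph-CNN weight initialisation.
rtruncnorm <- function(n, sd = 0.1) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
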