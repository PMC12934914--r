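#' Nearest positive semi-definite repair for a correlation matrix
#'
#' Clips negative eigenvalues at zero and rescales so the diagonal is exactly
#' one. Used wherever an empirical correlation matrix must be fed to a solver
#' that assumes positive semi-definiteness.
#'
#' @param S symmetric matrix.
#' @param eps eigenvalue floor.
#' @return repaired symmetric matrix with unit diagonal.
#' @export
nearest_psd <- function(S, eps = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(S)
  v <- pmax(e$values, eps)
  R <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(R), .Machine$double.eps))
  R <- R / outer(d, d)
  diag(R) <- 1
  dimnames(R) <- dimnames(S)
  (R + t(R)) / 2
}

#' Convert a precision matrix to partial correlations
#'
#' @param K precision (inverse covariance) matrix.
#' @return symmetric partial-correlation matrix with zero diagonal.
#' @export
precision_to_pcor <- function(K) {
  d <- sqrt(abs(diag(K)))
  W <- -K / outer(d, d)
  diag(W) <- 0
  dimnames(W) <- dimnames(K)
  (W + t(W)) / 2
}

#' Convert a partial-correlation matrix to a unit-diagonal precision matrix
#'
#' @param P partial-correlation matrix (zero diagonal).
#' @return precision matrix with unit diagonal.
#' @export
pcor_to_precision <- function(P) {
  K <- -P
  diag(K) <- 1
  K
}

# Polynomial string hash modulo the Mersenne prime 2^31 - 1 (exact in double
# arithmetic). Used for provenance tokens and for deriving named substream
# seeds so adding a pipeline stage never perturbs earlier stages' randomness.
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 69069) %% 2147483647
  }
  h
}

#' Derive a deterministic substream seed
#'
#' Hashes a stream name together with a global seed so each pipeline stage
#' (or each participant in the cohort generator) draws from its own
#' reproducible stream.
#'
#' @param seed global integer seed.
#' @param name stream name (string) or integer index.
#' @return integer seed in `[1, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  h <- string_hash(paste0(as.character(name), "#", as.integer(seed)))
  as.integer(h %% 2147483646 + 1)
}

# Upper-triangle vectorization helpers used throughout for edge lists.
upper_vec <- function(M) M[upper.tri(M)]

upper_pairs <- function(nodes) {
  p <- length(nodes)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
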