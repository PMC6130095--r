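# Non-negative matrix factorization by multiplicative updates under the
# Frobenius objective (Lee & Seung). V (types x samples) ~ W (types x K) %*%
# H (K x samples). The Frobenius error is non-increasing across iterations,
# which the tests assert on the recorded trace.

#' Column-wise cosine similarity between two matrices
#'
#' @param X,Y numeric matrices with the same number of rows; columns are
#'   compared pairwise (`Y` defaults to `X`).
#' @return `ncol(X)` x `ncol(Y)` similarity matrix in [-1, 1].
#' @export
cosine_similarity <- function(X, Y = X) {
  Xn <- sweep(X, 2L, pmax(sqrt(colSums(X^2)), 1e-300), `/`)
  Yn <- sweep(Y, 2L, pmax(sqrt(colSums(Y^2)), 1e-300), `/`)
  crossprod(Xn, Yn)
}

cosine_dist <- function(X) {
  d <- 1 - cosine_similarity(X)
  d[d < 0] <- 0
  as.dist(d)
}

#' Rank-K NMF with multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (mutation types x samples) into
#' `W %*% H` with non-negative factors, minimizing the Frobenius
#' reconstruction error. The best of `n_restarts` random initializations is
#' returned; `W` columns are normalized to sum to one, with the scale moved
#' into `H`.
#'
#' @param V non-negative numeric matrix (192 x samples for strand catalogs).
#' @param K factorization rank.
#' @param n_restarts random restarts, best final error kept (default 10).
#' @param max_iter maximum update iterations per restart (default 10000).
#' @param tol relative decrease of the error below which iteration stops
#'   (default 1e-9).
#' @param seed optional integer seed.
#' @return list with `W`, `H`, `error` (final Frobenius norm of the
#'   residual), and `error_trace` of the winning restart.
#' @export
nmf_mu <- function(V, K, n_restarts = 10, max_iter = 10000, tol = 1e-9,
                   seed = NULL) {
  stopifnot(all(V >= 0), K >= 1, K <= ncol(V))
  if (!is.null(seed)) set.seed(seed)
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(runif(nrow(V) * K, 0.1, 1), nrow(V), K)
    H <- matrix(runif(K * ncol(V), 0.1, 1), K, ncol(V))
    trace <- numeric(0)
    err <- sqrt(sum((V - W %*% H)^2))
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
      W <- W * ((V %*% t(H)) / (W %*% tcrossprod(H) + eps))
      new_err <- sqrt(sum((V - W %*% H)^2))
      trace <- c(trace, new_err)
      if (err - new_err < tol * max(err, eps)) { err <- new_err; break }
      err <- new_err
    }
    if (is.null(best) || err < best$error) {
      best <- list(W = W, H = H, error = err, error_trace = trace)
    }
  }
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  best$W <- sweep(best$W, 2L, scale, `/`)
  best$H <- sweep(best$H, 1L, scale, `*`)
  best
}
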