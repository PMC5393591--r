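#' Whiten a data matrix
#'
#' Row-centers `X` and applies the eigendecomposition of its sample covariance
#' so that the rows of the result are uncorrelated with unit variance. The
#' output is truncated to the numerical rank `r` of the centered matrix:
#' eigen-directions carrying only round-off variance (relative eigenvalue
#' below `rank_tol`) hold no data and are discarded. When more components are
#' requested downstream than `r` can supply, the surplus simply cannot be
#' extracted — the mechanism by which overextracted (spurious) components end
#' up with reproducibility zero.
#'
#' @param X Numeric matrix, `N` channels x `p` samples, `p > N`.
#' @param rank_tol Relative eigenvalue tolerance defining the numerical rank.
#'   Default `1e-10`.
#' @return List with `Z` (`r` x `p` whitened rows), `W` (the `r` x `N`
#'   whitening map), `M` (row means), `eigenvalues` of the covariance (all
#'   `N`), and `rank`, so that `Z = W %*% (X - M)`.
#' @export
whiten <- function(X, rank_tol = 1e-10) {
  X <- check_matrix(X)
  N <- nrow(X); p <- ncol(X)
  if (p <= N) stop("whitening requires more samples than channels (p > N)")
  M <- rowMeans(X)
  Y <- X - M
  v <- apply(Y, 1, var)
  if (any(v == 0)) stop("zero-variance row at index ",
                        paste(which(v == 0), collapse = ", "))
  C <- tcrossprod(Y) / (p - 1)
  e <- eigen(C, symmetric = TRUE)
  r <- sum(e$values > max(e$values) * rank_tol)
  W <- diag(1 / sqrt(e$values[seq_len(r)]), r) %*%
    t(e$vectors[, seq_len(r), drop = FALSE])
  list(Z = W %*% Y, W = W, M = M, eigenvalues = e$values, rank = r)
}

#' One seeded FastICA realization
#'
#' Runs deflationary FastICA with the logcosh (tanh) contrast from a seeded
#' random orthogonal start on the whitened data. Components are extracted one
#' at a time; at most the numerical rank of `X` can be delivered, so
#' overextraction of a rank-deficient mixture exhausts the available variance
#' and yields fewer components than requested. Components that hit the
#' iteration cap without meeting the tolerance are returned with
#' `converged = FALSE`: directions inside a Gaussian subspace have no stable
#' FastICA fixed point, yet they are genuine unit-variance directions of the
#' data and the reproducibility analysis needs them.
#'
#' @param X Numeric matrix `N` x `p`.
#' @param n_components Number of components to request, at most `N`.
#' @param seed Integer seed (controls the random orthogonal start).
#' @param tol Convergence tolerance on the direction update. Default `1e-4`.
#' @param max_iter Iteration cap per component. Default 200.
#' @param exhaust_tol Variance-exhaustion threshold. Default `1e-6`.
#' @return Object of class `ica_realization`: list with `S_hat`
#'   (`n_extracted` x `p` unit-variance estimated sources), `A_hat`
#'   (`N` x `n_extracted` estimated mixing), `converged` flags, `iterations`,
#'   `n_requested`, and `seed`. `n_extracted` can be smaller than
#'   `n_components`; an empty realization (nothing extracted) is returned,
#'   not an error.
#' @examples
#' mix <- make_mixture(list(source_spec("laplace"), source_spec("laplace")),
#'                     n = 2000, mix_rows = 2, seed = 3)
#' r <- fastica_realization(mix$X, 2, seed = 11)
#' abs(cor(t(r$S_hat), t(mix$S_true)))
#' @export
fastica_realization <- function(X, n_components, seed, tol = 1e-4,
                                max_iter = 200L, exhaust_tol = 1e-6) {
  X <- check_matrix(X)
  N <- nrow(X)
  if (n_components > N) stop("'n_components' must be at most nrow(X)")
  wh <- whiten(X)
  n_eff <- min(n_components, wh$rank)
  W0 <- random_orthogonal_mixing(wh$rank, n_eff, seed)
  fit <- .fastica_deflate_cpp(wh$Z, W0, tol, as.integer(max_iter), exhaust_tol)
  k <- ncol(fit$W)
  if (k == 0L) {
    return(structure(list(S_hat = matrix(0, 0, ncol(X)),
                          A_hat = matrix(0, N, 0),
                          converged = logical(0), iterations = integer(0),
                          n_requested = n_components, seed = seed),
                     class = "ica_realization"))
  }
  S <- crossprod(fit$W, wh$Z)                  # k x p, then exact unit variance
  S <- t(apply(S, 1, standardize))
  if (k == 1L) S <- matrix(S, 1L)
  # least-squares mixing in the original channel space: Xc ~ A S
  Y <- X - wh$M
  A <- t(solve(tcrossprod(S), S %*% t(Y)))
  structure(list(S_hat = S, A_hat = A,
                 converged = as.logical(fit$converged),
                 iterations = as.integer(fit$iterations),
                 n_requested = n_components, seed = seed),
            class = "ica_realization")
}

#' @export
print.ica_realization <- function(x, ...) {
  cat(sprintf("FastICA realization: %d/%d components extracted (%d converged)\n",
              nrow(x$S_hat), x$n_requested, sum(x$converged)))
  invisible(x)
}
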