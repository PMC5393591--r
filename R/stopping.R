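# PCA stopping rules for the dimension of the residual Gaussian subspace.
# All rules operate on the eigenvalue spectrum of the sample covariance
# C = Y Y^T / (p - 1) of the row-centered residual, except parallel analysis,
# which standardizes rows first so C is the correlation matrix.

#' Covariance eigenvalue spectrum
#'
#' Eigenvalues of the sample covariance of the row-centered matrix,
#' descending, with their fractions of total variance.
#'
#' @param X Numeric matrix `n` x `p`, `p >= 2`.
#' @return List with `lambda` (descending), `fractions`
#'   (`lambda / sum(lambda)`), `n` (matrix order), `p`.
#' @export
covariance_eigenvalues <- function(X) {
  X <- check_matrix(X)
  if (ncol(X) < 2) stop("need at least 2 samples")
  Y <- X - rowMeans(X)
  lam <- eigen(tcrossprod(Y) / (ncol(X) - 1), symmetric = TRUE,
               only.values = TRUE)$values
  lam <- pmax(lam, 0)          # clamp eigen() round-off at the zero boundary
  list(lambda = lam, fractions = lam / sum(lam), n = nrow(X), p = ncol(X))
}

#' Kaiser-Guttman criterion
#'
#' Retains components whose eigenvalue strictly exceeds the mean eigenvalue.
#'
#' @param lambda Numeric vector of eigenvalues.
#' @return Integer count retained.
#' @export
kaiser_guttman <- function(lambda) {
  if (!length(lambda)) stop("empty spectrum")
  sum(lambda > mean(lambda))
}

#' Jolliffe's modified Kaiser-Guttman criterion
#'
#' Retains components whose eigenvalue strictly exceeds 0.7 times the mean,
#' a correction for sampling variance in the estimated eigenvalues.
#'
#' @inheritParams kaiser_guttman
#' @return Integer count retained.
#' @export
jolliffe_kg <- function(lambda) {
  if (!length(lambda)) stop("empty spectrum")
  sum(lambda > 0.7 * mean(lambda))
}

#' Expected broken-stick segment lengths
#'
#' Expected ordered segment lengths when the unit interval is broken at
#' `n - 1` uniform points: `l_k = (1/n) * sum_{i=k}^{n} 1/i`. These sum to 1.
#'
#' @param n Number of segments.
#' @return Numeric vector of length `n`.
#' @export
broken_stick_lengths <- function(n) {
  rev(cumsum(rev(1 / seq_len(n)))) / n
}

#' Broken-stick stopping rule
#'
#' Compares eigenvalue fractions `f_k = lambda_k / sum(lambda)` with the
#' expected broken-stick segment lengths and retains components contiguously
#' from the top while `f_k > l_k`.
#'
#' @inheritParams kaiser_guttman
#' @return Integer count retained.
#' @export
broken_stick <- function(lambda) {
  if (!length(lambda)) stop("empty spectrum")
  f <- lambda / sum(lambda)
  l <- broken_stick_lengths(length(lambda))
  keep <- f > l
  if (!keep[1]) 0L else if (all(keep)) length(keep)
  else which.min(keep) - 1L
}

#' Information dimension
#'
#' Treats the eigenvalue fractions as probabilities `p_k`, computes the
#' normalized spectral entropy `H = -sum p_k log2 p_k / log2 N`, and reports
#' the real-valued dimension `n0 = N^H`. Equal eigenvalues give `n0 = N`; a
#' single nonzero eigenvalue gives `n0 = 1`; zero eigenvalues contribute
#' nothing (`0 * log 0 = 0`).
#'
#' @param lambda Nonnegative eigenvalues with positive sum.
#' @param N Matrix order (row dimension of the covariance matrix). Defaults
#'   to `length(lambda)`.
#' @return Real number in `[1, N]`.
#' @export
information_dimension <- function(lambda, N = length(lambda)) {
  if (!length(lambda) || any(lambda < 0) || sum(lambda) <= 0)
    stop("'lambda' must be nonnegative with positive sum")
  pk <- lambda / sum(lambda)
  pk <- pk[pk > 0]
  H <- -sum(pk * log2(pk)) / log2(N)
  N^H
}

#' Horn's parallel analysis
#'
#' Standardizes each row of `X` (so the covariance becomes the correlation
#' matrix), then compares each observed eigenvalue with the `level` quantile
#' of the corresponding rank eigenvalue over `n_null` standard-normal matrices
#' of identical dimensions (also on the correlation scale). Components are
#' retained contiguously from the top; retention stops once an observed
#' eigenvalue drops below its critical value.
#'
#' @param X Numeric matrix.
#' @param n_null Number of null matrices. Default 1000.
#' @param level Quantile for the critical values. Default 0.95.
#' @param seed Integer seed for the null ensemble.
#' @return Integer count retained.
#' @export
parallel_analysis <- function(X, n_null = 1000L, level = 0.95, seed = 1L) {
  X <- check_matrix(X)
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) stop("constant row: cannot standardize for parallel analysis")
  Ys <- (X - rowMeans(X)) / sds
  lam <- eigen(tcrossprod(Ys) / (p - 1), symmetric = TRUE,
               only.values = TRUE)$values
  null_lam <- with_seed(seed, {
    t(vapply(seq_len(n_null), function(i) {
      G <- matrix(rnorm(n * p), n, p)
      G <- (G - rowMeans(G)) / apply(G, 1, sd)
      eigen(tcrossprod(G) / (p - 1), symmetric = TRUE,
            only.values = TRUE)$values
    }, numeric(n)))
  })
  crit <- apply(null_lam, 2, quantile, probs = level, names = FALSE)
  keep <- lam > crit
  if (!keep[1]) 0L else if (all(keep)) n else which.min(keep) - 1L
}

#' Permutation ("random lambda") stopping rule
#'
#' Shuffles all entries of `X` jointly (destroying the row/column structure),
#' recomputes the covariance spectrum for each of `n_perm` permutations, and
#' computes a per-rank permutation p-value `(n_exceed + 1) / (n_perm + 1)`,
#' where `n_exceed` counts permuted eigenvalues larger than the observed one
#' at that rank. Components with `p <= alpha` are retained, contiguously from
#' the top by default; `mode = "any"` instead counts every rank passing the
#' test.
#'
#' @param X Numeric matrix.
#' @param n_perm Number of permutations. Default 999.
#' @param alpha Significance level. Default 0.05.
#' @param seed Integer seed.
#' @param mode `"contiguous"` (default) or `"any"`.
#' @return Integer count retained.
#' @export
random_lambda <- function(X, n_perm = 999L, alpha = 0.05, seed = 1L,
                          mode = c("contiguous", "any")) {
  mode <- match.arg(mode)
  X <- check_matrix(X)
  n <- nrow(X); p <- ncol(X)
  lam <- covariance_eigenvalues(X)$lambda
  exceed <- integer(n)
  vals <- as.vector(X)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      G <- matrix(sample(vals), n, p)
      lamb <- eigen(tcrossprod(G - rowMeans(G)) / (p - 1), symmetric = TRUE,
                    only.values = TRUE)$values
      exceed <- exceed + (lamb > lam)
    }
  })
  pval <- (exceed + 1) / (n_perm + 1)
  keep <- pval <= alpha
  if (mode == "any") return(sum(keep))
  if (!keep[1]) 0L else if (all(keep)) n else which.min(keep) - 1L
}

#' Consensus Gaussian-subspace dimension
#'
#' Mean of the broken-stick, information-dimension, parallel-analysis and
#' permutation-rule estimates, rounded to the nearest integer. The two
#' Kaiser-Guttman variants are excluded: they are fast and popular but
#' systematically unreliable, and the remaining four rules perform well over
#' a wide range of correlation structures.
#'
#' @param rule_dims Numeric vector of per-rule dimensions (at least one).
#' @return Integer consensus dimension.
#' @export
consensus_dimension <- function(rule_dims) {
  if (!length(rule_dims)) stop("empty rule_dims")
  as.integer(round(mean(rule_dims)))
}

#' Orthonormal basis sources for the Gaussian subspace
#'
#' Projects the row-centered matrix onto its top `dim` covariance
#' eigenvectors; the resulting rows are mutually uncorrelated.
#'
#' @param X Numeric matrix.
#' @param dim Number of basis sources, at most `nrow(X)`. If `dim` exceeds
#'   the numerical rank the basis is truncated with a warning.
#' @return A `dim` x `ncol(X)` matrix (0 rows when `dim = 0`).
#' @export
gaussian_basis <- function(X, dim) {
  X <- check_matrix(X)
  if (dim > nrow(X)) stop("'dim' must be at most nrow(X)")
  if (dim == 0) return(matrix(0, 0, ncol(X)))
  Y <- X - rowMeans(X)
  e <- eigen(tcrossprod(Y) / (ncol(X) - 1), symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (dim > rank) {
    warning(sprintf("requested dim %d exceeds numerical rank %d; truncating",
                    dim, rank))
    dim <- rank
  }
  crossprod(e$vectors[, seq_len(dim), drop = FALSE], Y)
}

#' Estimate the Gaussian-subspace dimension by six stopping rules
#'
#' Runs Kaiser-Guttman, Jolliffe's Kaiser-Guttman, broken stick, information
#' dimension, parallel analysis and the permutation rule on the residual
#' matrix, and forms the consensus dimension (mean of the last four, rounded).
#'
#' @param X Residual matrix (`n` channels x `p` samples).
#' @param n_null,level Parallel-analysis parameters.
#' @param n_perm,alpha Permutation-rule parameters.
#' @param seed Integer seed shared by the two resampling rules.
#' @return Object of class `eigen_selection`: list with `lambda`,
#'   `fractions`, `rule_dims` (named, information dimension real-valued),
#'   `consensus_dim`, `n`, `p`.
#' @examples
#' mix <- make_mixture(list(source_spec("gaussian"), source_spec("gaussian")),
#'                     n = 2000, mix_rows = 4, seed = 8)
#' sel <- subspace_dim(mix$X, n_null = 100, n_perm = 99, seed = 2)
#' sel$rule_dims
#' @export
subspace_dim <- function(X, n_null = 1000L, level = 0.95, n_perm = 999L,
                         alpha = 0.05, seed = 1L) {
  spec <- covariance_eigenvalues(X)
  seeds <- derive_seeds(seed, 2L)
  dims <- c(
    kaiser_guttman = kaiser_guttman(spec$lambda),
    jolliffe_kg = jolliffe_kg(spec$lambda),
    broken_stick = broken_stick(spec$lambda),
    information_dimension = information_dimension(spec$lambda, spec$n),
    parallel_analysis = parallel_analysis(X, n_null = n_null, level = level,
                                          seed = seeds[1]),
    random_lambda = random_lambda(X, n_perm = n_perm, alpha = alpha,
                                  seed = seeds[2]))
  structure(list(lambda = spec$lambda, fractions = spec$fractions,
                 rule_dims = dims,
                 consensus_dim = consensus_dimension(
                   dims[c("broken_stick", "information_dimension",
                          "parallel_analysis", "random_lambda")]),
                 n = spec$n, p = spec$p),
            class = "eigen_selection")
}

#' @export
print.eigen_selection <- function(x, ...) {
  cat(sprintf("Eigenvalue selection (n = %d, p = %d)\n", x$n, x$p))
  d <- x$rule_dims
  for (nm in names(d))
    cat(sprintf("  %-22s %s\n", nm,
                if (nm == "information_dimension") sprintf("%.2f", d[[nm]])
                else format(d[[nm]])))
  cat(sprintf("  consensus (no KG rules) %d\n", x$consensus_dim))
  invisible(x)
}
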