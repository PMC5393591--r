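# The MIPReSt pipeline. RAICAR reproducibilities from the parent data matrix
# are compared with those from an ensemble of random column decimations: true
# sparse sources keep uniformly high R under decimation, Gaussian-subspace
# components fluctuate (the subspace reorients with each subsample), and
# overextracted components stay unreproducible. The delta statistic
#   delta_ij = R^i_j - R^0_j
# (ensemble i, source j, superscript 0 = parent) quantifies that stability.

#' Random column decimation
#'
#' Keeps a uniform random sample of `floor(p / factor)` distinct columns of
#' `X`, preserving the original column order.
#'
#' @param X Numeric matrix `N` x `p`.
#' @param factor Integer decimation factor, at least 2 (default 2; two-fold).
#' @param seed Integer seed.
#' @return Matrix `N` x `floor(p / factor)`.
#' @export
decimate <- function(X, factor = 2L, seed = 1L) {
  X <- check_matrix(X)
  if (factor < 2) stop("'factor' must be at least 2")
  keep <- floor(ncol(X) / factor)
  if (keep < nrow(X)) stop("too few surviving columns after decimation")
  cols <- with_seed(seed, sort(sample.int(ncol(X), keep)))
  X[, cols, drop = FALSE]
}

#' Reproducibility-stability table
#'
#' Collects the parent reproducibilities `R0` and an ensemble of decimated-run
#' reproducibilities, matched source-by-source, and forms
#' `delta[i, j] = R_dec[i, j] - R0[j]`.
#'
#' Matching across runs uses descending-reproducibility rank by default
#' (parent rank j vs decimated rank j, the convention under which the delta
#' statistic is written). `match = "mixing"` instead matches runs by Hungarian
#' assignment on the absolute correlations of averaged mixing-matrix columns
#' (the sources themselves have different sample counts across decimations).
#'
#' @param parent A [raicar_decompose()] result on the parent matrix.
#' @param decimated List of `raicar` results on decimated copies, all with the
#'   same `N_s` as the parent.
#' @param match `"rank"` (default) or `"mixing"`.
#' @return Object of class `delta_table`: list with `R0`, `R_dec`
#'   (`n_ensembles` x `N_s`), `delta`, `n_ensembles`, `match`.
#' @export
delta_table <- function(parent, decimated, match = c("rank", "mixing")) {
  match <- match.arg(match)
  if (!inherits(parent, "raicar")) stop("'parent' must be a raicar object")
  ns <- vapply(decimated, function(r) as.integer(r$N_s), 0L)
  if (any(ns != parent$N_s))
    stop("all runs must extract the same number of sources N_s")
  N_s <- parent$N_s
  R0 <- parent$R
  R_dec <- matrix(0, length(decimated), N_s)
  for (i in seq_along(decimated)) {
    Ri <- decimated[[i]]$R
    if (match == "rank") {
      R_dec[i, ] <- Ri          # R vectors are already rank-sorted
    } else {
      cost <- 1 - abs(cor(parent$A_avg, decimated[[i]]$A_avg))
      cost[!is.finite(cost)] <- 1   # zero columns of empty groups
      perm <- hungarian_assignment(cost)
      R_dec[i, ] <- Ri[perm]
    }
  }
  structure(list(R0 = R0, R_dec = R_dec, delta = sweep(R_dec, 2, R0),
                 n_ensembles = length(decimated), match = match),
            class = "delta_table")
}

#' Classify sources as sparse, Gaussian, or spurious
#'
#' Thresholds the per-source medians (over the decimation ensemble) of
#' reproducibility and `|delta|`. A source is `sparse` when its median
#' decimated reproducibility is at least `r_hi` and its median `|delta|` at
#' most `d_lo` (reproducible and stable); `spurious` when median
#' reproducibility is at most `r_lo` with median `|delta|` at most `d_lo`
#' (unreproducible and flat); `gaussian` otherwise (the subspace reorients
#' from subsample to subsample, so reproducibility fluctuates).
#'
#' @param dt A [delta_table()].
#' @param r_hi,r_lo,d_lo Thresholds; defaults 0.9, 0.3, 0.1 reflect the clean
#'   three-way separation the method produces on benchmark mixtures.
#' @return Object of class `source_classification`: list with `labels`,
#'   `median_R`, `median_abs_delta`, `n_sparse`, and `thresholds`.
#' @export
classify_sources <- function(dt, r_hi = 0.9, r_lo = 0.3, d_lo = 0.1) {
  if (!inherits(dt, "delta_table")) stop("'dt' must be a delta_table")
  if (!(r_lo < r_hi)) stop("thresholds must satisfy r_lo < r_hi")
  med_R <- apply(dt$R_dec, 2, median)
  med_d <- apply(abs(dt$delta), 2, median)
  labels <- ifelse(med_R >= r_hi & med_d <= d_lo, "sparse",
            ifelse(med_R <= r_lo & med_d <= d_lo, "spurious", "gaussian"))
  structure(list(labels = labels, median_R = med_R, median_abs_delta = med_d,
                 n_sparse = sum(labels == "sparse"),
                 thresholds = c(r_hi = r_hi, r_lo = r_lo, d_lo = d_lo)),
            class = "source_classification")
}

#' @export
print.source_classification <- function(x, ...) {
  cat("Source classification:",
      sprintf("%d sparse, %d gaussian, %d spurious\n",
              sum(x$labels == "sparse"), sum(x$labels == "gaussian"),
              sum(x$labels == "spurious")))
  print(data.frame(label = x$labels, median_R = round(x$median_R, 3),
                   median_abs_delta = round(x$median_abs_delta, 3)))
  invisible(x)
}

#' Project the sparse subspace out of the data
#'
#' Removes the selected sparse components using the parent decomposition:
#' `Xt = X - A S`, where `A` (`N` x `N'`) and `S` (`N'` x `p`) are the
#' averaged mixing columns and averaged sources of the parent RAICAR run
#' restricted to `sparse_idx`. The residual contains only the Gaussian
#' subspace (plus estimation leftovers) and has numerical rank at most
#' `N - N'` up to centering slack.
#'
#' @param X Parent data matrix.
#' @param parent The parent `raicar` object.
#' @param sparse_idx Indices (into the parent's rank-sorted groups) of the
#'   components to remove; may be empty, in which case `X` is returned
#'   unchanged.
#' @param refit If `TRUE` (default) the mixing columns are re-fit to `X` by
#'   least squares on the selected averaged sources, which makes the
#'   projection exactly idempotent; `refit = FALSE` subtracts the stored
#'   averaged mixing columns literally. The two coincide up to estimation
#'   noise.
#' @return The residual matrix, same shape as `X`.
#' @export
project_out_sparse <- function(X, parent, sparse_idx, refit = TRUE) {
  X <- check_matrix(X)
  if (!length(X)) stop("'X' is empty")
  if (!length(sparse_idx)) return(X)
  if (any(sparse_idx < 1 | sparse_idx > parent$N_s))
    stop("'sparse_idx' out of range")
  S <- parent$S_avg[sparse_idx, , drop = FALSE]
  A <- if (refit) {
    Y <- X - rowMeans(X)
    t(solve(tcrossprod(S), S %*% t(Y)))
  } else {
    parent$A_avg[, sparse_idx, drop = FALSE]
  }
  X - A %*% S
}

#' Run the full mixed ICA/PCA pipeline
#'
#' End to end: RAICAR on the parent matrix, RAICAR on `n_ensembles` random
#' column decimations, the reproducibility-stability table, three-way source
#' classification, projection of the sparse subspace out of the parent data,
#' and the PCA stopping rules on the residual.
#'
#' @param X Numeric matrix `N` x `p` (rows = channels, columns = samples).
#' @param N_s Components per realization; default `nrow(X)` (extract as many
#'   as possible and let reproducibility flag the surplus).
#' @param K Realizations per RAICAR run. Default 30.
#' @param n_ensembles Number of decimated copies. Default 30.
#' @param factor Decimation factor. Default 2.
#' @param seed Integer seed; all stage seeds are derived from it.
#' @param r_hi,r_lo,d_lo Classification thresholds, see [classify_sources()].
#' @param match Source matching across runs, see [delta_table()].
#' @param n_null,n_perm,alpha,level Stopping-rule parameters, see
#'   [subspace_dim()].
#' @param ... Passed to [raicar_decompose()] (FastICA settings).
#' @return Object of class `miprest`: list with `parent` (raicar), `delta`
#'   (delta_table), `classification`, `residual` (the projected matrix),
#'   `eigen` ([subspace_dim()] result on the residual), and `config`.
#' @examples
#' \donttest{
#' mix <- make_mixture(list(source_spec("laplace"), source_spec("gaussian"),
#'                          source_spec("gaussian")), n = 4000, mix_rows = 3,
#'                     seed = 2)
#' fit <- run_miprest(mix$X, K = 6, n_ensembles = 8, seed = 4)
#' fit$classification$labels
#' }
#' @export
run_miprest <- function(X, N_s = nrow(X), K = 30L, n_ensembles = 30L,
                        factor = 2L, seed = 1L,
                        r_hi = 0.9, r_lo = 0.3, d_lo = 0.1,
                        match = c("rank", "mixing"),
                        n_null = 1000L, n_perm = 999L, alpha = 0.05,
                        level = 0.95, ...) {
  match <- match.arg(match)
  X <- check_matrix(X)
  seeds <- derive_seeds(seed, 2L * n_ensembles + 2L)
  parent <- raicar_decompose(X, N_s = N_s, K = K, seed = seeds[1], ...)
  decimated <- vector("list", n_ensembles)
  for (i in seq_len(n_ensembles)) {
    Xd <- decimate(X, factor = factor, seed = seeds[2 * i])
    decimated[[i]] <- raicar_decompose(Xd, N_s = N_s, K = K,
                                       seed = seeds[2 * i + 1], ...)
  }
  dt <- delta_table(parent, decimated, match = match)
  cls <- classify_sources(dt, r_hi = r_hi, r_lo = r_lo, d_lo = d_lo)
  resid <- project_out_sparse(X, parent, which(cls$labels == "sparse"))
  eig <- subspace_dim(resid, n_null = n_null, n_perm = n_perm, alpha = alpha,
                      level = level, seed = seeds[2L * n_ensembles + 2L])
  structure(list(parent = parent, delta = dt, classification = cls,
                 residual = resid, eigen = eig,
                 config = list(N_s = N_s, K = K, n_ensembles = n_ensembles,
                               factor = factor, seed = seed,
                               thresholds = c(r_hi = r_hi, r_lo = r_lo,
                                              d_lo = d_lo),
                               match = match)),
            class = "miprest")
}

#' @export
print.miprest <- function(x, ...) {
  cat(sprintf("MIPReSt decomposition of a %d x %d matrix\n",
              nrow(x$residual), ncol(x$residual)))
  cat(sprintf("  K = %d, ensembles = %d (factor %d), seed = %s\n",
              x$config$K, x$config$n_ensembles, x$config$factor,
              format(x$config$seed)))
  print(x$classification)
  cat("Residual Gaussian subspace:\n")
  print(x$eigen)
  invisible(x)
}
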