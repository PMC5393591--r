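# RAICAR: ranking and averaging independent components by reproducibility.
# K seeded FastICA realizations are aligned across realizations by absolute
# cross-correlation; each aligned group's mean pairwise |corr| is its
# reproducibility R.

#' Absolute cross-correlation matrices between realizations
#'
#' For each unordered pair of realizations, computes the matrix of absolute
#' Pearson correlations between their estimated source rows: exactly
#' `K*(K-1)/2` matrices.
#'
#' @param realizations List of at least two [fastica_realization()] results on
#'   the same sample set.
#' @return List of class `crcm`; each element has the pair indices `i < j` and
#'   the `|corr|` matrix `m` (rows = components of `i`, cols = components of
#'   `j`).
#' @export
cross_correlation_matrices <- function(realizations) {
  K <- length(realizations)
  if (K < 2) stop("need at least 2 realizations")
  ps <- vapply(realizations, function(r) ncol(r$S_hat), 0L)
  if (length(unique(ps)) != 1L)
    stop("realizations have mismatched sample counts")
  out <- list()
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      Si <- realizations[[i]]$S_hat
      Sj <- realizations[[j]]$S_hat
      m <- if (nrow(Si) && nrow(Sj)) abs(cor(t(Si), t(Sj)))
           else matrix(0, nrow(Si), nrow(Sj))
      out[[paste0(i, ":", j)]] <- list(i = i, j = j, m = m)
    }
  }
  structure(out, class = "crcm", K = K)
}

# |corr| between component a_c of realization a and b_c of realization b
crcm_entry <- function(crcm, a, a_c, b, b_c) {
  if (a < b) crcm[[paste0(a, ":", b)]]$m[a_c, b_c]
  else crcm[[paste0(b, ":", a)]]$m[b_c, a_c]
}

#' Greedy alignment of components across realizations
#'
#' Re-sorts `K` sets of components into at most `N_s` groups: repeatedly find
#' the largest remaining `|corr|` entry over all pair matrices, seed a group
#' with that pair, extend the group with the best-matching unused component
#' from every other realization (scored by summed `|corr|` to the two seed
#' members), and mark the members used. Leftover components that can no
#' longer be paired become singleton groups; if fewer than `N_s` groups can
#' be formed (realizations delivered fewer components), empty groups pad the
#' result, and these carry reproducibility 0.
#'
#' @param crcm Result of [cross_correlation_matrices()].
#' @param K Number of realizations.
#' @param N_s Number of groups to form.
#' @return List of `N_s` groups; each group is a two-column matrix
#'   (`realization`, `component`), possibly with zero rows.
#' @export
align_components <- function(crcm, K, N_s) {
  n_comp <- integer(K)
  for (e in unclass(crcm)) {
    n_comp[e$i] <- nrow(e$m)
    n_comp[e$j] <- ncol(e$m)
  }
  used <- lapply(n_comp, function(n) rep(FALSE, n))
  groups <- list()

  best_pair <- function() {
    bv <- -Inf; ba <- NULL
    for (e in unclass(crcm)) {
      if (!nrow(e$m) || !ncol(e$m)) next
      m <- e$m
      m[used[[e$i]], ] <- -Inf
      m[, used[[e$j]]] <- -Inf
      if (!length(m) || max(m) <= bv) next
      idx <- arrayInd(which.max(m), dim(m))
      bv <- m[idx]
      ba <- c(e$i, idx[1], e$j, idx[2])
    }
    if (is.null(ba)) NULL else ba
  }

  while (length(groups) < N_s) {
    bp <- best_pair()
    if (is.null(bp)) break
    a <- bp[1]; ia <- bp[2]; b <- bp[3]; jb <- bp[4]
    used[[a]][ia] <- TRUE
    used[[b]][jb] <- TRUE
    members <- rbind(c(a, ia), c(b, jb))
    for (cc in setdiff(seq_len(K), c(a, b))) {
      cand <- which(!used[[cc]])
      if (!length(cand)) next
      score <- vapply(cand, function(m)
        crcm_entry(crcm, a, ia, cc, m) + crcm_entry(crcm, b, jb, cc, m), 0)
      pick <- cand[which.max(score)]
      used[[cc]][pick] <- TRUE
      members <- rbind(members, c(cc, pick))
    }
    colnames(members) <- c("realization", "component")
    groups[[length(groups) + 1L]] <- members
  }
  # leftovers that could not be paired -> singleton groups
  for (k in seq_len(K)) {
    for (m in which(!used[[k]])) {
      if (length(groups) >= N_s) break
      used[[k]][m] <- TRUE
      g <- matrix(c(k, m), 1, 2,
                  dimnames = list(NULL, c("realization", "component")))
      groups[[length(groups) + 1L]] <- g
    }
  }
  while (length(groups) < N_s) {
    g <- matrix(integer(0), 0, 2,
                dimnames = list(NULL, c("realization", "component")))
    groups[[length(groups) + 1L]] <- g
  }
  groups
}

#' Reproducibility of an aligned group
#'
#' Mean absolute pairwise cross-correlation over all member pairs of the group
#' (the unthresholded variant). Groups with fewer than two members — including
#' groups left empty by dropped components — have reproducibility 0.
#'
#' @param group Two-column member matrix as produced by [align_components()].
#' @param crcm Result of [cross_correlation_matrices()].
#' @return A value in `[0, 1]`.
#' @export
reproducibility <- function(group, crcm) {
  n <- nrow(group)
  if (is.null(n) || n < 2) return(0)
  tot <- 0; cnt <- 0L
  for (u in seq_len(n - 1)) {
    for (v in seq(u + 1, n)) {
      tot <- tot + crcm_entry(crcm, group[u, 1], group[u, 2],
                              group[v, 1], group[v, 2])
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

#' RAICAR decomposition
#'
#' Runs `K` seeded FastICA realizations of `X`, aligns components across
#' realizations, computes the reproducibility of every aligned group, and
#' returns groups sorted by descending reproducibility together with
#' sign-aligned averaged sources (re-standardized to unit variance) and
#' averaged mixing columns.
#'
#' @param X Numeric matrix `N` x `p`.
#' @param N_s Number of sources to extract per realization, at most `N`
#'   (default `nrow(X)`).
#' @param K Number of realizations. Default 30.
#' @param seed Integer seed; realization seeds are derived from it.
#' @param ... Passed to [fastica_realization()] (`tol`, `max_iter`,
#'   `exhaust_tol`).
#' @return Object of class `raicar`: list with `R` (length `N_s`, sorted
#'   descending), `groups`, `S_avg` (`N_s` x `p`; zero rows for empty
#'   groups), `A_avg` (`N` x `N_s`), `K`, `N_s`, and `seed`.
#' @examples
#' mix <- make_mixture(list(source_spec("laplace"), source_spec("inverse_cosh")),
#'                     n = 2000, mix_rows = 2, seed = 5)
#' res <- raicar_decompose(mix$X, K = 4, seed = 9)
#' res$R
#' @export
raicar_decompose <- function(X, N_s = nrow(X), K = 30L, seed = 1L, ...) {
  X <- check_matrix(X)
  if (N_s > nrow(X)) stop("'N_s' must be at most nrow(X)")
  seeds <- derive_seeds(seed, K)
  realizations <- lapply(seeds, function(s)
    fastica_realization(X, N_s, seed = s, ...))
  crcm <- cross_correlation_matrices(realizations)
  groups <- align_components(crcm, K, N_s)
  R <- vapply(groups, reproducibility, 0, crcm = crcm)
  ord <- order(R, decreasing = TRUE)
  R <- R[ord]
  groups <- groups[ord]

  p <- ncol(X); N <- nrow(X)
  S_avg <- matrix(0, N_s, p)
  A_avg <- matrix(0, N, N_s)
  for (g in seq_along(groups)) {
    mem <- groups[[g]]
    if (!nrow(mem)) next
    ref <- realizations[[mem[1, 1]]]$S_hat[mem[1, 2], ]
    s_sum <- numeric(p); a_sum <- numeric(N)
    for (u in seq_len(nrow(mem))) {
      s <- realizations[[mem[u, 1]]]$S_hat[mem[u, 2], ]
      a <- realizations[[mem[u, 1]]]$A_hat[, mem[u, 2]]
      sgn <- if (u == 1) 1 else sign(cor(s, ref))
      if (sgn == 0) sgn <- 1
      s_sum <- s_sum + sgn * s
      a_sum <- a_sum + sgn * a
    }
    S_avg[g, ] <- standardize(s_sum / nrow(mem))
    A_avg[, g] <- a_sum / nrow(mem)
  }
  structure(list(R = R, groups = groups, S_avg = S_avg, A_avg = A_avg,
                 K = as.integer(K), N_s = as.integer(N_s), seed = seed),
            class = "raicar")
}

#' @export
print.raicar <- function(x, ...) {
  cat(sprintf("RAICAR decomposition: N_s = %d, K = %d realizations\n",
              x$N_s, x$K))
  cat("  R:", paste(sprintf("%.3f", x$R), collapse = " "), "\n")
  invisible(x)
}

#' Serialize / load a RAICAR result
#'
#' Writes the reproducibility table, averaged sources and mixing as
#' tab-separated text and the group membership as JSON into a directory.
#'
#' @param res A `raicar` object.
#' @param dir Output directory (created if missing).
#' @return `write_raicar` returns `dir` invisibly; `read_raicar` the restored
#'   object (class `raicar`).
#' @export
write_raicar <- function(res, dir) {
  if (!inherits(res, "raicar")) stop("'res' must be a raicar object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(matrix(res$R, ncol = 1), file.path(dir, "reproducibility.tsv"))
  write_matrix(res$S_avg, file.path(dir, "sources.tsv"))
  write_matrix(res$A_avg, file.path(dir, "mixing.tsv"))
  meta <- list(K = res$K, N_s = res$N_s, seed = res$seed,
               groups = lapply(res$groups, function(g)
                 list(realization = as.integer(g[, 1]),
                      component = as.integer(g[, 2]))))
  jsonlite::write_json(meta, file.path(dir, "groups.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_raicar
#' @export
read_raicar <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "groups.json"),
                              simplifyVector = FALSE)
  groups <- lapply(meta$groups, function(g) {
    m <- cbind(unlist(g$realization), unlist(g$component))
    if (!length(m)) m <- matrix(integer(0), 0, 2)
    colnames(m) <- c("realization", "component")
    m
  })
  structure(list(
    R = as.numeric(load_matrix(file.path(dir, "reproducibility.tsv"))),
    groups = groups,
    S_avg = load_matrix(file.path(dir, "sources.tsv")),
    A_avg = load_matrix(file.path(dir, "mixing.tsv")),
    K = meta$K, N_s = meta$N_s, seed = meta$seed),
    class = "raicar")
}
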