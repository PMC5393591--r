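# Evaluation: optimal matching of estimated sources to ground truth through
# the linear assignment problem (Hungarian/Munkres algorithm), with absolute
# correlation as the similarity (ICA recovers sources only up to sign and
# permutation).

#' Solve the linear assignment problem
#'
#' Minimizes the total cost of a one-to-one assignment of rows to columns
#' using the O(n^3) shortest-augmenting-path form of the Hungarian algorithm.
#' Rectangular matrices are handled by assigning every row when
#' `nrow <= ncol` (and symmetrically otherwise): exactly
#' `min(nrow, ncol)` pairs are matched.
#'
#' @param cost Numeric cost matrix.
#' @return Integer vector of length `nrow(cost)`: `out[i]` is the column
#'   assigned to row `i` (`NA` for unassigned rows when `nrow > ncol`).
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("'cost' must be finite")
  if (nrow(cost) > ncol(cost)) {
    # transpose, solve, invert the mapping
    colmatch <- hungarian_assignment(t(cost))
    out <- rep(NA_integer_, nrow(cost))
    out[colmatch] <- seq_along(colmatch)
    return(out)
  }
  n <- nrow(cost); m <- ncol(cost)
  # potentials u (rows), v (cols); p[j] = row currently assigned to column j;
  # index 1 is the virtual 0-column of the augmenting-path formulation
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) {
          minv[j + 1] <- cur
          way[j + 1] <- j0
        }
        if (minv[j + 1] < delta) {
          delta <- minv[j + 1]
          j1 <- j
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) out[p[j + 1]] <- j
  out
}

#' Match estimated sources to ground truth
#'
#' Solves the linear assignment problem with cost `1 - |corr|` between
#' estimated and true source rows, so that each estimate is paired with the
#' distinct true source it best recovers regardless of sign or ordering.
#'
#' @param S_est Estimated sources (`n_est` x `p`).
#' @param S_true True sources (`n_true` x `p`), same sample count.
#' @return Object of class `assignment_result`: list with `permutation`
#'   (`permutation[i]` = true-source index matched to estimate `i`, `NA` if
#'   unmatched), `pair_cor` (per matched pair `|corr|`), and `mean_cor`.
#' @examples
#' S <- matrix(rnorm(40), 2)
#' assignment_match(-S[2:1, ], S)$permutation
#' @export
assignment_match <- function(S_est, S_true) {
  S_est <- check_matrix(S_est, "S_est")
  S_true <- check_matrix(S_true, "S_true")
  if (ncol(S_est) != ncol(S_true)) stop("sample counts differ")
  ac <- abs(cor(t(S_est), t(S_true)))
  ac[!is.finite(ac)] <- 0
  perm <- hungarian_assignment(1 - ac)
  pair <- vapply(seq_len(nrow(S_est)), function(i)
    if (is.na(perm[i])) NA_real_ else ac[i, perm[i]], 0)
  structure(list(permutation = perm, pair_cor = pair,
                 mean_cor = mean(pair, na.rm = TRUE)),
            class = "assignment_result")
}

#' Summarize recovery quality by true-source kind
#'
#' Groups the matched absolute correlations of an assignment by the kind of
#' the true source (`gaussian`, `supergaussian`, `subgaussian`) and reports
#' per-kind mean, minimum and count.
#'
#' @param result An [assignment_match()] result.
#' @param kinds Character vector of true-source kinds, aligned with the rows
#'   of `S_true` used in the match.
#' @return A data frame with one row per kind: `kind`, `n`, `mean_cor`,
#'   `min_cor`.
#' @export
recovery_report <- function(result, kinds) {
  if (!inherits(result, "assignment_result"))
    stop("'result' must come from assignment_match()")
  matched <- !is.na(result$permutation)
  kind <- kinds[result$permutation[matched]]
  cors <- result$pair_cor[matched]
  out <- do.call(rbind, lapply(split(cors, kind), function(v)
    data.frame(n = length(v), mean_cor = mean(v), min_cor = min(v))))
  data.frame(kind = rownames(out), out, row.names = NULL)
}
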