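# Independent oracles used across tests.

# Excess kurtosis of a density via quadrature (moments computed directly on
# the stated density; standardization-invariant).
quadrature_excess_kurtosis <- function(density, lower = -Inf, upper = Inf) {
  m2 <- stats::integrate(function(x) x^2 * density(x), lower, upper,
                         rel.tol = 1e-10)$value
  m4 <- stats::integrate(function(x) x^4 * density(x), lower, upper,
                         rel.tol = 1e-10)$value
  m4 / m2^2 - 3
}

# Table of benchmark densities (zero-mean forms)
dens_inverse_cosh <- function(x) 0.5 / cosh(pi * x / 2)
dens_double_cosh <- function(x)                       # mixture at +/- sqrt(2)
  0.5 * (stats::dnorm(x, -sqrt(2)) + stats::dnorm(x, sqrt(2)))

sample_excess_kurtosis <- function(x) mean(x^4) / mean(x^2)^2 - 3

# Brute-force minimal assignment by exhaustive enumeration (n <= 6)
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      cc <- sum(cost[cbind(seq_len(n), p)])
      if (cc < best_cost) { best_cost <- cc; best <- p }
    }
  }
  list(assignment = best, cost = best_cost)
}

assignment_cost <- function(cost, perm) {
  ok <- !is.na(perm)
  sum(cost[cbind(which(ok), perm[ok])])
}

# Exhaustive component alignment for tiny instances: partition K realizations'
# components into groups of one-per-realization maximizing total within-group
# |corr|; returns the best list of groups (as sets of (realization, comp)).
exhaustive_alignment <- function(crcm, K, N_s) {
  stopifnot(K == 3, N_s <= 4)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  idx <- seq_len(N_s)
  best <- NULL; best_score <- -Inf
  for (p2 in perms(idx)) {
    for (p3 in perms(idx)) {
      score <- 0
      for (g in idx) {
        a <- g; b <- p2[g]; cc <- p3[g]
        score <- score +
          crcm[["1:2"]]$m[a, b] + crcm[["1:3"]]$m[a, cc] +
          crcm[["2:3"]]$m[b, cc]
      }
      if (score > best_score) {
        best_score <- score
        best <- lapply(idx, function(g)
          rbind(c(1L, g), c(2L, p2[g]), c(3L, p3[g])))
      }
    }
  }
  best
}

# canonical form for comparing group partitions (order-insensitive)
group_signature <- function(groups) {
  sig <- lapply(groups, function(g) {
    if (!nrow(g)) return("empty")
    paste(sort(paste(g[, 1], g[, 2], sep = ":")), collapse = ",")
  })
  sort(unlist(sig))
}

# standard simulated designs
design_overextraction <- function(n = 2e4, seed = 5) {
  specs <- c(lapply(1:2, function(i) source_spec("inverse_cosh")),
             lapply(1:3, function(i) source_spec("gaussian")))
  make_mixture(specs, n = n, mix_rows = 10, seed = seed)
}

design_full_rank <- function(n = 1e5, seed = 21) {
  specs <- list(source_spec("inverse_cosh"), source_spec("double_cosh"),
                source_spec("gaussian"), source_spec("gaussian"),
                source_spec("gaussian"))
  make_mixture(specs, n = n, mix_rows = 5, seed = seed)
}

design_speech <- function(n = 2e4, seed = 13) {
  specs <- c(lapply(1:5, function(i) source_spec("speech_proxy")),
             lapply(1:5, function(i) source_spec("gaussian")))
  make_mixture(specs, n = n, mix_rows = 15, seed = seed)
}

# d unit-variance Gaussian factors mixed into n_rows channels (no noise)
planted_gaussian_residual <- function(d, n_rows, p, seed) {
  specs <- lapply(seq_len(d), function(i) source_spec("gaussian"))
  make_mixture(specs, n = p, mix_rows = n_rows, seed = seed)$X
}
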