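# construct a bare ICA realization from a source matrix (tests that exercise
# alignment logic directly, without running FastICA)
fake_realization <- function(S) {
  structure(list(S_hat = S, A_hat = diag(nrow(S)),
                 converged = rep(TRUE, nrow(S)),
                 iterations = rep(1L, nrow(S)),
                 n_requested = nrow(S), seed = 0L),
            class = "ica_realization")
}

test_that("cross-correlation matrices: one per unordered pair, values in [0,1]", {
  set.seed(2)
  S <- matrix(rnorm(3 * 200), 3)
  reals <- lapply(1:4, function(i) fake_realization(S + 0.1 * matrix(rnorm(600), 3)))
  crcm <- cross_correlation_matrices(reals)
  expect_length(crcm, 4 * 3 / 2)
  for (e in unclass(crcm)) {
    expect_true(all(e$m >= 0 & e$m <= 1))
    expect_equal(dim(e$m), c(3, 3))
  }
  # identical realizations give a permutation-like matrix of ones on matches
  crcm2 <- cross_correlation_matrices(list(fake_realization(S),
                                           fake_realization(S[c(2, 3, 1), ])))
  m <- crcm2[["1:2"]]$m
  expect_equal(m[cbind(1:3, c(3, 1, 2))], rep(1, 3))
  expect_error(cross_correlation_matrices(list(fake_realization(S))),
               "at least 2")
  expect_error(
    cross_correlation_matrices(list(fake_realization(S),
                                    fake_realization(S[, 1:100]))),
    "mismatched sample counts")
})

test_that("alignment groups identical realizations into full groups", {
  set.seed(3)
  S <- matrix(rnorm(4 * 500), 4)
  K <- 5
  reals <- lapply(seq_len(K), function(i)
    fake_realization(S[sample(4), ] * sample(c(-1, 1), 4, replace = TRUE)))
  crcm <- cross_correlation_matrices(reals)
  groups <- align_components(crcm, K, 4)
  expect_length(groups, 4)
  expect_true(all(vapply(groups, nrow, 0L) == K))
  # each realization contributes at most one member per group
  for (g in groups) expect_false(anyDuplicated(g[, 1]) > 0)
  # reproducibility 1 for every group
  for (g in groups) expect_equal(reproducibility(g, crcm), 1, tolerance = 1e-12)
})

test_that("a realization missing a component yields a short group and empty
           groups pad to N_s", {
  set.seed(4)
  S <- matrix(rnorm(3 * 500), 3)
  reals <- list(fake_realization(S), fake_realization(S),
                fake_realization(S[1:2, ]))
  crcm <- cross_correlation_matrices(reals)
  groups <- align_components(crcm, 3, 3)
  sizes <- sort(vapply(groups, nrow, 0L))
  expect_equal(sizes, c(2L, 3L, 3L))
  # padding: request more groups than components exist
  groups5 <- align_components(crcm, 3, 5)
  expect_length(groups5, 5)
  expect_equal(sum(vapply(groups5, nrow, 0L) == 0), 2L)
  expect_equal(reproducibility(groups5[[5]], crcm), 0)
})

test_that("greedy alignment matches the exhaustive oracle on a separated
           3x3 instance", {
  set.seed(5)
  base <- matrix(rnorm(3 * 2000), 3)
  reals <- lapply(1:3, function(i) {
    noisy <- base + 0.05 * matrix(rnorm(6000), 3)
    fake_realization(noisy[sample(3), , drop = FALSE])
  })
  crcm <- cross_correlation_matrices(reals)
  greedy <- align_components(crcm, 3, 3)
  oracle <- exhaustive_alignment(crcm, 3, 3)
  expect_equal(group_signature(greedy), group_signature(oracle))
})

test_that("reproducibility of independent noise components is near zero", {
  set.seed(6)
  p <- 1e4
  reals <- lapply(1:4, function(i) fake_realization(matrix(rnorm(p), 1)))
  crcm <- cross_correlation_matrices(reals)
  g <- cbind(1:4, rep(1L, 4))
  expect_lt(reproducibility(g, crcm), 0.05)
  # singleton group
  expect_equal(reproducibility(cbind(1L, 1L), crcm), 0)
})

test_that("raicar results are rank-sorted, sign-invariant, and deterministic", {
  mix <- make_mixture(list(source_spec("laplace"), source_spec("inverse_cosh"),
                           source_spec("gaussian")),
                      n = 1e4, mix_rows = 3, seed = 6)
  res <- raicar_decompose(mix$X, K = 5, seed = 10)
  expect_true(all(diff(res$R) <= 0))
  expect_true(all(res$R >= 0 & res$R <= 1))
  # averaged sources are unit variance
  expect_equal(apply(res$S_avg, 1, var), rep(1, 3), tolerance = 1e-8)
  # groups never contain two members from one realization
  for (g in res$groups) if (nrow(g)) expect_false(anyDuplicated(g[, 1]) > 0)
  # determinism under fixed seed
  res2 <- raicar_decompose(mix$X, K = 5, seed = 10)
  expect_identical(res$R, res2$R)
  expect_identical(res$S_avg, res2$S_avg)
  # the two sparse sources are highly reproducible and match the truth
  # (an occasional realization lands on a local optimum, so group R can sit
  # slightly below 1 at K = 5 while the averaged source still recovers truth)
  am <- assignment_match(res$S_avg, mix$S_true)
  sparse_rows <- which(am$permutation %in% 1:2)
  expect_true(all(res$R[sparse_rows] > 0.9))
  expect_true(all(am$pair_cor[sparse_rows] > 0.99))
})

test_that("a single replicated sparse source gives one perfect group and
           empty remainder", {
  s <- sample_source(source_spec("laplace"), 5000, seed = 3)
  X <- rbind(s, 0.5 * s) + 1e-6 * matrix(rnorm(10000), 2)  # rank ~1
  res <- raicar_decompose(X, N_s = 2, K = 4, seed = 5)
  expect_equal(res$R[1], 1, tolerance = 1e-6)
  expect_equal(res$R[2], 0)
  expect_equal(abs(cor(res$S_avg[1, ], s)), 1, tolerance = 1e-4)
})

test_that("raicar serialization round-trips", {
  mix <- make_mixture(list(source_spec("laplace"), source_spec("gaussian")),
                      n = 3000, mix_rows = 2, seed = 2)
  res <- raicar_decompose(mix$X, K = 3, seed = 4)
  dir <- tempfile("raicar")
  write_raicar(res, dir)
  back <- read_raicar(dir)
  expect_equal(back$R, res$R, tolerance = 1e-12)
  expect_equal(back$S_avg, res$S_avg, tolerance = 1e-12)
  expect_equal(back$A_avg, res$A_avg, tolerance = 1e-12)
  expect_equal(back$groups, res$groups, ignore_attr = TRUE)
})
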