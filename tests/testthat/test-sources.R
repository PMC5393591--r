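test_that("standardize gives exact zero mean, unit variance, preserves order", {
  v <- standardize(c(1, 2, 3))
  expect_equal(mean(v), 0)
  expect_equal(var(v), 1)
  expect_true(all(diff(v) > 0))
  # idempotence
  expect_equal(standardize(v), v, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "zero-variance")
  expect_error(standardize(3), "at least 2")
})

test_that("source_spec derives kinds and validates parameters", {
  expect_equal(source_spec("gaussian")$kind, "gaussian")
  expect_equal(source_spec("inverse_cosh")$kind, "supergaussian")
  expect_equal(source_spec("laplace")$kind, "supergaussian")
  expect_equal(source_spec("logistic")$kind, "supergaussian")
  expect_equal(source_spec("exp_arcsinh")$kind, "supergaussian")
  expect_equal(source_spec("speech_proxy")$kind, "supergaussian")
  expect_equal(source_spec("double_cosh")$kind, "subgaussian")
  expect_equal(source_spec("exp_sinh")$kind, "subgaussian")
  expect_equal(source_spec("gen_gaussian", beta = 1)$kind, "supergaussian")
  expect_equal(source_spec("gen_gaussian", beta = 4)$kind, "subgaussian")
  expect_error(source_spec("gen_gaussian", beta = 2), "exactly Gaussian")
  expect_error(source_spec("cauchy"), "unknown source law")
  expect_error(source_spec("exp_arcsinh", alpha = -1), "positive")
})

test_that("samples are standardized and reproducible under a fixed seed", {
  for (law in c("gaussian", "laplace", "exp_sinh", "speech_proxy")) {
    x <- sample_source(source_spec(law), 1e4, seed = 7)
    expect_equal(mean(x), 0, tolerance = 1e-12)
    expect_equal(var(x), 1, tolerance = 1e-12)
    expect_identical(x, sample_source(source_spec(law), 1e4, seed = 7))
  }
  expect_error(sample_source(source_spec("laplace"), 1, seed = 1), "at least 2")
})

test_that("sampled kurtosis agrees with closed-form / quadrature oracles", {
  n <- 1e6
  # Laplace: excess kurtosis 3 exactly (closed form)
  x <- sample_source(source_spec("laplace"), n, seed = 11)
  expect_equal(sample_excess_kurtosis(x), 3, tolerance = 0.25)
  # hyperbolic secant: oracle by quadrature on the stated density
  k_ic <- quadrature_excess_kurtosis(dens_inverse_cosh)
  expect_equal(k_ic, 2, tolerance = 1e-6)       # known value for this law
  x <- sample_source(source_spec("inverse_cosh"), n, seed = 12)
  expect_equal(sample_excess_kurtosis(x), k_ic, tolerance = 0.2)
  # cosh-tilted Gaussian (two-component mixture): subgaussian by quadrature
  k_dc <- quadrature_excess_kurtosis(dens_double_cosh)
  expect_lt(k_dc, 0)
  x <- sample_source(source_spec("double_cosh"), n, seed = 13)
  expect_equal(sample_excess_kurtosis(x), k_dc, tolerance = 0.05)
})

test_that("every nongaussian law's kurtosis sign matches its kind", {
  n <- 2e5
  specs <- list(source_spec("inverse_cosh"), source_spec("laplace"),
                source_spec("logistic"), source_spec("exp_arcsinh"),
                source_spec("speech_proxy"), source_spec("gen_gaussian", beta = 1),
                source_spec("double_cosh"), source_spec("exp_sinh"),
                source_spec("gen_gaussian", beta = 4))
  for (sp in specs) {
    k <- sample_excess_kurtosis(sample_source(sp, n, seed = 19))
    if (sp$kind == "supergaussian") expect_gt(k, 0.2)
    else expect_lt(k, -0.2)
  }
  # the speech surrogate is far more leptokurtic than Laplace
  k_sp <- sample_excess_kurtosis(sample_source(source_spec("speech_proxy"),
                                               n, seed = 23))
  expect_gt(k_sp, 10)
})

test_that("random orthogonal mixing has orthonormal columns", {
  A <- random_orthogonal_mixing(5, 5, seed = 1)
  expect_equal(crossprod(A), diag(5), tolerance = 1e-10)
  B <- random_orthogonal_mixing(10, 5, seed = 1)
  expect_equal(crossprod(B), diag(5), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(random_orthogonal_mixing(5, 5, seed = 1),
                                random_orthogonal_mixing(5, 5, seed = 2))))
  expect_error(random_orthogonal_mixing(3, 5, seed = 1), ">=")
})

test_that("make_mixture satisfies the construction identity X = A S", {
  specs <- list(source_spec("inverse_cosh"), source_spec("double_cosh"),
                source_spec("gaussian"))
  mix <- make_mixture(specs, n = 2000, mix_rows = 5, seed = 9)
  expect_equal(dim(mix$X), c(5, 2000))
  expect_identical(mix$X, mix$A_true %*% mix$S_true)
  expect_equal(apply(mix$S_true, 1, mean), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(mix$S_true, 1, var), rep(1, 3), tolerance = 1e-12)
  expect_equal(mix$kinds, c("supergaussian", "subgaussian", "gaussian"))
  # reproducible under seed
  mix2 <- make_mixture(specs, n = 2000, mix_rows = 5, seed = 9)
  expect_identical(mix$X, mix2$X)
  expect_error(make_mixture(specs, n = 100, mix_rows = 2, seed = 1), ">=")
})

test_that("single-source mixture reproduces the source up to sign", {
  mix <- make_mixture(list(source_spec("laplace")), n = 500, mix_rows = 1,
                      seed = 4)
  expect_equal(abs(cor(mix$X[1, ], mix$S_true[1, ])), 1, tolerance = 1e-12)
})

test_that("mixture round-trips through delimited text + JSON sidecar", {
  mix <- make_mixture(list(source_spec("gen_gaussian", beta = 4),
                           source_spec("exp_arcsinh", alpha = 2)),
                      n = 50, mix_rows = 3, seed = 17)
  stem <- tempfile("mix")
  write_mixture(mix, stem)
  back <- read_mixture(stem)
  expect_equal(back$X, mix$X, tolerance = 1e-12)
  expect_equal(back$S_true, mix$S_true, tolerance = 1e-12)
  expect_equal(back$A_true, mix$A_true, tolerance = 1e-12)
  expect_equal(back$kinds, mix$kinds)
  expect_equal(back$specs[[2]]$params$alpha, 2)
})
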