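#' Specify a benchmark source distribution
#'
#' Constructs the description of one ground-truth source law used by the
#' simulated mixtures. The available laws are the standard benchmark
#' distributions for blind source separation: a standard normal, four
#' supergaussian (leptokurtic) laws, two subgaussian laws, the generalized
#' Gaussian family, and a strongly leptokurtic `speech_proxy` surrogate that
#' emulates the near-zero spike of natural speech amplitude histograms.
#'
#' Each law is labelled with a `kind` in `gaussian`, `supergaussian` or
#' `subgaussian`, derived from the law (and from `beta` for
#' `gen_gaussian`: supergaussian for `0 < beta < 2`, subgaussian for
#' `beta > 2`; `beta = 2` is exactly Gaussian and is rejected).
#'
#' @param law Character; one of `"gaussian"`, `"inverse_cosh"`, `"laplace"`,
#'   `"logistic"`, `"exp_arcsinh"`, `"double_cosh"`, `"exp_sinh"`,
#'   `"gen_gaussian"`, `"speech_proxy"`.
#' @param alpha Positive scale parameter of `exp_arcsinh` (the source is
#'   `alpha * sinh(Z)` before standardization). Default 1.
#' @param beta Positive shape parameter of `gen_gaussian`; must differ
#'   from 2. Default 1 (supergaussian); use e.g. 4 for a subgaussian source.
#' @return An object of class `source_spec`: a list with `law`, `params` and
#'   `kind`.
#' @examples
#' source_spec("inverse_cosh")
#' source_spec("gen_gaussian", beta = 4)$kind
#' @export
source_spec <- function(law, alpha = 1, beta = 1) {
  laws <- c("gaussian", "inverse_cosh", "laplace", "logistic", "exp_arcsinh",
            "double_cosh", "exp_sinh", "gen_gaussian", "speech_proxy")
  if (length(law) != 1L || !law %in% laws)
    stop("unknown source law: ", paste(law, collapse = ", "), call. = FALSE)
  params <- list()
  if (law == "exp_arcsinh") {
    if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
    params$alpha <- alpha
  }
  if (law == "gen_gaussian") {
    if (!is.finite(beta) || beta <= 0) stop("'beta' must be positive")
    if (beta == 2)
      stop("beta = 2 is exactly Gaussian; use law = \"gaussian\"")
    params$beta <- beta
  }
  kind <- switch(law,
    gaussian = "gaussian",
    inverse_cosh = , laplace = , logistic = , exp_arcsinh = ,
    speech_proxy = "supergaussian",
    double_cosh = , exp_sinh = "subgaussian",
    gen_gaussian = if (beta < 2) "supergaussian" else "subgaussian")
  structure(list(law = law, params = params, kind = kind),
            class = "source_spec")
}

#' Draw a standardized sample from a source law
#'
#' Samples `n` i.i.d. values from the law named in `spec` and standardizes the
#' result to mean 0 and sample variance 1 (all benchmark sources enter the
#' mixtures standardized). Closed-form inverse CDFs are used where available;
#' `exp_sinh` is `asinh(Z)` and `exp_arcsinh` is `alpha * sinh(Z)` with `Z`
#' standard normal; `double_cosh` is the equal mixture of unit-variance
#' normals centered at +/- sqrt(2), which is the cosh-tilted Gaussian density
#' proportional to exp(-x^2/2) * cosh(sqrt(2) x); `gen_gaussian` uses signed
#' Gamma(1/beta)^(1/beta) draws; `speech_proxy` is `gen_gaussian` with
#' beta = 0.5.
#'
#' @param spec A [source_spec()].
#' @param n Sample size, at least 2.
#' @param seed Integer seed.
#' @return Numeric vector of length `n` with mean 0 and sample variance 1.
#' @examples
#' x <- sample_source(source_spec("laplace"), 1000, seed = 1)
#' c(mean(x), var(x))
#' @export
sample_source <- function(spec, n, seed) {
  if (!inherits(spec, "source_spec")) stop("'spec' must be a source_spec")
  if (n < 2) stop("'n' must be at least 2")
  raw <- with_seed(seed, {
    u <- NULL
    switch(spec$law,
      gaussian = rnorm(n),
      inverse_cosh = {
        u <- runif(n)
        (2 / pi) * log(tan(pi * u / 2))
      },
      laplace = {
        u <- runif(n) - 0.5
        -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
      },
      logistic = stats::qlogis(runif(n), location = 0, scale = sqrt(3) / pi),
      exp_arcsinh = spec$params$alpha * sinh(rnorm(n)),
      double_cosh = rnorm(n, mean = sample(c(-1, 1), n, replace = TRUE) * sqrt(2)),
      exp_sinh = asinh(rnorm(n)),
      gen_gaussian = gen_gaussian_draw(n, spec$params$beta),
      speech_proxy = gen_gaussian_draw(n, 0.5))
  })
  standardize(raw)
}

gen_gaussian_draw <- function(n, beta) {
  s <- sample(c(-1, 1), n, replace = TRUE)
  s * rgamma(n, shape = 1 / beta, scale = 1)^(1 / beta)
}

#' Standardize a vector to mean zero, unit sample variance
#'
#' @param v Numeric vector with at least two entries and nonzero variance.
#' @return `(v - mean(v)) / sd(v)`.
#' @export
standardize <- function(v) {
  if (length(v) < 2) stop("'v' must have at least 2 entries")
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance vector")
  (v - mean(v)) / s
}

#' Random column-orthonormal mixing matrix
#'
#' Gram-Schmidt orthonormalization of a seeded `rows` x `cols` standard-normal
#' matrix, the construction used for both square and overcomplete mixing.
#'
#' @param rows,cols Matrix dimensions, `rows >= cols`.
#' @param seed Integer seed.
#' @return A `rows` x `cols` matrix `A` with `t(A) %*% A` the identity.
#' @export
random_orthogonal_mixing <- function(rows, cols, seed) {
  if (rows < cols) stop("'rows' must be >= 'cols'")
  G <- with_seed(seed, matrix(rnorm(rows * cols), rows, cols))
  A <- matrix(0, rows, cols)
  for (j in seq_len(cols)) {
    v <- G[, j]
    if (j > 1) {
      Q <- A[, seq_len(j - 1), drop = FALSE]
      v <- v - Q %*% crossprod(Q, v)
    }
    A[, j] <- v / sqrt(sum(v^2))
  }
  A
}

#' Assemble a simulated signal mixture
#'
#' Samples each source law, standardizes it, draws a random `mix_rows` x
#' `length(specs)` column-orthonormal mixing matrix, and returns
#' `X = A %*% S` with the ground truth attached. With `mix_rows` larger than
#' the number of sources this produces an overcomplete ("overmixed") dataset
#' whose true rank is the source count.
#'
#' @param specs List of [source_spec()] objects (a single spec is accepted).
#' @param n Samples per source.
#' @param mix_rows Number of mixture channels, at least `length(specs)`.
#' @param seed Integer seed controlling both sources and mixing.
#' @return An object of class `mixture`: list with `X` (`mix_rows` x `n`),
#'   `S_true`, `A_true`, `kinds` (per-source labels), and `seed`.
#' @examples
#' mix <- make_mixture(list(source_spec("laplace"), source_spec("gaussian")),
#'                     n = 500, mix_rows = 2, seed = 7)
#' dim(mix$X)
#' @export
make_mixture <- function(specs, n, mix_rows, seed) {
  if (inherits(specs, "source_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "source_spec")))
    stop("'specs' must be a list of source_spec objects")
  m <- length(specs)
  if (mix_rows < m) stop("'mix_rows' must be >= number of sources")
  seeds <- derive_seeds(seed, m + 1L)
  S <- matrix(0, m, n)
  for (i in seq_len(m)) S[i, ] <- sample_source(specs[[i]], n, seeds[i])
  A <- if (mix_rows == 1L && m == 1L) matrix(1, 1, 1)
       else random_orthogonal_mixing(mix_rows, m, seeds[m + 1L])
  structure(list(X = A %*% S, S_true = S, A_true = A,
                 kinds = vapply(specs, `[[`, "", "kind"),
                 specs = specs, seed = seed),
            class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  cat(sprintf("Simulated mixture: %d channels x %d samples, %d true sources\n",
              nrow(x$X), ncol(x$X), nrow(x$S_true)))
  cat("  kinds:", paste(x$kinds, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a mixture as delimited text with a JSON sidecar
#'
#' The data matrix is written as tab-separated text (rows = channels,
#' columns = samples) to `<path>.tsv`; ground-truth sources and mixing, when
#' present, to `<path>_sources.tsv` and `<path>_mixing.tsv`; and a JSON
#' sidecar `<path>.json` records the source laws, kinds, seed and dimensions.
#'
#' @param mix A `mixture` object (for `write_mixture`).
#' @param path File stem, without extension.
#' @return `write_mixture` returns `path` invisibly; `read_mixture` returns a
#'   `mixture` object.
#' @export
write_mixture <- function(mix, path) {
  if (!inherits(mix, "mixture")) stop("'mix' must be a mixture object")
  write_matrix(mix$X, paste0(path, ".tsv"))
  if (!is.null(mix$S_true)) write_matrix(mix$S_true, paste0(path, "_sources.tsv"))
  if (!is.null(mix$A_true)) write_matrix(mix$A_true, paste0(path, "_mixing.tsv"))
  meta <- list(
    laws = lapply(mix$specs, function(s) c(list(law = s$law), s$params)),
    kinds = mix$kinds, seed = mix$seed,
    n_channels = nrow(mix$X), n_samples = ncol(mix$X))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  specs <- lapply(meta$laws, function(l) do.call(source_spec, l))
  out <- list(X = load_matrix(paste0(path, ".tsv")), S_true = NULL,
              A_true = NULL, kinds = unlist(meta$kinds), specs = specs,
              seed = meta$seed)
  fs <- paste0(path, "_sources.tsv")
  fa <- paste0(path, "_mixing.tsv")
  if (file.exists(fs)) out$S_true <- load_matrix(fs)
  if (file.exists(fa)) out$A_true <- load_matrix(fa)
  structure(out, class = "mixture")
}
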