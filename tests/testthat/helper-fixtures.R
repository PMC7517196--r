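# Small in-code fixtures shared across test files.

# clean linear-model data with known truth
make_fixture <- function(n = 20, p = 2, alpha = 1, beta = NULL, sigma = 1,
                         seed = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- seq_len(p)
  X <- matrix(rnorm(n * p), n, p)
  y <- alpha + drop(X %*% beta) + rnorm(n, 0, sigma)
  list(data = regression_data(y, X),
       true = model_params(alpha, beta, sigma^2))
}

# a fixed tiny 5-point, one-covariate fixture for hand-checked formulas
five_point <- function() {
  x <- c(-1.2, -0.4, 0.1, 0.8, 1.5)
  y <- c(-1.0, 0.3, 0.2, 1.4, 2.1)
  regression_data(y, x)
}

# nearly-flat configuration (effectively uniform priors)
flat_config <- function(gamma = 0.2, ...) {
  fit_config(gamma = gamma, s_alpha = 1e8, s_beta = 1e8, a = 1e-8, ...)
}
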