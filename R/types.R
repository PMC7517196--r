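#' Regression data container
#'
#' Bundles a continuous response vector with its covariate matrix and
#' validates dimensions.  The design matrix must not contain an intercept
#' column; samplers that use an intercept handle it as a separate parameter.
#'
#' @param y numeric response vector of length n (no missing values).
#' @param X numeric n x p covariate matrix (no intercept column).  A vector
#'   is accepted and treated as a single column.
#' @return An object of class `"regression_data"`: a list with elements
#'   `y`, `X`, `n`, `p`.
#' @examples
#' d <- regression_data(rnorm(10), matrix(rnorm(20), 10, 2))
#' d$n; d$p
#' @export
regression_data <- function(y, X) {
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations")
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed")
  structure(list(y = y, X = X, n = n, p = ncol(X)),
            class = "regression_data")
}

#' @export
print.regression_data <- function(x, ...) {
  cat(sprintf("regression data: n = %d observations, p = %d covariates\n",
              x$n, x$p))
  invisible(x)
}

#' Model parameter point
#'
#' The (alpha, beta, sigma2) point that the MM algorithm moves.
#'
#' @param alpha intercept (scalar; use 0 for no-intercept models).
#' @param beta coefficient vector.
#' @param sigma2 error variance, strictly positive.
#' @return An object of class `"model_params"`.
#' @export
model_params <- function(alpha = 0, beta, sigma2) {
  beta <- as.numeric(beta)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  structure(list(alpha = as.numeric(alpha)[1L], beta = beta,
                 sigma2 = as.numeric(sigma2)[1L]),
            class = "model_params")
}

#' Fitting configuration
#'
#' Collects the robustness parameter gamma, prior hyperparameters, MM and
#' MCMC controls, and the seed.  The error-variance prior is
#' IG(a/2, a/2), i.e. density proportional to
#' (sigma2)^(-a/2-1) exp(-a / (2 sigma2)); `a = 2` corresponds to a
#' Ga(1, 1) prior on the precision 1/sigma2.
#'
#' @param gamma robustness tuning parameter, >= 0.  `gamma = 0` requests the
#'   exact normal likelihood (conjugate formulas); small positive values
#'   (default 0.2) give robustness with little efficiency loss.
#' @param s_alpha prior variance of the intercept (> 0).
#' @param s_beta prior covariance of beta in normal-prior mode: a scalar
#'   (multiplying the identity) or a p x p SPD matrix.
#' @param a inverse-gamma hyperparameter (> 0), see above.
#' @param c1,c2 Gamma hyperparameters (> 0) of the global shrinkage scale:
#'   lambda^2 ~ Ga(c1, c2) (Laplace) or lambda ~ Ga(c1, c2) (horseshoe).
#' @param mm_tol relative-objective convergence tolerance of the MM loop.
#' @param mm_max_iter iteration cap for standalone MM fits.
#' @param n_samples number of retained posterior draws.
#' @param n_burnin number of discarded warm-up scans (Gibbs samplers).
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(gamma = 0.2, s_alpha = 100, s_beta = 100, a = 1,
                       c1 = 1, c2 = 1, mm_tol = 1e-8, mm_max_iter = 1000L,
                       n_samples = 2000L, n_burnin = 1000L, seed = NULL) {
  stopifnot(gamma >= 0, s_alpha > 0, a > 0, c1 > 0, c2 > 0, mm_tol > 0,
            mm_max_iter >= 1, n_samples >= 0, n_burnin >= 0)
  if (is.matrix(s_beta)) {
    if (!isTRUE(all.equal(s_beta, t(s_beta))) ||
        any(eigen(s_beta, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("s_beta must be symmetric positive definite")
  } else stopifnot(s_beta > 0)
  structure(list(gamma = gamma, s_alpha = s_alpha, s_beta = s_beta, a = a,
                 c1 = c1, c2 = c2, mm_tol = mm_tol,
                 mm_max_iter = as.integer(mm_max_iter),
                 n_samples = as.integer(n_samples),
                 n_burnin = as.integer(n_burnin), seed = seed),
            class = "fit_config")
}

#' Shrinkage prior specification
#'
#' @param kind one of `"normal"`, `"laplace"` (Bayesian lasso) or
#'   `"horseshoe"`.  Both shrinkage kinds are scale mixtures of normals:
#'   beta_k | u_k ~ N(0, u_k) with u_k | lambda ~ Exp(lambda^2/2) (Laplace)
#'   or u_k | xi_k, lambda ~ IG(1/2, lambda/xi_k), xi_k ~ IG(1/2, 1)
#'   (horseshoe, for which u_k | lambda is half-Cauchy).
#' @param c1,c2 Gamma hyperparameters of the global scale (see
#'   [fit_config()]); when `NULL` the values in the fit configuration apply.
#' @return An object of class `"shrinkage_prior"`.
#' @export
shrinkage_prior <- function(kind = c("normal", "laplace", "horseshoe"),
                            c1 = NULL, c2 = NULL) {
  kind <- match.arg(kind)
  if (!is.null(c1)) stopifnot(c1 > 0)
  if (!is.null(c2)) stopifnot(c2 > 0)
  structure(list(kind = kind, c1 = c1, c2 = c2), class = "shrinkage_prior")
}

# resolve prior precision matrix for the normal-prior mode
prior_precision_normal <- function(config, p) {
  if (is.matrix(config$s_beta)) {
    if (nrow(config$s_beta) != p) stop("s_beta dimension does not match p")
    solve(config$s_beta)
  } else diag(1 / config$s_beta, p)
}

#' Bayesian-bootstrap weight validation
#'
#' Checks the invariants of a weight vector (nonnegative, summing to n) and
#' returns it unchanged.  Both the Dirichlet bootstrap weights w and the MM
#' working weights s* satisfy the same contract.
#'
#' @param w numeric weight vector.
#' @param n expected length / sum.
#' @return `w`, invisibly validated.
#' @export
bootstrap_weights <- function(w, n = length(w)) {
  w <- as.numeric(w)
  if (length(w) != n) stop("weight vector has wrong length")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - n) > 1e-8 * n) stop("weights must sum to n")
  w
}

#' Read a regression dataset from CSV
#'
#' Reads a headed CSV, takes one named column as the response and all other
#' numeric columns as covariates.
#'
#' @param path CSV file with a header row.
#' @param response name of the response column.
#' @param standardize if `TRUE`, center and scale the covariates (the
#'   response is left untouched).
#' @return A [regression_data()] object with a `"columns"` attribute naming
#'   the covariates.
#' @export
read_regression_csv <- function(path, response, standardize = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  if (!response %in% names(df))
    stop(sprintf("response column '%s' not found", response))
  y <- df[[response]]
  covs <- df[setdiff(names(df), response)]
  ok <- vapply(covs, is.numeric, logical(1L))
  if (!all(ok))
    stop(sprintf("non-numeric covariate column(s): %s",
                 paste(names(covs)[!ok], collapse = ", ")))
  X <- as.matrix(covs)
  if (standardize) X <- scale(X)
  d <- regression_data(as.numeric(y), X)
  attr(d, "columns") <- colnames(X)
  d
}
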