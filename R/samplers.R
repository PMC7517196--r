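# Posterior samplers: Bayesian-bootstrap-within-Gibbs for the synthetic
# posterior, and classical conjugate Gibbs baselines.

new_posterior_draws <- function(alpha, beta, sigma2, u = NULL, lambda = NULL,
                                xi = NULL, converged = NULL, method, prior,
                                gamma, data, config) {
  B <- length(alpha)
  if (is.null(converged)) converged <- rep(TRUE, B)
  structure(list(alpha = as.numeric(alpha),
                 beta = matrix(beta, nrow = B),
                 sigma2 = as.numeric(sigma2),
                 u = u, lambda = lambda, xi = xi,
                 converged = as.logical(converged),
                 method = method, prior = prior, gamma = gamma,
                 n = data$n, p = data$p, config = config),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior draws: %d retained, method = %s, prior = %s, gamma = %g\n",
              length(x$alpha), x$method, x$prior, x$gamma))
  if (any(!x$converged))
    cat(sprintf("  %d draw(s) flagged as MM non-converged\n",
                sum(!x$converged)))
  invisible(x)
}

#' Posterior summary: medians and equal-tailed credible intervals
#'
#' @param object a `posterior_draws` object.
#' @param level credible level, default 0.95.
#' @param ... unused.
#' @return data.frame with one row per parameter (alpha, beta_k, sigma2):
#'   posterior median, lower and upper equal-tailed interval bounds.
#' @export
summary.posterior_draws <- function(object, level = 0.95, ...) {
  lo <- (1 - level) / 2; hi <- 1 - lo
  mat <- cbind(alpha = object$alpha, object$beta, sigma2 = object$sigma2)
  colnames(mat) <- c("alpha", paste0("beta_", seq_len(object$p)), "sigma2")
  data.frame(parameter = colnames(mat),
             median = apply(mat, 2, median),
             lower = apply(mat, 2, quantile, probs = lo),
             upper = apply(mat, 2, quantile, probs = hi),
             row.names = NULL)
}

#' Draw Bayesian-bootstrap weights
#'
#' One draw of (w_1, ..., w_n) ~ n * Dirichlet(1, ..., 1): unit
#' exponentials normalized to sum exactly n.
#'
#' @param n number of observations.
#' @return nonnegative length-n vector summing to n.
#' @export
draw_dirichlet_weights <- function(n) {
  stopifnot(n >= 1)
  e <- rexp(n)
  n * e / sum(e)
}

# all-column weight matrix for a batch of bootstrap draws
draw_weight_matrix <- function(n, B) {
  W <- matrix(rexp(n * B), n, B)
  sweep(W, 2, colSums(W) / n, "/")
}

#' Bootstrap synthetic-posterior sampler (normal prior)
#'
#' Generates B independent draws from the gamma-divergence synthetic
#' posterior by the weighted likelihood bootstrap: each draw is the MM
#' minimizer of the objective under a fresh n*Dirichlet(1,...,1) weight
#' vector.  Draws are exchangeable by construction (no serial dependence);
#' the bootstrap approximation to the synthetic posterior improves with n.
#'
#' @param data a [regression_data()] object.
#' @param config a [fit_config()] with `gamma > 0`; `n_samples` draws are
#'   produced (no burn-in is needed for independent draws).
#' @param prior a [shrinkage_prior()] of kind `"normal"`.
#' @param intercept fit an intercept?
#' @return a `posterior_draws` object; MM convergence failures are flagged
#'   per draw in `$converged`.
#' @export
bootstrap_posterior <- function(data, config,
                                prior = shrinkage_prior("normal"),
                                intercept = TRUE) {
  stopifnot(inherits(prior, "shrinkage_prior"), prior$kind == "normal")
  if (config$gamma <= 0) stop("bootstrap_posterior requires gamma > 0")
  if (!is.null(config$seed)) set.seed(config$seed)
  P <- prior_precision_normal(config, data$p)
  # warm start every bootstrap solve from the uniform-weight minimizer
  init <- minimize_weighted_objective(data, rep(1, data$n), config,
                                      prior_precision = P,
                                      intercept = intercept)
  W <- draw_weight_matrix(data$n, config$n_samples)
  fit <- mm_boot_cpp(data$y, data$X, W, config$gamma, P, config$a,
                     config$s_alpha, intercept, config$mm_tol,
                     config$mm_max_iter, init$alpha, init$beta, init$sigma2)
  new_posterior_draws(fit$alpha, fit$beta, fit$sigma2,
                      converged = fit$converged,
                      method = "bootstrap", prior = "normal",
                      gamma = config$gamma, data = data, config = config)
}

#' Bootstrap-within-Gibbs sampler under shrinkage priors
#'
#' One outer scan draws fresh Dirichlet weights, runs the inner MM loop on
#' (alpha, beta, sigma2) to convergence with the scale-mixture variances
#' u_1..u_p held fixed (adopting the final values as the draw from that
#' block's full conditional), then refreshes the latent scales by their
#' exact full conditionals:
#' \itemize{
#'   \item Laplace: 1/u_k ~ inverse-Gaussian(mu = sqrt(lambda^2/beta_k^2),
#'     delta = lambda^2); lambda^2 ~ Ga(c1 + p, c2 + sum(u_k)/2).
#'   \item Horseshoe: u_k ~ IG(1, lambda/xi_k + beta_k^2/2);
#'     xi_k ~ IG(1, 1 + lambda/u_k);
#'     lambda ~ Ga(c1 + p/2, c2 + sum(1/(u_k xi_k))).
#' }
#' The inner MM warm-starts from the previous scan and is capped at 200
#' iterations per scan; failures to reach `mm_tol` are flagged, never
#' silently accepted.  |beta_k| is floored at 1e-10 in the Laplace
#' 1/u_k update to keep its mean parameter finite.
#'
#' @param data a [regression_data()] object.
#' @param config a [fit_config()] with `gamma > 0`.
#' @param prior a [shrinkage_prior()] of kind `"laplace"` or `"horseshoe"`.
#' @return a `posterior_draws` object with latent trajectories `u`,
#'   `lambda` (the global scale: sqrt(lambda^2) draws under Laplace, lambda
#'   draws under horseshoe) and, for the horseshoe, `xi`.
#' @export
gibbs_shrinkage <- function(data, config, prior) {
  stopifnot(inherits(prior, "shrinkage_prior"),
            prior$kind %in% c("laplace", "horseshoe"))
  if (config$gamma <= 0) stop("gibbs_shrinkage requires gamma > 0")
  total <- config$n_samples + config$n_burnin
  stopifnot(total >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  c1 <- if (!is.null(prior$c1)) prior$c1 else config$c1
  c2 <- if (!is.null(prior$c2)) prior$c2 else config$c2
  n <- data$n; p <- data$p
  inner_max <- min(config$mm_max_iter, 200L)

  state <- robust_init(data, intercept = TRUE)
  u <- rep(1, p); lam2 <- 1; lam <- 1; xi <- rep(1, p)
  B <- config$n_samples
  alpha_s <- numeric(B); sigma2_s <- numeric(B)
  beta_s <- matrix(0, B, p); u_s <- matrix(0, B, p)
  lambda_s <- numeric(B); conv_s <- logical(B)
  xi_s <- if (prior$kind == "horseshoe") matrix(0, B, p) else NULL

  for (t in seq_len(total)) {
    w <- draw_dirichlet_weights(n)
    fit <- mm_fit_cpp(data$y, data$X, w, config$gamma, diag(1 / u, p),
                      config$a, config$s_alpha, TRUE, config$mm_tol,
                      inner_max, state$alpha, state$beta, state$sigma2)
    state <- model_params(fit$alpha, drop(fit$beta), fit$sigma2)
    # latent scales are refreshed from a draw of beta under the converged
    # surrogate's Gaussian full conditional, not the bare minimizer: the
    # minimizer carries no conditional spread, which would starve u_k (and
    # through it lambda) of the beta_k^2 variability the exact Gibbs chain
    # has, degenerating the scale-mixture block.  The recorded regression
    # draw remains the adopted MM point.
    beta <- state$beta + rnorm(p, 0, sqrt(pmax(fit$beta_cond_var, 0)))
    if (prior$kind == "laplace") {
      babs <- pmax(abs(beta), 1e-10)
      v <- sample_inverse_gaussian(p, sqrt(lam2) / babs, lam2)
      u <- pmax(1 / v, 1e-12)
      lam2 <- rgamma(1, shape = c1 + p, rate = c2 + sum(u) / 2)
      lam <- sqrt(lam2)
    } else {
      u <- pmax((lam / xi + beta^2 / 2) / rgamma(p, shape = 1, rate = 1),
                1e-12)
      xi <- (1 + lam / u) / rgamma(p, shape = 1, rate = 1)
      lam <- rgamma(1, shape = c1 + p / 2, rate = c2 + sum(1 / (u * xi)))
    }
    k <- t - config$n_burnin
    if (k >= 1) {
      alpha_s[k] <- state$alpha; beta_s[k, ] <- state$beta
      sigma2_s[k] <- state$sigma2; u_s[k, ] <- u
      lambda_s[k] <- lam; conv_s[k] <- fit$converged
      if (!is.null(xi_s)) xi_s[k, ] <- xi
    }
  }
  new_posterior_draws(alpha_s, beta_s, sigma2_s, u = u_s, lambda = lambda_s,
                      xi = xi_s, converged = conv_s,
                      method = "bootstrap_gibbs", prior = prior$kind,
                      gamma = config$gamma, data = data, config = config)
}

#' Conjugate Gibbs baselines under the exact normal likelihood
#'
#' Non-robust comparison arms: the standard normal-model posterior
#' (normal prior on coefficients; flat limits via a large `s_beta`) and the
#' classical Bayesian lasso (Laplace prior through the exponential scale
#' mixture).  All full conditionals are conjugate: (alpha, beta) jointly
#' normal, sigma2 inverse-gamma IG(a/2 + n/2, (a + RSS)/2), and the
#' Laplace latents exactly as in [gibbs_shrinkage()].
#'
#' @param data a [regression_data()] object.
#' @param config a [fit_config()]; `gamma` is ignored (the likelihood is
#'   the exact normal one).
#' @param prior a [shrinkage_prior()] of kind `"normal"` or `"laplace"`.
#' @param intercept fit an intercept?
#' @return a `posterior_draws` object.
#' @export
baseline_gibbs <- function(data, config, prior = shrinkage_prior("normal"),
                           intercept = TRUE) {
  stopifnot(inherits(prior, "shrinkage_prior"),
            prior$kind %in% c("normal", "laplace"))
  if (!is.null(config$seed)) set.seed(config$seed)
  c1 <- if (!is.null(prior$c1)) prior$c1 else config$c1
  c2 <- if (!is.null(prior$c2)) prior$c2 else config$c2
  n <- data$n; p <- data$p
  Xa <- if (intercept) cbind(1, data$X) else data$X
  q <- ncol(Xa)
  XtX <- crossprod(Xa)
  Xty <- crossprod(Xa, data$y)
  total <- config$n_samples + config$n_burnin
  B <- config$n_samples
  u <- rep(1, p); lam2 <- 1
  sigma2 <- max(var(data$y), 1e-8)
  coefs <- numeric(q)
  alpha_s <- numeric(B); sigma2_s <- numeric(B)
  beta_s <- matrix(0, B, p); u_s <- matrix(0, B, p); lambda_s <- numeric(B)

  prior_prec <- function() {
    Pb <- if (prior$kind == "laplace") diag(1 / u, p)
          else prior_precision_normal(config, p)
    if (intercept) {
      P <- matrix(0, q, q)
      P[1, 1] <- 1 / config$s_alpha
      P[-1, -1] <- Pb
      P
    } else Pb
  }
  for (t in seq_len(total)) {
    A <- XtX / sigma2 + prior_prec()
    R <- chol(A)
    m <- backsolve(R, forwardsolve(t(R), Xty / sigma2))
    coefs <- drop(m + backsolve(R, rnorm(q)))
    r <- data$y - drop(Xa %*% coefs)
    sigma2 <- 1 / rgamma(1, shape = config$a / 2 + n / 2,
                         rate = (config$a + sum(r^2)) / 2)
    if (prior$kind == "laplace") {
      beta <- if (intercept) coefs[-1L] else coefs
      babs <- pmax(abs(beta), 1e-10)
      v <- sample_inverse_gaussian(p, sqrt(lam2) / babs, lam2)
      u <- 1 / v
      lam2 <- rgamma(1, shape = c1 + p, rate = c2 + sum(u) / 2)
    }
    k <- t - config$n_burnin
    if (k >= 1) {
      alpha_s[k] <- if (intercept) coefs[1L] else 0
      beta_s[k, ] <- if (intercept) coefs[-1L] else coefs
      sigma2_s[k] <- sigma2
      u_s[k, ] <- u
      lambda_s[k] <- sqrt(lam2)
    }
  }
  new_posterior_draws(alpha_s, beta_s, sigma2_s,
                      u = if (prior$kind == "laplace") u_s else NULL,
                      lambda = if (prior$kind == "laplace") lambda_s else NULL,
                      converged = rep(TRUE, B),
                      method = "conjugate_gibbs", prior = prior$kind,
                      gamma = 0, data = data, config = config)
}

#' Flatten draws to a data frame / write to CSV with a JSON sidecar
#'
#' One row per retained draw; columns `alpha`, `beta_1..beta_p`, `sigma2`
#' and, where present, `u_1..u_p`, `lambda`, `xi_1..xi_p`.
#'
#' @param draws a `posterior_draws` object.
#' @param path optional CSV path; when given, a `<path>.json` sidecar with
#'   the fit configuration and convergence flags is written alongside.
#' @return the data frame, invisibly when `path` is given.
#' @export
draws_to_frame <- function(draws, path = NULL) {
  df <- data.frame(alpha = draws$alpha, draws$beta, sigma2 = draws$sigma2)
  names(df) <- c("alpha", paste0("beta_", seq_len(draws$p)), "sigma2")
  if (!is.null(draws$u)) {
    u <- as.data.frame(draws$u); names(u) <- paste0("u_", seq_len(draws$p))
    df <- cbind(df, u, lambda = draws$lambda)
  }
  if (!is.null(draws$xi)) {
    xi <- as.data.frame(draws$xi); names(xi) <- paste0("xi_", seq_len(draws$p))
    df <- cbind(df, xi)
  }
  if (is.null(path)) return(df)
  write.csv(df, path, row.names = FALSE)
  cfg <- draws$config
  cfg$s_beta <- if (is.matrix(cfg$s_beta)) as.vector(cfg$s_beta) else cfg$s_beta
  jsonlite::write_json(
    list(method = draws$method, prior = draws$prior, gamma = draws$gamma,
         n = draws$n, p = draws$p, config = unclass(cfg),
         converged = draws$converged),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(df)
}
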