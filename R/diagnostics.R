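# Robustness diagnostics: Bayesian influence functions for posterior means,
# Kullback-Leibler distance to a clean-data oracle posterior, and the
# frequentist interval metrics used in contamination experiments.

#' Contamination derivative H(theta, z | x)
#'
#' The derivative of the (pseudo-)likelihood under point contamination at
#' residual z, evaluated for the simple model y = alpha + beta x + eps with
#' true data density g(.|x) = N(x, 1).  Under the standard likelihood
#' \deqn{H = \log f(\alpha+\beta x+z \mid x;\theta) - E_g \log f(t|x;\theta),}
#' which is unbounded (quadratic) in z; under the gamma-divergence
#' \deqn{H = \frac{1}{\gamma}\Big\{\frac{f(\alpha+\beta x+z|x;\theta)^\gamma}
#'   {E_g f(t|x;\theta)^\gamma} - 1\Big\},}
#' which is bounded and tends to -1/gamma as |z| grows -- the mechanism
#' behind the redescending influence function.  The expectation over g is
#' approximated by Monte Carlo (default 2000 draws).
#'
#' @param params a [model_params()] with a single slope coefficient.
#' @param z contamination residual (scalar).
#' @param x covariate value at which the contamination is placed.
#' @param method `"standard"` or `"gamma"`.
#' @param gamma robustness parameter (> 0, gamma method only).
#' @param mc_draws Monte Carlo sample size for the integral.
#' @param mc_sample optional pre-drawn sample from g(.|x) = N(x, 1) to share
#'   across calls; overrides `mc_draws`.
#' @return a finite scalar.
#' @export
influence_h <- function(params, z, x, method = c("standard", "gamma"),
                        gamma = 0.2, mc_draws = 2000, mc_sample = NULL) {
  method <- match.arg(method)
  if (method == "gamma" && gamma <= 0) stop("gamma must be > 0")
  if (is.null(mc_sample)) mc_sample <- rnorm(mc_draws, mean = x, sd = 1)
  mu <- params$alpha + params$beta[1L] * x
  sdv <- sqrt(params$sigma2)
  logf_z <- dnorm(mu + z, mu, sdv, log = TRUE)
  logf_t <- dnorm(mc_sample, mu, sdv, log = TRUE)
  if (method == "standard") {
    logf_z - mean(logf_t)
  } else {
    (exp(gamma * logf_z) / mean(exp(gamma * logf_t)) - 1) / gamma
  }
}

#' Bayesian influence function of the posterior means
#'
#' For each parameter theta_k among (alpha, beta, sigma2) and each grid
#' point (x, z), computes
#' \deqn{IF_k(z \mid x) = n\,\mathrm{Cov}_{\theta|D}(\theta_k, H(\theta,z|x)),}
#' the sample covariance being taken across the supplied posterior draws.
#' Under the gamma-divergence H the curves redescend to ~0 for large |z|,
#' while the standard-likelihood curves grow without bound.
#'
#' @param posterior a `posterior_draws` object for the simple
#'   one-covariate model (its `n` is the n in the definition).
#' @param x_values covariate points (default the conventional c(-0.5, 1)).
#' @param z_values residual grid (default 81 points from -10 to 10).
#' @param method `"standard"` or `"gamma"`.
#' @param gamma robustness parameter for the gamma method.
#' @param mc_draws Monte Carlo sample size for the inner integral (one
#'   shared sample per x value).
#' @return an object of class `"influence_grid"`: list with `x_values`,
#'   `z_values` and `if_values`, a length(x) list of 3 x length(z) matrices
#'   with rows alpha, beta, sigma2.
#' @export
influence_function <- function(posterior, x_values = c(-0.5, 1),
                               z_values = seq(-10, 10, length.out = 81),
                               method = c("standard", "gamma"), gamma = 0.2,
                               mc_draws = 2000) {
  method <- match.arg(method)
  if (method == "gamma" && gamma <= 0) stop("gamma must be > 0")
  B <- length(posterior$alpha)
  if (B < 100) warning("fewer than 100 posterior draws: covariance estimate is noisy")
  theta <- cbind(alpha = posterior$alpha, beta = posterior$beta[, 1L],
                 sigma2 = posterior$sigma2)
  n <- posterior$n
  out <- vector("list", length(x_values))
  for (ix in seq_along(x_values)) {
    x <- x_values[ix]
    tsamp <- rnorm(mc_draws, mean = x, sd = 1)
    mu <- theta[, "alpha"] + theta[, "beta"] * x        # B
    sdv <- sqrt(theta[, "sigma2"])
    # E_g terms per draw
    d2 <- outer(-mu, tsamp, "+")                        # B x M: t - mu
    logf_t <- -0.5 * log(2 * pi * theta[, "sigma2"]) - d2^2 / (2 * theta[, "sigma2"])
    logf_z <- outer(-0.5 * log(2 * pi * theta[, "sigma2"]),
                    rep(0, length(z_values)), "+") -
      outer(1 / (2 * theta[, "sigma2"]), z_values^2)    # B x Z
    if (method == "standard") {
      H <- logf_z - rowMeans(logf_t)
    } else {
      denom <- rowMeans(exp(gamma * logf_t))            # B
      H <- (exp(gamma * logf_z) / denom - 1) / gamma
    }
    ifm <- n * cov(theta, H)                            # 3 x Z
    rownames(ifm) <- colnames(theta)
    out[[ix]] <- ifm
  }
  structure(list(x_values = x_values, z_values = z_values, if_values = out,
                 method = method, gamma = gamma),
            class = "influence_grid")
}

#' Kullback-Leibler divergence from an oracle posterior
#'
#' Estimates KL(pi* || pi) over (alpha, beta), where pi* is the oracle
#' posterior (clean data, normal likelihood) and pi the posterior under
#' scrutiny, from their draw sets.  The default estimator moment-matches
#' each draw set to a multivariate normal and applies the closed-form
#' Gaussian KL; both posteriors are unimodal and near-Gaussian at moderate
#' n, and the estimator is deterministic given the draws.  A
#' nearest-neighbour nonparametric estimator is available as a cross-check.
#'
#' @param posterior,oracle `posterior_draws` objects (the oracle is the
#'   reference distribution pi*).
#' @param method `"gaussian"` (moment matching, default) or `"knn"`
#'   (1-nearest-neighbour density-ratio estimator).
#' @return nonnegative scalar (nats); the knn estimate may go slightly
#'   negative from sampling noise.
#' @export
kl_to_oracle <- function(posterior, oracle, method = c("gaussian", "knn")) {
  method <- match.arg(method)
  draws_of <- function(d) cbind(d$alpha, d$beta[, 1L])
  P <- draws_of(oracle)    # samples from pi*
  Q <- draws_of(posterior) # samples from pi
  if (any(apply(P, 2, sd) == 0) || any(apply(Q, 2, sd) == 0))
    stop("degenerate (zero-variance) draw set")
  if (method == "gaussian") {
    m0 <- colMeans(P); S0 <- cov(P)
    m1 <- colMeans(Q); S1 <- cov(Q)
    k <- ncol(P)
    S1inv <- solve(S1)
    dm <- m1 - m0
    kl <- 0.5 * (sum(diag(S1inv %*% S0)) + drop(t(dm) %*% S1inv %*% dm) - k +
                   determinant(S1)$modulus - determinant(S0)$modulus)
    max(as.numeric(kl), 0)
  } else {
    kl_knn(P, Q)
  }
}

# 1-NN Kullback-Leibler estimator (Wang, Kulkarni & Verdu 2009):
# KL(P||Q) ~ (d/n) sum log(nu_i / rho_i) + log(m / (n - 1)),
# rho_i: distance from P_i to its nearest other point of P,
# nu_i: distance from P_i to the nearest point of Q.
kl_knn <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q); d <- ncol(P)
  nn_dist <- function(A, B, self = FALSE) {
    a2 <- rowSums(A^2); b2 <- rowSums(B^2)
    D2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
    if (self) diag(D2) <- Inf
    sqrt(pmax(apply(D2, 1, min), .Machine$double.xmin))
  }
  rho <- nn_dist(P, P, self = TRUE)
  nu <- nn_dist(P, Q)
  (d / n) * sum(log(nu / rho)) + log(m / (n - 1))
}

#' Interval-estimation metrics for simulated data
#'
#' Given posterior draws and the generative coefficients, computes the
#' standard contamination-study metrics: mean squared error of the
#' coordinatewise posterior medians
#' \eqn{p^{-1}\sum_k(\hat\beta_k-\beta_k)^2}, average length of the
#' equal-tailed credible intervals \eqn{p^{-1}\sum_k |CI_k|}, and their
#' empirical coverage \eqn{p^{-1}\sum_k 1(\beta_k \in CI_k)}.
#'
#' @param posterior a `posterior_draws` object.
#' @param true_beta generative coefficient vector (length p).
#' @param level credible level, default 0.95.
#' @return list of class `"metrics_report"`: `mse`, `al`, `cp`.
#' @export
evaluate_metrics <- function(posterior, true_beta, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(true_beta) != posterior$p)
    stop("true_beta length does not match number of coefficients")
  lo <- (1 - level) / 2
  est <- apply(posterior$beta, 2, median)
  ci <- apply(posterior$beta, 2, quantile, probs = c(lo, 1 - lo))
  structure(list(mse = mean((est - true_beta)^2),
                 al = mean(ci[2L, ] - ci[1L, ]),
                 cp = mean(true_beta >= ci[1L, ] & true_beta <= ci[2L, ])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MSE = %.4g, AL = %.4g, CP = %.3f\n", x$mse, x$al, x$cp))
  invisible(x)
}

#' @export
as.data.frame.influence_grid <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$x_values), function(ix) {
    m <- x$if_values[[ix]]
    data.frame(x = x$x_values[ix],
               z = rep(x$z_values, each = nrow(m)),
               parameter = rep(rownames(m), length(x$z_values)),
               if_value = as.vector(m))
  }))
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(mse = x$mse, al = x$al, cp = x$cp)
}

#' Plot influence-function curves
#'
#' Draws IF_k(z|x) against z, one panel per x value, for the intercept and
#' slope.  When `file` is given the plot is written as a PNG.
#'
#' @param x an `influence_grid`.
#' @param params which parameter rows to draw.
#' @param file optional PNG path.
#' @param ... passed to `matplot`.
#' @return invisibly, `x`.
#' @export
plot.influence_grid <- function(x, params = c("alpha", "beta"), file = NULL,
                                ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 480 * length(x$x_values), height = 480)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, length(x$x_values)))
  on.exit(graphics::par(old), add = TRUE)
  for (ix in seq_along(x$x_values)) {
    graphics::matplot(x$z_values, t(x$if_values[[ix]][params, , drop = FALSE]),
                      type = "l", lty = 1, xlab = "z", ylab = "IF(z|x)",
                      main = sprintf("x = %g (%s)", x$x_values[ix], x$method),
                      ...)
    graphics::legend("topright", legend = params, lty = 1,
                     col = seq_along(params), bty = "n")
  }
  invisible(x)
}
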