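# gamma-divergence pseudo-likelihood, reweighted objective and MM minimizer

test_that("gamma_norm_constant matches numerical quadrature", {
  expect_equal(gamma_norm_constant(1, 0), 1)
  expect_equal(gamma_norm_constant(17.3, 0), 1)
  for (par in list(c(1, 0.5), c(4, 0.2), c(0.3, 1))) {
    s2 <- par[1]; g <- par[2]
    quad <- integrate(function(t) dnorm(t, 0, sqrt(s2))^(1 + g),
                      -Inf, Inf, rel.tol = 1e-12)$value^(1 / (1 + g))
    expect_equal(gamma_norm_constant(s2, g), quad, tolerance = 1e-10)
  }
  # independent of the mean by construction: quadrature with shifted mean
  quad <- integrate(function(t) dnorm(t, 5, 2)^(1.2), -Inf, Inf,
                    rel.tol = 1e-12)$value^(1 / 1.2)
  expect_equal(gamma_norm_constant(4, 0.2), quad, tolerance = 1e-10)
  expect_error(gamma_norm_constant(-1, 0.2), "sigma2")
})

test_that("gamma_loglik reduces to the normal log-likelihood and matches the formula", {
  d <- five_point()
  th <- model_params(0.2, 1.1, 0.8)
  mu <- 0.2 + 1.1 * d$X[, 1]
  expect_equal(gamma_loglik(th, d, 0), sum(dnorm(d$y, mu, sqrt(0.8), log = TRUE)))
  # explicit term-by-term evaluation of the pseudo-likelihood at gamma = 0.2
  g <- 0.2
  nrm <- integrate(function(t) dnorm(t, 0, sqrt(0.8))^(1 + g), -Inf, Inf,
                   rel.tol = 1e-12)$value^(1 / (1 + g))
  acc <- 0
  for (i in 1:d$n) acc <- acc + (dnorm(d$y[i], mu[i], sqrt(0.8)) / nrm)^g
  expect_equal(gamma_loglik(th, d, g), (d$n / g) * log(acc / d$n),
               tolerance = 1e-12)
  # gamma -> 0 continuity
  expect_equal(gamma_loglik(th, d, 1e-6), gamma_loglik(th, d, 0),
               tolerance = 1e-3)
  expect_error(gamma_loglik(model_params(0, 1, 1e-3), d, -0.1), "gamma")
})

test_that("an extreme outlier's term in the pseudo-likelihood vanishes", {
  # the robustness mechanism: f(y_out; .)^gamma -> 0, so the outlier's term
  # contributes nothing to the within-log average, while an on-line
  # observation contributes a full-sized term
  d <- five_point()
  th <- model_params(0.2, 1.1, 1)
  add_obs <- function(y_new, x_new) {
    regression_data(c(d$y, y_new), c(d$X[, 1], x_new))
  }
  d_far <- add_obs(0.2 + 1.1 * 0.5 + 100, 0.5)
  d_on <- add_obs(0.2 + 1.1 * 0.5, 0.5)
  # reference: same 6-point geometry but the extra term dropped from the sum
  g <- 0.2
  mu <- 0.2 + 1.1 * d$X[, 1]
  nrm <- gamma_norm_constant(1, g)
  acc5 <- sum((dnorm(d$y, mu, 1) / nrm)^g)
  ref_dropped <- (6 / g) * log(acc5 / 6)
  expect_equal(gamma_loglik(th, d_far, g), ref_dropped, tolerance = 1e-8)
  expect_gt(abs(gamma_loglik(th, d_on, g) - ref_dropped), 0.1)
  expect_true(is.finite(gamma_loglik(th, d_far, g)))
})

test_that("weighted_objective matches a loop-based evaluation of the formula", {
  d <- five_point()
  cfg <- fit_config(gamma = 0.2, s_alpha = 10, s_beta = 5, a = 1.4)
  th <- model_params(0.3, 0.9, 0.7)
  set.seed(4)
  w <- draw_dirichlet_weights(d$n)
  g <- 0.2
  mu <- 0.3 + 0.9 * d$X[, 1]
  acc <- 0
  for (i in 1:d$n) acc <- acc + w[i] * dnorm(d$y[i], mu[i], sqrt(0.7))^g
  ref <- -(d$n / g) * log(acc / d$n) + 0.9^2 / (2 * 5) + 0.3^2 / (2 * 10) +
    (1 + 1.4 / 2 - d$n * g / (2 * (1 + g))) * log(0.7) + 1.4 / (2 * 0.7)
  expect_equal(weighted_objective(th, d, w, cfg), ref, tolerance = 1e-12)
  # uniform weights, gamma = 0: penalized negative normal log-likelihood
  cfg0 <- fit_config(gamma = 0, s_alpha = 10, s_beta = 5, a = 1.4)
  ref0 <- -sum(dnorm(d$y, mu, sqrt(0.7), log = TRUE)) + 0.9^2 / (2 * 5) +
    0.3^2 / (2 * 10) + (1 + 0.7) * log(0.7) + 1.4 / (2 * 0.7)
  expect_equal(weighted_objective(th, d, rep(1, d$n), cfg0), ref0,
               tolerance = 1e-12)
  expect_error(weighted_objective(th, d, rep(2, d$n), cfg), "sum")
  expect_error(weighted_objective(model_params(0, 1, -1), d, w, cfg), "sigma2")
})

test_that("mm_weights normalizes, orders by residual and handles extremes", {
  # symmetric case: equal residuals, equal weights
  d <- regression_data(c(1, -1, 1, -1), matrix(0, 4, 1))
  s <- mm_weights(model_params(0, 0, 1), d, rep(1, 4), gamma = 0.3)
  expect_equal(s, rep(1, 4))
  # one 10-sigma outlier gets the smallest weight, < 1
  fx <- make_fixture(n = 12, p = 1, seed = 7)
  d2 <- regression_data(c(fx$data$y, fx$true$alpha + 10), rbind(fx$data$X, 0))
  s2 <- mm_weights(fx$true, d2, rep(1, d2$n), gamma = 0.2)
  expect_equal(which.min(s2), d2$n)
  expect_lt(s2[d2$n], 1)
  # sums to n over random parameter/weight draws, monotone in |residual|
  set.seed(11)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    dd <- regression_data(rnorm(n, 0, 3), matrix(rnorm(n), n, 1))
    w <- draw_dirichlet_weights(n)
    th <- model_params(rnorm(1), rnorm(1), rexp(1) + 0.1)
    s <- mm_weights(th, dd, w, gamma = runif(1, 0.05, 1))
    expect_lt(abs(sum(s) - n), 1e-10 * n)
    expect_true(all(s >= 0))
  }
  su <- mm_weights(model_params(0, 1, 1), five_point(), rep(1, 5), 0.2)
  r2 <- (five_point()$y - five_point()$X[, 1])^2
  expect_equal(order(su, decreasing = TRUE), order(r2))
  # huge residuals do not produce NaN (log-space path)
  dbig <- regression_data(c(0, 1e8), matrix(c(0, 0), 2, 1))
  sbig <- mm_weights(model_params(0, 0, 1), dbig, c(1, 1), 0.2)
  expect_equal(sum(sbig), 2)
  expect_false(anyNA(sbig))
})

test_that("mm_update reproduces the closed forms", {
  fx <- make_fixture(n = 30, p = 2, seed = 3)
  d <- fx$data
  # degenerate-prior limit: OLS and RSS/(n+2) without intercept handling
  cfg <- fit_config(gamma = 1e-12, s_alpha = 1e12, s_beta = 1e12, a = 1e-12)
  up <- mm_update(model_params(0, c(0, 0), 1), d, rep(1, d$n), cfg,
                  prior_precision = diag(1e-12, 2), intercept = FALSE)
  ols <- drop(solve(crossprod(d$X), crossprod(d$X, d$y)))
  expect_equal(up$beta, ols, tolerance = 1e-8)
  rss <- sum((d$y - drop(d$X %*% ols))^2)
  expect_equal(up$sigma2, rss / (d$n + 2), tolerance = 1e-6)
  # from-scratch linear-algebra oracle on the 5-point fixture
  d5 <- five_point()
  cfg2 <- fit_config(gamma = 0.3, s_alpha = 7, s_beta = 4, a = 1.2)
  th <- model_params(0.4, 0.8, 0.6)
  set.seed(8)
  s <- mm_weights(th, d5, draw_dirichlet_weights(5), 0.3)
  up2 <- mm_update(th, d5, s, cfg2, intercept = TRUE)
  x <- d5$X[, 1]; y <- d5$y
  a_ref <- (sum(s * (y - x * 0.8)) / 0.6) / (5 / 0.6 + 1 / 7)
  b_ref <- (sum(s * x * (y - a_ref)) / 0.6) / (sum(s * x^2) / 0.6 + 1 / 4)
  s2_ref <- (1.2 + sum(s * (y - a_ref - x * b_ref)^2)) /
    (2 + 1.2 + 5 / 1.3)
  expect_equal(up2$alpha, a_ref, tolerance = 1e-12)
  expect_equal(up2$beta, b_ref, tolerance = 1e-12)
  expect_equal(up2$sigma2, s2_ref, tolerance = 1e-12)
  # intercept mode with beta = 0: the shrunken mean
  up3 <- mm_update(model_params(0, 0, 2), d5, rep(1, 5),
                   fit_config(gamma = 0.2, s_alpha = 3), intercept = TRUE)
  expect_equal(up3$alpha, (sum(d5$y) / 2) / (5 / 2 + 1 / 3), tolerance = 1e-12)
})

test_that("MM iteration is monotone and agrees with the plain-R update loop", {
  set.seed(21)
  for (r in 1:100) {
    n <- sample(10:40, 1); p <- sample(1:3, 1)
    fx <- make_fixture(n = n, p = p, beta = rnorm(p), seed = 100 + r)
    w <- draw_dirichlet_weights(n)
    cfg <- fit_config(gamma = runif(1, 0.05, 0.8), s_alpha = 20, s_beta = 20,
                      a = 1, mm_tol = 1e-10)
    init <- model_params(rnorm(1), rnorm(p), rexp(1) + 0.2)
    fit <- minimize_weighted_objective(fx$data, w, cfg, init = init)
    expect_lte(weighted_objective(fit, fx$data, w, cfg),
               weighted_objective(init, fx$data, w, cfg) + 1e-10)
  }
  # the compiled path solves the same fixed point as the R-level updates
  fx <- make_fixture(n = 25, p = 2, seed = 5)
  cfg <- fit_config(gamma = 0.25, s_alpha = 10, s_beta = 10, a = 1,
                    mm_tol = 1e-12)
  set.seed(6)
  w <- draw_dirichlet_weights(25)
  fit <- minimize_weighted_objective(fx$data, w, cfg)
  th <- model_params(fit$alpha, fit$beta, fit$sigma2)
  for (k in 1:3) {
    s <- mm_weights(th, fx$data, w, 0.25)
    th <- mm_update(th, fx$data, s, cfg, intercept = TRUE)
  }
  expect_equal(th$alpha, fit$alpha, tolerance = 1e-6)
  expect_equal(th$beta, fit$beta, tolerance = 1e-6)
  expect_equal(th$sigma2, fit$sigma2, tolerance = 1e-6)
})

test_that("MM recovers generative parameters and the OLS limit", {
  fx <- make_fixture(n = 50, p = 2, alpha = 0.5, beta = c(1.5, -0.7), seed = 31)
  cfg <- fit_config(gamma = 0.2, s_alpha = 100, s_beta = 100, a = 1)
  fit <- minimize_weighted_objective(fx$data, rep(1, 50), cfg)
  se <- sqrt(fx$true$sigma2 / 50)
  expect_lt(abs(fit$alpha - 0.5), 2 * 3 * se)
  expect_true(all(abs(fit$beta - c(1.5, -0.7)) < 6 * se))
  # gamma -> 0 with flat priors: OLS to 1e-3 relative
  f0 <- minimize_weighted_objective(fx$data, rep(1, 50), flat_config(1e-6))
  ols <- coef(lm(fx$data$y ~ fx$data$X))
  expect_equal(f0$alpha, unname(ols[1]), tolerance = 1e-3)
  expect_equal(f0$beta, unname(ols[-1]), tolerance = 1e-3)
})

test_that("MM minimizer matches a dense grid search on a p = 1 problem", {
  fx <- make_fixture(n = 20, p = 1, alpha = 0, beta = 1.2, seed = 41)
  cfg <- fit_config(gamma = 0.2, s_beta = 50, a = 1, mm_tol = 1e-12)
  w <- rep(1, 20)
  fit <- minimize_weighted_objective(fx$data, w, cfg, intercept = FALSE)
  bg <- seq(fit$beta - 0.3, fit$beta + 0.3, length.out = 400)
  sg <- seq(max(fit$sigma2 - 0.5, 0.01), fit$sigma2 + 0.5, length.out = 400)
  vals <- outer(bg, sg, Vectorize(function(b, s2)
    weighted_objective(model_params(0, b, s2), fx$data, w, cfg,
                       intercept = FALSE)))
  ix <- which(vals == min(vals), arr.ind = TRUE)
  expect_lt(abs(bg[ix[1]] - fit$beta), diff(bg[1:2]) * 1.5)
  expect_lt(abs(sg[ix[2]] - fit$sigma2), diff(sg[1:2]) * 1.5)
})

test_that("a well-separated outlier leaves the gamma fit essentially unchanged", {
  fx <- make_fixture(n = 2000, p = 2, alpha = 1, beta = c(2, -1), seed = 51)
  cfg <- fit_config(gamma = 0.2, s_alpha = 1e8, s_beta = 1e8, a = 1e-8,
                    mm_tol = 1e-12)
  f1 <- minimize_weighted_objective(fx$data, rep(1, 2000), cfg)
  d2 <- regression_data(c(fx$data$y, 1e6), rbind(fx$data$X, c(0, 0)))
  f2 <- minimize_weighted_objective(d2, rep(1, 2001), cfg)
  expect_lt(abs(f2$alpha - f1$alpha), 1e-6)
  expect_lt(max(abs(f2$beta - f1$beta)), 1e-6)
  expect_lt(abs(f2$sigma2 - f1$sigma2), 1e-6)
})
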