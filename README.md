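# robbayesreg

Robust Bayesian linear regression with gamma-divergence synthetic
posteriors.

## What problem this solves, and for whom

Ordinary Bayesian linear regression is fragile: a handful of outlying
responses biases the coefficient posterior and inflates the error-variance
posterior, so both point estimates and credible intervals go wrong.  This
package is for analysts — biostatisticians, epidemiologists, anyone fitting
linear models to contamination-prone continuous outcomes — who want full
Bayesian uncertainty quantification that simply ignores well-separated
outliers instead of being dragged by them, including sparse settings where
shrinkage priors do variable selection at the same time.

## The method

The log-likelihood in the posterior is replaced by the gamma-divergence
pseudo-likelihood

```
R_γ(θ) = (n/γ) log{ (1/n) Σ_i ( f(y_i; α + x_i'β, σ²) / ||f||_{γ+1} )^γ },
```

giving the synthetic posterior `π_γ(θ|D) ∝ π(θ) exp{R_γ(θ)}`.  An
observation with tiny model density contributes `f^γ ≈ 0`, so extreme
outliers drop out of the average; as `γ → 0` the ordinary posterior is
recovered.  The default is `γ = 0.2`.

Draws come from a Bayesian bootstrap within Gibbs: each draw of
`(α, β, σ²)` is the minimizer of a Dirichlet-reweighted objective, found by
a Majorization–Minimization algorithm with closed-form updates (compiled,
monotone by construction, no rejection steps), while the latent scales of
the Laplace (Bayesian lasso) or horseshoe prior are refreshed by their
exact conjugate full conditionals.  Classical conjugate Gibbs samplers for
the non-robust normal model and Bayesian lasso are included as baselines,
plus robustness diagnostics: Bayesian influence functions (redescending
under the gamma-divergence, unbounded under the likelihood) and the KL
divergence from a clean-data oracle posterior.

## Worked example

Simulate the sparse contaminated design (n = 100, p = 20, 10% of errors
from N(10, 1)) and fit the robust Bayesian lasso:

```r
library(robbayesreg)

spec   <- contamination_spec("scenario", scenario_kind = "II",
                             probability_kind = "homo", omega = 0.1)
sim    <- generate_scenario_data(spec, seed = 1)
config <- fit_config(gamma = 0.2, n_samples = 1000, n_burnin = 500, seed = 2)
fit    <- gibbs_shrinkage(sim$data, config, shrinkage_prior("laplace"))
fit
#> posterior draws: 1000 retained, method = bootstrap_gibbs, prior = laplace, gamma = 0.2
#>   1 draw(s) flagged as MM non-converged

head(summary(fit), 6)
#>   parameter     median        lower     upper
#> 1     alpha  0.4204098  0.177961540 0.6236944
#> 2    beta_1  0.3345255  0.089561838 0.6098834
#> 3    beta_2  0.1886957 -0.006721927 0.4215504
#> 4    beta_3 -0.1097092 -0.387642967 0.2034836
#> 5    beta_4  0.5781505  0.338176477 0.8604597
#> 6    beta_5  0.1223361 -0.086937034 0.3177719
```

`summary()` rows are posterior medians with equal-tailed 95% intervals;
here the generative truth has `α = 0.5`, `β₁ = β₄ = 0.5` and most other
coefficients zero, and the intervals for the true signals exclude zero
while the null coefficients shrink toward it.  Comparing interval metrics
against the non-robust Bayesian lasso on the same data:

```r
evaluate_metrics(fit, sim$true$beta)
#> MSE = 0.01471, AL = 0.5066, CP = 0.950
evaluate_metrics(baseline_gibbs(sim$data, config, shrinkage_prior("laplace")),
                 sim$true$beta)
#> MSE = 0.04449, AL = 1.394, CP = 1.000
```

The robust fit has a third of the point-estimation error and intervals
less than half as long: the non-robust sampler buys its coverage with a
variance posterior inflated by the outliers.

Shell entry points wrap the same functions: `inst/cli/fit.R` fits a CSV
(`--csv data.csv --response y --prior laplace --gamma 0.2`) and
`inst/cli/simulate.R` runs replicated experiments from a YAML config; both
write draws/results, a posterior summary and a JSON run manifest.

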