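# gsscox

Group spike-and-slab lasso Cox models for pathway-structured survival
analysis.

## What it does

Predicting right-censored survival from high-dimensional molecular data
(gene expression, hundreds of patients, thousands of genes) is harder when
the grouping of genes into biological pathways is ignored.  gsscox fits a
Bayesian hierarchical Cox proportional-hazards model

    h(t | X) = h0(t) exp(X beta)

in which every coefficient carries a spike-and-slab double-exponential
(Laplace) mixture prior: a spike `de(0, s0)` that shrinks noise to exactly
zero and a slab `de(0, s1)` that leaves real effects nearly untouched.
The latent spike/slab indicators of all predictors in a group share a
group probability `theta_g ~ beta(a, b)`, so a pathway containing detected
signals lowers the penalty on its other members — bi-level selection of
groups and of individual genes.  Groups may overlap; overlapping
predictors are replicated into each of their groups and the replicate
coefficients are summed back afterwards, preserving the fitted prognostic
index exactly.

Estimation is a deterministic EM coordinate-descent algorithm: the E-step
computes each coefficient's conditional slab probability `p_j` and expected
inverse prior scale `E[S_j^-1] = (1 - p_j)/s0 + p_j/s1`; the M-step
maximizes the partial likelihood penalized by those factors,
`pl(beta) - sum_j E[S_j^-1] |beta_j|`, by cyclic coordinate descent
(compiled inner loop), then updates
`theta_g = (sum_{j in g} p_j + a - 1) / (J_g + a + b - 2)`.
Setting `s0 = s1` recovers the plain lasso Cox exactly.

Around the model the package provides Harrell's C-index, the
cross-validated partial likelihood, K-fold pre-validation, a spike-scale
path with cross-validated selection of `s0`, a six-design survival-data
simulator (block-correlated Gaussian predictors, exponential survival and
censoring), the standard expression-matrix gene filters, GMT pathway-file
input, and a small command line (`inst/cli/gsscox.R`) with
`simulate` / `fit` / `path` / `cv` subcommands.

## Worked example

Simulate the non-overlapping benchmark design (500 subjects, 1000
predictors in 20 correlated blocks, 8 true effects), fit at the
spike/slab scales `(0.02, 1)`, and score the independent test half:

```r
library(gsscox)

sim <- generate_scenario(scenario_spec(1), seed = 11)
fit <- fit_gsslasso(sim$train$x, sim$train$y,
                    groups = sim$train$groups, s0 = 0.02, s1 = 1)
fit
#> Group spike-and-slab lasso Cox fit
#>   s0 = 0.02, s1 = 1; 1000 predictors in 20 group(s) (1000 expanded)
#>   9 EM iterations (converged); deviance 2216.605
#>   8 nonzero coefficient(s)

round(coef(fit)[coef(fit) != 0], 3)
#>     x5    x20    x40   x210   x220   x240   x975   x995
#>  0.723 -0.434  0.997 -0.857 -0.802  0.912 -1.045  0.793

c_index(sim$test$y, predict(fit, sim$test$x))
#> [1] 0.8399532
```

The eight selected predictors are exactly the eight simulated signals
(true effects 0.8, -0.7, 1.0, -0.9, -0.8, 0.9, -1.0, 0.7), and the
test-set concordance of 0.84 says that for a random usable pair of test
subjects the model ranks their risks correctly 84% of the time.  The
fitted group probabilities point at the three signal-bearing groups:

```r
round(fit$theta[c(1, 2, 5, 20)], 3)
#>    g1    g2    g5   g20
#> 0.061 0.000 0.061 0.041
```

For real data, `filter_genes()` applies the usual expression filters,
`read_gmt()` loads pathway membership, and `fit_path()` selects `s0` over
a grid by cross-validated partial likelihood.

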