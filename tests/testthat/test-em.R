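test_that("double-exponential density follows the (1/s) exp(-|b|/s) form", {
  expect_equal(de_density(0, 1), 1)
  expect_equal(de_density(0, 0.02), 50)
  expect_equal(de_density(1, 1), exp(-1))
  expect_error(de_density(1, 0), "positive")
})

test_that("inclusion probability matches its closed form and is monotone", {
  pr <- ss_prior(s0 = 0.02, s1 = 1)
  expect_equal(inclusion_prob(0, 0.5, pr), 1 / 51, tolerance = 1e-12)
  expect_equal(inclusion_prob(c(0, 1, 5), 0, pr), c(0, 0, 0))
  expect_equal(inclusion_prob(c(0, 2), 1, pr), c(1, 1))
  expect_equal(inclusion_prob(10, 0.5, pr), 1, tolerance = 1e-12)
  # monotone nondecreasing in |beta| at fixed theta
  for (th in c(0.1, 0.5, 0.9)) {
    p <- inclusion_prob(seq(0, 3, by = 0.05), th, pr)
    expect_true(all(diff(p) >= -1e-14))
  }
})

test_that("expected inverse scale interpolates between 1/s0 and 1/s1", {
  pr <- ss_prior(s0 = 0.02, s1 = 1)
  expect_equal(expected_inv_scale(0, pr), 50)
  expect_equal(expected_inv_scale(1, pr), 1)
  expect_equal(expected_inv_scale(0.5, pr), 25.5)
  p <- runif(100)
  s <- expected_inv_scale(p, pr)
  expect_true(all(s >= 1 - 1e-12 & s <= 50 + 1e-12))
})

test_that("group probability update matches its closed form", {
  pr1 <- ss_prior(a = 1, b = 1)
  expect_equal(update_theta(c(0.1, 0.2, 0.3, 0.4), rep(1, 4), pr1), 0.25)
  expect_equal(update_theta(1, 1L, pr1), 1)
  pr2 <- ss_prior(a = 2, b = 2)
  expect_equal(update_theta(c(0, 0), c(1, 1), pr2), 0.25)
  pr_bad <- ss_prior(a = 0.2, b = 0.2)
  expect_error(update_theta(0.5, 1L, pr_bad), "positive")
})

test_that("s0 = s1 collapses the EM fit to the uniform-penalty lasso", {
  d <- small_surv_data(n = 60, p = 8, seed = 31,
                       beta = c(1, -0.8, rep(0, 6)))
  s <- 0.08
  em <- fit_gsslasso(d$x, d$y, groups = list(a = 1:4, b = 5:8),
                     s0 = s, s1 = s, standardize = FALSE,
                     solver_tol = 1e-10, eps = 1e-12, warn = FALSE)
  lasso <- fit_weighted_l1_cox(d$x, d$y, penalty_factor = rep(1 / s, 8),
                               tol = 1e-10)
  expect_lt(max(abs(coef(em) - lasso$beta[order(c(1:4, 5:8))])), 1e-8)
  # penalty factors were constant at 1/s throughout
  expect_equal(unname(em$s_inv), rep(1 / s, 8), tolerance = 1e-12)
})

test_that("the marginal log posterior ascends over EM iterations", {
  for (seed in c(32, 33)) {
    d <- small_surv_data(n = 80, p = 10, seed = seed,
                         beta = c(1, -0.8, rep(0, 8)))
    fit <- fit_gsslasso(d$x, d$y, groups = list(a = 1:5, b = 6:10),
                        s0 = 0.05, s1 = 1, warn = FALSE)
    expect_true(all(diff(fit$logpost_trace) >= -1e-6))
  }
})

test_that("expected log joint posterior has its closed form at the start", {
  d <- small_surv_data(n = 30, p = 6, seed = 34)
  y <- d$y
  pr <- ss_prior(s0 = 0.02, s1 = 1, a = 1, b = 1)
  group <- rep(1:2, each = 3)
  lp <- log_joint_posterior(beta = rep(0, 6), p = rep(0.5, 6),
                            theta = c(0.5, 0.5), group = group,
                            eta = rep(0, 30), y = y, prior = pr)
  expect_equal(lp, cox_partial_loglik(rep(0, 30), y) + 6 * log(0.5),
               tolerance = 1e-10)
  # invariant to group relabeling
  lp2 <- log_joint_posterior(beta = rep(0, 6), p = rep(0.5, 6),
                             theta = c(0.5, 0.5), group = 3 - group,
                             eta = rep(0, 30), y = y, prior = pr)
  expect_equal(lp, lp2)
})

test_that("EM is deterministic given the data", {
  d <- small_surv_data(n = 60, p = 8, seed = 35)
  f1 <- fit_gsslasso(d$x, d$y, groups = list(a = 1:4, b = 5:8), s0 = 0.05,
                     warn = FALSE)
  f2 <- fit_gsslasso(d$x, d$y, groups = list(a = 1:4, b = 5:8), s0 = 0.05,
                     warn = FALSE)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$theta, f2$theta)
})

test_that("signal groups end with larger slab probabilities than null groups", {
  # moderate-dimensional design: signals concentrated in group 1
  gaps <- vapply(1:5, function(r) {
    set.seed(40 + r)
    n <- 150; p <- 40
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("x", 1:p)
    beta <- numeric(p); beta[c(1, 3, 5)] <- c(1, -0.9, 0.8)
    eta <- drop(x %*% beta)
    tt <- rexp(n, exp(eta)); cc <- rexp(n, exp(rnorm(n)))
    y <- surv_outcome(pmin(tt, cc), as.numeric(cc > tt))
    gr <- split(1:p, rep(1:4, each = 10))
    fit <- fit_gsslasso(x, y, groups = gr, s0 = 0.04, s1 = 1, warn = FALSE)
    fit$theta[1] - max(fit$theta[2:4])
  }, 0)
  expect_gt(median(gaps), 0)
})

test_that("overlapping groups fit collapses onto the original predictors", {
  d <- small_surv_data(n = 100, p = 10, seed = 36,
                       beta = c(1.2, rep(0, 8), -1))
  gr <- list(a = 1:6, b = 5:10)         # predictors 5, 6 shared
  fit <- fit_gsslasso(d$x, d$y, groups = gr, s0 = 0.05, warn = FALSE)
  expect_length(coef(fit), 10)
  expect_length(fit$beta_expanded, 12)
  # linear predictor identity between expanded and collapsed forms
  expect_equal(unname(predict(fit, d$x)),
               unname(drop(d$x %*% coef(fit))), tolerance = 1e-12)
})

test_that("unpenalized covariates bypass the prior machinery", {
  d <- small_surv_data(n = 80, p = 6, seed = 37, beta = c(1, rep(0, 5)))
  set.seed(38)
  clin <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "age"))
  fit <- fit_gsslasso(d$x, d$y, groups = list(a = 1:3, b = 4:6),
                      s0 = 0.02, s1 = 0.02,  # maximal shrinkage on genes
                      x_unpen = clin, warn = FALSE)
  expect_length(fit$beta_unpen, 1)
  # the E-step state covers only the penalized expanded columns
  expect_length(fit$p, 6)
  eta <- predict(fit, d$x, newx_unpen = clin)
  expect_length(eta, 80)
  expect_error(predict(fit, d$x), "newx_unpen")
})

test_that("prior specification is validated", {
  expect_error(ss_prior(s0 = -0.1), "positive")
  expect_error(ss_prior(s0 = 2, s1 = 1), "s0 <= s1")
  expect_error(ss_prior(a = 0), "positive")
})
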