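test_that("partial log-likelihood matches direct risk-set evaluation", {
  y <- surv_outcome(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cox_partial_loglik(rep(0, 3), y), log(1/3) + log(1/2) + log(1),
               tolerance = 1e-12)
  expect_equal(cox_deviance(rep(0, 3), y), 3.583519, tolerance = 1e-6)

  for (seed in 1:3) {
    d <- small_surv_data(n = 25, seed = seed)
    eta <- rnorm(25)
    expect_equal(cox_partial_loglik(eta, d$y),
                 pl_brute(eta, d$y$time, d$y$status), tolerance = 1e-10)
  }
})

test_that("partial log-likelihood is invariant to shifting eta", {
  d <- small_surv_data(n = 30, seed = 4)
  eta <- rnorm(30)
  for (ties in c("breslow", "efron")) {
    expect_equal(cox_partial_loglik(eta, d$y, ties),
                 cox_partial_loglik(eta + 17.3, d$y, ties), tolerance = 1e-10)
  }
})

test_that("Breslow and Efron agree exactly without ties, differ with ties", {
  d <- small_surv_data(n = 30, seed = 5)
  eta <- rnorm(30)
  expect_equal(cox_partial_loglik(eta, d$y, "breslow"),
               cox_partial_loglik(eta, d$y, "efron"), tolerance = 1e-12)
  dt <- small_surv_data(n = 30, seed = 5, tie_times = TRUE)
  expect_false(isTRUE(all.equal(cox_partial_loglik(eta, dt$y, "breslow"),
                                cox_partial_loglik(eta, dt$y, "efron"))))
})

test_that("both tie corrections reproduce survival::coxph log-likelihoods", {
  dt <- small_surv_data(n = 35, p = 3, seed = 6, tie_times = TRUE)
  beta <- c(0.3, -0.2, 0.1)
  eta <- drop(dt$x %*% beta)
  for (ties in c("breslow", "efron")) {
    cp <- survival::coxph(survival::Surv(dt$y$time, dt$y$status) ~ dt$x,
                          ties = ties, init = beta,
                          control = survival::coxph.control(iter.max = 0))
    expect_equal(cox_partial_loglik(eta, dt$y, ties), cp$loglik[2],
                 tolerance = 1e-8)
  }
})

test_that("quadratic approximation gradient matches finite differences", {
  for (seed in c(7, 8)) {
    for (tie_times in c(FALSE, TRUE)) {
      d <- small_surv_data(n = 10, seed = seed, tie_times = tie_times)
      eta <- rnorm(10) / 2
      for (ties in c("breslow", "efron")) {
        qa <- cox_quadratic_approx(eta, d$y, ties)
        h <- 1e-5
        fd <- vapply(1:10, function(i) {
          ep <- em <- eta; ep[i] <- ep[i] + h; em[i] <- em[i] - h
          (cox_partial_loglik(ep, d$y, ties) -
             cox_partial_loglik(em, d$y, ties)) / (2 * h)
        }, 0)
        expect_lt(max(abs(fd - qa$gradient)) / max(1, max(abs(fd))), 1e-5)
      }
    }
  }
})

test_that("subject censored before every event carries no information", {
  y <- surv_outcome(c(0.5, 1, 2, 3), c(0, 1, 1, 1))
  qa <- cox_quadratic_approx(c(2, 0, 0, 0), y)
  expect_equal(qa$gradient[1], 0)
  expect_equal(qa$weights[1], 1e-8)  # floored at the documented minimum
})

test_that("one Newton step on the quadratic approximation increases pl", {
  d <- small_surv_data(n = 20, p = 2, seed = 9)
  eta0 <- rep(0, 20)
  qa <- cox_quadratic_approx(eta0, d$y)
  # unpenalized weighted least-squares refit of the working response
  w <- qa$weights
  step <- solve(crossprod(d$x, w * d$x), crossprod(d$x, w * (qa$working - eta0)))
  eta1 <- drop(d$x %*% step)
  expect_gt(cox_partial_loglik(eta1, d$y), cox_partial_loglik(eta0, d$y))
})

test_that("degenerate inputs are rejected", {
  expect_error(surv_outcome(c(1, 2), c(0, 0)), "at least one event")
  expect_error(surv_outcome(c(0, 2), c(1, 1)), "strictly positive")
  expect_error(surv_outcome(c(1, 2), c(1, 2)), "0.*or 1|status")
  y <- surv_outcome(c(1, 2), c(1, 0))
  expect_error(cox_partial_loglik(c(1, NA), y), "non-finite")
  expect_error(cox_partial_loglik(c(1, 2, 3), y), "lengths differ")
})

test_that("results are independent of input subject order", {
  d <- small_surv_data(n = 30, seed = 10, tie_times = TRUE)
  eta <- rnorm(30)
  perm <- sample(30)
  yp <- surv_outcome(d$y$time[perm], d$y$status[perm])
  for (ties in c("breslow", "efron")) {
    expect_equal(cox_partial_loglik(eta, d$y, ties),
                 cox_partial_loglik(eta[perm], yp, ties), tolerance = 1e-12)
    qa <- cox_quadratic_approx(eta, d$y, ties)
    qp <- cox_quadratic_approx(eta[perm], yp, ties)
    expect_equal(qa$gradient[perm], qp$gradient, tolerance = 1e-12)
    expect_equal(qa$weights[perm], qp$weights, tolerance = 1e-12)
  }
})
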