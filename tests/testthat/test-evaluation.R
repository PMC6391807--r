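test_that("C-index hits its extremes for perfect and inverted rankings", {
  y <- surv_outcome(c(1, 2, 3, 4, 5), rep(1, 5))
  eta <- c(5, 4, 3, 2, 1)       # higher risk -> shorter time
  expect_equal(c_index(y, eta), 1)
  expect_equal(c_index(y, -eta), 0)
  expect_equal(c_index(y, rep(0, 5)), 0.5)   # all eta tied
})

test_that("C-index agrees with a brute-force pair count and with survival", {
  for (seed in c(51, 52)) {
    d <- small_surv_data(n = 60, seed = seed, tie_times = TRUE)
    eta <- round(rnorm(60), 1)  # induce eta ties too
    ci <- c_index(d$y, eta)
    expect_equal(ci, cindex_brute(d$y$time, d$y$status, eta), tolerance = 1e-12)
    conc <- survival::concordance(
      survival::Surv(d$y$time, d$y$status) ~ eta, reverse = TRUE)
    expect_equal(ci, unname(conc$concordance), tolerance = 1e-12)
  }
})

test_that("C-index of -eta complements C-index of eta without eta ties", {
  d <- small_surv_data(n = 50, seed = 53)
  eta <- rnorm(50)
  expect_equal(c_index(d$y, eta), 1 - c_index(d$y, -eta), tolerance = 1e-12)
})

test_that("an uninformative score concentrates near one half", {
  set.seed(54)
  n <- 2000
  tt <- rexp(n); cc <- rexp(n, exp(rnorm(n)))
  y <- surv_outcome(pmin(tt, cc), as.numeric(cc > tt))
  expect_lt(abs(c_index(y, rnorm(n)) - 0.5), 0.03)
})

test_that("CVPL at the null fit matches direct evaluation of its definition", {
  d <- small_surv_data(n = 10, seed = 55)
  null_fitter <- function(x, y) numeric(ncol(x))
  folds <- make_folds(d$y$status, K = 2, seed = 1)
  got <- cvpl(null_fitter, d$x, d$y, folds = folds)
  expected <- 0
  for (k in 1:2) {
    tr <- folds != k
    ytr <- surv_outcome(d$y$time[tr], d$y$status[tr])
    expected <- expected + pl_brute(rep(0, 10), d$y$time, d$y$status) -
      pl_brute(rep(0, sum(tr)), ytr$time, ytr$status)
  }
  expect_equal(got, expected, tolerance = 1e-10)
  # finite and deterministic for K = 5 too
  expect_equal(cvpl(null_fitter, d$x, d$y, K = 5, seed = 2),
               cvpl(null_fitter, d$x, d$y, K = 5, seed = 2))
})

test_that("CVPL is invariant to subject permutation given fixed folds", {
  d <- small_surv_data(n = 30, p = 2, seed = 56)
  fitter <- function(x, y) fit_weighted_l1_cox(x, y, c(0.5, 0.5),
                                               warn = FALSE)$beta
  folds <- make_folds(d$y$status, K = 3, seed = 3)
  v1 <- cvpl(fitter, d$x, d$y, folds = folds)
  perm <- sample(30)
  yp <- surv_outcome(d$y$time[perm], d$y$status[perm])
  v2 <- cvpl(fitter, d$x[perm, ], yp, folds = folds[perm])
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("oracle coefficients beat the null fit on informative data", {
  d <- small_surv_data(n = 120, p = 4, seed = 57, beta = c(1, -0.8, 0, 0))
  oracle <- function(x, y) c(1, -0.8, 0, 0)
  null_f <- function(x, y) numeric(4)
  folds <- make_folds(d$y$status, K = 5, seed = 4)
  expect_gt(cvpl(oracle, d$x, d$y, folds = folds),
            cvpl(null_f, d$x, d$y, folds = folds))
})

test_that("pre-validation never uses a subject's own fold for its index", {
  d <- small_surv_data(n = 40, p = 2, seed = 58)
  fitter <- function(x, y) fit_weighted_l1_cox(x, y, c(0, 0),
                                               warn = FALSE)$beta
  cv <- prevalidate(fitter, d$x, d$y, K = 4, reps = 1, seed = 5)
  folds <- cv$folds[1, ]
  # corrupt the outcomes of fold 2; indices of fold-2 subjects are fitted
  # without fold 2, so they must be unchanged
  y_bad <- d$y
  tamper <- folds == 2
  y_bad$time[tamper] <- y_bad$time[tamper] * 10 + 5
  cv_bad <- prevalidate(fitter, d$x, y_bad, K = 4, reps = 1, seed = 5)
  expect_equal(cv$eta[1, tamper], cv_bad$eta[1, tamper], tolerance = 1e-10)
  # ... while other folds' indices do change
  expect_false(isTRUE(all.equal(cv$eta[1, !tamper], cv_bad$eta[1, !tamper])))
})

test_that("pre-validation is reproducible and leave-one-out works", {
  d <- small_surv_data(n = 12, p = 2, seed = 59)
  d$y$status[] <- 1  # all events so K = n folds are valid
  y <- surv_outcome(d$y$time, d$y$status)
  fitter <- function(x, y) fit_weighted_l1_cox(x, y, c(1, 1),
                                               warn = FALSE)$beta
  cv1 <- prevalidate(fitter, d$x, y, K = 12, reps = 1, seed = 6)
  cv2 <- prevalidate(fitter, d$x, y, K = 12, reps = 1, seed = 6)
  expect_identical(cv1$eta, cv2$eta)
  expect_identical(cv1$cindex, cv2$cindex)
  # each fold holds exactly one subject
  expect_equal(sort(unique(cv1$folds[1, ])), 1:12)
  expect_equal(unname(table(cv1$folds[1, ]))[1], 1)
})

test_that("folds are stratified by event status", {
  status <- c(rep(1, 12), rep(0, 28))
  f <- make_folds(status, K = 4, seed = 7)
  per_fold_events <- tapply(status, f, sum)
  expect_true(all(per_fold_events == 3))
  expect_error(make_folds(c(1, rep(0, 20)), K = 4), "fewer events")
})
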