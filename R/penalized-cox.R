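# Inner M-step solver: cyclic coordinate descent for the Cox partial
# likelihood with per-coefficient L1 penalty factors, iterating the diagonal
# quadratic (IRLS) approximation from cox_quadratic_approx().

#' Soft-thresholding operator
#'
#' The scalar coordinate-descent kernel
#' `sign(z) * max(|z| - lam, 0)`.
#'
#' @param z Numeric input (vectorized).
#' @param lam Nonnegative threshold (scalar or vector).
#' @return Thresholded values.
#' @examples
#' soft_threshold(c(2, -2, 0.3), 0.5)   # 1.5 -1.5 0.0
#' @export
soft_threshold <- function(z, lam) {
  if (any(lam < 0)) stop("'lam' must be nonnegative")
  sign(z) * pmax(abs(z) - lam, 0)
}

#' Weighted-L1 penalized Cox fit by IRLS + cyclic coordinate descent
#'
#' Maximizes `Q1(beta) = pl(beta) - sum_j pf_j * |beta_j|`, the Cox partial
#' log-likelihood penalized by per-coefficient L1 penalty factors `pf_j`
#' (the expected inverse prior scales in the EM algorithm; a constant
#' `1/s` yields the plain lasso Cox).  Each outer iteration forms the
#' diagonal quadratic approximation of the partial likelihood at the current
#' linear predictor and solves the resulting penalized weighted
#' least-squares problem by cyclic coordinate descent with soft-thresholding
#' (active-set strategy).  A step-halving safeguard keeps `Q1`
#' nondecreasing across outer iterations.
#'
#' @param x Design matrix (samples x coefficients); typically standardized,
#'   and the expanded design when groups overlap.
#' @param y A [surv_outcome] (or coercible).
#' @param penalty_factor Nonnegative penalty factor per column of `x`; `0`
#'   leaves a column unpenalized (e.g. clinical covariates), very large
#'   values force the coefficient to exactly zero.
#' @param beta_init Starting coefficients (default all zero).
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @param tol Outer convergence tolerance on the maximum absolute
#'   coefficient change.
#' @param max_iter Maximum outer (IRLS) iterations.
#' @param max_sweep Maximum coordinate-descent sweeps per inner solve.
#' @param warn Emit a warning when the outer loop hits `max_iter`.
#' @return A list with `beta` (named as the columns of `x`), `objective`
#'   (final `Q1`), `objective_trace` (per outer iteration), `iterations`,
#'   and `converged`.
#' @export
fit_weighted_l1_cox <- function(x, y, penalty_factor,
                                beta_init = NULL,
                                ties = c("breslow", "efron"),
                                tol = 1e-6, max_iter = 100, max_sweep = 10000,
                                warn = TRUE) {
  ties <- match.arg(ties)
  y <- as_surv_outcome(y)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  if (nrow(x) != y$n) stop("nrow(x) != number of subjects")
  penalty_factor <- rep_len(as.numeric(penalty_factor), p)
  if (any(!is.finite(penalty_factor)) || any(penalty_factor < 0))
    stop("penalty factors must be finite and nonnegative")
  if (tol <= 0) stop("'tol' must be positive")
  beta <- if (is.null(beta_init)) numeric(p) else rep_len(as.numeric(beta_init), p)

  obj_at <- function(b, eta) cox_partial_loglik(eta, y, ties) -
    sum(penalty_factor * abs(b))
  eta <- drop(x %*% beta)
  obj <- obj_at(beta, eta)
  obj_trace <- obj
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    qa <- cox_quadratic_approx(eta, y, ties)
    sol <- cd_wls_l1(x, qa$weights, qa$working, penalty_factor, beta,
                     tol = tol * 1e-2, max_sweep = max_sweep)
    beta_new <- sol$beta
    eta_new <- drop(x %*% beta_new)
    obj_new <- obj_at(beta_new, eta_new)
    # step-halving safeguard: the quadratic model can overshoot pl()
    half <- 0
    while (obj_new < obj - 1e-12 && half < 12) {
      beta_new <- (beta + beta_new) / 2
      eta_new <- drop(x %*% beta_new)
      obj_new <- obj_at(beta_new, eta_new)
      half <- half + 1
    }
    delta <- max(abs(beta_new - beta))
    if (obj_new >= obj) {
      beta <- beta_new
      eta <- eta_new
      obj <- obj_new
    } else delta <- 0  # halving exhausted; keep previous iterate
    obj_trace <- c(obj_trace, obj)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && it >= max_iter && warn)
    warning("fit_weighted_l1_cox: not converged after ", max_iter,
            " outer iterations; returning best iterate")
  names(beta) <- colnames(x)
  list(beta = beta, objective = obj, objective_trace = obj_trace,
       iterations = it, converged = converged)
}

#' Karush-Kuhn-Tucker check for a weighted-L1 Cox fit
#'
#' Verifies the stationarity conditions of `Q1(beta) = pl(beta) -
#' sum_j pf_j |beta_j|` at a fitted coefficient vector: for `beta_j = 0`
#' the score must satisfy `|d pl / d beta_j| <= pf_j + tol`; for
#' `beta_j != 0` it must equal `sign(beta_j) * pf_j` within `tol`.
#'
#' @inheritParams fit_weighted_l1_cox
#' @param beta Fitted coefficients to check.
#' @param tol Slack allowed on each condition.
#' @return A list with `ok` (logical), `slack` (per-coefficient violation,
#'   nonpositive when satisfied), and `gradient` (score per coefficient).
#' @export
kkt_check <- function(beta, x, y, penalty_factor,
                      ties = c("breslow", "efron"), tol = 1e-3) {
  ties <- match.arg(ties)
  y <- as_surv_outcome(y)
  x <- as.matrix(x)
  penalty_factor <- rep_len(as.numeric(penalty_factor), ncol(x))
  eta <- drop(x %*% beta)
  qa <- cox_quadratic_approx(eta, y, ties)
  g <- drop(crossprod(x, qa$gradient))   # d pl / d beta_j
  slack <- ifelse(beta == 0,
                  abs(g) - penalty_factor,
                  abs(g - sign(beta) * penalty_factor))
  viol <- ifelse(beta == 0, pmax(slack, 0), slack)
  list(ok = all(viol <= tol), slack = viol, gradient = g)
}
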