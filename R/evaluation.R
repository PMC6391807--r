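# Predictive-performance machinery: Harrell's C-index, the cross-validated
# partial likelihood, and K-fold pre-validation.

#' Harrell's concordance index
#'
#' Estimates the probability that, of two comparable subjects, the one with
#' the higher predicted risk (`eta`) fails earlier.  A pair is usable iff
#' the earlier observed time is an event (for tied observed times, an event
#' is treated as preceding a censoring at the same time; two events at the
#' same time are not comparable).  Ties in `eta` count 1/2.
#'
#' @param y A [surv_outcome] (or coercible).
#' @param eta Predicted risk score / prognostic index per subject (higher =
#'   shorter expected survival).
#' @return The concordance index in `[0, 1]`.
#' @export
c_index <- function(y, eta) {
  y <- as_surv_outcome(y)
  eta <- as.numeric(eta)
  if (length(eta) != y$n) stop("'eta' and 'y' lengths differ")
  t <- y$time; d <- y$status
  conc <- 0; usable <- 0
  for (i in which(d == 1)) {
    comp <- (t > t[i]) | (t == t[i] & d == 0)
    comp[i] <- FALSE
    nc <- sum(comp)
    if (nc == 0) next
    usable <- usable + nc
    conc <- conc + sum(eta[comp] < eta[i]) + 0.5 * sum(eta[comp] == eta[i])
  }
  if (usable == 0) stop("no usable pairs for the concordance index")
  conc / usable
}

#' Cross-validated partial likelihood
#'
#' For each fold `k`, fits on the data excluding the fold and accumulates
#' `pl(beta_hat_(-k))` evaluated on all subjects minus `pl_(-k)(beta_hat_(-k))`
#' evaluated on the retained (training) subjects, so the held-out subjects'
#' event times contribute through the full-data risk sets.
#'
#' @param fitter A function `function(x, y)` returning a coefficient vector
#'   of length `ncol(x)` (on the scale of `x`).
#' @param x Predictor matrix.
#' @param y A [surv_outcome] (or coercible).
#' @param K Number of folds (default 10).
#' @param seed Seed for the (event-stratified) fold assignment.
#' @param folds Optional explicit fold vector, overrides `K`/`seed`.
#' @param ties Tie handling for the partial likelihood.
#' @return The CVPL, a single number.
#' @export
cvpl <- function(fitter, x, y, K = 10, seed = NULL, folds = NULL,
                 ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  y <- as_surv_outcome(y)
  x <- as.matrix(x)
  if (is.null(folds)) folds <- make_folds(y$status, K, seed)
  total <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k
    ytr <- surv_outcome(y$time[tr], y$status[tr])
    beta <- fitter(x[tr, , drop = FALSE], ytr)
    eta <- drop(x %*% beta)
    total <- total + cox_partial_loglik(eta, y, ties) -
      cox_partial_loglik(eta[tr], ytr, ties)
  }
  total
}

#' K-fold pre-validation
#'
#' Splits the data into `K` event-stratified folds; for every fold, fits on
#' the remaining folds and computes the held-out subjects' prognostic
#' indices, so each subject's index never uses its own outcome.  The
#' pre-validated dataset `(t, d, eta_hat)` is then scored by the C-index
#' and by the partial likelihood of the whole data evaluated at the
#' pre-validated index (`pl`, the cross-validated partial-likelihood
#' measure reported by this package's benchmark summaries); the fold-sum
#' CVPL of [cvpl] is accumulated from the same fold fits.  The whole scheme
#' is repeated `reps` times with fresh fold draws and measures are reported
#' per replicate.
#'
#' @inheritParams cvpl
#' @param reps Number of independent fold replicates.
#' @param seed Base seed; replicate `r` uses `seed + r - 1` for its folds.
#' @return An object of class `"cv_result"`: list with `eta` (`reps` x `n`
#'   matrix of pre-validated indices), `cindex`, `pl` and `cvpl` (per
#'   replicate), `nonzero` (mean nonzero coefficient count per replicate),
#'   `folds` (`reps` x `n`), plus `K`, `reps`, `seed`.
#' @export
prevalidate <- function(fitter, x, y, K = 10, reps = 1, seed = 1,
                        ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  y <- as_surv_outcome(y)
  x <- as.matrix(x)
  n <- y$n
  eta_mat <- matrix(NA_real_, reps, n)
  fold_mat <- matrix(NA_integer_, reps, n)
  ci <- cvp <- plv <- nz <- numeric(reps)
  for (r in seq_len(reps)) {
    folds <- make_folds(y$status, K, seed + r - 1)
    fold_mat[r, ] <- folds
    eta_hat <- numeric(n)
    total <- 0
    nzk <- numeric(K)
    for (k in seq_len(K)) {
      tr <- folds != k
      ytr <- surv_outcome(y$time[tr], y$status[tr])
      beta <- fitter(x[tr, , drop = FALSE], ytr)
      nzk[k] <- sum(beta != 0)
      eta_all <- drop(x %*% beta)
      eta_hat[!tr] <- eta_all[!tr]
      total <- total + cox_partial_loglik(eta_all, y, ties) -
        cox_partial_loglik(eta_all[tr], ytr, ties)
    }
    eta_mat[r, ] <- eta_hat
    ci[r] <- c_index(y, eta_hat)
    plv[r] <- cox_partial_loglik(eta_hat, y, ties)
    cvp[r] <- total
    nz[r] <- mean(nzk)
  }
  structure(list(eta = eta_mat, cindex = ci, pl = plv, cvpl = cvp,
                 nonzero = nz, folds = fold_mat, K = K, reps = reps,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Pre-validation: K = %d, %d replicate(s)\n", x$K, x$reps))
  cat(sprintf("  C-index: %.4f (sd %.4f)\n", mean(x$cindex), sd(x$cindex)))
  cat(sprintf("  pre-validated pl: %.3f (sd %.3f)\n", mean(x$pl), sd(x$pl)))
  cat(sprintf("  fold-sum CVPL:    %.3f (sd %.3f)\n", mean(x$cvpl), sd(x$cvpl)))
  cat(sprintf("  mean nonzero coefficients: %.2f\n", mean(x$nonzero)))
  invisible(x)
}

#' Fitter factory for cross-validation of the group spike-and-slab model
#'
#' Returns a `function(x, y)` suitable for [cvpl] and [prevalidate] that
#' fits [fit_gsslasso] with the supplied settings and returns the collapsed
#' coefficients on the input scale.
#'
#' @param groups,s0,s1,... Passed on to [fit_gsslasso].
#' @return A fitter function.
#' @export
gsslasso_fitter <- function(groups = NULL, s0 = 0.02, s1 = 1, ...) {
  function(x, y) {
    fit <- fit_gsslasso(x, y, groups = groups, s0 = s0, s1 = s1,
                        warn = FALSE, ...)
    fit$beta
  }
}
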