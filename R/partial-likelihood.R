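# Cox partial log-likelihood, deviance, and the diagonal (IRLS) quadratic
# approximation that the penalized coordinate-descent solver consumes.
# Subjects are sorted by observed time internally; results are mapped back to
# input order.  Risk sets use the convention "at risk at t <=> observed
# time >= t"; event ties are grouped by exact time equality and handled by the
# Breslow or Efron approximation.

# Shared preparation on sorted data.  Returns per-event-time quantities:
#   S   risk-set sum of exp(eta) at each unique event time
#   D   number of tied events at each unique event time
#   Q   sum of exp(eta) over tied events (Efron only; 0 for Breslow)
.cox_sorted <- function(eta, y, ties) {
  ord <- order(y$time)
  t <- y$time[ord]
  d <- y$status[ord]
  ec <- eta[ord] - mean(eta)          # location invariance; numeric stability
  ee <- exp(ec)
  rs <- rev(cumsum(rev(ee)))          # sum of ee over {time >= t_k}
  ev <- which(d == 1)
  uet <- unique(t[ev])                # sorted unique event times
  pos <- match(uet, t)                # first sorted index at each event time
  grp <- match(t[ev], uet)
  D <- tabulate(grp, nbins = length(uet))
  S <- rs[pos]
  Q <- if (ties == "efron") as.numeric(rowsum(ee[ev], grp)) else numeric(length(uet))
  list(ord = ord, t = t, d = d, ec = ec, ee = ee, ev = ev,
       uet = uet, grp = grp, D = D, S = S, Q = Q)
}

#' Cox partial log-likelihood
#'
#' Evaluates the partial log-likelihood of a Cox proportional-hazards model
#' at a given linear predictor (prognostic index) `eta = X beta`:
#' the sum over events of `eta_i` minus the log of the risk-set total of
#' `exp(eta)`.  Tied event times are handled by the Breslow or the Efron
#' approximation; the two coincide when all event times are distinct.  The
#' value is invariant to adding a constant to `eta` (the baseline hazard
#' absorbs any intercept).
#'
#' @param eta Numeric linear predictor, one value per subject.
#' @param y A [surv_outcome] (or anything coercible: a `Surv` object or a
#'   data frame with `time`/`status` columns).
#' @param ties Tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return The partial log-likelihood, a single number.
#' @examples
#' y <- surv_outcome(1:3, c(1, 1, 1))
#' cox_partial_loglik(rep(0, 3), y)   # log(1/3) + log(1/2) + log(1)
#' @export
cox_partial_loglik <- function(eta, y, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  y <- as_surv_outcome(y)
  eta <- as.numeric(eta)
  if (length(eta) != y$n) stop("'eta' and 'y' lengths differ")
  if (any(!is.finite(eta))) stop("non-finite values in linear predictor")
  s <- .cox_sorted(eta, y, ties)
  # Breslow is the l = 0..D-1 sum with Q = 0, so one expression covers both.
  e_idx <- rep(seq_along(s$D), s$D)
  l <- sequence(s$D) - 1
  den <- s$S[e_idx] - (l / s$D[e_idx]) * s$Q[e_idx]
  sum(s$ec[s$ev]) - sum(log(den))
}

#' Deviance of a Cox model fit
#'
#' Returns `-2` times [cox_partial_loglik]; the quantity tracked by the EM
#' algorithm's convergence criterion.
#'
#' @inheritParams cox_partial_loglik
#' @return The deviance, a single number.
#' @export
cox_deviance <- function(eta, y, ties = c("breslow", "efron")) {
  -2 * cox_partial_loglik(eta, y, match.arg(ties))
}

#' Diagonal quadratic approximation of the Cox partial likelihood
#'
#' Computes, at the current linear predictor, the per-subject gradient of the
#' partial log-likelihood together with the diagonal of its negative Hessian
#' (the IRLS weights) and the working response
#' `z_i = eta_i + grad_i / w_i`.  One penalized weighted least-squares fit of
#' the working response reproduces a Newton step on the (diagonal
#' approximation of the) partial likelihood; this is the inner problem of the
#' coordinate-descent solver.
#'
#' Subjects carrying no information (censored before every event time) have
#' zero gradient and zero curvature; their weights are floored at
#' `weight_floor` so the working response stays finite.
#'
#' @inheritParams cox_partial_loglik
#' @param weight_floor Lower bound applied to the IRLS weights.
#' @return A list with numeric vectors `weights`, `working` and `gradient`,
#'   each in input subject order.
#' @export
cox_quadratic_approx <- function(eta, y, ties = c("breslow", "efron"),
                                 weight_floor = 1e-8) {
  ties <- match.arg(ties)
  y <- as_surv_outcome(y)
  eta <- as.numeric(eta)
  if (length(eta) != y$n) stop("'eta' and 'y' lengths differ")
  if (any(!is.finite(eta))) stop("non-finite values in linear predictor")
  s <- .cox_sorted(eta, y, ties)
  idx <- findInterval(s$t, s$uet)     # number of event times <= each subject's time

  if (ties == "breslow") {
    a <- s$D / s$S
    b <- s$D / s$S^2
    Ak <- c(0, cumsum(a))[idx + 1]
    Bk <- c(0, cumsum(b))[idx + 1]
  } else {
    e_idx <- rep(seq_along(s$D), s$D)
    l <- sequence(s$D) - 1
    den <- s$S[e_idx] - (l / s$D[e_idx]) * s$Q[e_idx]
    phi <- 1 - l / s$D[e_idx]
    a <- as.numeric(rowsum(1 / den, e_idx))
    b <- as.numeric(rowsum(1 / den^2, e_idx))
    at <- as.numeric(rowsum(phi / den, e_idx))
    bt <- as.numeric(rowsum(phi^2 / den^2, e_idx))
    Ak <- c(0, cumsum(a))[idx + 1]
    Bk <- c(0, cumsum(b))[idx + 1]
    # tied events see the Efron-deflated denominators at their own time
    own <- s$d == 1
    g_own <- match(s$t[own], s$uet)
    Ak[own] <- Ak[own] - a[g_own] + at[g_own]
    Bk[own] <- Bk[own] - b[g_own] + bt[g_own]
  }

  grad_s <- s$d - s$ee * Ak
  w_s <- pmax(s$ee * Ak - s$ee^2 * Bk, 0)
  flo <- w_s < weight_floor
  w_s[flo] <- weight_floor
  z_s <- eta[s$ord] + grad_s / w_s

  weights <- working <- gradient <- numeric(y$n)
  weights[s$ord] <- w_s
  working[s$ord] <- z_s
  gradient[s$ord] <- grad_s
  list(weights = weights, working = working, gradient = gradient)
}
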