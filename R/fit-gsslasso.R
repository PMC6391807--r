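# EM coordinate-descent fitting of the group spike-and-slab lasso Cox model.

#' Fit a group spike-and-slab lasso Cox model
#'
#' Estimates the posterior mode of a Cox proportional-hazards model whose
#' coefficients carry a group-structured spike-and-slab double-exponential
#' prior, by an EM algorithm with the latent slab indicators as missing data.
#' Each E-step computes the conditional inclusion probabilities
#' ([inclusion_prob]) and expected inverse prior scales
#' ([expected_inv_scale]); each M-step maximizes the penalized partial
#' likelihood by cyclic coordinate descent ([fit_weighted_l1_cox]) with the
#' expected inverse scales as L1 penalty factors, then updates the group slab
#' probabilities in closed form ([update_theta]).  Overlapping groups are
#' handled by replicating each predictor once per group it belongs to;
#' fitted replicate coefficients are summed back onto the original
#' predictors, which preserves the fitted linear predictor exactly.
#'
#' Convergence is declared when the relative deviance change
#' `|d(t) - d(t-1)| / (0.1 + |d(t)|)` falls below `eps`, with
#' `d(t) = -2 pl(beta(t))`.
#'
#' @param x Predictor matrix (samples x predictors), ideally with column
#'   names.
#' @param y A [surv_outcome] (or coercible).
#' @param groups A [group_structure], a plain list of index/name vectors
#'   (converted with a catch-all group for leftover predictors), or `NULL`
#'   for a single group containing every predictor.
#' @param s0,s1 Spike and slab scales, `0 < s0 <= s1`.  Setting `s0 = s1`
#'   makes the penalty factors constant at `1/s1` and the fit reduces
#'   exactly to a plain lasso Cox fit.
#' @param a,b Beta hyperparameters of the group probabilities (default 1, 1:
#'   uniform hyperprior).
#' @param prior Alternatively, a complete [ss_prior]; overrides
#'   `s0`/`s1`/`a`/`b`.
#' @param ties Tie handling for the partial likelihood.
#' @param eps Relative-deviance convergence tolerance (default `1e-5`).
#' @param max_iter Maximum EM iterations.
#' @param standardize Standardize the (expanded) predictor columns to mean 0,
#'   sd 1 (sample sd) before fitting; the prior then acts on a common scale.
#'   Returned coefficients are always mapped back to the input scale.
#' @param x_unpen Optional matrix of covariates exempt from the penalty
#'   (e.g. clinical variables); they bypass the spike-and-slab machinery
#'   entirely.
#' @param beta_init,theta_init Starting values for the expanded coefficients
#'   and group probabilities (defaults 0 and 0.5).
#' @param solver_tol,solver_max_iter,warn Passed to the inner M-step solver.
#'
#' @return An object of class `"gsslasso_fit"` with elements
#'   \describe{
#'     \item{beta}{collapsed coefficients on the original predictors (input
#'       scale)}
#'     \item{beta_unpen}{coefficients of the unpenalized covariates, if any}
#'     \item{beta_expanded}{coefficients on the standardized expanded design}
#'     \item{p, s_inv}{inclusion probabilities and expected inverse scales
#'       per expanded coefficient}
#'     \item{theta}{group slab probabilities}
#'     \item{eta}{fitted linear predictor on the training data}
#'     \item{deviance_trace, logpost_trace}{per-iteration deviance and
#'       (marginal) log-posterior diagnostics}
#'     \item{iterations, converged}{EM iteration count and convergence flag}
#'   }
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 10), 60)
#' colnames(x) <- paste0("x", 1:10)
#' eta <- x[, 1] - 0.8 * x[, 6]
#' y <- surv_outcome(rexp(60, exp(eta)), rbinom(60, 1, 0.7))
#' fit <- fit_gsslasso(x, y, groups = list(a = 1:5, b = 6:10), s0 = 0.05)
#' coef(fit)
#' @export
fit_gsslasso <- function(x, y, groups = NULL,
                         s0 = 0.02, s1 = 1, a = 1, b = 1,
                         prior = ss_prior(s0, s1, a, b),
                         ties = c("breslow", "efron"),
                         eps = 1e-5, max_iter = 200,
                         standardize = TRUE, x_unpen = NULL,
                         beta_init = NULL, theta_init = 0.5,
                         solver_tol = 1e-6, solver_max_iter = 50,
                         warn = TRUE) {
  ties <- match.arg(ties)
  y <- as_surv_outcome(y)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != y$n) stop("nrow(x) != number of subjects")
  m <- ncol(x)
  gs <- if (is.null(groups)) .default_groups(m)
        else if (inherits(groups, "group_structure")) groups
        else group_structure(groups, m = m, predictor_names = colnames(x))
  ed <- expand_overlap(x, gs)
  J <- ed$J
  G <- gs$G

  # standardization of the expanded design (constant columns left unscaled)
  if (standardize) {
    ctr <- colMeans(ed$x)
    scl <- apply(ed$x, 2, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    xs <- sweep(sweep(ed$x, 2, ctr), 2, scl, "/")
  } else {
    ctr <- numeric(J); scl <- rep(1, J)
    xs <- ed$x
  }
  q <- 0
  if (!is.null(x_unpen)) {
    x_unpen <- as.matrix(x_unpen)
    q <- ncol(x_unpen)
    xu <- if (standardize) scale(x_unpen) else x_unpen
    scl_u <- if (standardize) attr(xu, "scaled:scale") else rep(1, q)
    xs <- cbind(xs, xu)
  }
  pen_idx <- seq_len(J)

  beta <- if (is.null(beta_init)) numeric(J + q) else rep_len(as.numeric(beta_init), J + q)
  theta <- rep_len(as.numeric(theta_init), G)
  eta <- drop(xs %*% beta)
  dev <- cox_deviance(eta, y, ties)
  dev_trace <- dev
  lp_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  p <- rep(NA_real_, J); s_inv <- rep(NA_real_, J)
  while (it < max_iter) {
    it <- it + 1
    th <- pmin(pmax(theta, 1e-8), 1 - 1e-8)
    # E-step on the expanded, standardized coefficients
    p <- inclusion_prob(beta[pen_idx], th[ed$group], prior)
    s_inv <- expected_inv_scale(p, prior)
    pf <- c(s_inv, numeric(q))
    # M-step: penalized partial-likelihood maximization + closed-form theta
    mfit <- fit_weighted_l1_cox(xs, y, pf, beta_init = beta, ties = ties,
                                tol = solver_tol, max_iter = solver_max_iter,
                                warn = FALSE)
    beta <- mfit$beta
    theta <- update_theta(p, ed$group, prior, G = G)
    eta <- drop(xs %*% beta)
    dev_new <- cox_deviance(eta, y, ties)
    dev_trace <- c(dev_trace, dev_new)
    lp_trace <- c(lp_trace,
                  .log_marginal_posterior(beta[pen_idx], theta, ed$group, eta,
                                          y, prior, ties))
    if (abs(dev_new - dev) / (0.1 + abs(dev_new)) < eps) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged && warn)
    warning("EM did not converge in ", max_iter, " iterations")

  # back-transform to the input scale and collapse replicates
  beta_orig_exp <- beta[pen_idx] / scl
  beta_m <- collapse_coefficients(beta_orig_exp, ed)
  names(beta_m) <- colnames(x)
  beta_unpen <- if (q > 0) beta[J + seq_len(q)] / scl_u else NULL
  names(theta) <- names(gs$groups)

  structure(list(
    beta = beta_m, beta_unpen = beta_unpen, beta_expanded = beta,
    p = p, s_inv = s_inv, theta = theta,
    prior = prior, ties = ties,
    groups = gs, expanded = ed[c("orig", "group", "group_sizes", "J", "m")],
    center = ctr, scale = scl,
    eta = eta, deviance = dev, deviance_trace = dev_trace,
    logpost_trace = lp_trace,
    iterations = it, converged = converged,
    n = y$n, call = match.call()
  ), class = "gsslasso_fit")
}

# Marginal (indicator-integrated) log posterior: the quantity the EM
# algorithm ascends.  Used as the per-iteration diagnostic trace.
.log_marginal_posterior <- function(beta, theta, group, eta, y, prior, ties) {
  th <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
  thj <- th[group]
  mix <- (1 - thj) * de_density(beta, prior$s0) + thj * de_density(beta, prior$s1)
  cox_partial_loglik(eta, y, ties) + sum(log(mix)) +
    sum((prior$a - 1) * log(th) + (prior$b - 1) * log(1 - th))
}

#' Expected log joint posterior of a group spike-and-slab Cox state
#'
#' Evaluates the log joint posterior of `(beta, gamma, theta)` with the
#' latent indicators replaced by their conditional expectations `p`:
#' partial log-likelihood, minus the expected-inverse-scale L1 term, plus the
#' expected Bernoulli and beta-hyperprior terms.  At `beta = 0`,
#' `theta = 0.5`, `a = b = 1` this reduces to `pl(0) + J * log(0.5)`.
#'
#' @param beta Expanded coefficients.
#' @param p Inclusion probabilities per expanded coefficient.
#' @param theta Group probabilities (length `G`).
#' @param group Group index per expanded coefficient.
#' @param eta Linear predictor corresponding to `beta`.
#' @param y A [surv_outcome].
#' @param prior An [ss_prior].
#' @param ties Tie handling.
#' @return A single number (up to the additive constant dropped from the
#'   proportionality).
#' @export
log_joint_posterior <- function(beta, p, theta, group, eta, y, prior,
                                ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  th <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
  thj <- th[group]
  s_inv <- expected_inv_scale(p, prior)
  cox_partial_loglik(eta, y, ties) - sum(s_inv * abs(beta)) +
    sum(p * log(thj) + (1 - p) * log(1 - thj)) +
    sum((prior$a - 1) * log(th) + (prior$b - 1) * log(1 - th))
}

#' @export
print.gsslasso_fit <- function(x, ...) {
  cat("Group spike-and-slab lasso Cox fit\n")
  cat(sprintf("  s0 = %g, s1 = %g; %d predictors in %d group(s) (%d expanded)\n",
              x$prior$s0, x$prior$s1, x$expanded$m, x$groups$G, x$expanded$J))
  cat(sprintf("  %d EM iterations (%s); deviance %.3f\n", x$iterations,
              if (x$converged) "converged" else "not converged", x$deviance))
  cat(sprintf("  %d nonzero coefficient(s)\n", sum(x$beta != 0)))
  invisible(x)
}

#' @export
coef.gsslasso_fit <- function(object, ...) object$beta

#' Linear predictor for new data from a fitted model
#'
#' @param object A `gsslasso_fit`.
#' @param newx Matrix of predictors on the original (input) scale with the
#'   same columns as the training matrix.  Omitted: returns the training
#'   linear predictor.
#' @param newx_unpen Unpenalized covariates matching `x_unpen` at fit time.
#' @param ... Unused.
#' @return Numeric linear predictor (prognostic index), one value per row.
#'   An additive constant relative to the training parameterization is
#'   immaterial for the Cox model.
#' @export
predict.gsslasso_fit <- function(object, newx = NULL, newx_unpen = NULL, ...) {
  if (is.null(newx)) return(object$eta)
  eta <- drop(as.matrix(newx) %*% object$beta)
  if (!is.null(object$beta_unpen)) {
    if (is.null(newx_unpen)) stop("fit has unpenalized covariates; supply 'newx_unpen'")
    eta <- eta + drop(as.matrix(newx_unpen) %*% object$beta_unpen)
  }
  eta
}
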