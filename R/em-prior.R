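# E-step building blocks of the group spike-and-slab lasso prior: the
# double-exponential density, the conditional inclusion probability, the
# expected inverse prior scale, and the closed-form group-probability update.

#' Spike-and-slab prior specification
#'
#' The prior on each coefficient is a mixture of two double-exponential
#' (Laplace) distributions centred at zero: a sharply peaked spike with scale
#' `s0` and a diffuse slab with scale `s1` (`0 < s0 < s1`), switched by a
#' latent indicator whose group-specific probability `theta_g` carries a
#' `beta(a, b)` hyperprior (`a = b = 1` gives the uniform hyperprior).
#'
#' @param s0 Spike scale (strong shrinkage), `0 < s0 <= s1`.
#' @param s1 Slab scale (weak shrinkage); default 1.
#' @param a,b Beta hyperparameters for the group inclusion probabilities.
#' @return An object of class `"ss_prior"`.
#' @export
ss_prior <- function(s0 = 0.02, s1 = 1, a = 1, b = 1) {
  if (!is.numeric(s0) || s0 <= 0) stop("'s0' must be positive")
  if (!is.numeric(s1) || s1 <= 0) stop("'s1' must be positive")
  if (s0 > s1) stop("require s0 <= s1")
  if (a <= 0 || b <= 0) stop("'a' and 'b' must be positive")
  structure(list(s0 = s0, s1 = s1, a = a, b = b), class = "ss_prior")
}

#' @export
print.ss_prior <- function(x, ...) {
  cat(sprintf("Spike-and-slab double-exponential prior: s0 = %g, s1 = %g, beta(%g, %g) hyperprior\n",
              x$s0, x$s1, x$a, x$b))
  invisible(x)
}

#' Double-exponential density kernel
#'
#' `de(beta | 0, s) = (1/s) * exp(-|beta| / s)`, the form used throughout
#' the hierarchical model.  (Only ratios of this kernel enter the E-step,
#' so the constant normalization is immaterial there.)
#'
#' @param beta Numeric (vectorized).
#' @param scale Positive scale.
#' @return Density values.
#' @export
de_density <- function(beta, scale) {
  if (any(scale <= 0)) stop("'scale' must be positive")
  exp(-abs(beta) / scale) / scale
}

#' Conditional posterior inclusion probability
#'
#' The E-step expectation of the latent slab indicator for a coefficient in
#' group `g`:
#' `p = de(beta|s1) * theta / (de(beta|s0) * (1 - theta) + de(beta|s1) * theta)`.
#' Monotone nondecreasing in `|beta|`; degenerate `theta` values 0 and 1 map
#' to 0 and 1.  Computed on the log scale for numerical stability.
#'
#' @param beta Coefficient value(s).
#' @param theta Group slab probability in `[0, 1]` (recycled).
#' @param prior An [ss_prior].
#' @return Probabilities in `[0, 1]`.
#' @export
inclusion_prob <- function(beta, theta, prior) {
  stopifnot(inherits(prior, "ss_prior"))
  if (any(theta < 0 | theta > 1)) stop("'theta' must lie in [0, 1]")
  # log odds of slab vs spike membership
  l1 <- -abs(beta) / prior$s1 - log(prior$s1)
  l0 <- -abs(beta) / prior$s0 - log(prior$s0)
  p <- 1 / (1 + exp(log1p(-pmin(theta, 1)) - log(pmax(theta, 0)) + l0 - l1))
  p[theta == 0] <- 0
  p[theta == 1] <- 1
  p
}

#' Expected inverse prior scale
#'
#' E-step expectation of the inverse mixture scale,
#' `(1 - p)/s0 + p/s1`; used as the L1 penalty factor of the M-step.  Always
#' lies in `[1/s1, 1/s0]`.
#'
#' @param p Inclusion probabilities in `[0, 1]`.
#' @param prior An [ss_prior].
#' @return Expected inverse scales.
#' @export
expected_inv_scale <- function(p, prior) {
  stopifnot(inherits(prior, "ss_prior"))
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  (1 - p) / prior$s0 + p / prior$s1
}

#' Closed-form update of the group slab probabilities
#'
#' M-step maximizer of the expected log posterior in `theta_g`:
#' `theta_g = (sum_{j in g} p_j + a - 1) / (J_g + a + b - 2)`.
#' With the uniform hyperprior (`a = b = 1`) this is the within-group mean
#' of the inclusion probabilities.
#'
#' @param p Inclusion probabilities, one per expanded coefficient.
#' @param group Integer group index per expanded coefficient (each expanded
#'   coefficient belongs to exactly one group).
#' @param prior An [ss_prior] (supplies `a`, `b`).
#' @param G Number of groups (defaults to `max(group)`).
#' @return Numeric vector of `G` group probabilities, clipped to `[0, 1]`.
#' @export
update_theta <- function(p, group, prior, G = max(group)) {
  stopifnot(inherits(prior, "ss_prior"))
  Jg <- tabulate(group, nbins = G)
  denom <- Jg + prior$a + prior$b - 2
  if (any(denom <= 0))
    stop("J_g + a + b - 2 must be positive for every group")
  num <- as.numeric(rowsum(p, factor(group, levels = seq_len(G)))) + prior$a - 1
  pmin(pmax(num / denom, 0), 1)
}
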