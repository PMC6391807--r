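# Synthetic survival-data engine: block-correlated Gaussian predictors,
# six benchmark group layouts (non-overlapping, overlapping, varying group
# size / number of non-null groups / within-group correlation, and a
# varying-effect design), with exponential survival and censoring times.

.effect_values <- c(0.8, -0.7, 1.0, -0.9, -0.8, 0.9, -1.0, 0.7)

# Disjoint 20 x 50 partition used as the correlation-block structure in all
# scenarios (overlap affects group membership for the prior, not Sigma).
.corr_blocks <- function(m = 1000, n_blocks = 20) {
  split(seq_len(m), rep(seq_len(n_blocks), each = m / n_blocks))
}

#' Benchmark group layouts
#'
#' Returns the [group_structure] of a simulation scenario over `m = 1000`
#' predictors.  Scenario 1 uses 20 disjoint groups of 50.  Scenarios 2, 4,
#' 5 and 6 use the overlapping layout in which consecutive groups share five
#' predictors (`x1-x50`, `x46-x100`, ..., `x896-x950`) and the last group
#' (`x951-x1000`) stands alone.  Scenario 3 shrinks groups 1 and 11 to the
#' chosen size (4, 20 or 50 members) with the neighbouring groups adjusted
#' as printed in the benchmark design.
#'
#' @param scenario Integer 1-6.
#' @param variant Scenario 3 group size (4, 20 or 50); ignored elsewhere.
#' @return A [group_structure] with 20 groups.
#' @export
scenario_groups <- function(scenario, variant = NULL) {
  stopifnot(scenario %in% 1:6)
  s2 <- c(list(1:50),
          lapply(2:19, function(k) (50 * (k - 1) - 4):(50 * k)),
          list(951:1000))
  g <- if (scenario == 1) .corr_blocks() else s2
  if (scenario == 3) {
    size <- if (is.null(variant)) 50 else as.integer(variant)
    if (!size %in% c(4L, 20L, 50L)) stop("scenario 3 group size must be 4, 20 or 50")
    g[[1]] <- 1:size
    g[[2]] <- (if (size == 50L) 46L else size + 1L):100L
    g[[11]] <- 501:(500L + size)
    g[[12]] <- (if (size == 50L) 546L else 500L + size + 1L):600L
  }
  names(g) <- paste0("g", seq_along(g))
  group_structure(g, m = 1000, catch_all = FALSE)
}

# Nonzero predictor indices (1-based) per scenario/variant.
.scenario_signal_idx <- function(scenario, variant = NULL) {
  if (scenario %in% c(1, 2, 5, 6)) return(c(5, 20, 40, 210, 220, 240, 975, 995))
  if (scenario == 3) return(c(1:4, 501:504))
  if (scenario == 4) {
    v <- if (is.null(variant)) 8 else as.integer(variant)
    return(switch(as.character(v),
                  "8" = c(5, 55, 305, 355, 505, 555, 905, 955),
                  "3" = c(5, 15, 25, 355, 365, 375, 905, 915),
                  "1" = c(5, 10, 15, 20, 25, 30, 35, 40),
                  stop("scenario 4 variant must be 8, 3 or 1 non-null groups")))
  }
  stop("unknown scenario: ", scenario)
}

#' Simulation scenario specification
#'
#' Assembles everything a replicate needs: sample size, predictor count,
#' group layout, correlation-block structure, within-block correlation, and
#' the true coefficient vector (eight nonzero effects
#' `0.8 -0.7 1.0 -0.9 -0.8 0.9 -1.0 0.7` placed per scenario).
#'
#' @param scenario Integer 1-6.
#' @param n Subjects per data set (default 500).
#' @param m Number of predictors (default 1000; the benchmark layouts
#'   require 1000).
#' @param r Within-block correlation (default 0.5; scenario 5 varies it over
#'   0, 0.5, 0.7).
#' @param variant Scenario 3: group size (4/20/50); scenario 4: number of
#'   non-null groups (8/3/1).
#' @param beta5 Scenario 6 only: the varying effect assigned to `x5`
#'   (swept over `(-2, 2)`).
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario, n = 500, m = 1000, r = 0.5,
                          variant = NULL, beta5 = NULL) {
  stopifnot(scenario %in% 1:6)
  if (m != 1000) stop("the benchmark layouts are defined for m = 1000")
  if (r < 0 || r >= 1) stop("'r' must lie in [0, 1)")
  idx <- .scenario_signal_idx(scenario, variant)
  eff <- .effect_values
  if (scenario == 6) {
    if (is.null(beta5)) stop("scenario 6 requires 'beta5'")
    if (abs(beta5) > 2) stop("scenario 6 sweeps beta5 over (-2, 2)")
    eff[1] <- beta5
  }
  beta <- numeric(m)
  beta[idx] <- eff
  structure(list(scenario = scenario, n = n, m = m, r = r, variant = variant,
                 beta5 = beta5, signal_idx = idx, effects = eff,
                 beta = beta,
                 groups = scenario_groups(scenario, variant),
                 blocks = .corr_blocks(m)),
            class = "scenario_spec")
}

#' Block covariance matrix
#'
#' Dense covariance with unit diagonal, correlation `r` inside each
#' (disjoint) block and zero across blocks.  Positive definite for
#' `r` in `[0, 1)`.  The simulator itself samples block-by-block and never
#' materializes this matrix; it is exposed for inspection and testing.
#'
#' @param m Number of predictors.
#' @param gs A [group_structure] with non-overlapping groups covering
#'   `1..m`, or a plain list of disjoint index vectors.
#' @param r Within-block correlation in `[0, 1)`.
#' @return An `m` x `m` covariance matrix.
#' @export
make_block_covariance <- function(m, gs, r) {
  if (r < 0 || r >= 1) stop("'r' must lie in [0, 1)")
  blocks <- if (inherits(gs, "group_structure")) gs$groups else gs
  idx <- unlist(blocks)
  if (anyDuplicated(idx))
    stop("correlation blocks must be disjoint")
  sigma <- diag(m)
  for (b in blocks) sigma[b, b] <- (1 - r) * diag(length(b)) + r
  sigma
}

#' Sample block-correlated Gaussian predictors
#'
#' Draws `n` rows of zero-mean unit-variance Gaussian predictors with
#' correlation `r` within each block and independence across blocks,
#' sampling block-by-block through the Cholesky factor of the
#' equicorrelation matrix.
#'
#' @param n Number of samples.
#' @param blocks List of disjoint predictor index vectors.
#' @param r Within-block correlation in `[0, 1)`.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return An `n` x `m` matrix with columns named `x1..xm`.
#' @export
simulate_predictors <- function(n, blocks, r, seed = NULL) {
  if (r < 0 || r >= 1) stop("'r' must lie in [0, 1)")
  m <- length(unlist(blocks))
  with_seed(seed, {
    x <- matrix(rnorm(n * m), n, m)
    if (r > 0) {
      chol_cache <- list()
      for (b in blocks) {
        key <- as.character(length(b))
        if (is.null(chol_cache[[key]]))
          chol_cache[[key]] <- chol((1 - r) * diag(length(b)) + r)
        x[, b] <- x[, b, drop = FALSE] %*% chol_cache[[key]]
      }
    }
    colnames(x) <- paste0("x", seq_len(m))
    x
  })
}

#' Simulate exponential survival and censoring times
#'
#' True survival times are exponential with rate `exp(X beta)`; censoring
#' times are exponential with rate `exp(r_i)` where `r_i` is standard
#' normal.  The observed time is the minimum and the event indicator is 1
#' iff the censoring time exceeds the true survival time.  At `beta = 0`
#' the expected censoring fraction is exactly 1/2 by symmetry of `r_i`.
#'
#' @param x Predictor matrix.
#' @param beta True coefficient vector.
#' @param seed Optional seed.
#' @return A list with `y` (a [surv_outcome]), `T_true`, `C`, and
#'   `censor_frac`.
#' @export
simulate_survival <- function(x, beta, seed = NULL) {
  n <- nrow(x)
  eta <- drop(as.matrix(x) %*% beta)
  with_seed(seed, {
    T_true <- rexp(n, rate = exp(eta))
    ri <- rnorm(n)
    C <- rexp(n, rate = exp(ri))
    t <- pmin(T_true, C)
    d <- as.numeric(C > T_true)
    list(y = surv_outcome(t, d), T_true = T_true, C = C,
         censor_frac = mean(d == 0))
  })
}

.simulate_one <- function(spec, seed) {
  with_seed(seed, {
    x <- simulate_predictors(spec$n, spec$blocks, spec$r)
    sv <- simulate_survival(x, spec$beta)
    structure(list(x = x, y = sv$y, beta_true = spec$beta,
                   T_true = sv$T_true, C = sv$C,
                   censor_frac = sv$censor_frac,
                   groups = spec$groups, spec = spec, seed = seed),
              class = "gsscox_sim")
  })
}

#' @export
print.gsscox_sim <- function(x, ...) {
  cat(sprintf("Simulated dataset (scenario %d): n = %d, m = %d, r = %g, %.1f%% censored\n",
              x$spec$scenario, x$spec$n, x$spec$m, x$spec$r,
              100 * x$censor_frac))
  invisible(x)
}

#' Generate a training/test pair for a simulation scenario
#'
#' Draws two independent data sets from the same [scenario_spec]: the first
#' for model fitting, the second for evaluating predictive performance.
#' Sub-seeds for the two sets are derived deterministically from `seed`.
#'
#' @param spec A [scenario_spec] (or a scenario number, converted with
#'   defaults).
#' @param seed Replicate seed.
#' @return A list with elements `train` and `test`, each a `"gsscox_sim"`
#'   with fields `x`, `y`, `beta_true`, `T_true`, `C`, `censor_frac`,
#'   `groups`.
#' @export
generate_scenario <- function(spec, seed = 1) {
  if (is.numeric(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  sub <- with_seed(seed, sample.int(2147483646L, 2))
  list(train = .simulate_one(spec, sub[1]),
       test = .simulate_one(spec, sub[2]))
}
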