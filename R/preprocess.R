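# Expression-matrix preprocessing: the three-rule gene filter and predictor
# standardization.

#' Filter an expression matrix
#'
#' Applies three rules in order to a samples x genes expression matrix:
#' \enumerate{
#'   \item drop genes whose expression never (or, with `summary = "mean"`,
#'     on average does not) reach `min_expression`;
#'   \item drop genes with more than `max_zero_fraction` zero values;
#'   \item among the remaining genes, keep those whose coefficient of
#'     variation (sample sd / mean) exceeds the `cv_quantile` quantile of
#'     the remaining genes' CVs.
#' }
#' The low-expression rule is per-gene; the summary used ("max" by default)
#' is configurable because a per-value reading would not leave a rectangular
#' matrix.
#'
#' @param expr Nonnegative numeric matrix, samples in rows, named genes in
#'   columns.
#' @param min_expression Low-expression threshold (default 10).
#' @param max_zero_fraction Maximum tolerated fraction of zeros (default 0.30).
#' @param cv_quantile Quantile of the CV distribution below which genes are
#'   dropped (default 0.20; 0 disables the rule).
#' @param summary Per-gene summary compared against `min_expression`:
#'   `"max"` (default) or `"mean"`.
#' @return A list with `x` (filtered matrix), `kept` (retained column
#'   names), and `attrition` (genes removed by each rule, in order).
#' @export
filter_genes <- function(expr, min_expression = 10, max_zero_fraction = 0.30,
                         cv_quantile = 0.20, summary = c("max", "mean")) {
  summary <- match.arg(summary)
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression values must be nonnegative")
  if (is.null(colnames(expr))) colnames(expr) <- paste0("gene", seq_len(ncol(expr)))
  n0 <- ncol(expr)

  stat <- if (summary == "max") apply(expr, 2, max) else colMeans(expr)
  keep1 <- stat >= min_expression
  expr <- expr[, keep1, drop = FALSE]

  zfrac <- colMeans(expr == 0)
  keep2 <- zfrac <= max_zero_fraction
  expr <- expr[, keep2, drop = FALSE]

  if (ncol(expr) == 0)
    stop(sprintf("no genes left (low-expression removed %d, zero-fraction removed %d)",
                 sum(!keep1), sum(!keep2)))
  cv <- apply(expr, 2, sd) / colMeans(expr)
  keep3 <- cv > quantile(cv, cv_quantile)
  if (cv_quantile == 0) keep3 <- rep(TRUE, ncol(expr))
  out <- expr[, keep3, drop = FALSE]
  if (ncol(out) == 0)
    stop("no genes left after the CV rule")
  attrition <- c(low_expression = sum(!keep1), zero_fraction = sum(!keep2),
                 low_cv = sum(!keep3))
  list(x = out, kept = colnames(out), attrition = attrition, n_input = n0)
}

#' Standardize predictor columns
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator), returning the transform so fitted coefficients can
#' be mapped back.  Idempotent up to numerical tolerance.
#'
#' @param x Numeric matrix.
#' @return A list with `x` (standardized matrix), `center`, and `scale`.
#' @export
standardize_predictors <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  bad <- !is.finite(scl) | scl < 1e-12
  if (any(bad))
    stop("constant column(s): ",
         paste(if (is.null(colnames(x))) which(bad) else colnames(x)[bad],
               collapse = ", "))
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}
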