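# High-level entry points backing the command-line interface: each reads
# delimited inputs, runs one workflow, and writes plain-text outputs (TSV
# tables with a JSON metadata sidecar).

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_meta <- function(cfg, path, extra = list()) {
  meta <- c(list(config = cfg, config_fingerprint = config_fingerprint(cfg),
                 package = "gsscox",
                 version = as.character(utils::packageVersion("gsscox"))),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.load_inputs <- function(x_path, surv_path, groups_path = NULL,
                         catch_all = TRUE) {
  x <- read_predictors(x_path)
  y <- read_survival(surv_path)
  if (nrow(x) != y$n)
    stop("row count of ", x_path, " does not match ", surv_path)
  gs <- NULL
  if (!is.null(groups_path)) {
    gs <- read_gmt(groups_path, predictor_names = colnames(x),
                   m = ncol(x), catch_all = catch_all)
  } else {
    message("no groups file supplied; using a single catch-all group")
  }
  list(x = x, y = y, groups = gs)
}

#' Simulate a benchmark scenario to disk
#'
#' Generates a training/test pair from one of the six benchmark designs and
#' writes `X.tsv`, `survival.tsv`, `X_test.tsv`, `survival_test.tsv`,
#' `groups.gmt`, `truth.tsv` and `meta.json` into `out`.
#'
#' @param scenario Scenario number 1-6.
#' @param seed Replicate seed.
#' @param out Output directory (created if missing).
#' @param n,r,variant,beta5 Passed to [scenario_spec].
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(scenario, seed, out, n = 500, r = 0.5,
                         variant = NULL, beta5 = NULL) {
  spec <- scenario_spec(scenario, n = n, r = r, variant = variant, beta5 = beta5)
  sim <- generate_scenario(spec, seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "test")) {
    d <- sim[[part]]
    suffix <- if (part == "train") "" else "_test"
    .write_tsv(data.frame(sample = seq_len(nrow(d$x)), d$x, check.names = FALSE),
               file.path(out, paste0("X", suffix, ".tsv")))
    .write_tsv(data.frame(time = d$y$time, status = d$y$status),
               file.path(out, paste0("survival", suffix, ".tsv")))
  }
  write_gmt(spec$groups, file.path(out, "groups.gmt"),
            predictor_names = colnames(sim$train$x))
  .write_tsv(data.frame(predictor = colnames(sim$train$x), beta = spec$beta),
             file.path(out, "truth.tsv"))
  cfg <- list(command = "simulate", scenario = scenario, seed = seed, n = n,
              r = r, variant = variant, beta5 = beta5)
  .write_meta(cfg, file.path(out, "meta.json"),
              list(censor_frac_train = sim$train$censor_frac,
                   censor_frac_test = sim$test$censor_frac))
  invisible(out)
}

#' Fit a group spike-and-slab lasso Cox model from files
#'
#' Reads a predictor matrix, survival outcomes, and (optionally) GMT group
#' membership; fits [fit_gsslasso]; writes `coefficients.tsv` (one row per
#' expanded coefficient with the collapsed coefficient per predictor),
#' `theta.tsv` (group probabilities) and `fit.json` (convergence report and
#' config echo) into `out`.
#'
#' @param x_path,surv_path,groups_path Input files (TSV/CSV; GMT for groups).
#' @param out Output directory.
#' @param s0,s1,a,b,ties,eps,max_iter,standardize Model settings, passed to
#'   [fit_gsslasso].
#' @return The fitted model, invisibly.
#' @export
run_fit <- function(x_path, surv_path, groups_path = NULL, out,
                    s0 = 0.02, s1 = 1, a = 1, b = 1,
                    ties = "breslow", eps = 1e-5, max_iter = 200,
                    standardize = TRUE) {
  inp <- .load_inputs(x_path, surv_path, groups_path)
  fit <- fit_gsslasso(inp$x, inp$y, groups = inp$groups, s0 = s0, s1 = s1,
                      a = a, b = b, ties = ties, eps = eps,
                      max_iter = max_iter, standardize = standardize)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ed <- fit$expanded
  coefs <- data.frame(
    predictor = names(fit$beta)[ed$orig],
    group = names(fit$theta)[ed$group],
    beta_expanded = fit$beta_expanded[seq_len(ed$J)],
    p = fit$p,
    s_inv = fit$s_inv,
    beta = fit$beta[ed$orig])
  .write_tsv(coefs, file.path(out, "coefficients.tsv"))
  .write_tsv(data.frame(group = names(fit$theta), size = ed$group_sizes,
                        theta = fit$theta),
             file.path(out, "theta.tsv"))
  cfg <- list(command = "fit", x = x_path, surv = surv_path,
              groups = groups_path, s0 = s0, s1 = s1, a = a, b = b,
              ties = ties, eps = eps, max_iter = max_iter,
              standardize = standardize)
  .write_meta(cfg, file.path(out, "fit.json"),
              list(iterations = fit$iterations, converged = fit$converged,
                   deviance = fit$deviance,
                   deviance_trace = fit$deviance_trace,
                   nonzero = sum(fit$beta != 0)))
  invisible(fit)
}

#' Spike-scale path with cross-validated selection, from files
#'
#' Runs [fit_path] on file inputs and writes `path_cv.tsv` (one row per
#' `s0`: CVPL mean/sd, pre-validated C-index mean/sd, mean nonzero count)
#' and `path.json` (selected scale and config echo) into `out`.
#'
#' @inheritParams run_fit
#' @param s0_grid Spike-scale grid.
#' @param selection `"cvpl"` or `"cindex"`.
#' @param K,reps,seed Cross-validation settings.
#' @return The `gsslasso_path` object, invisibly.
#' @export
run_path_cv <- function(x_path, surv_path, groups_path = NULL, out,
                        s0_grid = seq(0.01, 0.09, by = 0.01), s1 = 1,
                        selection = "cvpl", K = 10, reps = 1, seed = 1,
                        ties = "breslow") {
  inp <- .load_inputs(x_path, surv_path, groups_path)
  path <- fit_path(inp$x, inp$y, groups = inp$groups, s1 = s1,
                   s0_grid = s0_grid, selection = selection,
                   K = K, reps = reps, seed = seed, ties = ties)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(path$cv, file.path(out, "path_cv.tsv"))
  cfg <- list(command = "path", x = x_path, surv = surv_path,
              groups = groups_path, s0_grid = s0_grid, s1 = s1,
              selection = selection, K = K, reps = reps, seed = seed,
              ties = ties)
  .write_meta(cfg, file.path(out, "path.json"),
              list(s0_opt = path$s0_opt,
                   nonzero_opt = sum(path$fit_opt$beta != 0)))
  invisible(path)
}

#' Cross-validated evaluation of a method, from files
#'
#' Pre-validates either the group spike-and-slab model (at fixed `s0`) or
#' the cross-validated lasso comparator, and writes `measures.tsv` with the
#' per-replicate and summary CVPL, C-index and nonzero counts.
#'
#' @inheritParams run_fit
#' @param method `"gsslasso"` or `"lasso"`.
#' @param K,reps,seed Cross-validation settings.
#' @return The `cv_result`, invisibly.
#' @export
run_evaluate <- function(x_path, surv_path, groups_path = NULL, out,
                         method = c("gsslasso", "lasso"),
                         s0 = 0.02, s1 = 1, K = 10, reps = 10, seed = 1,
                         ties = "breslow") {
  method <- match.arg(method)
  inp <- .load_inputs(x_path, surv_path, groups_path)
  fitter <- if (method == "gsslasso") {
    gsslasso_fitter(groups = inp$groups, s0 = s0, s1 = s1, ties = ties)
  } else {
    lasso_fitter(K = K, seed = seed)
  }
  cv <- prevalidate(fitter, inp$x, inp$y, K = K, reps = reps, seed = seed,
                    ties = ties)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(replicate = seq_len(reps), pl = cv$pl, cvpl = cv$cvpl,
                    cindex = cv$cindex, nonzero = cv$nonzero)
  tab <- rbind(tab, data.frame(replicate = NA, pl = mean(cv$pl),
                               cvpl = mean(cv$cvpl),
                               cindex = mean(cv$cindex),
                               nonzero = mean(cv$nonzero)))
  .write_tsv(tab, file.path(out, "measures.tsv"))
  cfg <- list(command = "evaluate", x = x_path, surv = surv_path,
              groups = groups_path, method = method, s0 = s0, s1 = s1,
              K = K, reps = reps, seed = seed, ties = ties)
  .write_meta(cfg, file.path(out, "measures.json"),
              list(pl_mean = mean(cv$pl), pl_sd = sd(cv$pl),
                   cvpl_mean = mean(cv$cvpl), cvpl_sd = sd(cv$cvpl),
                   cindex_mean = mean(cv$cindex), cindex_sd = sd(cv$cindex),
                   nonzero_mean = mean(cv$nonzero)))
  invisible(cv)
}
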